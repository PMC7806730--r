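test_that("best-eye selection prefers the higher valid fraction, ties to right", {
  left <- raw_gaze(1:10 / 500, rnorm(10), rnorm(10),
                   valid = c(rep(TRUE, 9), FALSE), eye = "left")
  right <- raw_gaze(1:10 / 500, rnorm(10), rnorm(10),
                    valid = c(rep(TRUE, 8), FALSE, FALSE), eye = "right")
  expect_identical(attr(select_best_eye(left, right), "eye"), "left")
  expect_identical(attr(select_best_eye(left, left), "eye"), "left")
  right2 <- left; attr(right2, "eye") <- "right"
  expect_identical(attr(select_best_eye(left, right2), "eye"), "right")
  expect_identical(attr(select_best_eye(left, NULL), "eye"), "left")
  expect_error(select_best_eye(NULL, NULL), "no data")
})

test_that("median prefilter removes isolated spikes and preserves ramps", {
  t <- (1:100) / 500
  const <- raw_gaze(t, rep(2, 100), rep(-1, 100))
  expect_equal(median_prefilter(const)$x, rep(2, 100))
  spiked <- raw_gaze(t, replace(rep(2, 100), 50, 500), rep(0, 100))
  expect_equal(median_prefilter(spiked)$x[50], 2)
  ramp <- raw_gaze(t, 3 * t, rep(0, 100))
  out <- median_prefilter(ramp)
  expect_equal(out$x[10:90], 3 * t[10:90], tolerance = 1e-12)
})

test_that("uniform resampling is exact for lines and flags long gaps", {
  set.seed(11)
  t <- cumsum(runif(600, 0.001, 0.003))
  ramp <- raw_gaze(t, 2 * t + 1, -t)
  sig <- resample_uniform(ramp)
  expect_equal(diff(sig$t), rep(1 / 500, nrow(sig) - 1), tolerance = 1e-12)
  expect_equal(sig$x, 2 * sig$t + 1, tolerance = 1e-9)
  # an already uniform 500 Hz stream is reproduced at its own knots
  tu <- (0:499) / 500
  su <- resample_uniform(raw_gaze(tu, sin(tu * 3), cos(tu * 3)))
  expect_equal(su$x, sin(su$t * 3), tolerance = 1e-9)
  # a 200 ms dropout exceeds the 75 ms bridgeable gap
  tg <- c(seq(0, 0.5, by = 0.002), seq(0.7, 1.2, by = 0.002))
  sg <- resample_uniform(raw_gaze(tg, tg, tg))
  gap_pts <- sg$t > 0.5 & sg$t < 0.7
  expect_true(all(!sg$valid[gap_pts]))
  expect_true(all(sg$valid[!gap_pts]))
  expect_error(resample_uniform(raw_gaze(0.1, 1, 1)), "valid")
})

test_that("zero-phase Butterworth: DC unity, 5 Hz intact, -6 dB at cutoff", {
  rate <- 500
  t <- (1:1000) / rate
  dc <- uniform_signal(rep(3.5, 1000))
  expect_equal(lowpass_zero_phase(dc)$x, rep(3.5, 1000), tolerance = 1e-5)
  s5 <- lowpass_zero_phase(uniform_signal(sin(2 * pi * 5 * t)))
  i <- 200:800
  expect_equal(max(abs(s5$x[i])), 1, tolerance = 0.01)
  # zero net phase: peak positions unshifted (< 0.5 ms resolution via ccf)
  cc <- ccf(s5$x[i], sin(2 * pi * 5 * t)[i], lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  s40 <- lowpass_zero_phase(uniform_signal(sin(2 * pi * 40 * t)))
  expect_equal(max(abs(s40$x[i])), 0.5, tolerance = 0.05 * 0.5)
})

test_that("noise-robust differentiator is exact on ramps and quieter than central differences", {
  rate <- 500
  d0 <- differentiate_nr(rep(4, 200), rate = rate)
  expect_equal(d0, rep(0, 200), tolerance = 1e-10)
  t <- (1:200) / rate
  d1 <- differentiate_nr(3 * t, rate = rate)
  expect_equal(d1[5:196], rep(3, 192), tolerance = 1e-9)
  set.seed(5)
  xn <- rnorm(1e5)
  dn <- differentiate_nr(xn, rate = rate)
  dc <- (xn[3:1e5] - xn[1:(1e5 - 2)]) / (2 / rate)
  expect_lt(sd(dn[10:99990]), sd(dc))
})

test_that("kinematic channels obey the vector-sum definition", {
  rate <- 500
  t <- (1:500) / rate
  sig <- kinematics(uniform_signal(3 * t, 4 * t))
  i <- 10:490
  expect_equal(sig$vx[i], rep(3, length(i)), tolerance = 1e-8)
  expect_equal(sig$vy[i], rep(4, length(i)), tolerance = 1e-8)
  expect_equal(sig$v[i], rep(5, length(i)), tolerance = 1e-8)
  expect_true(all(sig$v >= 0, na.rm = TRUE))
  expect_equal(sig$v, sqrt(sig$vx^2 + sig$vy^2))
  # pure horizontal motion: track velocity equals |vx|
  sh <- kinematics(uniform_signal(sin(t * 6), 0 * t))
  expect_equal(sh$v[i], abs(sh$vx[i]), tolerance = 1e-12)
})

test_that("full chain preserves a noiseless saccade's endpoints within 0.05 deg", {
  lay <- build_layout("C")
  nm <- noise_model(noise_sd_deg = 1e-9, bias_amplitude_deg = 0,
                    blink_rate_per_min = 0)
  tr <- simulate_trial(reader_profile(age = 10), lay, nm, seed = 3,
                       errorless = TRUE)
  sig <- preprocess_gaze(tr$stream)
  ev <- tr$truth$events
  sc <- ev[ev$type == "saccade", ][c(5, 20, 60), ]
  for (k in seq_len(nrow(sc))) {
    i0 <- which.min(abs(sig$t - (sc$onset[k] - 0.005)))
    i1 <- which.min(abs(sig$t - (sc$offset[k] + 0.005)))
    expect_lt(abs(sig$x[i0] - sc$x0[k]), 0.05)
    expect_lt(abs(sig$x[i1] - sc$x1[k]), 0.05)
    expect_lt(abs(sig$y[i1] - sc$y1[k]), 0.05)
  }
})

test_that("gaze streams round-trip through the text format", {
  g <- raw_gaze((1:50) / 500, rnorm(50), rnorm(50),
                valid = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 10))
  path <- tempfile(fileext = ".tsv")
  write_gaze(g, path, header = c("demo"))
  back <- read_gaze(path)
  expect_equal(back$t, g$t, tolerance = 1e-6)
  expect_equal(back$x, g$x, tolerance = 1e-4)
  expect_identical(back$valid, g$valid)
})
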