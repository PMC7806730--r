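test_that("noise thresholds: two passes agree on pure noise, floor applies", {
  set.seed(21)
  rate <- 500
  n <- 5000
  sig <- uniform_signal(cumsum(rnorm(n, 0, 0.002)), cumsum(rnorm(n, 0, 0.002)))
  sig <- kinematics(sig)
  m <- 3
  v <- abs(sig$v[is.finite(sig$v)])
  thr1 <- median(v) + m * median(abs(v - median(v)))
  noise <- v[v < thr1]
  thr2 <- median(noise) + m * median(abs(noise - median(noise)))
  expect_equal(thr2 / thr1, 1, tolerance = 0.10)
  thr <- estimate_noise_thresholds(sig)
  # degenerate-quiet traces hit the documented floor
  expect_gte(thr$velocity, 10)
  expect_lte(thr$velocity, 100)
  expect_gt(thr$acceleration, 0)
})

test_that("velocity threshold lands at a plausible scale on default fixation noise", {
  # stationary fixation with default measurement noise: the adaptive
  # threshold must stay in the tens of deg/s (the scale reported for this
  # detector family), and median track velocity well below 20 deg/s
  lay <- build_layout("C")
  tr <- simulate_trial(reader_profile(age = 10), lay, noise_model(), seed = 4,
                       errorless = TRUE)
  sig <- preprocess_gaze(tr$stream)
  thr <- estimate_noise_thresholds(sig)
  expect_gte(thr$velocity, 10)
  expect_lt(thr$velocity, 40)
  expect_lt(median(sig$v, na.rm = TRUE), 20)
})

test_that("detection recovers ground-truth saccades with high recall/precision", {
  fx <- errorless_c_trial()
  ts <- fx$trial$truth$events
  ts <- ts[ts$type == "saccade", ]
  sacc <- fx$saccades
  tol_s <- 0.020
  m <- vapply(seq_len(nrow(ts)), function(i) {
    d <- abs(sacc$onset - ts$onset[i])
    j <- which.min(d)
    if (d[j] < tol_s) j else NA_integer_
  }, 1L)
  big <- ts$amplitude >= 1
  recall <- mean(!is.na(m[big]))
  expect_gte(recall, 0.95)
  det_big <- which(sacc$amplitude >= 1)
  precision <- mean(vapply(det_big, function(j)
    min(abs(ts$onset - sacc$onset[j])) < tol_s, TRUE))
  expect_gte(precision, 0.95)
  matched <- which(big & !is.na(m))
  amp_err <- abs(sacc$amplitude[m[matched]] - ts$amplitude[matched])
  expect_lte(median(amp_err), 0.2)
  expect_lte(stats::quantile(amp_err, 0.95), 0.2)
  onset_err_ms <- abs(sacc$onset[m[matched]] - ts$onset[matched]) * 1000
  expect_lte(median(onset_err_ms), 10)
})

test_that("noise-only traces yield no saccades and micro-jitter fails verification", {
  set.seed(31)
  n <- 4000
  sig <- kinematics(uniform_signal(rnorm(n, 0, 0.03), rnorm(n, 0, 0.03)))
  expect_equal(nrow(detect_saccades(sig)), 0L)
  # square-wave jitter: velocity spikes but no net displacement
  sq <- rep(c(0, 0.08), each = 2, length.out = n)
  sig2 <- kinematics(uniform_signal(sq + rnorm(n, 0, 0.01), rnorm(n, 0, 0.01)))
  expect_equal(nrow(detect_saccades(sig2)), 0L)
})

test_that("main sequence emerges: peak velocity grows with amplitude", {
  fx <- errorless_c_trial()
  sacc <- fx$saccades
  expect_gt(cor(sacc$amplitude, sacc$peak_velocity, method = "spearman"), 0.9)
})

test_that("axis classification uses the strict 45-degree meridian rule", {
  expect_equal(classify_axis(cos(30 * pi / 180), sin(30 * pi / 180)), "horizontal")
  expect_equal(classify_axis(cos(60 * pi / 180), sin(60 * pi / 180)), "vertical")
  expect_equal(classify_axis(1, 1), "vertical")        # exactly 45 degrees
  expect_equal(classify_axis(-1, -1), "vertical")
  expect_equal(classify_axis(-1, 0.1), "horizontal")   # leftward near-meridian
  expect_equal(classify_axis(0, -1), "vertical")
  expect_error(classify_axis(0, 0), "zero displacement")
})

test_that("fixations tile every valid segment together with saccades", {
  fx <- errorless_c_trial()
  sig <- fx$signal
  segs <- oculodem:::.valid_segments(sig$valid)
  sacc <- fx$saccades
  fix <- fx$fixations
  for (i in seq_len(nrow(segs))) {
    t0 <- sig$t[segs[i, 1]]; t1 <- sig$t[segs[i, 2]]
    ss <- sacc[sacc$onset >= t0 & sacc$offset <= t1, ]
    ff <- fix[fix$start >= t0 & fix$end <= t1, ]
    expect_equal(sum(ss$offset - ss$onset) + sum(ff$end - ff$start),
                 t1 - t0, tolerance = 1e-9)
  }
})

test_that("long blink-bridging fixations are flagged as duration outliers", {
  # 50 fixations around 200 ms plus one of 1200 ms
  set.seed(41)
  rate <- 500
  durs <- c(rnorm(50, 0.2, 0.01), 1.2)
  gap <- 0.03
  onsets <- cumsum(c(0.2, durs[-length(durs)] + gap))
  t <- seq(0, max(onsets) + 1.5, by = 1 / rate)
  x <- numeric(length(t))
  pos <- 0
  for (k in seq_along(onsets)) {
    pos <- pos + 2
    x[t >= onsets[k] - gap] <- pos   # 2-deg step before each fixation
  }
  sacc <- data.frame(onset = onsets - gap, offset = onsets,
                     duration_ms = gap * 1000, dx = 2, dy = 0, amplitude = 2,
                     direction = 0, peak_velocity = 100, axis = "horizontal")
  sig <- uniform_signal(x)
  fix <- parse_fixations(sacc, sig)
  longest <- which.max(fix$duration_ms)
  expect_true(fix$outlier[longest])
  expect_gte(fix$duration_ms[longest], 1100)
  expect_lte(mean(fix$outlier), 3 / nrow(fix))
  # no saccades: the whole segment is one fixation
  f1 <- parse_fixations(sacc[0, ], uniform_signal(rep(1, 2500)))
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$duration_ms, 2499 / 500 * 1000, tolerance = 1e-6)
})
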