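test_that("row assignment labels on-centre fixations and leaves midway ones out", {
  lay <- build_layout("C")
  pos <- lay$positions
  row_y <- tapply(pos$y_deg, pos$row, mean)
  spacing <- mm_to_deg(14.6, 650)
  fix <- data.frame(start = 1:3, end = 2:4, duration_ms = 100,
                    cx = c(0, 0, 0),
                    cy = c(row_y[3], row_y[1] + 2 * spacing, row_y[7] + 0.2),
                    outlier = FALSE)
  out <- assign_rows(fix, lay)
  expect_equal(out$row[1], 3L)
  expect_true(is.na(out$row[2]))       # far above the top row: unlabeled
  expect_equal(out$row[3], 7L)
})

test_that("row sequence is non-decreasing for errorless reading", {
  fx <- errorless_c_trial()
  rows <- fx$fixations$row
  rows <- rows[!is.na(rows)]
  # drift can blur single labels; the labelled sequence must still be
  # monotone up to one row of slack
  expect_true(all(diff(rows) >= -1))
  expect_equal(min(rows), 1L)
  expect_equal(max(rows), 16L)
})

test_that("errorless C recording yields 16 identification epochs and 15 sweeps", {
  fx <- errorless_c_trial()
  ep <- fx$epochs
  expect_equal(sum(ep$kind == "identification"), 16L)
  expect_equal(sum(ep$kind == "return_sweep"), 15L)
  expect_true(all(ep$end > ep$start))
})

test_that("vertical subtests yield one sweep between two identification epochs", {
  for (st in c("A", "B")) {
    lay <- build_layout(st)
    tr <- simulate_trial(reader_profile(age = 9), lay, noise_model(), seed = 17)
    sig <- preprocess_gaze(tr$stream)
    sacc <- detect_saccades(sig)
    fix <- assign_rows(parse_fixations(sacc, sig), lay)
    ep <- segment_epochs(sacc, fix, lay)
    expect_equal(sum(ep$kind == "identification"), 2L)
    expect_equal(sum(ep$kind == "return_sweep"), 1L)
    expect_equal(ep$kind[2], "return_sweep")
  }
})

test_that("segmentation survives reading errors and multi-hop sweeps", {
  lay <- build_layout("C")
  for (seed in c(101, 202, 303, 404)) {
    tr <- simulate_trial(reader_profile(age = 8), lay, noise_model(), seed = seed)
    sig <- preprocess_gaze(tr$stream)
    sacc <- detect_saccades(sig)
    fix <- assign_rows(parse_fixations(sacc, sig), lay)
    ep <- segment_epochs(sacc, fix, lay)
    expect_equal(sum(ep$kind == "return_sweep"), 15L)
    expect_equal(sum(ep$kind == "identification"), 16L)
  }
})

test_that("a skipped row removes one identification epoch and one sweep", {
  lay <- build_layout("C")
  tr <- simulate_trial(reader_profile(age = 10), lay, noise_model(),
                       seed = 33, skip_lines = 7)
  sig <- preprocess_gaze(tr$stream)
  sacc <- detect_saccades(sig)
  fix <- assign_rows(parse_fixations(sacc, sig), lay)
  ep <- segment_epochs(sacc, fix, lay)
  expect_equal(sum(ep$kind == "identification"), 15L)
  expect_equal(sum(ep$kind == "return_sweep"), 14L)
})

test_that("epochs tile the trial and times are conserved", {
  fx <- errorless_c_trial()
  ep <- fx$epochs
  expect_equal(ep$start[-1], ep$end[-nrow(ep)], tolerance = 1e-12)
  met <- epoch_metrics(ep, fx$saccades, fx$fixations)
  pe <- met$per_epoch
  # fixation + saccade time never exceeds epoch duration, equality on
  # epochs with no invalid samples
  expect_true(all(pe$fixation_time + pe$saccade_time <=
                  pe$end - pe$start + 1e-9))
  # identification + sweep time = first-to-last-number interval
  expect_equal(sum(met$summary$total_time), max(ep$end) - min(ep$start),
               tolerance = 1e-9)
})

test_that("per-epoch metrics match the reading structure", {
  fx <- errorless_c_trial()
  met <- epoch_metrics(fx$epochs, fx$saccades, fx$fixations)
  s <- met$summary
  id <- s[s$kind == "identification", ]
  sw <- s[s$kind == "return_sweep", ]
  # errorless reader: no backwards saccades during identification
  expect_equal(id$backwards, 0L)
  # within-row steps are small, sweeps are large
  expect_gt(sw$median_sacc_amp, id$median_sacc_amp)
  # 4 within-row saccades per line, 1 hop per sweep
  expect_equal(id$n_saccades, 64L)
  expect_equal(sw$n_saccades, 15L)
  # reading spends far more time identifying than sweeping
  expect_gt(id$total_time, 3 * sw$total_time)
  expect_gt(id$fixation_time, id$saccade_time)
})

test_that("sweep splitting couples sweep saccade count to completion time", {
  ca <- cohort_analysis()
  m <- ca$analysis$measures
  expect_gt(pearson(m$sweep_n_saccades, m$raw_time_C)$r, 0)
  expect_gt(pearson(m$id_median_fix_ms, m$raw_time_C)$r, 0)
  expect_gt(pearson(m$n_saccades, m$raw_time_C)$r, 0)
})
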