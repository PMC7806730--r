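# Shared fixtures, built once per test run and memoized across test files.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default 36-subject cohort, fully analysed (the study's eye-tracked
# subsample size); reused by recovery, sign-structure and acceptance tests
cohort_analysis <- function() {
  memo("cohort36", {
    coh <- simulate_cohort(36, seed = 2026)
    list(cohort = coh, analysis = analyse_cohort(coh))
  })
}

# one errorless C trial with default noise, analysed end to end
errorless_c_trial <- function(seed = 42) {
  memo(paste0("errC", seed), {
    lay <- build_layout("C")
    tr <- simulate_trial(reader_profile(age = 10), lay, noise_model(),
                         seed = seed, errorless = TRUE)
    sig <- preprocess_gaze(tr$stream)
    sacc <- detect_saccades(sig)
    fix <- assign_rows(parse_fixations(sacc, sig), lay)
    ep <- segment_epochs(sacc, fix, lay)
    list(layout = lay, trial = tr, signal = sig, saccades = sacc,
         fixations = fix, epochs = ep)
  })
}

# uniform gaze_signal helper for filter tests
uniform_signal <- function(x, y = 0 * x, rate = 500) {
  t <- seq_along(x) / rate
  structure(data.frame(t = t, x = x, y = y, valid = TRUE),
            rate = rate, class = c("gaze_signal", "data.frame"))
}
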