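#' Reader profile for the synthetic gaze generator
#'
#' Describes one simulated child. The central parameter is the latent
#' visual processing speed \code{s}: the median identification fixation
#' duration in ms, decreasing with age on a log-linear trend. Skill-linked
#' behaviours (extra refixations, regressions, splitting return sweeps into
#' several hops) are driven by \code{s} so that slower readers produce more
#' and smaller eye movements, as observed in developing readers.
#'
#' @param age Age in years.
#' @param s Latent processing speed in ms; if NULL, drawn from the
#'   log-linear age trend \code{exp(log(s6) - age_slope (age - 6) + e)},
#'   e ~ N(0, s_sdlog).
#' @param s6 Median identification fixation duration at age 6 (default
#'   550 ms).
#' @param age_slope Log-linear decrease per year of age (default 0.055).
#' @param s_sdlog Between-subject lognormal sd of s (default 0.12).
#' @param fix_sdlog Within-subject lognormal spread of fixation durations
#'   (default 0.25).
#' @param refixation_rate Probability of an extra fixation on a number; if
#'   NULL, skill-linked: 0.08 + 0.25 plogis((s - 450)/80).
#' @param regression_prob Probability of a regressive saccade per number
#'   (default 0.03).
#' @param sweep_hop_prob Per-trial probability parameter of extra return
#'   sweep hops (hops = 1 + Binomial(2, p)); if NULL, skill-linked:
#'   plogis((s - 420)/90).
#' @param sweep_fix_median_ms Median duration of intermittent sweep
#'   fixations (default 250 ms).
#' @param main_seq_intercept_ms,main_seq_slope_ms_per_deg Saccade duration
#'   main-sequence parameters (defaults 21 ms and 2.2 ms/deg).
#' @param landing_sd_deg Saccade landing noise sd (default 0.25 deg).
#' @return A list of class \code{reader_profile}.
#' @export
reader_profile <- function(age = 10, s = NULL, s6 = 550, age_slope = 0.055,
                           s_sdlog = 0.12, fix_sdlog = 0.25,
                           refixation_rate = NULL, regression_prob = 0.03,
                           sweep_hop_prob = NULL, sweep_fix_median_ms = 250,
                           main_seq_intercept_ms = 21,
                           main_seq_slope_ms_per_deg = 2.2,
                           landing_sd_deg = 0.25) {
  if (is.null(s))
    s <- exp(log(s6) - age_slope * (age - 6) + stats::rnorm(1, 0, s_sdlog))
  if (is.null(refixation_rate))
    refixation_rate <- 0.08 + 0.25 * stats::plogis((s - 450) / 80)
  if (is.null(sweep_hop_prob))
    sweep_hop_prob <- stats::plogis((s - 420) / 90)
  structure(list(age = age, s = s, fix_sdlog = fix_sdlog,
                 refixation_rate = refixation_rate,
                 regression_prob = regression_prob,
                 sweep_hop_prob = sweep_hop_prob,
                 sweep_fix_median_ms = sweep_fix_median_ms,
                 main_seq_intercept_ms = main_seq_intercept_ms,
                 main_seq_slope_ms_per_deg = main_seq_slope_ms_per_deg,
                 landing_sd_deg = landing_sd_deg),
            class = "reader_profile")
}

#' Measurement noise model of the gaze tracker
#'
#' Emulates a remote video tracker whose two cameras run asynchronously:
#' two independent ~250 Hz sample clocks with timestamp jitter merge into
#' an irregular stream averaging ~500 Hz; white sample-to-sample noise
#' below 0.05 deg; a slow sinusoidal bias of up to ~0.7 deg emulating
#' calibration drift / limited spatial accuracy; blink dropouts.
#'
#' @param noise_sd_deg Sample-to-sample noise sd (default 0.03; must stay
#'   below 0.05).
#' @param bias_amplitude_deg Peak amplitude of the slow sinusoidal bias
#'   (default 0.7). Each axis gets an amplitude drawn uniformly up to this
#'   value with a random phase and a 20-40 s period.
#' @param blink_rate_per_min Blink rate (default 2).
#' @param blink_duration_ms_range Blink duration range (default c(100, 300)).
#' @param clock_rate_hz Per-camera nominal rate (default 250).
#' @param clock_jitter Relative sd of inter-sample intervals (default 0.1).
#' @return A list of class \code{noise_model}.
#' @export
noise_model <- function(noise_sd_deg = 0.03, bias_amplitude_deg = 0.7,
                        blink_rate_per_min = 2,
                        blink_duration_ms_range = c(100, 300),
                        clock_rate_hz = 250, clock_jitter = 0.1) {
  stopifnot(noise_sd_deg < 0.05)
  structure(as.list(environment()), class = "noise_model")
}

## raised-cosine saccade displacement profile: fraction of the total
## displacement completed at phase u in [0, 1]
.rc_disp <- function(u) u - sin(2 * pi * u) / (2 * pi)

## append a fixation / saccade to the scanpath under construction
.sp_env <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- character(0); e$t0 <- e$t1 <- numeric(0)
  e$x0 <- e$y0 <- e$x1 <- e$y1 <- numeric(0)
  e$target <- integer(0); e$phase <- character(0)
  e$t <- 0
  e
}
.sp_fix <- function(e, dur_s, x, y, target = NA_integer_, phase = "identification") {
  i <- length(e$type) + 1L
  e$type[i] <- "fixation"; e$t0[i] <- e$t; e$t1[i] <- e$t + dur_s
  e$x0[i] <- e$x1[i] <- x; e$y0[i] <- e$y1[i] <- y
  e$target[i] <- target; e$phase[i] <- phase
  e$t <- e$t + dur_s
}
.sp_sacc <- function(e, profile, x1, y1, phase = "identification") {
  i <- length(e$type) + 1L
  x0 <- e$x1[i - 1L]; y0 <- e$y1[i - 1L]
  amp <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  dur_s <- (profile$main_seq_intercept_ms +
            profile$main_seq_slope_ms_per_deg * amp) / 1000
  e$type[i] <- "saccade"; e$t0[i] <- e$t; e$t1[i] <- e$t + dur_s
  e$x0[i] <- x0; e$y0[i] <- y0; e$x1[i] <- x1; e$y1[i] <- y1
  e$target[i] <- NA_integer_; e$phase[i] <- phase
  e$t <- e$t + dur_s
}

.rlnorm_med <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' Simulate one DEM trial with full ground truth
#'
#' Generates a scanpath that visits the layout's numbers in reading order,
#' with optional refixations, regressions and multi-hop return sweeps
#' (children often split the sweep into a large undershooting saccade plus
#' corrective hops rather than one swift saccade). Saccades follow a
#' duration main sequence with raised-cosine velocity profiles; fixation
#' durations are lognormal with median equal to the reader's latent speed
#' s. Measurement noise, slow bias, blink dropouts and asynchronous
#' two-camera sampling are applied last. Identical seeds give identical
#' output.
#'
#' @param profile A \code{reader_profile}.
#' @param layout A \code{dem_layout}.
#' @param noise A \code{noise_model}.
#' @param seed Integer seed.
#' @param errorless If TRUE, refixations, regressions and extra sweep hops
#'   are disabled (single-saccade sweeps, strict reading order).
#' @param skip_lines Integer vector of line (C) or column-slot indices the
#'   reader skips entirely, emulating a row-skip reading error.
#' @return List with \code{stream} (a \code{raw_gaze}) and \code{truth}: the
#'   true event table, epoch boundaries, subtest time and latent s.
#' @export
simulate_trial <- function(profile, layout, noise = noise_model(),
                           seed = 1L, errorless = FALSE,
                           skip_lines = integer(0)) {
  set.seed(seed)
  pos <- layout$positions
  e <- .sp_env()
  s_ms <- profile$s
  land <- function(x, y) {
    if (errorless) c(x, y)
    else c(x + stats::rnorm(1, 0, profile$landing_sd_deg),
           y + stats::rnorm(1, 0, profile$landing_sd_deg))
  }
  fixdur <- function() .rlnorm_med(1, s_ms, profile$fix_sdlog) / 1000
  sweepdur <- function() .rlnorm_med(1, profile$sweep_fix_median_ms,
                                     profile$fix_sdlog) / 1000

  if (layout$subtest == "C") {
    lines <- split(pos, pos$row)
  } else {
    lines <- split(pos, pos$col)
  }
  if (length(skip_lines)) lines <- lines[-skip_lines]
  line_arrival_fix <- integer(length(lines))   # index of arrival fixation
  sweep_onset_idx <- integer(0)

  for (ln in seq_along(lines)) {
    lp <- lines[[ln]]
    for (j in seq_len(nrow(lp))) {
      tgt <- lp$index[j]
      if (j == 1L) {
        ## the arrival fixation of every line after the first is emitted by
        ## the return-sweep block below; line 1 starts on the first number
        if (ln == 1L) {
          xy <- c(lp$x_deg[j], lp$y_deg[j])
          .sp_fix(e, fixdur(), xy[1], xy[2], tgt)
          line_arrival_fix[ln] <- length(e$type)
        }
      } else {
        xy <- land(lp$x_deg[j], lp$y_deg[j])
        .sp_sacc(e, profile, xy[1], xy[2])
        .sp_fix(e, fixdur(), xy[1], xy[2], tgt)
      }
      if (!errorless && stats::runif(1) < profile$refixation_rate) {
        xy2 <- land(lp$x_deg[j] + 0.15, lp$y_deg[j])
        .sp_sacc(e, profile, xy2[1], xy2[2])
        .sp_fix(e, fixdur(), xy2[1], xy2[2], tgt)
      }
      if (!errorless && j > 1L && stats::runif(1) < profile$regression_prob) {
        xyb <- land(lp$x_deg[j - 1L], lp$y_deg[j - 1L])
        .sp_sacc(e, profile, xyb[1], xyb[2])
        .sp_fix(e, 0.6 * fixdur(), xyb[1], xyb[2], lp$index[j - 1L])
        xyf <- land(lp$x_deg[j], lp$y_deg[j])
        .sp_sacc(e, profile, xyf[1], xyf[2])
        .sp_fix(e, fixdur(), xyf[1], xyf[2], tgt)
      }
    }
    if (ln < length(lines)) {
      ## return sweep to the first number of the next line
      np <- lines[[ln + 1L]][1L, ]
      hops <- if (errorless) 1L else
        1L + stats::rbinom(1, 2, profile$sweep_hop_prob)
      cur <- c(e$x1[length(e$type)], e$y1[length(e$type)])
      tgt_xy <- c(np$x_deg, np$y_deg)
      sweep_onset_idx <- c(sweep_onset_idx, length(e$type) + 1L)
      for (h in seq_len(hops)) {
        if (h == hops) {
          xy <- land(tgt_xy[1], tgt_xy[2])
        } else {
          frac <- stats::runif(1, 0.65, 0.85)
          xy <- land(cur[1] + frac * (tgt_xy[1] - cur[1]),
                     cur[2] + frac * (tgt_xy[2] - cur[2]))
        }
        .sp_sacc(e, profile, xy[1], xy[2], phase = "return_sweep")
        if (h < hops) .sp_fix(e, sweepdur(), xy[1], xy[2],
                              phase = "return_sweep")
        cur <- xy
      }
      .sp_fix(e, fixdur(), cur[1], cur[2], np$index)
      line_arrival_fix[ln + 1L] <- length(e$type)
    }
  }

  truth_events <- data.frame(type = e$type, onset = e$t0, offset = e$t1,
                             x0 = e$x0, y0 = e$y0, x1 = e$x1, y1 = e$y1,
                             target = e$target, phase = e$phase)
  truth_events$amplitude <- ifelse(truth_events$type == "saccade",
                                   sqrt((e$x1 - e$x0)^2 + (e$y1 - e$y0)^2), NA)
  subtest_time <- e$t1[length(e$type)] - e$t0[1L]
  epoch_bounds <- data.frame(
    line = seq_along(lines),
    arrival = e$t0[line_arrival_fix],
    sweep_onset = c(e$t0[sweep_onset_idx], NA))

  ## ---- continuous gaze evaluation on the merged two-camera clock ----
  total_t <- e$t1[length(e$type)]
  mk_clock <- function() {
    n <- ceiling(total_t * noise$clock_rate_hz * 1.3) + 10L
    dt <- pmax(1e-4, (1 / noise$clock_rate_hz) *
                 (1 + stats::rnorm(n, 0, noise$clock_jitter)))
    ts <- stats::runif(1, 0, 1 / noise$clock_rate_hz) + cumsum(dt)
    ts[ts < total_t]
  }
  tt <- sort(c(mk_clock(), mk_clock()))
  tt <- tt[!duplicated(tt)]
  seg <- findInterval(tt, e$t0, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  u <- (tt - e$t0[seg]) / pmax(e$t1[seg] - e$t0[seg], 1e-12)
  u <- pmin(pmax(u, 0), 1)
  frac <- ifelse(e$type[seg] == "saccade", .rc_disp(u), 0)
  gx <- e$x0[seg] + frac * (e$x1[seg] - e$x0[seg])
  gy <- e$y0[seg] + frac * (e$y1[seg] - e$y0[seg])

  ## measurement imperfections
  per <- stats::runif(2, 20, 40)
  phs <- stats::runif(2, 0, 2 * pi)
  ampl <- stats::runif(2, 0, noise$bias_amplitude_deg)
  gx <- gx + ampl[1] * sin(2 * pi * tt / per[1] + phs[1]) +
    stats::rnorm(length(tt), 0, noise$noise_sd_deg)
  gy <- gy + ampl[2] * sin(2 * pi * tt / per[2] + phs[2]) +
    stats::rnorm(length(tt), 0, noise$noise_sd_deg)

  valid <- rep(TRUE, length(tt))
  n_blinks <- stats::rpois(1, noise$blink_rate_per_min * total_t / 60)
  if (n_blinks > 0) {
    b0 <- stats::runif(n_blinks, 0, total_t)
    bd <- stats::runif(n_blinks, noise$blink_duration_ms_range[1],
                       noise$blink_duration_ms_range[2]) / 1000
    for (k in seq_len(n_blinks)) valid[tt >= b0[k] & tt <= b0[k] + bd[k]] <- FALSE
  }

  stream <- raw_gaze(tt, gx, gy, valid, eye = "right")
  truth <- list(events = truth_events, epoch_bounds = epoch_bounds,
                subtest_time = subtest_time, s = profile$s,
                bias_amplitude = ampl)
  list(stream = stream, truth = truth)
}

#' Simulate a cohort of readers with coupled reaction times
#'
#' Draws n subjects with ages around the eye-tracked subsample of a school
#' cohort (mean 10.2, sd 1.4 years, truncated to 7-12.5), latent speed s on
#' a negative age trend, gaze recordings for subtests A, B and C, and
#' reaction-time tables for the speed-acuity (SA), visual-detection and
#' auditory-detection tasks in which the subject mean RT is positively
#' coupled to s. Naming errors (omissions/additions) are drawn sparsely to
#' mirror the low error counts of healthy readers.
#'
#' @param n_subjects Number of subjects (default 36).
#' @param seed Integer seed.
#' @param layout_seed Seed of the shared C layout gap scheme.
#' @param gamma_sa Coupling of SA mean RT (s) to latent s (ms); default
#'   1.2e-3 s per ms.
#' @param rt_noise_sd Between-subject RT noise sd (default 0.04 s).
#' @param rt_trial_sd Within-subject trial RT sd (default 0.08 s).
#' @param n_trials_rt Trials per RT task (default 10).
#' @param noise A \code{noise_model}.
#' @param subtests Character vector of subtests to simulate (default
#'   c("A", "B", "C")).
#' @param age_mean,age_sd,age_range Age distribution parameters.
#' @return List of class \code{dem_cohort}: per-subject list with
#'   \code{profile}, \code{trials} (named by subtest: stream + truth) and a
#'   cohort-level \code{rt} trial table, plus \code{layouts}.
#' @export
simulate_cohort <- function(n_subjects = 36, seed = 1L, layout_seed = 1L,
                            gamma_sa = 1.2e-3, rt_noise_sd = 0.04,
                            rt_trial_sd = 0.08, n_trials_rt = 10L,
                            noise = noise_model(),
                            subtests = c("A", "B", "C"),
                            age_mean = 10.2, age_sd = 1.4,
                            age_range = c(7, 12.5)) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  set.seed(seed)
  ages <- stats::rnorm(n_subjects, age_mean, age_sd)
  ages <- pmin(pmax(ages, age_range[1]), age_range[2])
  subj_seeds <- sample.int(2^30, n_subjects * (length(subtests) + 1L))
  layouts <- lapply(stats::setNames(subtests, subtests), function(st)
    build_layout(st, gap_seed = layout_seed))

  subjects <- vector("list", n_subjects)
  rt_rows <- list()
  for (i in seq_len(n_subjects)) {
    prof <- reader_profile(age = ages[i])
    trials <- lapply(stats::setNames(subtests, subtests), function(st) {
      k <- match(st, subtests)
      simulate_trial(prof, layouts[[st]], noise,
                     seed = subj_seeds[(i - 1L) * (length(subtests) + 1L) + k])
    })
    set.seed(subj_seeds[i * (length(subtests) + 1L)])
    base_sa <- 0.15 + gamma_sa * prof$s + stats::rnorm(1, 0, rt_noise_sd)
    base_vis <- 0.18 + 0.6 * gamma_sa * prof$s + stats::rnorm(1, 0, rt_noise_sd)
    base_aud <- 0.16 + 0.55 * gamma_sa * prof$s + stats::rnorm(1, 0, rt_noise_sd)
    mk <- function(task, base) data.frame(
      subject = i, task = task, size = if (task == "speed-acuity") "0.68" else "",
      rt = pmax(0.12, base + stats::rnorm(n_trials_rt, 0, rt_trial_sd)))
    rt_rows[[i]] <- rbind(mk("speed-acuity", base_sa),
                          mk("visual-detection", base_vis),
                          mk("auditory-detection", base_aud))
    omissions <- stats::rpois(1, 0.4)
    additions <- stats::rpois(1, 0.15)
    subjects[[i]] <- list(id = i, profile = prof, trials = trials,
                          omissions = omissions, additions = additions)
  }
  structure(list(subjects = subjects, rt = do.call(rbind, rt_rows),
                 layouts = layouts, seed = seed),
            class = "dem_cohort")
}
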