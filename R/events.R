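#' Saccade detection configuration
#'
#' @param threshold_multiplier Multiplier on the MAD of the noise for both
#'   the velocity and the acceleration threshold (default 3).
#' @param verify_window_ms Length of the pre-onset / post-offset position
#'   windows used to verify that gaze actually moved (default 20 ms).
#' @param min_duration_ms Minimum saccade duration (default 6 ms).
#' @param merge_gap_ms Saccades separated by less than this are merged
#'   (default 20 ms).
#' @param fixation_outlier_multiplier Multiplier on the MAD of fixation
#'   durations beyond which a fixation is flagged as an outlier, e.g. a
#'   blink-bridging interval (default 3).
#' @param velocity_floor,velocity_ceiling Bounds applied to the adaptive
#'   velocity threshold, deg/s (defaults 10 and 100).
#' @param max_invalid_fraction Recordings with a larger fraction of invalid
#'   samples are flagged as lost-signal (default 0.10).
#' @return A list of class \code{detection_config}.
#' @export
detection_config <- function(threshold_multiplier = 3,
                             verify_window_ms = 20,
                             min_duration_ms = 6,
                             merge_gap_ms = 20,
                             fixation_outlier_multiplier = 3,
                             velocity_floor = 10,
                             velocity_ceiling = 100,
                             max_invalid_fraction = 0.10) {
  structure(as.list(environment()), class = "detection_config")
}

## unscaled median absolute deviation from the median
.mad_raw <- function(x) {
  x <- x[is.finite(x)]
  stats::median(abs(x - stats::median(x)))
}

#' Adaptive noise thresholds for saccade detection
#'
#' Two-pass estimate on the |velocity| (and |acceleration|) series. Each
#' pass places the threshold 3 x MAD above the median (track velocity noise
#' is non-negative and skewed, so the deviation is anchored at the median,
#' exactly as in the fixation-duration outlier rule): pass one over the
#' full series gives a provisional threshold, pass two recomputes median
#' and MAD over the samples below it (the noise samples). The MAD is
#' unscaled (no normal consistency factor). The velocity threshold is
#' clamped to \[velocity_floor, velocity_ceiling\].
#'
#' @param sig A \code{gaze_signal} with kinematic channels.
#' @param config A \code{detection_config}.
#' @return List with \code{velocity} (deg/s) and \code{acceleration}
#'   (deg/s^2) thresholds.
#' @export
estimate_noise_thresholds <- function(sig, config = detection_config()) {
  m <- config$threshold_multiplier
  one <- function(series) {
    s <- abs(series[sig$valid & is.finite(series)])
    thr1 <- stats::median(s) + m * .mad_raw(s)
    noise <- s[s < thr1]
    if (length(noise) < 500L) {
      warning("fewer than 500 noise samples; single-pass MAD threshold used")
      return(thr1)
    }
    stats::median(noise) + m * .mad_raw(noise)
  }
  vthr <- one(sig$v)
  vthr <- min(max(vthr, config$velocity_floor), config$velocity_ceiling)
  list(velocity = vthr, acceleration = one(sig$a))
}

#' Detect saccades with velocity and acceleration threshold criteria
#'
#' A candidate saccade starts where track velocity crosses the velocity
#' threshold upward with track acceleration having exceeded the
#' acceleration threshold within the preceding 20 ms, and ends where the
#' velocity falls back below threshold. Candidates closer than
#' \code{merge_gap_ms} are merged, candidates shorter than
#' \code{min_duration_ms} are dropped, and each survivor is verified by
#' requiring that mean gaze position in the 20 ms before onset differs from
#' the mean in the 20 ms after offset by more than 3 x the pooled
#' within-window position MAD.
#'
#' @param sig A \code{gaze_signal} with kinematic channels.
#' @param config A \code{detection_config}.
#' @param thresholds Optional precomputed thresholds from
#'   \code{estimate_noise_thresholds}.
#' @return Data frame of class \code{saccade_events}: one row per saccade
#'   with \code{onset, offset, duration_ms, dx, dy, amplitude, direction,
#'   peak_velocity, axis}.
#' @export
detect_saccades <- function(sig, config = detection_config(), thresholds = NULL) {
  rate <- attr(sig, "rate")
  if (is.null(thresholds)) thresholds <- estimate_noise_thresholds(sig, config)
  vthr <- thresholds$velocity; athr <- thresholds$acceleration
  w <- max(1L, round(config$verify_window_ms / 1000 * rate))
  events <- list()
  segs <- .valid_segments(sig$valid)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]; e <- segs[i, 2]
    v <- sig$v[s:e]; a <- sig$a[s:e]
    hi <- v >= vthr
    if (!any(hi)) next
    r <- rle(hi)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    on <- starts[r$values]; off <- ends[r$values]
    ## acceleration gate on onsets: |a| must exceed athr within preceding 20 ms
    keep <- vapply(on, function(k) {
      lo <- max(1L, k - w)
      any(abs(a[lo:k]) >= athr, na.rm = TRUE)
    }, TRUE)
    on <- on[keep]; off <- off[keep]
    if (!length(on)) next
    ## merge candidates separated by < merge_gap_ms
    gap <- config$merge_gap_ms / 1000 * rate
    j <- 1L
    mon <- on[1]; moff <- off[1]
    m_on <- integer(0); m_off <- integer(0)
    for (k in seq_along(on)[-1]) {
      if (on[k] - moff < gap) {
        moff <- off[k]
      } else {
        m_on <- c(m_on, mon); m_off <- c(m_off, moff)
        mon <- on[k]; moff <- off[k]
      }
    }
    m_on <- c(m_on, mon); m_off <- c(m_off, moff)
    for (k in seq_along(m_on)) {
      ev <- .verify_candidate(sig, s, e, m_on[k], m_off[k], w, rate, config)
      if (!is.null(ev)) events[[length(events) + 1L]] <- ev
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(onset = numeric(0), offset = numeric(0), duration_ms = numeric(0),
               dx = numeric(0), dy = numeric(0), amplitude = numeric(0),
               direction = numeric(0), peak_velocity = numeric(0),
               axis = character(0))
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("saccade_events", "data.frame"),
            thresholds = thresholds)
}

.verify_candidate <- function(sig, seg_s, seg_e, on, off, w, rate, config) {
  dur_ms <- (off - on) / rate * 1000
  if (dur_ms < config$min_duration_ms) return(NULL)
  i_on <- seg_s + on - 1L; i_off <- seg_s + off - 1L
  pre <- max(seg_s, i_on - w):(i_on - 1L)
  post <- (i_off + 1L):min(seg_e, i_off + w)
  if (i_on - 1L < seg_s || i_off + 1L > seg_e ||
      length(pre) < 2L || length(post) < 2L) {
    pre <- i_on; post <- i_off        # window unavailable at segment edge
  }
  mx0 <- mean(sig$x[pre]); my0 <- mean(sig$y[pre])
  mx1 <- mean(sig$x[post]); my1 <- mean(sig$y[post])
  ## pooled within-window spread: deviations from each window's own median
  dev <- c(sqrt((sig$x[pre] - stats::median(sig$x[pre]))^2 +
                (sig$y[pre] - stats::median(sig$y[pre]))^2),
           sqrt((sig$x[post] - stats::median(sig$x[post]))^2 +
                (sig$y[post] - stats::median(sig$y[post]))^2))
  pooled_mad <- stats::median(dev)
  dx <- mx1 - mx0; dy <- my1 - my0
  disp <- sqrt(dx^2 + dy^2)
  if (!(disp > config$threshold_multiplier * pooled_mad) || disp == 0)
    return(NULL)
  dir_deg <- atan2(dy, dx) * 180 / pi
  data.frame(onset = sig$t[i_on], offset = sig$t[i_off],
             duration_ms = (sig$t[i_off] - sig$t[i_on]) * 1000,
             dx = dx, dy = dy, amplitude = disp, direction = dir_deg,
             peak_velocity = max(sig$v[i_on:i_off], na.rm = TRUE),
             axis = classify_axis(dx, dy))
}

#' Classify a saccade as horizontal or vertical
#'
#' Horizontal iff the direction lies strictly within 45 degrees of the
#' horizontal meridian (either side); a direction at exactly 45 degrees is
#' vertical. Oblique saccades are not distinguished.
#'
#' @param dx,dy Displacement components in degrees.
#' @return "horizontal" or "vertical".
#' @export
classify_axis <- function(dx, dy) {
  if (length(dx) != length(dy)) stop("dx and dy must have equal length")
  amp <- sqrt(dx^2 + dy^2)
  if (any(amp == 0)) stop("classification error: zero displacement")
  dir_deg <- abs(atan2(dy, dx) * 180 / pi)
  from_horiz <- pmin(dir_deg, 180 - dir_deg)
  ifelse(from_horiz < 45, "horizontal", "vertical")
}

#' Parse fixations from inter-saccadic intervals
#'
#' One fixation per interval between consecutive saccades within a valid
#' segment, plus the leading and trailing intervals of each segment.
#' Fixations whose duration exceeds median + 3 x MAD of all fixation
#' durations in the recording (single pass, unscaled MAD) are flagged
#' \code{outlier = TRUE}: they still count toward epoch time but are
#' excluded from duration statistics (they are typically blink bridges).
#'
#' @param saccades A \code{saccade_events} table.
#' @param sig The \code{gaze_signal} the saccades were detected in.
#' @param config A \code{detection_config}.
#' @return Data frame of class \code{fixation_events} with \code{start, end,
#'   duration_ms, cx, cy, outlier} (centroid in degrees).
#' @export
parse_fixations <- function(saccades, sig, config = detection_config()) {
  segs <- .valid_segments(sig$valid)
  rows <- list()
  for (i in seq_len(nrow(segs))) {
    t0 <- sig$t[segs[i, 1]]; t1 <- sig$t[segs[i, 2]]
    sc <- saccades[saccades$onset >= t0 & saccades$offset <= t1, , drop = FALSE]
    bounds_start <- c(t0, sc$offset)
    bounds_end <- c(sc$onset, t1)
    for (k in seq_along(bounds_start)) {
      if (bounds_end[k] - bounds_start[k] <= 0) next
      in_fix <- sig$t >= bounds_start[k] & sig$t <= bounds_end[k] & sig$valid
      rows[[length(rows) + 1L]] <- data.frame(
        start = bounds_start[k], end = bounds_end[k],
        duration_ms = (bounds_end[k] - bounds_start[k]) * 1000,
        cx = mean(sig$x[in_fix]), cy = mean(sig$y[in_fix]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = numeric(0), end = numeric(0), duration_ms = numeric(0),
               cx = numeric(0), cy = numeric(0))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    med <- stats::median(out$duration_ms)
    madv <- .mad_raw(out$duration_ms)
    out$outlier <- out$duration_ms >
      med + config$fixation_outlier_multiplier * madv
  } else out$outlier <- logical(0)
  structure(out, class = c("fixation_events", "data.frame"))
}

#' Write detected events as delimited text
#'
#' @param saccades A \code{saccade_events} table.
#' @param fixations A \code{fixation_events} table.
#' @param path File path.
#' @param header Optional '#' comment lines.
#' @export
write_events <- function(saccades, fixations, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  sa <- data.frame(type = "saccade", onset = saccades$onset,
                   offset = saccades$offset, dx = saccades$dx, dy = saccades$dy,
                   amplitude = saccades$amplitude, direction = saccades$direction,
                   peak_velocity = saccades$peak_velocity, axis = saccades$axis,
                   outlier = FALSE)
  fx <- data.frame(type = "fixation", onset = fixations$start,
                   offset = fixations$end, dx = NA, dy = NA,
                   amplitude = NA, direction = NA, peak_velocity = NA,
                   axis = NA, outlier = fixations$outlier)
  all <- rbind(sa, fx)
  all <- all[order(all$onset), ]
  utils::write.table(format(all, digits = 8), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
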