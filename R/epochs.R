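#' Segmentation configuration
#'
#' Quantifies the verbal epoch definitions: gaze "arriving at the beginning
#' of a line" and "starting to move towards the beginning of another line".
#'
#' @param row_tolerance_frac Row-assignment tolerance as a fraction of the
#'   inter-row angular spacing (default 0.5, i.e. half the spacing).
#' @param line_start_tolerance_deg How close (deg, horizontal) a fixation
#'   must be to the leftmost column to count as a line-start arrival
#'   (default 2.0).
#' @param sweep_trigger_frac Minimum amplitude of the sweep-initiating
#'   leftward saccade, as a fraction of the row extent (default 0.5).
#' @return A list of class \code{segmentation_config}.
#' @export
segmentation_config <- function(row_tolerance_frac = 0.5,
                                line_start_tolerance_deg = 2.0,
                                sweep_trigger_frac = 0.5) {
  structure(as.list(environment()), class = "segmentation_config")
}

#' Assign fixations to stimulus rows
#'
#' Labels each fixation with the nearest row (subtest C) or within-column
#' position (A/B) centre in the vertical coordinate, provided the vertical
#' distance is within the tolerance; otherwise the label is NA. For A/B the
#' column (1 or 2) is also assigned by horizontal proximity.
#'
#' @param fixations A \code{fixation_events} table.
#' @param layout A \code{dem_layout}.
#' @param config A \code{segmentation_config}.
#' @return The fixation table with columns \code{row} (and \code{col} for
#'   A/B) added.
#' @export
assign_rows <- function(fixations, layout, config = segmentation_config()) {
  spacing_deg <- mm_to_deg(layout$vertical_spacing_mm, layout$viewing_distance_mm)
  tol <- config$row_tolerance_frac * spacing_deg
  pos <- layout$positions
  if (layout$subtest == "C") {
    row_y <- tapply(pos$y_deg, pos$row, mean)
    idx <- as.integer(names(row_y))
    fixations$row <- vapply(fixations$cy, function(y) {
      d <- abs(y - row_y)
      k <- which.min(d)
      if (d[k] <= tol) idx[k] else NA_integer_
    }, 1L)
  } else {
    col_x <- tapply(pos$x_deg, pos$col, mean)
    fixations$col <- vapply(fixations$cx, function(x)
      as.integer(which.min(abs(x - col_x))), 1L)
    slot_y <- tapply(pos$y_deg, pos$row, mean)   # rows 1..20 top to bottom
    idx <- as.integer(names(slot_y))
    fixations$row <- vapply(fixations$cy, function(y) {
      d <- abs(y - slot_y)
      k <- which.min(d)
      if (d[k] <= tol) idx[k] else NA_integer_
    }, 1L)
  }
  fixations
}

## line arrivals: fixation indices where a new line/column begins.
## A transition is a displacement between consecutive fixations at least as
## large as the sweep trigger (a sweep's first hop, or the jump left by a
## blink that swallowed the sweep); the arrival is then the fixation that
## settles at the line start. Displacement-based detection is robust to
## slow gaze drift and to fixation landing noise, which are both much
## smaller than a sweep.
.line_arrivals <- function(fixations, layout, config) {
  spacing_deg <- mm_to_deg(layout$vertical_spacing_mm, layout$viewing_distance_mm)
  pos <- layout$positions
  tol <- config$line_start_tolerance_deg
  n <- nrow(fixations)
  cx <- fixations$cx; cy <- fixations$cy
  dcx <- c(0, diff(cx))
  if (layout$subtest == "C") {
    x_start <- mean(pos$x_deg[pos$col == 1])
    extent_deg <- diff(range(pos$x_deg[pos$row == 1]))
    trigger <- config$sweep_trigger_frac * extent_deg
    first <- which(sqrt((cx - pos$x_deg[1])^2 +
                        (cy - pos$y_deg[1])^2) <= tol)[1]
    if (is.na(first)) stop("segmentation error: no fixation near the first number")
    trans <- which(dcx <= -trigger & seq_len(n) > first)
    arrivals <- first
    for (i in trans) {
      nxt <- trans[trans > i]
      lim <- if (length(nxt)) nxt[1] - 1L else n
      cand <- which(abs(cx - x_start) <= tol)
      cand <- cand[cand >= i & cand <= lim]
      if (!length(cand)) next
      j <- cand[1]
      ## corrective hops still closing in on the line start supersede
      while (j < lim && abs(cx[j + 1L] - x_start) <= tol &&
             cx[j + 1L] <= cx[j] + 0.3) j <- j + 1L
      ## a pure horizontal re-read of the same line is not a new line
      if (cy[j] > cy[i - 1L] + 0.3 * spacing_deg) next
      if (j > arrivals[length(arrivals)]) arrivals <- c(arrivals, j)
    }
  } else {
    gap_deg <- mm_to_deg(layout$column_gap_mm, layout$viewing_distance_mm)
    col_x <- tapply(pos$x_deg, pos$col, mean)
    trigger <- config$sweep_trigger_frac * gap_deg
    top1 <- pos[pos$col == 1 & pos$row == 1, ]
    first <- which(sqrt((cx - top1$x_deg)^2 +
                        (cy - top1$y_deg)^2) <= tol)[1]
    if (is.na(first)) stop("segmentation error: no fixation near the first number")
    trans <- which(dcx >= trigger & seq_len(n) > first)
    arrivals <- first
    for (i in trans) {
      nxt <- trans[trans > i]
      lim <- if (length(nxt)) nxt[1] - 1L else n
      cand <- which(abs(cx - col_x[2]) <= tol)
      cand <- cand[cand >= i & cand <= lim]
      if (!length(cand)) next
      j <- cand[1]
      ## the sweep ascends to the top of column 2; reading then descends
      while (j < lim && abs(cx[j + 1L] - col_x[2]) <= tol &&
             cy[j + 1L] >= cy[j] - 0.3) j <- j + 1L
      if (j > arrivals[length(arrivals)]) arrivals <- c(arrivals, j)
    }
  }
  arrivals
}

#' Segment a DEM recording into identification and return-sweep epochs
#'
#' For subtest C, a return sweep starts at the onset of the first leftward
#' saccade whose horizontal amplitude is at least
#' \code{sweep_trigger_frac} x row extent after the gaze has entered the
#' final-position region of the current row, and ends at the start of the
#' first fixation at the beginning of a lower line; intermittent fixations
#' and saccades belong to the sweep. If the initiating saccade is not
#' observable (e.g. lost to a blink), the sweep starts at the end of the
#' last fixation on the origin line. All remaining time is identification
#' time of the corresponding line. Subtests A/B yield one sweep (bottom of
#' column 1 to top of column 2) and two identification epochs. Epochs are
#' contiguous, non-overlapping, and tile the interval from the first to the
#' last number fixation.
#'
#' @param saccades A \code{saccade_events} table.
#' @param fixations A \code{fixation_events} table with rows assigned.
#' @param layout A \code{dem_layout}.
#' @param config A \code{segmentation_config}.
#' @return Data frame of class \code{dem_epochs}: \code{kind}
#'   ("identification" or "return_sweep"), \code{line} (origin line),
#'   \code{start}, \code{end}.
#' @export
segment_epochs <- function(saccades, fixations, layout,
                           config = segmentation_config()) {
  if (!nrow(fixations)) stop("segmentation error: no fixations")
  if (is.null(fixations$row)) fixations <- assign_rows(fixations, layout, config)
  arrivals <- .line_arrivals(fixations, layout, config)
  pos <- layout$positions
  if (layout$subtest == "C") {
    extent_deg <- diff(range(pos$x_deg[pos$row == 1]))
    trigger <- config$sweep_trigger_frac * extent_deg
    x_end <- mean(pos$x_deg[pos$col == max(pos$col)])
    sweep_dx <- function(s) s$dx <= -trigger
    end_region <- function(sx) sx >= x_end - config$line_start_tolerance_deg
  } else {
    gap_deg <- mm_to_deg(layout$column_gap_mm, layout$viewing_distance_mm)
    trigger <- config$sweep_trigger_frac * gap_deg
    y_bottom <- min(pos$y_deg)
    sweep_dx <- function(s) s$dx >= trigger
    end_region <- function(sy) TRUE   # column end checked via arrival logic
  }

  trial_start <- fixations$start[arrivals[1]]
  trial_end <- {
    last_pos <- pos[nrow(pos), ]
    near_last <- which(sqrt((fixations$cx - last_pos$x_deg)^2 +
                            (fixations$cy - last_pos$y_deg)^2) <=
                       config$line_start_tolerance_deg)
    if (!length(near_last)) stop("segmentation error: no fixation near the last number")
    fixations$end[max(near_last)]
  }

  n_lines <- length(arrivals)
  epochs <- list()
  for (k in seq_len(n_lines)) {
    id_start <- fixations$start[arrivals[k]]
    if (k == 1L) id_start <- trial_start
    if (k < n_lines) {
      next_arrival_t <- fixations$start[arrivals[k + 1L]]
      ## last fixation of line k = last fixation starting before the next
      ## arrival whose x has not yet left the line (any fixation works as a
      ## lower bound for the trigger search)
      window_sacc <- saccades[saccades$onset >= id_start &
                              saccades$onset < next_arrival_t, , drop = FALSE]
      cand <- window_sacc[sweep_dx(window_sacc), , drop = FALSE]
      if (layout$subtest == "C" && nrow(cand)) {
        onset_x <- vapply(cand$onset, function(tt) {
          prev_fix <- fixations[fixations$end <= tt + 1e-9, , drop = FALSE]
          if (nrow(prev_fix)) prev_fix$cx[nrow(prev_fix)] else -Inf
        }, 0)
        cand <- cand[end_region(onset_x), , drop = FALSE]
      }
      if (nrow(cand)) {
        sweep_start <- cand$onset[1]
      } else {
        ## initiating saccade unobservable (blink): sweep starts at the end
        ## of the last fixation before the next arrival
        prior_fix <- fixations[fixations$end <= next_arrival_t &
                               fixations$start >= id_start, , drop = FALSE]
        sweep_start <- if (nrow(prior_fix) > 1L)
          prior_fix$end[nrow(prior_fix) - 1L] else id_start
      }
      if (sweep_start <= id_start) sweep_start <- id_start + 1e-6
      epochs[[length(epochs) + 1L]] <- data.frame(
        kind = "identification", line = k, start = id_start, end = sweep_start)
      epochs[[length(epochs) + 1L]] <- data.frame(
        kind = "return_sweep", line = k, start = sweep_start,
        end = next_arrival_t)
    } else {
      epochs[[length(epochs) + 1L]] <- data.frame(
        kind = "identification", line = k, start = id_start, end = trial_end)
    }
  }
  out <- do.call(rbind, epochs)
  rownames(out) <- NULL
  structure(out, class = c("dem_epochs", "data.frame"),
            subtest = layout$subtest)
}

#' Per-epoch and per-recording oculomotor metrics
#'
#' For each epoch: total duration, fixation time and saccade time (interval
#' overlaps, so the two together never exceed the epoch), saccade and
#' fixation counts, median fixation duration (excluding flagged duration
#' outliers), median saccade amplitude, and counts of backwards saccades
#' (horizontal-class leftward during C identification; vertical-class
#' upward during A/B identification) and orthogonal saccades
#' (vertical-class during C identification; horizontal-class during A/B).
#' Saccades are assigned to the epoch containing their onset, which places
#' boundary-straddling saccades in the sweep they initiate.
#'
#' @param epochs A \code{dem_epochs} table.
#' @param saccades A \code{saccade_events} table.
#' @param fixations A \code{fixation_events} table.
#' @return List with \code{per_epoch} (the epoch table with metric columns)
#'   and \code{summary} (one row per epoch kind with totals and medians).
#' @export
epoch_metrics <- function(epochs, saccades, fixations) {
  subtest <- attr(epochs, "subtest") %||% "C"
  overlap <- function(s0, e0, s1, e1) pmax(0, pmin(e0, e1) - pmax(s0, s1))
  n <- nrow(epochs)
  epochs$fixation_time <- epochs$saccade_time <- numeric(n)
  epochs$n_saccades <- epochs$n_fixations <- integer(n)
  epochs$median_fix_dur_ms <- epochs$median_sacc_amp <- NA_real_
  epochs$backwards <- epochs$orthogonal <- 0L
  for (i in seq_len(n)) {
    s0 <- epochs$start[i]; e0 <- epochs$end[i]
    epochs$fixation_time[i] <- sum(overlap(s0, e0, fixations$start, fixations$end))
    epochs$saccade_time[i] <- sum(overlap(s0, e0, saccades$onset, saccades$offset))
    in_ep_s <- saccades$onset >= s0 & saccades$onset < e0
    in_ep_f <- fixations$start >= s0 & fixations$start < e0
    epochs$n_saccades[i] <- sum(in_ep_s)
    epochs$n_fixations[i] <- sum(in_ep_f)
    fd <- fixations$duration_ms[in_ep_f & !fixations$outlier]
    if (length(fd)) epochs$median_fix_dur_ms[i] <- stats::median(fd)
    if (any(in_ep_s)) {
      epochs$median_sacc_amp[i] <- stats::median(saccades$amplitude[in_ep_s])
      if (epochs$kind[i] == "identification") {
        sc <- saccades[in_ep_s, , drop = FALSE]
        if (subtest == "C") {
          epochs$backwards[i] <- sum(sc$axis == "horizontal" & sc$dx < 0)
          epochs$orthogonal[i] <- sum(sc$axis == "vertical")
        } else {
          epochs$backwards[i] <- sum(sc$axis == "vertical" & sc$dy > 0)
          epochs$orthogonal[i] <- sum(sc$axis == "horizontal")
        }
      }
    }
  }
  summ <- do.call(rbind, lapply(split(epochs, epochs$kind), function(d) {
    fd <- unlist(mapply(function(s0, e0) {
      fixations$duration_ms[fixations$start >= s0 & fixations$start < e0 &
                            !fixations$outlier]
    }, d$start, d$end, SIMPLIFY = FALSE))
    am <- unlist(mapply(function(s0, e0) {
      saccades$amplitude[saccades$onset >= s0 & saccades$onset < e0]
    }, d$start, d$end, SIMPLIFY = FALSE))
    data.frame(kind = d$kind[1],
               total_time = sum(d$end - d$start),
               fixation_time = sum(d$fixation_time),
               saccade_time = sum(d$saccade_time),
               n_saccades = sum(d$n_saccades),
               n_fixations = sum(d$n_fixations),
               median_fix_dur_ms = if (length(fd)) stats::median(fd) else NA_real_,
               median_sacc_amp = if (length(am)) stats::median(am) else NA_real_,
               backwards = sum(d$backwards),
               orthogonal = sum(d$orthogonal))
  }))
  rownames(summ) <- NULL
  list(per_epoch = epochs, summary = summ)
}
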