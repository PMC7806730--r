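#' Preprocessing configuration
#'
#' Parameters of the gaze preprocessing chain: 13-point median prefilter on
#' the irregular stream, linear resampling to 500 Hz, zero-phase 5th-order
#' 40 Hz low-pass Butterworth, and 9-point smooth noise-robust
#' differentiation. Gaps in tracking longer than \code{max_bridgeable_gap_ms}
#' are not interpolated; the recording is segmented there instead.
#'
#' @param median_filter_length Odd window length of the median prefilter
#'   (samples; default 13).
#' @param resample_rate Target uniform rate in Hz (default 500).
#' @param butterworth_order Filter order (default 5).
#' @param butterworth_cutoff Low-pass cutoff in Hz (default 40).
#' @param differentiator_length Length of the noise-robust differentiator
#'   (odd; default 9).
#' @param max_bridgeable_gap_ms Longest gap between valid samples that is
#'   bridged by interpolation (default 75 ms; blinks are longer and become
#'   invalid stretches).
#' @return A list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(median_filter_length = 13L,
                              resample_rate = 500,
                              butterworth_order = 5L,
                              butterworth_cutoff = 40,
                              differentiator_length = 9L,
                              max_bridgeable_gap_ms = 75) {
  stopifnot(median_filter_length %% 2 == 1, differentiator_length %% 2 == 1,
            butterworth_cutoff < resample_rate / 2)
  structure(list(median_filter_length = as.integer(median_filter_length),
                 resample_rate = resample_rate,
                 butterworth_order = as.integer(butterworth_order),
                 butterworth_cutoff = butterworth_cutoff,
                 differentiator_length = as.integer(differentiator_length),
                 max_bridgeable_gap_ms = max_bridgeable_gap_ms),
            class = "preprocess_config")
}

#' Construct a raw gaze stream
#'
#' @param t Timestamps in seconds, strictly increasing, irregular.
#' @param x,y Gaze angles in degrees (screen-centred axes, x rightward,
#'   y upward).
#' @param valid Logical validity flag per sample.
#' @param eye "left" or "right".
#' @return A data frame of class \code{raw_gaze}.
#' @export
raw_gaze <- function(t, x, y, valid = rep(TRUE, length(t)), eye = "right") {
  if (length(t) && any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  structure(data.frame(t = t, x = x, y = y, valid = valid),
            eye = eye, class = c("raw_gaze", "data.frame"))
}

#' Select the eye with the best tracking signal
#'
#' Returns the stream with the larger fraction of valid samples; ties go to
#' the right eye.
#'
#' @param left,right \code{raw_gaze} streams (either may be NULL or empty).
#' @return The selected \code{raw_gaze}.
#' @export
select_best_eye <- function(left, right) {
  nl <- if (is.null(left)) 0L else nrow(left)
  nr <- if (is.null(right)) 0L else nrow(right)
  if (nl == 0L && nr == 0L) stop("no data: both eye streams are empty")
  if (nl == 0L) return(right)
  if (nr == 0L) return(left)
  fl <- mean(left$valid); fr <- mean(right$valid)
  if (fl > fr) left else right
}

#' Running-median prefilter on the irregular stream
#'
#' Applies a running median (window in samples, not time) to the valid
#' samples of x and y, before any interpolation. Edges use shrinking
#' windows. Timestamps and validity are unchanged.
#'
#' @param stream A \code{raw_gaze}.
#' @param config A \code{preprocess_config}.
#' @return The filtered \code{raw_gaze}.
#' @export
median_prefilter <- function(stream, config = preprocess_config()) {
  if (nrow(stream) == 0L) stop("no data: empty stream")
  k <- config$median_filter_length
  idx <- which(stream$valid)
  if (length(idx) >= 2L) {
    kk <- min(k, if (length(idx) %% 2 == 1) length(idx) else length(idx) - 1L)
    stream$x[idx] <- stats::runmed(stream$x[idx], kk, endrule = "median")
    stream$y[idx] <- stats::runmed(stream$y[idx], kk, endrule = "median")
  }
  stream
}

#' Resample an irregular gaze stream to a uniform grid
#'
#' Linear interpolation of the valid samples onto an exactly uniform grid at
#' \code{resample_rate}, spanning the first to last valid timestamp. Grid
#' points that fall inside a gap between valid samples longer than
#' \code{max_bridgeable_gap_ms} are marked invalid rather than interpolated.
#'
#' @param stream A \code{raw_gaze} (typically after \code{median_prefilter}).
#' @param config A \code{preprocess_config}.
#' @return A data frame of class \code{gaze_signal} with columns
#'   \code{t, x, y, valid} and attribute \code{rate}.
#' @export
resample_uniform <- function(stream, config = preprocess_config()) {
  v <- stream[stream$valid, , drop = FALSE]
  if (nrow(v) < 2L) stop("no data: fewer than 2 valid samples")
  rate <- config$resample_rate
  dt <- 1 / rate
  grid <- v$t[1] + dt * seq(0L, floor((v$t[nrow(v)] - v$t[1]) / dt))
  x <- stats::approx(v$t, v$x, xout = grid)$y
  y <- stats::approx(v$t, v$y, xout = grid)$y
  ## invalidate grid points bridging long gaps
  gap_s <- config$max_bridgeable_gap_ms / 1000
  valid <- rep(TRUE, length(grid))
  big <- which(diff(v$t) > gap_s)
  for (i in big) {
    valid[grid > v$t[i] & grid < v$t[i + 1L]] <- FALSE
  }
  sig <- data.frame(t = grid, x = x, y = y, valid = valid)
  structure(sig, rate = rate, class = c("gaze_signal", "data.frame"))
}

## index ranges of contiguous valid runs
.valid_segments <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

## forward-backward filter with reflective padding (zero net phase)
.filtfilt_refl <- function(b, a, x, pad = 100L) {
  n <- length(x)
  p <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p + 1L):(p + n)]
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Forward-backward 5th-order Butterworth (40 Hz cutoff by default) applied
#' to x and y within each contiguous valid segment, with reflective padding
#' to suppress edge transients. Two passes give -6 dB at the cutoff and no
#' net phase shift. Segments shorter than 3 x order samples are left
#' unfiltered with a warning. Invalid samples are untouched.
#'
#' @param sig A \code{gaze_signal}.
#' @param config A \code{preprocess_config}.
#' @return The filtered \code{gaze_signal}.
#' @export
lowpass_zero_phase <- function(sig, config = preprocess_config()) {
  rate <- attr(sig, "rate")
  bf <- signal::butter(config$butterworth_order,
                       config$butterworth_cutoff / (rate / 2), type = "low")
  segs <- .valid_segments(sig$valid)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]; e <- segs[i, 2]
    if (e - s + 1L < 3L * config$butterworth_order) {
      warning("segment too short for zero-phase filtering; left unfiltered")
      next
    }
    sig$x[s:e] <- .filtfilt_refl(bf$b, bf$a, sig$x[s:e])
    sig$y[s:e] <- .filtfilt_refl(bf$b, bf$a, sig$y[s:e])
  }
  sig
}

## taps of the smooth noise-robust differentiator (exact through degree 2);
## f'(k) ~ sum_j c_j (x[k+j] - x[k-j]) / h
.nr_diff_coefs <- function(N) {
  m <- (N - 3L) %/% 2L
  M <- (N - 1L) %/% 2L
  k <- seq_len(M)
  (choose(2 * m, m - k + 1) - choose(2 * m, m - k - 1)) / 2^(2 * m + 1)
}

#' Noise-robust differentiation of a uniformly sampled channel
#'
#' Central smooth noise-robust differentiator (9 taps by default; exact for
#' constant and linear signals) applied per contiguous valid segment. The
#' outermost (N-1)/2 samples of each segment use one-sided first
#' differences. Returns the derivative in input units per second.
#'
#' @param x Channel values on a uniform grid.
#' @param valid Logical validity mask (default all valid).
#' @param rate Sampling rate in Hz.
#' @param config A \code{preprocess_config}.
#' @return Numeric vector of derivatives; NA where invalid.
#' @export
differentiate_nr <- function(x, valid = rep(TRUE, length(x)), rate,
                             config = preprocess_config()) {
  N <- config$differentiator_length
  M <- (N - 1L) %/% 2L
  cf <- .nr_diff_coefs(N)
  h <- 1 / rate
  out <- rep(NA_real_, length(x))
  segs <- .valid_segments(valid)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]; e <- segs[i, 2]
    n <- e - s + 1L
    xs <- x[s:e]
    d <- rep(NA_real_, n)
    if (n < N) {
      warning("segment shorter than differentiator; one-sided differences used throughout")
      if (n >= 2L) d <- c(diff(xs) / h, (xs[n] - xs[n - 1L]) / h) else d <- 0
    } else {
      interior <- (M + 1L):(n - M)
      acc <- numeric(length(interior))
      for (k in seq_len(M)) {
        acc <- acc + cf[k] * (xs[interior + k] - xs[interior - k])
      }
      d[interior] <- acc / h
      for (j in seq_len(M)) {           # one-sided low-order edges
        d[j] <- (xs[j + 1L] - xs[j]) / h
        d[n - j + 1L] <- (xs[n - j + 1L] - xs[n - j]) / h
      }
    }
    out[s:e] <- d
  }
  out
}

#' Fill kinematic channels of a gaze signal
#'
#' Computes horizontal and vertical velocity by noise-robust differentiation
#' of the filtered positions, the track velocity (vector norm of the two),
#' and track acceleration (time derivative of track velocity).
#'
#' @param sig A filtered \code{gaze_signal}.
#' @param config A \code{preprocess_config}.
#' @return The \code{gaze_signal} with columns \code{vx, vy, v, a} added
#'   (deg/s, deg/s, deg/s, deg/s^2).
#' @export
kinematics <- function(sig, config = preprocess_config()) {
  rate <- attr(sig, "rate")
  sig$vx <- differentiate_nr(sig$x, sig$valid, rate, config)
  sig$vy <- differentiate_nr(sig$y, sig$valid, rate, config)
  sig$v <- sqrt(sig$vx^2 + sig$vy^2)
  sig$a <- differentiate_nr(sig$v, sig$valid, rate, config)
  sig
}

#' Full preprocessing chain
#'
#' median prefilter -> 500 Hz linear resampling -> zero-phase Butterworth ->
#' noise-robust differentiation, in that fixed order.
#'
#' @param stream A \code{raw_gaze}.
#' @param config A \code{preprocess_config}.
#' @return A \code{gaze_signal} with kinematic channels.
#' @export
preprocess_gaze <- function(stream, config = preprocess_config()) {
  stream <- median_prefilter(stream, config)
  sig <- resample_uniform(stream, config)
  sig <- lowpass_zero_phase(sig, config)
  kinematics(sig, config)
}

#' Read / write raw gaze streams
#'
#' The on-disk format is tab-separated text with a header line and columns
#' \code{t_s, x_deg, y_deg, valid, eye}. Comment lines start with '#'.
#'
#' @param path File path.
#' @param stream A \code{raw_gaze}.
#' @param header Optional character vector written as '#' comment lines.
#' @return \code{read_gaze} returns a \code{raw_gaze}.
#' @export
read_gaze <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  raw_gaze(d$t_s, d$x_deg, d$y_deg, as.logical(d$valid),
           eye = as.character(d$eye[1]))
}

#' @rdname read_gaze
#' @export
write_gaze <- function(stream, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  d <- data.frame(t_s = sprintf("%.6f", stream$t),
                  x_deg = sprintf("%.5f", stream$x),
                  y_deg = sprintf("%.5f", stream$y),
                  valid = stream$valid,
                  eye = attr(stream, "eye") %||% "right")
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
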