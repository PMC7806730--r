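#' Error-adjusted horizontal DEM time
#'
#' Adjusts the raw completion time of subtest C for naming errors:
#' adjusted = raw x 80 / (80 - omissions + additions). Times for subtests A
#' and B are never adjusted.
#'
#' @param raw_time Raw completion time in seconds (> 0).
#' @param omissions Number of omitted targets (0 <= omissions < 80).
#' @param additions Number of extra responses (>= 0).
#' @return Adjusted time in seconds.
#' @examples
#' adjust_time_C(60, 2, 0)   # 61.538
#' adjust_time_C(60, 0, 5)   # 56.471
#' @export
adjust_time_C <- function(raw_time, omissions, additions) {
  if (any(raw_time <= 0)) stop("invalid score: raw time must be positive")
  if (any(omissions < 0) || any(additions < 0)) stop("invalid score: negative error count")
  if (any(omissions >= 80)) stop("invalid score: omissions must be < 80")
  raw_time * 80 / (80 - omissions + additions)
}

## longest-common-subsequence match table between two token vectors;
## returns logical masks of matched elements
.lcs_match <- function(a, b) {
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L
                         else max(L[i, j + 1L], L[i + 1L, j])
  }
  ma <- logical(n); mb <- logical(m)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      ma[i] <- mb[j] <- TRUE; i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  list(target = ma, response = mb)
}

#' Count omissions and additions in a naming response
#'
#' Aligns the spoken response to the target number sequence with a
#' longest-common-subsequence alignment. Unmatched targets count as
#' omissions and unmatched responses as additions, except that a fully
#' skipped line counts as \code{skip_line_omissions} omission errors
#' (default 2, as scored in the DEM) instead of one per number, and a fully
#' repeated line counts as 5 addition errors (one per number, which the
#' token alignment already yields).
#'
#' @param response Character or numeric vector of named numbers in order.
#' @param target Target sequence in reading order (80 numbers for C).
#' @param line_length Numbers per line (default 5).
#' @param skip_line_omissions Omission weight of one fully skipped line
#'   (default 2).
#' @return List with \code{omissions} and \code{additions}.
#' @export
count_errors <- function(response, target, line_length = 5L,
                         skip_line_omissions = 2L) {
  target <- as.character(target); response <- as.character(response)
  if (!length(response)) {
    warning("empty response: scoring every target as omitted")
    n_lines <- length(target) %/% line_length
    return(list(omissions = n_lines * skip_line_omissions, additions = 0L))
  }
  mm <- .lcs_match(target, response)
  omitted <- !mm$target
  added <- !mm$response
  ## collapse fully skipped lines to the printed weight
  n_lines <- length(target) %/% line_length
  omissions <- 0L
  for (ln in seq_len(n_lines)) {
    idx <- ((ln - 1L) * line_length + 1L):(ln * line_length)
    o <- sum(omitted[idx])
    omissions <- omissions +
      if (o == line_length) as.integer(skip_line_omissions) else o
  }
  tail_idx <- if (n_lines * line_length < length(target))
    (n_lines * line_length + 1L):length(target) else integer(0)
  omissions <- omissions + sum(omitted[tail_idx])
  list(omissions = as.integer(omissions), additions = as.integer(sum(added)))
}

#' Vertical DEM time with the duplication rule
#'
#' Vertical time is DEM A time plus DEM B time. When only one of the two
#' subtests was completed with usable data, that time is duplicated
#' (counted twice) and the record flagged accordingly.
#'
#' @param time_A,time_B Subtest times in seconds, or NA when missing.
#' @return List with \code{vertical_time} and \code{flag} ("complete",
#'   "A-only" or "B-only").
#' @export
vertical_time <- function(time_A, time_B) {
  a_ok <- !is.na(time_A); b_ok <- !is.na(time_B)
  if (!a_ok && !b_ok) stop("no data: both subtest times missing")
  if (a_ok && b_ok) list(vertical_time = time_A + time_B, flag = "complete")
  else if (a_ok) list(vertical_time = 2 * time_A, flag = "A-only")
  else list(vertical_time = 2 * time_B, flag = "B-only")
}

#' Assemble a full DEM result for one subject
#'
#' @param time_A,time_B Vertical subtest times (s), NA when missing.
#' @param raw_time_C Raw horizontal time (s).
#' @param omissions,additions Error counts on subtest C.
#' @return List of class \code{dem_result}: vertical time, raw and adjusted
#'   C times, errors, DEM ratio (adjusted C / vertical) and naming
#'   percentage (vertical / adjusted C x 100).
#' @export
dem_result <- function(time_A, time_B, raw_time_C, omissions = 0L, additions = 0L) {
  v <- vertical_time(time_A, time_B)
  adj <- adjust_time_C(raw_time_C, omissions, additions)
  structure(list(
    time_A = time_A, time_B = time_B,
    vertical_time = v$vertical_time, duplication_flag = v$flag,
    raw_time_C = raw_time_C, omissions = omissions, additions = additions,
    errors = omissions + additions, adjusted_time_C = adj,
    dem_ratio = adj / v$vertical_time,
    naming_percent = v$vertical_time / adj * 100
  ), class = "dem_result")
}

#' Clean reaction-time trials
#'
#' Per subject and task (and optotype size where applicable): discard
#' reaction times below 0.1 s, then discard trials deviating more than
#' 3 x MAD (unscaled) from the median of the remaining trials, and average
#' the retained trials. The MAD rule is applied repeatedly until no trial
#' moves, which makes the cleaning a projection: re-cleaning an already
#' cleaned table changes nothing. Subjects whose mean deviates more than 3
#' group standard deviations from the group mean are flagged excluded.
#' When the MAD is zero (all trials equal) no trial is dropped (strict
#' inequality).
#'
#' @param rt Data frame with columns \code{subject}, \code{task},
#'   \code{rt} (seconds) and optionally \code{size}.
#' @param mad_multiplier MAD multiplier (default 3).
#' @param floor_s Minimum admissible reaction time (default 0.1 s).
#' @param group_sd_multiplier Group-level exclusion multiplier (default 3).
#' @return List with \code{trials} (input plus logical \code{retained}) and
#'   \code{subjects} (one row per subject x task: mean of retained trials,
#'   n retained, and \code{excluded} flag).
#' @export
clean_reaction_times <- function(rt, mad_multiplier = 3, floor_s = 0.1,
                                 group_sd_multiplier = 3) {
  if (is.null(rt$size)) rt$size <- ""
  key <- interaction(rt$subject, rt$task, rt$size, drop = TRUE)
  rt$retained <- FALSE
  for (k in levels(key)) {
    idx <- which(key == k)
    x <- rt$rt[idx]
    keep <- x >= floor_s
    repeat {
      if (!any(keep)) break
      med <- stats::median(x[keep])
      madv <- .mad_raw(x[keep])
      keep2 <- keep & !(abs(x - med) > mad_multiplier * madv)
      if (identical(keep2, keep)) break
      keep <- keep2
    }
    rt$retained[idx] <- keep
  }
  subj <- do.call(rbind, lapply(split(rt, list(rt$subject, rt$task, rt$size),
                                      drop = TRUE), function(d) {
    data.frame(subject = d$subject[1], task = d$task[1], size = d$size[1],
               mean_rt = if (any(d$retained)) mean(d$rt[d$retained]) else NA_real_,
               n_retained = sum(d$retained))
  }))
  rownames(subj) <- NULL
  subj$excluded <- FALSE
  for (task_key in unique(paste(subj$task, subj$size))) {
    idx <- which(paste(subj$task, subj$size) == task_key & !is.na(subj$mean_rt))
    if (length(idx) >= 3L) {
      mu <- mean(subj$mean_rt[idx]); sdev <- stats::sd(subj$mean_rt[idx])
      if (sdev > 0)
        subj$excluded[idx] <- abs(subj$mean_rt[idx] - mu) > group_sd_multiplier * sdev
    }
  }
  subj$excluded[is.na(subj$mean_rt)] <- NA
  list(trials = rt, subjects = subj)
}
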