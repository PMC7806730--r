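#' Default pipeline configuration
#'
#' Nested configuration for every stage of the DEM analysis pipeline, with
#' a single global seed from which all stage randomness is derived. Can be
#' written to / read from YAML. Unknown keys are rejected on merge.
#'
#' @param seed Global seed (default 1).
#' @param n_subjects Cohort size for the simulate stage (default 8 for the
#'   bundled demo scale; analyses in the package's tests use 36).
#' @param subtests Subtests to simulate/analyse.
#' @return A nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 8L,
                            subtests = c("A", "B", "C")) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_subjects = as.integer(n_subjects), subtests = subtests),
    preprocess = unclass(preprocess_config()),
    detection = unclass(detection_config()),
    segmentation = unclass(segmentation_config()),
    verbose = FALSE
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A \code{pipeline_config}.
#' @param path File path.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config};
#'   unknown keys raise an error.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  merge1 <- function(base, new, prefix = "") {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop(sprintf("unknown config key: %s%s", prefix, k))
      if (is.list(base[[k]]) && is.list(new[[k]]))
        base[[k]] <- merge1(base[[k]], new[[k]], paste0(prefix, k, "."))
      else base[[k]] <- new[[k]]
    }
    base
  }
  out <- merge1(unclass(base), raw)
  structure(out, class = "pipeline_config")
}

## analyse one already-simulated trial; returns events + epochs + metrics
.analyse_trial <- function(stream, layout, pre_cfg, det_cfg, seg_cfg) {
  sig <- preprocess_gaze(stream, pre_cfg)
  sacc <- detect_saccades(sig, det_cfg)
  fix <- parse_fixations(sacc, sig, det_cfg)
  fix <- assign_rows(fix, layout, seg_cfg)
  ep <- segment_epochs(sacc, fix, layout, seg_cfg)
  met <- epoch_metrics(ep, sacc, fix)
  list(signal = sig, saccades = sacc, fixations = fix,
       epochs = met$per_epoch, summary = met$summary,
       subtest_time = max(ep$end) - min(ep$start))
}

#' Analyse a simulated cohort end to end
#'
#' Runs preprocessing, saccade detection, fixation parsing, epoch
#' segmentation and DEM/RT scoring for every subject of a
#' \code{dem_cohort}, and assembles the per-subject measures used by the
#' statistical analyses.
#'
#' @param cohort A \code{dem_cohort} from \code{simulate_cohort}.
#' @param pre_cfg,det_cfg,seg_cfg Stage configurations.
#' @param keep_signals Keep the full per-trial analysis objects (memory
#'   heavy; default FALSE).
#' @return List with \code{measures} (one row per subject: age, true s,
#'   DEM times, oculomotor metrics, cleaned RT means) and optionally
#'   \code{trials}.
#' @export
analyse_cohort <- function(cohort,
                           pre_cfg = preprocess_config(),
                           det_cfg = detection_config(),
                           seg_cfg = segmentation_config(),
                           keep_signals = FALSE) {
  rtc <- clean_reaction_times(cohort$rt)
  rows <- list(); kept <- list()
  for (subj in cohort$subjects) {
    res <- lapply(names(subj$trials), function(st) {
      .analyse_trial(subj$trials[[st]]$stream, cohort$layouts[[st]],
                     pre_cfg, det_cfg, seg_cfg)
    })
    names(res) <- names(subj$trials)
    tA <- if ("A" %in% names(res)) res$A$subtest_time else NA
    tB <- if ("B" %in% names(res)) res$B$subtest_time else NA
    tC <- res$C$subtest_time
    dem <- if (!is.na(tA) || !is.na(tB)) {
      dem_result(tA, tB, tC, subj$omissions, subj$additions)
    } else {
      ## horizontal-only run: vertical-dependent scores are undefined
      list(vertical_time = NA_real_,
           adjusted_time_C = adjust_time_C(tC, subj$omissions, subj$additions),
           dem_ratio = NA_real_, naming_percent = NA_real_)
    }
    sC <- res$C$summary
    idr <- sC[sC$kind == "identification", ]
    swr <- sC[sC$kind == "return_sweep", ]
    get_rt <- function(task) {
      d <- rtc$subjects
      v <- d$mean_rt[d$subject == subj$id & d$task == task]
      if (length(v)) v[1] else NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subj$id, age = subj$profile$age, s_true = subj$profile$s,
      time_A = tA, time_B = tB, vertical_time = dem$vertical_time,
      raw_time_C = tC, adjusted_time_C = dem$adjusted_time_C,
      dem_ratio = dem$dem_ratio, naming_percent = dem$naming_percent,
      id_fix_time = idr$fixation_time, id_sacc_time = idr$saccade_time,
      sweep_fix_time = swr$fixation_time, sweep_sacc_time = swr$saccade_time,
      id_median_fix_ms = idr$median_fix_dur_ms,
      sweep_median_fix_ms = swr$median_fix_dur_ms,
      id_median_amp = idr$median_sacc_amp, sweep_median_amp = swr$median_sacc_amp,
      id_n_saccades = idr$n_saccades, sweep_n_saccades = swr$n_saccades,
      n_saccades = idr$n_saccades + swr$n_saccades,
      backwards = idr$backwards, orthogonal = idr$orthogonal,
      sa_rt = get_rt("speed-acuity"), vis_rt = get_rt("visual-detection"),
      aud_rt = get_rt("auditory-detection"))
    if (keep_signals) kept[[length(kept) + 1L]] <- res
  }
  measures <- do.call(rbind, rows)
  out <- list(measures = measures, rt = rtc)
  if (keep_signals) out$trials <- kept
  out
}

#' Statistical report over cohort measures
#'
#' Computes the correlation family of the study: age vs DEM times, DEM
#' times vs speed-acuity RT (with age-partialled versions), fixation
#' durations vs RT, oculomotor metrics vs horizontal time, with BH-FDR
#' adjustment over the family.
#'
#' @param measures The \code{measures} data frame from
#'   \code{analyse_cohort}.
#' @param q FDR level (default 0.05).
#' @return Data frame: one row per tested association with r, n, df, raw
#'   and FDR-adjusted p.
#' @export
stats_report <- function(measures, q = 0.05) {
  pairs <- list(
    c("age", "vertical_time"), c("age", "adjusted_time_C"),
    c("age", "dem_ratio"),
    c("vertical_time", "sa_rt"), c("adjusted_time_C", "sa_rt"),
    c("dem_ratio", "sa_rt"),
    c("id_median_fix_ms", "sa_rt"), c("sweep_median_fix_ms", "sa_rt"),
    c("id_median_fix_ms", "vis_rt"), c("id_median_fix_ms", "aud_rt"),
    c("id_median_fix_ms", "raw_time_C"), c("n_saccades", "raw_time_C"),
    c("sweep_n_saccades", "raw_time_C"), c("id_median_amp", "raw_time_C"),
    c("backwards", "raw_time_C"), c("orthogonal", "raw_time_C"))
  rows <- lapply(pairs, function(p) {
    ct <- tryCatch(pearson(measures[[p[1]]], measures[[p[2]]]),
                   error = function(e) NULL)
    if (is.null(ct))   # undefined on degenerate / incomplete columns
      return(data.frame(x = p[1], y = p[2], r = NA_real_, n = NA_integer_,
                        df = NA_integer_, p = NA_real_))
    data.frame(x = p[1], y = p[2], r = ct$r, n = ct$n, df = ct$df, p = ct$p)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q)
  out$p_fdr <- fdr$adjusted
  out$significant_fdr <- fdr$rejected
  out
}

#' Run the full pipeline and write a results directory
#'
#' simulate (optional) -> preprocess -> detect -> segment -> score ->
#' stats, writing each stage's outputs as delimited/structured text under
#' \code{out_dir}. Rerunning with the same config and seed reproduces the
#' outputs. Every file carries a header with the package version, seed and
#' a hash of the resolved configuration.
#'
#' @param config A \code{pipeline_config} (or a path to a YAML one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the cohort analysis list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(err)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(err)),
           call. = FALSE))
  }
  ver <- as.character(utils::packageVersion("oculodem"))
  cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))) %% 1e8
  hdr <- c(sprintf("oculodem %s", ver), sprintf("seed %d", config$seed),
           sprintf("config_hash %08d", cfg_hash))

  pre_cfg <- do.call(preprocess_config, config$preprocess)
  det_cfg <- do.call(detection_config, config$detection)
  seg_cfg <- do.call(segmentation_config, config$segmentation)

  cohort <- stage("simulate", simulate_cohort(
    n_subjects = config$simulate$n_subjects, seed = config$seed,
    subtests = config$simulate$subtests))
  for (st in names(cohort$layouts))
    write_layout(cohort$layouts[[st]],
                 file.path(out_dir, sprintf("layout_%s.tsv", st)))
  for (subj in cohort$subjects)
    for (st in names(subj$trials))
      write_gaze(subj$trials[[st]]$stream,
                 file.path(out_dir, sprintf("gaze_s%02d_%s.tsv", subj$id, st)),
                 header = hdr)

  ana <- stage("analyse", analyse_cohort(cohort, pre_cfg, det_cfg, seg_cfg,
                                         keep_signals = TRUE))
  for (i in seq_along(ana$trials)) {
    for (st in names(ana$trials[[i]])) {
      tr <- ana$trials[[i]][[st]]
      write_events(tr$saccades, tr$fixations,
                   file.path(out_dir, sprintf("events_s%02d_%s.tsv", i, st)),
                   header = hdr)
      ep <- tr$epochs
      con <- file(file.path(out_dir, sprintf("epochs_s%02d_%s.tsv", i, st)), "w")
      writeLines(paste0("# ", hdr), con)
      utils::write.table(format(ep, digits = 8), con, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      close(con)
    }
  }
  ana$trials <- NULL

  con <- file(file.path(out_dir, "measures.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(format(ana$measures, digits = 8), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  close(con)

  rep <- stage("stats", stats_report(ana$measures))
  con <- file(file.path(out_dir, "stats_report.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(format(rep, digits = 6), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  close(con)

  write_pipeline_config(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(c(ana, list(report = rep)))
}
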