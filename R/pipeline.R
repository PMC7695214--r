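#' Pipeline configuration
#'
#' Bundles the cohort specification (for simulation), filter and entropy
#' configurations, the adjacency map, and the statistics options into one
#' object consumed by [run_pipeline()].
#'
#' @param spec A [cohort_spec()].
#' @param filters A [filter_config()].
#' @param apen An [apen_config()].
#' @param adjacency Neighbor map, default [default_adjacency()].
#' @param alpha Significance level for the statistics layer.
#' @param B Bootstrap resample count.
#' @param seed Statistics-layer seed (bootstrap).
#' @param out_dir Optional output directory for CSV/JSON results.
#' @param preprocess Run the cleaning chain before epoching (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), filters = filter_config(),
                            apen = apen_config(), adjacency = default_adjacency(),
                            alpha = 0.05, B = 1000, seed = spec$seed,
                            out_dir = NULL, preprocess = TRUE) {
  structure(list(spec = spec, filters = filters, apen = apen,
                 adjacency = adjacency, alpha = alpha, B = B, seed = seed,
                 out_dir = out_dir, preprocess = preprocess),
            class = "pipeline_config")
}

#' Analyze one subject's pair of recordings
#'
#' The per-subject pipeline stage: optional preprocessing of both
#' recordings, epoching (task trials and resting windows), behavioral TOVA
#' scores, per-condition cordance tables, covariance images, and
#' approximate-entropy scores for the three conditions (resting, correct
#' target, correct nontarget).
#'
#' @param resting,tova [eeg_recording()]s for the two states.
#' @param session The subject's [tova_session()] with responses.
#' @param config A [pipeline_config()].
#' @return List with `tova_scores` (one-row data frame), `apen` (data frame
#'   condition/value/components/r), `cordance` (tidy data frame over the
#'   three conditions), `images` (list of [covariance_image()]s).
#' @export
analyze_subject <- function(resting, tova, session, config = pipeline_config()) {
  if (config$preprocess) {
    resting <- preprocess(resting, config$filters)
    tova <- preprocess(tova, config$filters)
  }
  ts_task <- segment(tova, session)
  ts_rest <- resting_segment(resting, session$trial_period)
  scores <- score_tova(session)
  scores$subject_id <- session$subject_id
  conds <- list(resting = list(ts = ts_rest, class = "resting"),
                target = list(ts = ts_task, class = "target_correct"),
                nontarget = list(ts = ts_task, class = "nontarget_correct"))
  images <- list(); apen_rows <- NULL; cord <- NULL
  for (nm in names(conds)) {
    ts <- conds[[nm]]$ts; cl <- conds[[nm]]$class
    if (!any(ts$classes == cl)) next  # e.g. full omission: no correct targets
    img <- covariance_image(ts, cl)
    img$condition <- nm
    images[[nm]] <- img
    sc <- apen_score(img, config$apen)
    apen_rows <- rbind(apen_rows, data.frame(
      subject_id = session$subject_id, condition = nm, value = sc$value,
      component_m1 = sc$component_m1, component_m2 = sc$component_m2,
      r = sc$r, m1 = sc$config$m1, m2 = sc$config$m2,
      norm = sc$config$norm, source = sc$config$source))
    ct <- cordance_table(ts, cl, config$adjacency,
                         subject_id = session$subject_id)
    ct$condition <- nm
    cord <- rbind(cord, ct)
  }
  list(tova_scores = scores, apen = apen_rows, cordance = cord,
       images = images)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates the cohort subject by subject, runs [analyze_subject()] on
#' each, then the statistical layer: two-way ANOVA (group x condition) with
#' Bonferroni post hoc on the entropy scores, channelwise theta-cordance
#' t-tests per condition, Spearman correlation of BDI with each subject's
#' mean entropy (patient arm), per-condition ROC, the omission-weight
#' sweep on the task-condition scores, and bootstrap resampling of the
#' group x condition means. When `config$out_dir` is set, results are
#' written as CSV plus a `manifest.json` carrying the seed and a config
#' hash for exact regeneration.
#'
#' @param config A [pipeline_config()].
#' @param progress Print one line per subject.
#' @return An object of class `qeeg_pipeline_result` with `subjects`,
#'   `tova_scores`, `apen`, `cordance`, `stats` (list), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  spec <- config$spec
  n_tot <- spec$n_control + spec$n_patient
  if (n_tot < 1) stop("cohort is empty")
  lay <- cohort_layout(spec)
  subjects <- NULL; tova_scores <- NULL; apen_df <- NULL; cord_df <- NULL
  for (i in seq_len(n_tot)) {
    t0 <- Sys.time()
    sub <- cohort_subject(spec, i)
    res <- tryCatch(
      analyze_subject(sub$resting, sub$tova, sub$session, config),
      error = function(e) stop("stage failure for subject ", sub$subject_id,
                               ": ", conditionMessage(e), call. = FALSE))
    subjects <- rbind(subjects, data.frame(
      subject_id = sub$subject_id, group = sub$group, bdi = sub$bdi,
      regularity_resting = sub$regularity[["resting"]],
      regularity_task = sub$regularity[["task"]]))
    tova_scores <- rbind(tova_scores, res$tova_scores)
    apen_df <- rbind(apen_df, res$apen)
    cord_df <- rbind(cord_df, res$cordance)
    if (progress)
      message(sprintf("[%s] subject %s (%s): %d apen rows, %.1f s",
                      format(Sys.time(), "%H:%M:%S"), sub$subject_id,
                      sub$group, nrow(res$apen),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  stats_out <- cohort_statistics(subjects, tova_scores, apen_df, cord_df,
                                 config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qeegtova")),
    seed = spec$seed, stats_seed = config$seed,
    n_subjects = n_tot,
    subjects = subjects$subject_id,
    config_hash = config_hash(config))
  out <- structure(list(subjects = subjects, tova_scores = tova_scores,
                        apen = apen_df, cordance = cord_df,
                        stats = stats_out, manifest = manifest,
                        config = config),
                   class = "qeeg_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# statistics layer shared by run_pipeline and the acceptance script
cohort_statistics <- function(subjects, tova_scores, apen_df, cord_df, config) {
  merged <- merge(apen_df, subjects[, c("subject_id", "group")],
                  by = "subject_id")
  out <- list()
  big_enough <- min(table(subjects$group)) >= 2
  if (length(unique(merged$group)) == 2) {
    if (big_enough)
      out$anova <- two_way_anova_bonferroni(merged$value, merged$group,
                                            merged$condition, config$alpha)
    out$roc <- lapply(split(merged, merged$condition), function(d)
      roc(d$value, d$group == "mdd"))
    # channelwise theta-cordance t-tests per condition
    if (!is.null(cord_df) && big_enough) {
      theta <- cord_df[cord_df$band == "theta", ]
      out$cordance_tests <- lapply(split(theta, theta$condition), function(d) {
        wide <- stats::reshape(
          d[, c("subject_id", "channel", "cordance")],
          idvar = "subject_id", timevar = "channel", direction = "wide")
        colnames(wide) <- sub("^cordance\\.", "", colnames(wide))
        grp <- subjects$group[match(wide$subject_id, subjects$subject_id)]
        m <- as.matrix(wide[, -1, drop = FALSE])
        channelwise_ttests(m[grp == "mdd", , drop = FALSE],
                           m[grp == "control", , drop = FALSE],
                           alpha = config$alpha)
      })
    }
    # ApEn + omission-rate combination on the task (target) condition
    tgt <- merged[merged$condition == "target", ]
    om <- tova_scores$omission_rate[match(tgt$subject_id,
                                          tova_scores$subject_id)]
    if (nrow(tgt) >= 4 && length(unique(tgt$group)) == 2) {
      out$omission_roc <- roc(om, tgt$group == "mdd")
      out$weight_sweep <- combine_weight_sweep(tgt$value, om,
                                               tgt$group == "mdd")
    }
    # bootstrap of group x condition means
    cells <- split(merged$value,
                   paste(merged$group, merged$condition, sep = ":"))
    if (all(lengths(cells) >= 2) && big_enough)
      out$bootstrap <- bootstrap_means(cells, B = config$B,
                                       seed = config$seed)
  }
  # BDI vs mean ApEn, per arm
  mean_apen <- tapply(merged$value, merged$subject_id, mean)
  bdi <- subjects$bdi[match(names(mean_apen), subjects$subject_id)]
  grp <- subjects$group[match(names(mean_apen), subjects$subject_id)]
  out$bdi_correlation <- lapply(split(seq_along(bdi), grp), function(ix) {
    if (length(ix) >= 3 && stats::sd(bdi[ix]) > 0 &&
        stats::sd(mean_apen[ix]) > 0)
      spearman(bdi[ix], as.numeric(mean_apen[ix]), config$alpha)
    else NULL
  })
  out
}

# md5 of the canonical JSON serialization of the configuration
config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(
    rapply(unclass(cfg), unclass, how = "replace"), tf,
    auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(result$tova_scores, file.path(dir, "tova_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$apen, file.path(dir, "apen_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cordance, file.path(dir, "cordance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.qeeg_pipeline_result <- function(x, ...) {
  cat(sprintf("<qeeg_pipeline_result> %d subjects (%d control, %d mdd)\n",
              nrow(x$subjects), sum(x$subjects$group == "control"),
              sum(x$subjects$group == "mdd")))
  if (!is.null(x$stats$anova))
    cat(sprintf("  ApEn two-way ANOVA interaction: F = %.3g, p = %.3g\n",
                x$stats$anova$statistic, x$stats$anova$p_value))
  for (nm in names(x$stats$roc))
    cat(sprintf("  ApEn ROC (%s): AUC = %.3f\n", nm, x$stats$roc[[nm]]$auc))
  invisible(x)
}

#' Validate input files against the pipeline's expectations
#'
#' Checks recording CSVs for the 19-label montage and a positive sampling
#' rate, session CSVs for the schedule/response schema, and (for paired
#' inputs) that every trial fits inside its recording. Failures are
#' collected into a machine-readable report, not raised.
#'
#' @param recording_paths Character vector of recording CSV paths.
#' @param session_paths Optional session CSV paths, matched by position to
#'   `recording_paths`.
#' @param labels Expected channel labels.
#' @return List with `ok` (logical) and `failures` (data frame: file,
#'   check, detail).
#' @export
validate_inputs <- function(recording_paths, session_paths = NULL,
                            labels = tova_montage()) {
  fails <- data.frame(file = character(), check = character(),
                      detail = character())
  add <- function(file, check, detail)
    fails <<- rbind(fails, data.frame(file = file, check = check,
                                      detail = detail))
  for (i in seq_along(recording_paths)) {
    p <- recording_paths[i]
    if (!file.exists(p)) { add(p, "exists", "file not found"); next }
    rec <- tryCatch(read_recording_csv(p), error = function(e) e)
    if (inherits(rec, "error")) { add(p, "parse", conditionMessage(rec)); next }
    missing <- setdiff(labels, rec$labels)
    if (length(missing) > 0)
      add(p, "montage", paste("missing channel(s):",
                              paste(missing, collapse = ", ")))
    if (rec$fs <= 0) add(p, "fs", "non-positive sampling rate")
    if (!is.null(session_paths) && i <= length(session_paths)) {
      sp <- session_paths[i]
      if (!file.exists(sp)) { add(sp, "exists", "file not found"); next }
      ses <- tryCatch(read_session_csv(sp), error = function(e) e)
      if (inherits(ses, "error")) { add(sp, "parse", conditionMessage(ses)); next }
      ends <- ses$trials$onset_s + ses$trial_period
      late <- which(ends > duration_s(rec) + 1e-9)
      if (length(late) > 0)
        add(sp, "onsets", paste("trial", ses$trials$trial_index[late[1]],
                                "extends past recording end"))
    }
  }
  list(ok = nrow(fails) == 0, failures = fails)
}
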