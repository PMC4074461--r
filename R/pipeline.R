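#' Run the full processing pipeline
#'
#' Executes reconstruct -> resample -> filter -> metrics -> aggregate ->
#' reliability for a manifest of trials, writing all report artifacts to
#' `out_dir`. The manifest either points at raw recording CSVs (`file`
#' column) or already carries precomputed metrics (`pl_cm`, `va_cm_s`
#' columns), in which case the signal stages are skipped — this is how
#' third-party metric tables enter the statistics layer.
#'
#' Trials that fail a signal-processing stage are dropped from the
#' aggregation with a machine-readable reason code (the condition class) and
#' logged, mirroring clinical practice of excluding unusable trials rather
#' than aborting a session. Comparisons whose sessions are absent from the
#' data are skipped with a warning; the others are still computed.
#'
#' @param config a [session_config()].
#' @param manifest data frame with `subject,task,session,trial` plus either
#'   `file` or `pl_cm,va_cm_s`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `trials`, `summary`, `report`,
#'   `bland_altman` (points data frame and per-cell stats), and `log`
#'   (dropped trials / skipped comparisons). Files written:
#'   `trial_metrics.csv`, `condition_summary.csv`, `reliability_report.csv`,
#'   `bland_altman_points.csv`, `bland_altman.json`, `pipeline_log.csv`.
#' @export
run_pipeline <- function(config, manifest, out_dir) {
  if (!inherits(config, "session_config"))
    abort_sb("`config` must be a session_config", "swayboard_parameter_error")
  need <- c("subject", "task", "session", "trial")
  if (!all(need %in% names(manifest)))
    abort_sb("manifest must have columns subject, task, session, trial",
             "swayboard_format_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log <- data.frame(stage = character(), subject = character(),
                    task = character(), session = character(),
                    trial = integer(), reason = character(),
                    detail = character(), stringsAsFactors = FALSE)

  if (all(c("pl_cm", "va_cm_s") %in% names(manifest))) {
    trials <- manifest[, c(need, "pl_cm", "va_cm_s")]
  } else {
    if (!"file" %in% names(manifest))
      abort_sb("manifest needs either a `file` column or pl_cm/va_cm_s columns",
               "swayboard_format_error")
    rows <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      mrow <- manifest[i, ]
      res <- tryCatch({
        rec <- read_raw_recording(mrow$file, geometry = config$geometry,
                                  meta = as.list(mrow[need]))
        traj <- compute_cop_series(rec)
        traj <- resample_uniform(traj, config$preprocessing$fs_hz)
        traj <- lowpass_filter(traj, config$preprocessing)
        trial_metrics(traj)
      }, swayboard_error = function(e) e)
      if (inherits(res, "error")) {
        log <- rbind(log, data.frame(
          stage = "process", subject = mrow$subject, task = mrow$task,
          session = mrow$session, trial = mrow$trial,
          reason = class(res)[1], detail = conditionMessage(res),
          stringsAsFactors = FALSE))
      } else rows[[i]] <- res
    }
    trials <- do.call(rbind, rows)
    if (is.null(trials) || nrow(trials) == 0L)
      abort_sb("every trial failed processing; see the pipeline log",
               "swayboard_signal_error")
  }

  summary <- summarize_trials(trials)

  present <- unique(summary$session)
  usable <- list()
  for (nm in names(config$comparisons)) {
    pair <- config$comparisons[[nm]]
    if (all(pair %in% present)) {
      usable[[nm]] <- pair
    } else {
      warning(sprintf("comparison '%s' skipped: session(s) %s absent", nm,
                      paste(setdiff(pair, present), collapse = ", ")))
      log <- rbind(log, data.frame(
        stage = "reliability", subject = NA, task = NA,
        session = paste(setdiff(pair, present), collapse = "+"),
        trial = NA, reason = "swayboard_missing_session",
        detail = sprintf("comparison '%s' skipped", nm),
        stringsAsFactors = FALSE))
    }
  }
  tasks_present <- intersect(config$tasks$task, unique(summary$task))
  for (task in setdiff(config$tasks$task, tasks_present))
    log <- rbind(log, data.frame(
      stage = "reliability", subject = NA, task = task, session = NA,
      trial = NA, reason = "swayboard_missing_task",
      detail = sprintf("task '%s' absent from the data", task),
      stringsAsFactors = FALSE))
  report <- NULL
  ba_points <- NULL
  ba_stats <- list()
  if (length(usable) && length(tasks_present)) {
    report <- reliability_report(summary, comparisons = usable,
                                 tasks = tasks_present)
    for (nm in names(usable)) {
      pair <- usable[[nm]]
      for (task in tasks_present) {
        for (metric in c("pl_cm", "va_cm_s")) {
          m <- ratings_matrix(summary, task, metric, pair)
          ba <- bland_altman(m[, 1], m[, 2])
          key <- sprintf("%s.%s.%s", nm, task,
                         if (metric == "pl_cm") "PL" else "VA")
          ba_stats[[key]] <- list(bias = ba$bias, sd_diff = ba$sd_diff,
                                  loa_low = ba$loa_low,
                                  loa_high = ba$loa_high)
          ba_points <- rbind(ba_points, data.frame(
            comparison = nm, task = task,
            metric = if (metric == "pl_cm") "PL" else "VA",
            subject = rownames(m), mean = ba$pairs$mean,
            difference = ba$pairs$difference, stringsAsFactors = FALSE))
        }
      }
    }
  }

  utils::write.csv(trials, file.path(out_dir, "trial_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "condition_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report))
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "reliability_report.csv"),
                     row.names = FALSE)
  if (!is.null(ba_points)) {
    utils::write.csv(ba_points, file.path(out_dir, "bland_altman_points.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ba_stats, file.path(out_dir, "bland_altman.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  utils::write.csv(log, file.path(out_dir, "pipeline_log.csv"),
                   row.names = FALSE)

  invisible(list(trials = trials, summary = summary, report = report,
                 bland_altman = list(points = ba_points, stats = ba_stats),
                 log = log))
}
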