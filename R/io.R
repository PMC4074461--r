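#' Read a raw board recording CSV
#'
#' Expects a comma-separated file with header columns `t,f_tl,f_tr,f_bl,f_br`
#' (any column order; extra columns ignored), period decimal separator,
#' UTF-8. Malformed content is reported with the offending data row number.
#'
#' @param path CSV file path.
#' @param geometry a [board_geometry()].
#' @param meta named list of identifiers to attach.
#' @return A [raw_recording()].
#' @export
read_raw_recording <- function(path, geometry = board_geometry(),
                               meta = list()) {
  if (!file.exists(path))
    abort_sb(sprintf("file not found: %s", path), "swayboard_format_error")
  d <- utils::read.csv(path, colClasses = "character",
                       strip.white = TRUE, fileEncoding = "UTF-8")
  req <- c("t", "f_tl", "f_tr", "f_bl", "f_br")
  missing <- setdiff(req, names(d))
  if (length(missing))
    abort_sb(sprintf("%s: missing column(s) %s", path,
                     paste(missing, collapse = ", ")),
             "swayboard_format_error")
  num <- lapply(d[req], function(col) suppressWarnings(as.numeric(col)))
  for (cn in req) {
    bad <- which(is.na(num[[cn]]) & !(d[[cn]] %in% c("", "NA")))
    if (length(bad))
      abort_sb(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                       path, d[[cn]][bad[1]], cn, bad[1]),
               "swayboard_format_error")
    if (anyNA(num[[cn]]))
      abort_sb(sprintf("%s: empty value in column '%s' at data row %d",
                       path, cn, which(is.na(num[[cn]]))[1]),
               "swayboard_format_error")
  }
  t <- num$t
  if (any(diff(t) <= 0))
    abort_sb(sprintf("%s: timestamps not strictly increasing at data row %d",
                     path, which(diff(t) <= 0)[1] + 1L),
             "swayboard_format_error")
  raw_recording(t, num$f_tl, num$f_tr, num$f_bl, num$f_br,
                geometry = geometry, meta = meta)
}

#' Write a raw board recording CSV
#'
#' @param rec a [raw_recording()].
#' @param path output CSV path.
#' @export
write_raw_recording <- function(rec, path) {
  utils::write.csv(rec$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Session configuration
#'
#' Bundles everything a processing run needs: board geometry, the filter
#' spec, the task protocol, session labels, and the comparison pairs of the
#' reliability design.
#'
#' @param geometry a [board_geometry()].
#' @param preprocessing a [filter_spec()].
#' @param tasks data frame `task,duration_s,n_trials`.
#' @param sessions session labels.
#' @param comparisons named list of length-2 session pairs.
#' @return Object of class `session_config`.
#' @export
session_config <- function(geometry = board_geometry(),
                           preprocessing = filter_spec(),
                           tasks = data.frame(
                             task = c("STOE", "STCE", "SOOE", "SOCE"),
                             duration_s = c(30, 30, 10, 10),
                             n_trials = 3L, stringsAsFactors = FALSE),
                           sessions = c("A1", "B", "A2", "A3"),
                           comparisons = list(inter_rater = c("A1", "B"),
                                              intra_rater = c("A1", "A2"),
                                              validity    = c("A1", "A3"))) {
  for (nm in names(comparisons))
    if (!all(comparisons[[nm]] %in% sessions))
      abort_sb(sprintf("comparison '%s' references undeclared session labels", nm),
               "swayboard_design_error")
  structure(list(geometry = geometry, preprocessing = preprocessing,
                 tasks = tasks, sessions = sessions,
                 comparisons = comparisons),
            class = "session_config")
}

#' Write a session configuration as JSON
#'
#' @param config a [session_config()].
#' @param path output JSON path.
#' @export
write_session_config <- function(config, path) {
  x <- list(geometry = list(width_x = config$geometry$width_x,
                            depth_y = config$geometry$depth_y),
            preprocessing = unclass(config$preprocessing),
            tasks = config$tasks,
            sessions = config$sessions,
            comparisons = config$comparisons)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a session configuration from JSON
#'
#' Inverse of [write_session_config()]: `read_session_config(write_session_config(x))`
#' reproduces `x`.
#'
#' @param path JSON path.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  if (!file.exists(path))
    abort_sb(sprintf("config not found: %s", path), "swayboard_format_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  session_config(
    geometry = board_geometry(x$geometry$width_x, x$geometry$depth_y),
    preprocessing = filter_spec(x$preprocessing$order,
                                x$preprocessing$cutoff_hz,
                                x$preprocessing$fs_hz,
                                x$preprocessing$mode),
    tasks = as.data.frame(x$tasks, stringsAsFactors = FALSE),
    sessions = x$sessions,
    comparisons = lapply(x$comparisons, as.character))
}
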