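#' Build a subjects-by-measurements ratings matrix
#'
#' Pivots a condition-summary table into the n x k grid consumed by
#' [icc_twoway()]: one row per subject, one column per session (rater,
#' occasion or device). Subjects missing any requested session are dropped
#' before analysis; the count is attached as attribute `n_dropped` and
#' reported with a message.
#'
#' @param summary condition-summary data frame
#'   (`subject,task,session,pl_cm,va_cm_s`).
#' @param task task label to select.
#' @param metric `"pl_cm"` or `"va_cm_s"`.
#' @param sessions character vector of session labels, in column order.
#' @return Numeric matrix with subject rownames and session colnames.
#' @export
ratings_matrix <- function(summary, task, metric = c("pl_cm", "va_cm_s"),
                           sessions) {
  metric <- match.arg(metric)
  d <- summary[summary$task == task & summary$session %in% sessions, ,
               drop = FALSE]
  if (nrow(d) == 0L)
    abort_sb(sprintf("no rows for task '%s' and sessions %s", task,
                     paste(sessions, collapse = "/")),
             "swayboard_design_error")
  wide <- stats::reshape(d[, c("subject", "session", metric)],
                         idvar = "subject", timevar = "session",
                         direction = "wide")
  cols <- paste(metric, sessions, sep = ".")
  missing_sess <- sessions[!cols %in% names(wide)]
  if (length(missing_sess))
    abort_sb(sprintf("session(s) %s absent for task '%s'",
                     paste(missing_sess, collapse = ", "), task),
             "swayboard_design_error")
  m <- as.matrix(wide[, cols, drop = FALSE])
  dimnames(m) <- list(wide$subject, sessions)
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("ratings_matrix: dropped %d subject(s) with missing cells (task %s, %s)",
                    n_dropped, task, metric))
  m <- m[complete, , drop = FALSE]
  attr(m, "n_dropped") <- n_dropped
  m
}

# Two-way crossed ANOVA mean squares without replication:
# rows = subjects, columns = measurements.
anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rmean <- rowMeans(m); cmean <- colMeans(m)
  ssr <- k * sum((rmean - grand)^2)
  ssc <- n * sum((cmean - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

spearman_brown <- function(r, k) k * r / (1 + (k - 1) * r)

#' Two-way intraclass correlation coefficient with 95% CI
#'
#' Reliability of an n-subjects x k-measurements grid under the two-way
#' crossed ANOVA model (subjects crossed with raters/sessions/devices).
#' Two definitions are offered:
#' \describe{
#'   \item{agreement}{absolute agreement, ICC(2,1)/ICC(A,1): rater variance
#'     counts as error, \eqn{(MS_R - MS_E) / (MS_R + (k-1)MS_E +
#'     \frac{k}{n}(MS_C - MS_E))}. The default for inter-rater and
#'     device-validity questions, and the form consistent with SEM and
#'     Bland-Altman, which both penalize systematic offsets.}
#'   \item{consistency}{ICC(3,1)/ICC(C,1): rater offsets forgiven,
#'     \eqn{(MS_R - MS_E)/(MS_R + (k-1)MS_E)}. Conventional for intra-rater
#'     repeatability.}
#' }
#' `unit = "average"` returns the reliability of the mean of the k
#' measurements (Spearman-Brown scaled). Confidence intervals follow the
#' F-distribution constructions of the McGraw-Wong conventions (Satterthwaite
#' degrees of freedom for the agreement form); average-measure bounds are the
#' Spearman-Brown transform of the single-measure bounds.
#'
#' @param m numeric matrix (or data frame), subjects in rows, measurements in
#'   columns; n >= 2, k >= 2, no missing cells.
#' @param definition `"agreement"` (default) or `"consistency"`.
#' @param unit `"single"` (default) or `"average"`.
#' @param conf_level confidence level for the CI (default 0.95).
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, the mean squares, and the call parameters.
#' @examples
#' m <- cbind(a = c(9, 6, 8, 7, 10, 6), b = c(2, 1, 4, 1, 5, 2))
#' icc_twoway(m, "agreement")   # low: systematic offset counts
#' icc_twoway(m, "consistency") # high: offset forgiven
#' @export
icc_twoway <- function(m, definition = c("agreement", "consistency"),
                       unit = c("single", "average"), conf_level = 0.95) {
  definition <- match.arg(definition)
  unit <- match.arg(unit)
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L)
    abort_sb("ratings must be a numeric matrix with n >= 2 subjects and k >= 2 measurements",
             "swayboard_shape_error")
  if (anyNA(m))
    abort_sb("ratings matrix has missing cells; drop incomplete subjects first",
             "swayboard_shape_error")
  if (stats::var(as.vector(m)) == 0)
    abort_sb("ICC undefined: all ratings identical (zero total variance)",
             "swayboard_icc_error")

  ms <- anova_ms(m)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf_level

  if (definition == "consistency") {
    icc1 <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      lo1 <- hi1 <- icc1
    } else {
      Fobs <- ms$msr / ms$mse
      FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo1 <- (FL - 1) / (FL + k - 1)
      hi1 <- (FU - 1) / (FU + k - 1)
    }
  } else {
    icc1 <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    if (ms$mse == 0 && ms$msc == 0) {
      lo1 <- hi1 <- icc1
    } else {
      a <- (k * icc1) / (n * (1 - icc1))
      b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
      v <- (a * ms$msc + b * ms$mse)^2 /
        ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      FL <- stats::qf(1 - alpha / 2, n - 1, v)
      FU <- stats::qf(1 - alpha / 2, v, n - 1)
      lo1 <- n * (ms$msr - FL * ms$mse) /
        (FL * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      hi1 <- n * (FU * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * FU * ms$msr)
    }
  }

  if (unit == "average") {
    est <- spearman_brown(icc1, k)
    lo <- spearman_brown(lo1, k); hi <- spearman_brown(hi1, k)
  } else {
    est <- icc1; lo <- lo1; hi <- hi1
  }
  structure(list(icc = est, ci_low = min(lo, est), ci_high = max(hi, est),
                 definition = definition, unit = unit,
                 conf_level = conf_level, n = n, k = k,
                 ms = ms[c("msr", "msc", "mse")]),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, %s measures): %.3f  (%d%% CI %.3f, %.3f)  [n=%d, k=%d]\n",
              x$definition, x$unit, x$icc, round(100 * x$conf_level),
              x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Reliability band of an ICC value
#'
#' The conventional clinical banding: >= 0.80 high, 0.60-0.79 moderate,
#' < 0.60 low. Band edges are half-open at the lower bound (an ICC of exactly
#' 0.80 is "high", exactly 0.60 "moderate").
#'
#' @param icc finite ICC value(s).
#' @return Character vector in `c("high", "moderate", "low")`.
#' @examples
#' classify_icc(c(0.918, 0.731, 0.42))
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc)))
    abort_sb("ICC must be finite", "swayboard_parameter_error")
  ifelse(icc >= 0.80, "high", ifelse(icc >= 0.60, "moderate", "low"))
}

#' Standard error of measurement
#'
#' \eqn{SEM = SD \sqrt{1 - ICC}}, the within-subject measurement error in the
#' metric's own units. For values that are themselves means (or sums) entering
#' a repeated-measures context, the SEM is additionally multiplied by
#' \eqn{\sqrt{n_{repeats}}}; the default of 1 applies when each analyzed value
#' is a single condition score.
#'
#' ICC estimates slightly outside `[0, 1]` (negative estimates occur in small
#' samples) are clamped with a warning rather than rejected.
#'
#' @param sd standard deviation of the measurement (>= 0).
#' @param icc reliability coefficient.
#' @param n_repeats repeated-measures multiplier count (default 1).
#' @return SEM in the metric's units.
#' @examples
#' sem(10, 0.84)      # 4
#' sem(10, 0.84, 3)   # 4 * sqrt(3)
#' @export
sem <- function(sd, icc, n_repeats = 1) {
  if (any(sd < 0))
    abort_sb("`sd` must be non-negative", "swayboard_parameter_error")
  if (n_repeats < 1)
    abort_sb("`n_repeats` must be >= 1", "swayboard_parameter_error")
  if (any(icc < 0) || any(icc > 1)) {
    warning("ICC outside [0, 1] clamped for SEM computation")
    icc <- pmin(pmax(icc, 0), 1)
  }
  sd * sqrt(1 - icc) * sqrt(n_repeats)
}

#' Paired difference between two measurement conditions
#'
#' Elementwise differences d = b - a (second condition minus first — the sign
#' convention of standard two-column reliability tables), their mean and SD
#' (n-1 denominator), and a two-sided paired t-test p-value. Significance
#' stars: `*` p < 0.05, `**` p < 0.01.
#'
#' @param a,b equal-length paired condition values (n >= 2).
#' @return List of class `paired_difference`: `diff_mean`, `diff_sd`,
#'   `t`, `p_value`, `stars`, `n`.
#' @export
paired_difference <- function(a, b) {
  if (length(a) != length(b))
    abort_sb("paired vectors must have equal length", "swayboard_pairing_error")
  if (length(a) < 2L)
    abort_sb("need at least 2 pairs", "swayboard_pairing_error")
  d <- b - a
  dm <- mean(d); ds <- stats::sd(d)
  tt <- tryCatch(stats::t.test(d), error = function(e) NULL)
  p <- if (is.null(tt)) NA_real_ else tt$p.value
  tstat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
  structure(list(diff_mean = dm, diff_sd = ds, t = tstat, p_value = p,
                 stars = if (!is.na(p) && p < 0.01) "**"
                         else if (!is.na(p) && p < 0.05) "*" else "",
                 n = length(d)),
            class = "paired_difference")
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements, plots-ready (mean, difference) points, the bias
#' (mean difference b - a), the SD of the differences, and the 95% limits of
#' agreement bias +/- 1.96 SD.
#'
#' @param a,b equal-length paired condition values (n >= 2).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, and a `pairs` data frame (`mean`, `difference`).
#' @examples
#' ba <- bland_altman(a = c(36, 40, 44), b = c(34, 41, 42))
#' ba$bias; c(ba$loa_low, ba$loa_high)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    abort_sb("paired vectors must have equal length", "swayboard_pairing_error")
  if (length(a) < 2L)
    abort_sb("need at least 2 pairs", "swayboard_pairing_error")
  d <- b - a
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 pairs = data.frame(mean = (a + b) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, SD of differences %.3f, 95%% LOA [%.3f, %.3f] (n=%d)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, nrow(x$pairs)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means with horizontal lines at the bias (solid)
#' and the 95% limits of agreement (dashed).
#'
#' @param x a [bland_altman()] result.
#' @param xlab,ylab,main usual plot labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, xlab = "Mean of measurements",
                              ylab = "Difference (b - a)",
                              main = "Bland-Altman plot", ...) {
  ylim <- range(c(x$pairs$difference, x$loa_low, x$loa_high))
  graphics::plot(x$pairs$mean, x$pairs$difference, xlab = xlab, ylab = ylab,
                 main = main, ylim = ylim, pch = 19, ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Full reliability report for a two-session comparison design
#'
#' For every configured session pair (e.g. inter-rater A1 vs B, intra-rater
#' A1 vs A2, device validity A1 vs A3) and every task x metric cell, computes
#' the two condition means +/- SD, the paired difference with t-test stars,
#' the agreement ICC(2,1) with 95% CI and its reliability band, the
#' consistency ICC(3,1) alongside (conventionally consulted for intra-rater
#' cells), and the SEM from the pooled two-condition SD
#' \eqn{\sqrt{(SD_a^2 + SD_b^2)/2}}.
#'
#' @param summary condition-summary data frame
#'   (`subject,task,session,pl_cm,va_cm_s`).
#' @param comparisons named list of length-2 session-label vectors; default
#'   `list(inter_rater = c("A1","B"), intra_rater = c("A1","A2"),
#'   validity = c("A1","A3"))`.
#' @param tasks task row order; defaults to order of appearance.
#' @param sem_n_repeats repeated-measures multiplier handed to [sem()]
#'   (default 1: the analyzed values are already trial means).
#' @return Data frame of class `reliability_report`, 2 rows (PL, VA) per task
#'   per comparison, columns
#'   `comparison,task,metric,mean_a,sd_a,mean_b,sd_b,diff_mean,diff_sd,p,stars,icc,ci_low,ci_high,band,sem,icc_consistency,ci_c_low,ci_c_high,n_subjects`.
#' @export
reliability_report <- function(summary,
                               comparisons = list(inter_rater = c("A1", "B"),
                                                  intra_rater = c("A1", "A2"),
                                                  validity    = c("A1", "A3")),
                               tasks = NULL,
                               sem_n_repeats = 1) {
  if (!all(c("subject", "task", "session", "pl_cm", "va_cm_s") %in%
           names(summary)))
    abort_sb("summary must have columns subject, task, session, pl_cm, va_cm_s",
             "swayboard_format_error")
  known <- unique(summary$session)
  for (nm in names(comparisons)) {
    pair <- comparisons[[nm]]
    if (length(pair) != 2L || !all(pair %in% known))
      abort_sb(sprintf("comparison '%s' references unknown session labels (%s); present: %s",
                       nm, paste(pair, collapse = ", "),
                       paste(known, collapse = ", ")),
               "swayboard_design_error")
  }
  tasks <- tasks %||% unique(summary$task)

  rows <- list()
  for (nm in names(comparisons)) {
    pair <- comparisons[[nm]]
    for (task in tasks) {
      for (metric in c("pl_cm", "va_cm_s")) {
        m <- ratings_matrix(summary, task, metric, pair)
        a <- m[, 1]; b <- m[, 2]
        pd <- paired_difference(a, b)
        ia <- icc_twoway(m, "agreement", "single")
        ic <- icc_twoway(m, "consistency", "single")
        pooled_sd <- sqrt((stats::sd(a)^2 + stats::sd(b)^2) / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = nm, task = task,
          metric = if (metric == "pl_cm") "PL" else "VA",
          mean_a = mean(a), sd_a = stats::sd(a),
          mean_b = mean(b), sd_b = stats::sd(b),
          diff_mean = pd$diff_mean, diff_sd = pd$diff_sd,
          p = pd$p_value, stars = pd$stars,
          icc = ia$icc, ci_low = ia$ci_low, ci_high = ia$ci_high,
          band = classify_icc(ia$icc),
          sem = sem(pooled_sd, max(0, min(1, ia$icc)), sem_n_repeats),
          icc_consistency = ic$icc,
          ci_c_low = ic$ci_low, ci_c_high = ic$ci_high,
          n_subjects = nrow(m),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  for (nm in unique(x$comparison)) {
    d <- x[x$comparison == nm, , drop = FALSE]
    cat(sprintf("\n== %s ==\n", nm))
    txt <- data.frame(
      task = d$task, metric = d$metric,
      A = sprintf("%.2f ± %.2f", d$mean_a, d$sd_a),
      B = sprintf("%.2f ± %.2f", d$mean_b, d$sd_b),
      Difference = sprintf("%.2f ± %.2f%s", d$diff_mean, d$diff_sd,
                           d$stars),
      `ICC (95% CI)` = sprintf("%.3f (%.3f, %.3f)", d$icc, d$ci_low,
                               d$ci_high),
      SEM = sprintf("%.3f", d$sem),
      band = d$band, check.names = FALSE)
    print(txt, row.names = FALSE)
  }
  invisible(x)
}
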