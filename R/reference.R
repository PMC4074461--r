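#' Published reference summary values
#'
#' Per-cell summary statistics (condition means and SDs, difference column,
#' ICC with 95% CI, reported SEM) from a published 20-subject reliability and
#' concurrent-validity study of a consumer four-load-cell balance board
#' against a laboratory force platform, across the four stance tasks and the
#' three comparison designs (inter-rater A1 vs B, intra-rater A1 vs A2,
#' device validity A1 vs A3). Shipped as a plain-text fixture so the
#' difference-sign convention and ICC banding can be checked against
#' published numbers without the (undeposited) raw data.
#'
#' Note the reported SEM column is retained as printed but is not
#' reconstructible from any printed SD/ICC combination, and the printed VA
#' values are about 6% larger than PL divided by the trial duration; neither
#' is treated as ground truth for computation (see the methods vignette).
#'
#' @return Data frame with one row per comparison x task x metric cell.
#' @examples
#' ref <- published_reference()
#' classify_icc(ref$icc)
#' @export
published_reference <- function() {
  utils::read.csv(system.file("extdata", "published_reference_summary.csv",
                              package = "swayboard"),
                  stringsAsFactors = FALSE)
}
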