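#' AAL-90 node labels
#'
#' Returns the 90 cerebral region names of the Automated Anatomical
#' Labeling atlas (45 per hemisphere, odd indices left, even right), the
#' node ordering used throughout the package.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "wmhnet",
                      mustWork = TRUE)
  readLines(path)
}

#' Published per-threshold global network metrics
#'
#' Reference table of whole-brain network attributes (gamma, lambda,
#' sigma, Cp, Lp, Eglob, Eloc) reported for two WMH-severity groups of a
#' cerebral small vessel disease cohort at sparsity thresholds 0.05-0.40.
#' Used to validate the across-threshold summary convention: the
#' arithmetic mean of the eight per-threshold values reproduces the
#' published summary figures (to their printed precision).
#'
#' @param summary logical; if `TRUE` return the published across-threshold
#'   summary figures instead of the per-threshold table.
#' @return A data frame with columns `metric`, `sparsity`, `group_a`,
#'   `group_b` (or `metric`, `mean_a`, `mean_b`, `digits` for the summary).
#' @export
#' @examples
#' ref <- reference_global_metrics()
#' aggregate(group_a ~ metric, ref, mean)
reference_global_metrics <- function(summary = FALSE) {
  file <- if (summary) "reference_global_summary.csv" else
    "reference_global_metrics.csv"
  path <- system.file("extdata", file, package = "wmhnet", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
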