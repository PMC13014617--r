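#' Scoring configuration
#'
#' Bundles the tunable parameters of the association-scoring pipeline. The
#' defaults reproduce the filtering rules used throughout the package: a
#' disease is scored only when both cohorts contain at least
#' \code{min_group_samples} samples, scoring is restricted to the
#' \code{n_top_microbes} species with the largest absolute change in median
#' relative abundance, and a confidence p-value is attached only when at least
#' \code{min_producers} producing species enter the paired t-test.
#'
#' @param n_top_microbes Number of top species (ranked by absolute change in
#'   median relative abundance) retained per disease before scoring.
#' @param min_group_samples Minimum number of samples required in each of the
#'   disease and healthy cohorts for a disease to be scored.
#' @param min_producers Minimum number of producing species required before a
#'   paired t-test p-value is attached to a record. The score itself is still
#'   reported for smaller producer sets.
#' @param alpha Significance level applied to confidence p-values.
#' @param fdr_threshold Benjamini-Hochberg FDR threshold for significance.
#' @param per_disease_top Number of top-ranked metabolites reported per disease
#'   by the candidate-selection functions.
#' @param fdr_scope Family over which the Benjamini-Hochberg adjustment is
#'   applied: \code{"global"} (all defined p-values in the run) or
#'   \code{"per_disease"}.
#'
#' @return An object of class \code{"scoring_config"}: a named list of the
#'   validated parameters.
#' @examples
#' scoring_config()
#' scoring_config(n_top_microbes = 50, fdr_scope = "per_disease")
#' @export
scoring_config <- function(n_top_microbes = 100L,
                           min_group_samples = 5L,
                           min_producers = 3L,
                           alpha = 0.05,
                           fdr_threshold = 0.1,
                           per_disease_top = 5L,
                           fdr_scope = c("global", "per_disease")) {
  fdr_scope <- match.arg(fdr_scope)
  n_top_microbes <- as.integer(n_top_microbes)
  min_group_samples <- as.integer(min_group_samples)
  min_producers <- as.integer(min_producers)
  per_disease_top <- as.integer(per_disease_top)
  stopifnot(
    length(n_top_microbes) == 1L, n_top_microbes >= 1L,
    length(min_group_samples) == 1L, min_group_samples >= 1L,
    length(min_producers) == 1L, min_producers >= 1L,
    length(per_disease_top) == 1L, per_disease_top >= 1L,
    length(alpha) == 1L, is.finite(alpha), alpha > 0, alpha < 1,
    length(fdr_threshold) == 1L, is.finite(fdr_threshold),
    fdr_threshold > 0, fdr_threshold < 1
  )
  structure(
    list(
      n_top_microbes = n_top_microbes,
      min_group_samples = min_group_samples,
      min_producers = min_producers,
      alpha = alpha,
      fdr_threshold = fdr_threshold,
      per_disease_top = per_disease_top,
      fdr_scope = fdr_scope
    ),
    class = "scoring_config"
  )
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("Scoring configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
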