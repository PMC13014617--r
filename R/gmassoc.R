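#' Fit disease-metabolite association scores
#'
#' The package's central fitting function. Takes microbial relative-abundance
#' data (per-sample, or already summarized to cohort medians) together with a
#' taxon-to-metabolite production map, and returns every disease-metabolite
#' association record: the abundance-integrated score, the number of
#' contributing producer species, the paired t-test confidence p-value, its
#' Benjamini-Hochberg FDR, and a normality diagnostic on the paired
#' differences.
#'
#' Per-sample input is first collapsed to per-cohort medians with
#' [summarize_medians()]. Strain-level production maps are collapsed to
#' species rank via \code{strain_map}. Scoring then proceeds as documented in
#' [score_all_pairs()], and confidence fields are attached over the retained
#' producer species, so score sign and test direction agree by construction.
#'
#' @param data Either a per-sample abundance table (columns \code{cohort},
#'   \code{disease_id}, \code{sample_id}, \code{species_id},
#'   \code{relative_abundance}) or a cohort abundance summary (columns
#'   \code{disease_id}, \code{species_id}, \code{median_disease},
#'   \code{median_healthy}, \code{n_disease}, \code{n_healthy}).
#' @param production Production map data.frame (\code{taxon_id},
#'   \code{taxon_rank}, \code{metabolite_id}).
#' @param config A [scoring_config()].
#' @param strain_map Optional strain-to-species mapping, required when
#'   \code{production} contains strain-rank taxa.
#' @return An object of class \code{"gmassoc"}: a list with components
#'   \code{records} (the association table), \code{summary} (the cohort
#'   medians scored), \code{config}, \code{filter_log} and \code{call}.
#' @examples
#' sim <- generate_cohort(simulation_spec(n_species = 20, n_metabolites = 5,
#'                                        n_samples_disease = 6,
#'                                        n_samples_healthy = 6, seed = 7))
#' fit <- gmassoc(sim$samples, sim$production)
#' fit
#' head(coef(fit))
#' @seealso [select_beneficial()], [select_biomarkers()],
#'   [direction_consistency()], [build_disease_metabolite_network()]
#' @export
gmassoc <- function(data, production, config = scoring_config(),
                    strain_map = NULL) {
  stopifnot(inherits(config, "scoring_config"))
  if (all(c("cohort", "sample_id", "relative_abundance") %in% names(data))) {
    summary <- summarize_medians(data)
  } else {
    summary <- validate_abundance_summary(data)
  }
  production <- validate_production_map(production)
  if (any(production$taxon_rank == "strain")) {
    if (is.null(strain_map)) {
      stop("production map contains strain-rank taxa; supply strain_map",
           call. = FALSE)
    }
    production <- collapse_to_species(production, strain_map)
  }
  records <- score_all_pairs(summary, production, config)
  filter_log <- attr(records, "filter_log")
  records <- attach_confidence(records, summary, config)
  attr(records, "filter_log") <- NULL
  structure(
    list(records = records, summary = summary, config = config,
         filter_log = filter_log, call = match.call()),
    class = "gmassoc")
}

#' @export
print.gmassoc <- function(x, ...) {
  r <- x$records
  sig <- significant_idx(r, x$config)
  cat("Disease-metabolite association fit\n")
  cat(sprintf("  diseases scored:      %d of %d (%d below sample-size threshold)\n",
              x$filter_log$n_diseases_scored, x$filter_log$n_diseases_in,
              x$filter_log$n_diseases_dropped_sample_size))
  cat(sprintf("  association records:  %d (%d metabolites)\n",
              nrow(r), length(unique(r$metabolite_id))))
  cat(sprintf("  defined p-values:     %d\n", sum(!is.na(r$p_value))))
  cat(sprintf("  significant (p < %g, FDR < %g): %d\n",
              x$config$alpha, x$config$fdr_threshold, sum(sig)))
  invisible(x)
}

# row indices of records passing the significance thresholds
significant_idx <- function(records, config) {
  !is.na(records$p_value) & !is.na(records$fdr) &
    records$p_value < config$alpha & records$fdr < config$fdr_threshold
}

#' @export
summary.gmassoc <- function(object, ...) {
  r <- object$records
  sig <- significant_idx(r, object$config)
  per_disease <- do.call(rbind, lapply(split(seq_len(nrow(r)), r$disease_id),
    function(idx) {
      data.frame(
        disease_id = r$disease_id[idx[1L]],
        n_records = length(idx),
        n_significant = sum(sig[idx]),
        min_score = min(r$score[idx]),
        max_score = max(r$score[idx]),
        stringsAsFactors = FALSE)
    }))
  rownames(per_disease) <- NULL
  structure(list(per_disease = per_disease, config = object$config,
                 n_records = nrow(r), n_significant = sum(sig)),
            class = "summary.gmassoc")
}

#' @export
print.summary.gmassoc <- function(x, ...) {
  cat(sprintf("gmassoc fit: %d records, %d significant (p < %g, FDR < %g)\n",
              x$n_records, x$n_significant, x$config$alpha,
              x$config$fdr_threshold))
  print(x$per_disease, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gmassoc <- function(object, ...) {
  stats::setNames(object$records$score,
                  paste(object$records$disease_id,
                        object$records$metabolite_id, sep = ":"))
}

#' @export
as.data.frame.gmassoc <- function(x, ...) {
  x$records
}

#' Volcano-style plot of an association fit
#'
#' Plots each record's score against \eqn{-\log_{10}} of its confidence
#' p-value; records passing both significance thresholds are filled. Records
#' without a defined p-value (too few producers, or degenerate differences)
#' are omitted.
#'
#' @param x A \code{"gmassoc"} fit.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.gmassoc <- function(x, ...) {
  r <- x$records[!is.na(x$records$p_value), , drop = FALSE]
  if (!nrow(r)) {
    stop("no records with defined p-values to plot", call. = FALSE)
  }
  sig <- significant_idx(r, x$config)
  graphics::plot(r$score, -log10(r$p_value),
                 pch = ifelse(sig, 19, 1),
                 xlab = "association score (D - H, summed over producers)",
                 ylab = expression(-log[10]~p), ...)
  graphics::abline(v = 0, lty = 3)
  graphics::abline(h = -log10(x$config$alpha), lty = 3)
  invisible(x)
}

#' Write an association table to TSV
#'
#' @param x A \code{"gmassoc"} fit or its record data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_associations <- function(x, path) {
  r <- if (inherits(x, "gmassoc")) x$records else x
  write_tsv(r, path)
}

#' Read an association table written by [write_associations()]
#'
#' @param path Path to the TSV.
#' @return The record data.frame with numeric columns restored.
#' @export
read_associations <- function(path) {
  df <- read_tsv_raw(path, c("disease_id", "metabolite_id", "score",
                             "k_producers", "direction",
                             "contributing_species", "t_statistic",
                             "p_value", "fdr", "normality_p", "normality_ok"))
  for (col in c("score", "t_statistic", "p_value", "fdr", "normality_p")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$k_producers <- as.integer(df$k_producers)
  df$normality_ok <- as.logical(df$normality_ok)
  df
}
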