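# Candidate nomination: beneficial (depleted, therefore supplementation
# candidates) and biomarker (large |score| of either sign) metabolites.

records_from <- function(x) {
  if (inherits(x, "gmassoc")) return(x$records)
  stopifnot(is.data.frame(x))
  x
}

#' Nominate beneficial metabolite candidates
#'
#' Within each disease, keeps records that are significantly depleted in the
#' disease state — score < 0, p-value below \code{alpha} and FDR below
#' \code{fdr_threshold} — sorts them by score ascending (most negative first)
#' and returns at most \code{per_disease_top} per disease with 1-based ranks.
#' Metabolites depleted in patients are candidates for supplementation
#' therapy. Ties in score are broken by \code{metabolite_id} ascending.
#'
#' @param x A \code{"gmassoc"} fit, or any data.frame with columns
#'   \code{disease_id} (or \code{disease}), \code{metabolite_id} (or
#'   \code{metabolite}), \code{score}, \code{p_value}, \code{fdr}.
#' @param config A [scoring_config()] supplying the thresholds.
#' @return A \code{data.frame} with columns \code{disease_id},
#'   \code{metabolite_id}, \code{score}, \code{p_value}, \code{fdr} and
#'   \code{rank_within_disease}, sorted by (disease_id, rank). Possibly empty.
#' @examples
#' select_beneficial(load_beneficial_reference())
#' @export
select_beneficial <- function(x, config = scoring_config()) {
  r <- normalize_call_columns(records_from(x))
  keep <- !is.na(r$p_value) & !is.na(r$fdr) &
    r$score < 0 & r$p_value < config$alpha & r$fdr < config$fdr_threshold
  r <- r[keep, , drop = FALSE]
  out <- lapply(split(r, r$disease_id), function(sub) {
    sub <- sub[order(sub$score, sub$metabolite_id), , drop = FALSE]
    sub <- sub[seq_len(min(nrow(sub), config$per_disease_top)), , drop = FALSE]
    sub$rank_within_disease <- seq_len(nrow(sub))
    sub
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(disease_id = character(0), metabolite_id = character(0),
                      score = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), rank_within_disease = integer(0))
  }
  res <- res[order(res$disease_id, res$rank_within_disease), , drop = FALSE]
  cols <- c("disease_id", "metabolite_id", "score", "p_value", "fdr",
            "rank_within_disease")
  res <- res[cols]
  rownames(res) <- NULL
  res
}

#' Nominate biomarker candidates
#'
#' Within each disease, ranks significant records (p-value below \code{alpha},
#' FDR below \code{fdr_threshold}) by absolute score descending — either sign
#' qualifies, since strongly enriched and strongly depleted metabolites are
#' both informative markers — and returns the top \code{top_k} per disease.
#' Ties in absolute score are broken by \code{metabolite_id} ascending.
#'
#' @inheritParams select_beneficial
#' @param top_k Number of candidates reported per disease.
#' @return A \code{data.frame} with columns \code{disease_id},
#'   \code{metabolite_id}, \code{score}, \code{p_value}, \code{fdr} and
#'   \code{abs_rank_within_disease}, sorted by (disease_id, rank).
#' @export
select_biomarkers <- function(x, config = scoring_config(), top_k = 5L) {
  r <- normalize_call_columns(records_from(x))
  keep <- !is.na(r$p_value) & !is.na(r$fdr) &
    r$p_value < config$alpha & r$fdr < config$fdr_threshold
  r <- r[keep, , drop = FALSE]
  out <- lapply(split(r, r$disease_id), function(sub) {
    sub <- sub[order(-abs(sub$score), sub$metabolite_id), , drop = FALSE]
    sub <- sub[seq_len(min(nrow(sub), top_k)), , drop = FALSE]
    sub$abs_rank_within_disease <- seq_len(nrow(sub))
    sub
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(disease_id = character(0), metabolite_id = character(0),
                      score = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), abs_rank_within_disease = integer(0))
  }
  res <- res[order(res$disease_id, res$abs_rank_within_disease), , drop = FALSE]
  cols <- c("disease_id", "metabolite_id", "score", "p_value", "fdr",
            "abs_rank_within_disease")
  res <- res[cols]
  rownames(res) <- NULL
  res
}

# Accept the packaged reference table's column names as synonyms.
normalize_call_columns <- function(r) {
  if (!"disease_id" %in% names(r) && "disease" %in% names(r)) {
    r$disease_id <- r$disease
  }
  if (!"metabolite_id" %in% names(r) && "metabolite" %in% names(r)) {
    r$metabolite_id <- r$metabolite
  }
  required <- c("disease_id", "metabolite_id", "score", "p_value", "fdr")
  missing <- setdiff(required, names(r))
  if (length(missing)) {
    stop("record table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r
}
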