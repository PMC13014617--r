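# Direction-consistency benchmarking of computed scores against
# literature-reported disease-metabolite change directions.

#' Direction consistency against literature labels
#'
#' Compares the sign of each computed association score with the
#' literature-reported change direction of the same disease-metabolite pair.
#' The predicted direction is \code{decreased} for score < 0 and
#' \code{increased} for score > 0; a zero score makes no direction claim and
#' counts as inconsistent with either label (silently excluding it would
#' inflate consistency). Truth pairs with no computed record are excluded from
#' the denominator and listed separately as unevaluated.
#'
#' @param x A \code{"gmassoc"} fit or a record data.frame with columns
#'   \code{disease_id}, \code{metabolite_id}, \code{score} (and, when
#'   \code{require_significant = TRUE}, \code{p_value} and \code{fdr}).
#' @param truth Validation table: columns \code{disease_id},
#'   \code{metabolite_id}, \code{direction} (\code{increased} or
#'   \code{decreased}) and \code{evidence_id}. Duplicate pairs are an error.
#' @param require_significant Restrict evaluation to records passing the
#'   significance thresholds in \code{config}.
#' @param config A [scoring_config()] supplying the thresholds.
#' @return An object of class \code{"consistency_report"}: a list with
#'   \code{n_evaluated}, \code{n_consistent}, \code{consistency_percent},
#'   \code{per_pair} (one row per evaluated pair) and \code{unevaluated}
#'   (truth pairs without a usable record).
#' @examples
#' rec <- data.frame(disease_id = "d1", metabolite_id = c("m1", "m2"),
#'                   score = c(-0.2, 0.1))
#' truth <- data.frame(disease_id = "d1", metabolite_id = c("m1", "m2"),
#'                     direction = c("decreased", "increased"),
#'                     evidence_id = "x")
#' direction_consistency(rec, truth)
#' @export
direction_consistency <- function(x, truth, require_significant = FALSE,
                                  config = scoring_config()) {
  r <- records_from(x)
  truth <- validate_validation_set(truth)
  if (require_significant) {
    r <- r[significant_idx(r, config), , drop = FALSE]
  }
  rkey <- paste(r$disease_id, r$metabolite_id, sep = "\r")
  tkey <- paste(truth$disease_id, truth$metabolite_id, sep = "\r")
  idx <- match(tkey, rkey)
  hit <- !is.na(idx)
  per_pair <- data.frame(
    disease_id = truth$disease_id[hit],
    metabolite_id = truth$metabolite_id[hit],
    score = r$score[idx[hit]],
    predicted_direction = score_direction(r$score[idx[hit]]),
    literature_direction = truth$direction[hit],
    stringsAsFactors = FALSE)
  per_pair$consistent <-
    per_pair$predicted_direction == per_pair$literature_direction
  n_eval <- nrow(per_pair)
  n_cons <- sum(per_pair$consistent)
  structure(
    list(n_evaluated = n_eval,
         n_consistent = n_cons,
         consistency_percent = if (n_eval > 0) 100 * n_cons / n_eval else NA_real_,
         per_pair = per_pair,
         unevaluated = truth[!hit, , drop = FALSE],
         require_significant = require_significant),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Direction consistency: %d/%d evaluated pairs consistent (%.2f%%); %d unevaluated%s\n",
    x$n_consistent, x$n_evaluated,
    if (is.na(x$consistency_percent)) NA_real_ else x$consistency_percent,
    nrow(x$unevaluated),
    if (x$require_significant) " [significant records only]" else ""))
  invisible(x)
}

#' Write a consistency report to TSV
#'
#' Writes the per-pair table; unevaluated truth pairs are appended with an
#' \code{NA} score and \code{predicted_direction} \code{"unevaluated"}.
#'
#' @param report A \code{"consistency_report"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_consistency_report <- function(report, path) {
  stopifnot(inherits(report, "consistency_report"))
  pp <- report$per_pair
  if (nrow(report$unevaluated)) {
    extra <- data.frame(
      disease_id = report$unevaluated$disease_id,
      metabolite_id = report$unevaluated$metabolite_id,
      score = NA_real_, predicted_direction = "unevaluated",
      literature_direction = report$unevaluated$direction,
      consistent = NA, stringsAsFactors = FALSE)
    pp <- rbind(pp, extra)
  }
  write_tsv(pp, path)
}

#' Sweep scoring configurations against a validation set
#'
#' Re-runs the full pipeline (top-species selection, scoring, confidence,
#' direction consistency) for each configuration in a grid, reporting the
#' consistency achieved by each. Useful for examining how the sample-size
#' threshold and top-species cut shape agreement with literature labels.
#'
#' @param summary Cohort abundance summary.
#' @param map Species-rank production map.
#' @param truth Validation table (see [direction_consistency()]).
#' @param grid List of [scoring_config()] objects.
#' @param require_significant Passed to [direction_consistency()].
#' @return A \code{data.frame} with one row per configuration: the
#'   configuration fields plus \code{consistency_percent} and
#'   \code{n_evaluated}.
#' @export
config_sweep <- function(summary, map, truth, grid,
                         require_significant = FALSE) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  rows <- lapply(grid, function(cfg) {
    stopifnot(inherits(cfg, "scoring_config"))
    fit <- gmassoc(summary, map, config = cfg)
    rep <- direction_consistency(fit, truth,
                                 require_significant = require_significant,
                                 config = cfg)
    data.frame(n_top_microbes = cfg$n_top_microbes,
               min_group_samples = cfg$min_group_samples,
               min_producers = cfg$min_producers,
               alpha = cfg$alpha, fdr_threshold = cfg$fdr_threshold,
               per_disease_top = cfg$per_disease_top,
               fdr_scope = cfg$fdr_scope,
               consistency_percent = rep$consistency_percent,
               n_evaluated = rep$n_evaluated,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
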