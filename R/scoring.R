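# Association-strength scoring. For a disease-metabolite pair the score is
#   sum_i (D_i - H_i) * m_i
# over the disease's retained species, where D_i/H_i are the median relative
# abundances of species i in the disease and healthy cohorts and m_i indicates
# whether species i produces the metabolite. A negative score predicts the
# metabolite is depleted in disease, a positive one that it is enriched.

#' Species with the largest abundance change in a disease
#'
#' Ranks the species profiled for one disease by the absolute change in median
#' relative abundance, \eqn{|D_i - H_i|}, and returns the top \code{n_top}.
#' Ties competing for the last slot are broken by \code{species_id} ascending
#' so the selection is deterministic.
#'
#' @param summary A cohort abundance summary (see [summarize_medians()]).
#' @param disease_id Disease to rank species for; must be present in
#'   \code{summary}.
#' @param n_top Number of species to retain; all species when fewer are
#'   profiled.
#' @return Character vector of retained \code{species_id}s, sorted by
#'   decreasing absolute change.
#' @export
select_top_changed_species <- function(summary, disease_id, n_top = 100L) {
  summary <- validate_abundance_summary(summary)
  sub <- summary[summary$disease_id == disease_id, , drop = FALSE]
  if (!nrow(sub)) {
    stop("lookup error: unknown disease_id: ", disease_id, call. = FALSE)
  }
  delta <- abs(sub$median_disease - sub$median_healthy)
  ord <- order(-delta, sub$species_id)
  sub$species_id[ord][seq_len(min(n_top, nrow(sub)))]
}

#' Association-strength score of one disease-metabolite pair
#'
#' The raw score: the producer-masked sum of abundance differences,
#' \eqn{\sum_i (d_i - h_i) m_i}, summed left to right with no normalization.
#' Non-producing species carry mask 0 and cannot contribute, so irrelevant
#' microbes never interfere with the score.
#'
#' @param d,h Numeric vectors of disease and healthy median abundances over
#'   the same N species.
#' @param producer_mask 0/1 vector of length N flagging producers of the
#'   target metabolite.
#' @return The score, a single dimensionless real (difference of fractions).
#' @examples
#' association_score(c(0.30, 0.20, 0.10), c(0.10, 0.20, 0.30), c(1, 1, 0))
#' @export
association_score <- function(d, h, producer_mask) {
  if (length(d) != length(h) || length(d) != length(producer_mask)) {
    stop("dimension error: d, h and producer_mask must share one length",
         call. = FALSE)
  }
  if (!length(d)) {
    stop("dimension error: vectors must have length >= 1", call. = FALSE)
  }
  sum((d - h) * producer_mask)
}

score_direction <- function(score) {
  ifelse(score < 0, "decreased", ifelse(score > 0, "increased", "null"))
}

#' Score every disease-metabolite pair
#'
#' Applies the scoring rules across a cohort summary and a species-rank
#' production map. Per disease passing the sample-size filter (both cohorts at
#' least \code{min_group_samples}), scoring is restricted to that disease's
#' top \code{n_top_microbes} species by absolute median-abundance change; each
#' metabolite with at least one producer among the retained species yields one
#' record. Species are summed in \code{species_id}-ascending order so results
#' are byte-reproducible. Confidence fields are left undefined here; the
#' fitting front end [gmassoc()] attaches them.
#'
#' @param summary Cohort abundance summary.
#' @param map Species-rank production map (collapse strain-level maps with
#'   [collapse_to_species()] first).
#' @param config A [scoring_config()].
#' @return A \code{data.frame} of association records with columns
#'   \code{disease_id}, \code{metabolite_id}, \code{score},
#'   \code{k_producers}, \code{direction}, \code{contributing_species}
#'   (semicolon-joined), plus a \code{"filter_log"} attribute counting what
#'   the silent filters removed. Sorted by (disease_id, score ascending).
#' @export
score_all_pairs <- function(summary, map, config = scoring_config()) {
  summary <- validate_abundance_summary(summary)
  map <- validate_production_map(map)
  if (any(map$taxon_rank != "species")) {
    stop("production map contains strain-rank taxa; ",
         "collapse_to_species() first", call. = FALSE)
  }
  diseases <- sort(unique(summary$disease_id))
  producers_of <- split(map$taxon_id, map$metabolite_id)
  rows <- list()
  n_dropped_diseases <- 0L
  for (dz in diseases) {
    sub <- summary[summary$disease_id == dz, , drop = FALSE]
    nd <- max(sub$n_disease)
    nh <- max(sub$n_healthy)
    if (nd < config$min_group_samples || nh < config$min_group_samples) {
      n_dropped_diseases <- n_dropped_diseases + 1L
      next
    }
    retained <- select_top_changed_species(sub, dz, config$n_top_microbes)
    retained <- sort(retained)                # fixed summation order
    sub <- sub[match(retained, sub$species_id), , drop = FALSE]
    delta <- sub$median_disease - sub$median_healthy
    for (met in names(producers_of)) {
      producing <- intersect(retained, producers_of[[met]])
      if (!length(producing)) next
      mask <- as.numeric(retained %in% producing)
      score <- association_score(sub$median_disease, sub$median_healthy, mask)
      rows[[length(rows) + 1L]] <- data.frame(
        disease_id = dz, metabolite_id = met, score = score,
        k_producers = length(producing),
        direction = score_direction(score),
        contributing_species = paste(sort(producing), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else data.frame(
    disease_id = character(0), metabolite_id = character(0),
    score = numeric(0), k_producers = integer(0),
    direction = character(0), contributing_species = character(0),
    stringsAsFactors = FALSE)
  records <- records[order(records$disease_id, records$score,
                           records$metabolite_id), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "filter_log") <- list(
    n_diseases_in = length(diseases),
    n_diseases_scored = length(diseases) - n_dropped_diseases,
    n_diseases_dropped_sample_size = n_dropped_diseases,
    n_metabolites_in_map = length(producers_of),
    n_records = nrow(records))
  records
}
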