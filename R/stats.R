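# Confidence machinery for association scores: paired t-test across producing
# species, a Shapiro-Wilk normality diagnostic on the paired differences, and
# Benjamini-Hochberg FDR over the family of defined tests.

#' Paired-sample t-test on cohort median vectors
#'
#' Tests whether the per-species differences between disease and healthy
#' median abundances are centred at zero: equivalent to a one-sample t-test on
#' \code{d - h}, with the sample standard deviation (k-1 denominator), k-1
#' degrees of freedom and a two-sided p-value. Two-sided because both score
#' signs are interpreted (depletion and enrichment).
#'
#' @param d,h Numeric vectors of equal length k >= 2 (typically the disease
#'   and healthy median abundances of the producing species).
#' @return A list with \code{t_statistic}, \code{degrees_of_freedom} and
#'   \code{p_value}.
#' @section Errors: fewer than two pairs raises an insufficient-data error;
#'   identical differences (zero variance) raise a degenerate-variance error —
#'   the statistic is genuinely undefined there, and callers record the
#'   p-value as undefined rather than forcing 0 or 1.
#' @examples
#' paired_t_test(c(0.3, 0.4, 0.5, 0.6, 0.7), c(0.2, 0.2, 0.2, 0.2, 0.2))
#' @export
paired_t_test <- function(d, h) {
  if (length(d) != length(h)) {
    stop("dimension error: d and h must have equal length", call. = FALSE)
  }
  k <- length(d)
  if (k < 2L) {
    stop("insufficient data: paired t-test needs at least 2 pairs",
         call. = FALSE)
  }
  if (anyNA(d) || anyNA(h)) {
    stop("paired t-test input contains missing values", call. = FALSE)
  }
  diffs <- d - h
  if (diff(range(diffs)) == 0) {
    stop("degenerate variance: all paired differences are identical",
         call. = FALSE)
  }
  fit <- stats::t.test(d, h, paired = TRUE, alternative = "two.sided")
  list(t_statistic = unname(fit$statistic),
       degrees_of_freedom = unname(fit$parameter),
       p_value = unname(fit$p.value))
}

#' Shapiro-Wilk normality diagnostic on paired differences
#'
#' Screens the paired differences feeding a t-test for gross departure from
#' normality. The result is a logged diagnostic only: records failing it keep
#' their p-value and carry a flag, since gating records on a per-pair
#' normality test would silently change the record set.
#'
#' @param differences Numeric vector of paired differences.
#' @return A list with \code{w_statistic} and \code{p_value}; both \code{NA}
#'   when the diagnostic is unavailable (fewer than 3 or more than 5000
#'   values, or zero variance).
#' @export
shapiro_wilk <- function(differences) {
  n <- length(differences)
  if (n < 3L || n > 5000L || anyNA(differences) ||
      diff(range(differences)) == 0) {
    return(list(w_statistic = NA_real_, p_value = NA_real_))
  }
  fit <- stats::shapiro.test(differences)
  list(w_statistic = unname(fit$statistic), p_value = unname(fit$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, multiply by m/i, enforce
#' monotonicity from the largest rank down, cap at 1, and return in the input
#' order. Adjusted values are never smaller than the raw p-values.
#'
#' @param p_values Numeric vector of p-values in \eqn{[0,1]}. Undefined tests
#'   must be excluded by the caller before adjustment so they do not inflate
#'   the family size.
#' @return Adjusted values in the original order.
#' @examples
#' bh_fdr(c(0.005, 0.04, 0.9))
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("validation error: p-values must lie in [0,1] with no missing",
         call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# Fill t/p/normality/fdr fields of a record table produced by the scorer.
# Records with fewer than min_producers contributing species keep undefined
# confidence fields; degenerate t-tests likewise. The BH family is either all
# defined tests in the run (global) or per disease, per config$fdr_scope.
attach_confidence <- function(records, summary, config = scoring_config()) {
  summary <- validate_abundance_summary(summary)
  n <- nrow(records)
  records$t_statistic <- rep(NA_real_, n)
  records$p_value <- rep(NA_real_, n)
  records$fdr <- rep(NA_real_, n)
  records$normality_p <- rep(NA_real_, n)
  records$normality_ok <- rep(NA, n)
  if (!n) return(records)
  key <- paste(summary$disease_id, summary$species_id, sep = "\r")
  for (i in seq_len(n)) {
    if (records$k_producers[i] < config$min_producers) next
    sp <- sort(strsplit(records$contributing_species[i], ";",
                        fixed = TRUE)[[1L]])
    idx <- match(paste(records$disease_id[i], sp, sep = "\r"), key)
    d <- summary$median_disease[idx]
    h <- summary$median_healthy[idx]
    tt <- tryCatch(paired_t_test(d, h), error = function(e) NULL)
    if (!is.null(tt)) {
      records$t_statistic[i] <- tt$t_statistic
      records$p_value[i] <- tt$p_value
    }
    sw <- shapiro_wilk(d - h)
    records$normality_p[i] <- sw$p_value
    records$normality_ok[i] <- if (is.na(sw$p_value)) NA else sw$p_value > 0.05
  }
  defined <- which(!is.na(records$p_value))
  if (length(defined)) {
    if (config$fdr_scope == "per_disease") {
      for (dz in unique(records$disease_id[defined])) {
        fam <- defined[records$disease_id[defined] == dz]
        records$fdr[fam] <- bh_fdr(records$p_value[fam])
      }
    } else {
      records$fdr[defined] <- bh_fdr(records$p_value[defined])
    }
  }
  records
}
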