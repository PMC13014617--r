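# Tab-separated readers/writers and table validation.
# Dialect is fixed: UTF-8, tab separator, one header line, "." decimal mark —
# matching the export style of the public microbiome abundance repositories
# these tables mirror.

read_tsv_raw <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

parse_fraction <- function(x, what, rows = seq_along(x)) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop("validation error: ", what, " not parseable as a number at row ",
         paste(rows[bad][seq_len(min(5, length(bad)))], collapse = ", "),
         call. = FALSE)
  }
  out <- which(v < 0 | v > 1)
  if (length(out)) {
    stop("validation error: ", what, " outside [0,1] at row ",
         paste(rows[out][seq_len(min(5, length(out)))], collapse = ", "),
         call. = FALSE)
  }
  v
}

stop_if_duplicated <- function(keys, what) {
  dup <- which(duplicated(keys))
  if (length(dup)) {
    stop("validation error: duplicate ", what, " at row ",
         paste(dup[seq_len(min(5, length(dup)))], collapse = ", "),
         call. = FALSE)
  }
  invisible(NULL)
}

validate_sample_abundances <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("cohort", "disease_id", "sample_id", "species_id",
                "relative_abundance")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  bad <- which(!df$cohort %in% c("disease", "healthy"))
  if (length(bad)) {
    stop("validation error: cohort must be 'disease' or 'healthy' at row ",
         paste(bad[seq_len(min(5, length(bad)))], collapse = ", "),
         call. = FALSE)
  }
  df$relative_abundance <- parse_fraction(df$relative_abundance,
                                          "relative_abundance")
  stop_if_duplicated(
    paste(df$cohort, df$disease_id, df$sample_id, df$species_id, sep = "\r"),
    "(cohort, disease_id, sample_id, species_id)")
  dz <- unique(df$disease_id[df$cohort == "disease"])
  no_ctrl <- setdiff(dz, unique(df$disease_id[df$cohort == "healthy"]))
  if (length(no_ctrl)) {
    stop("validation error: disease cohort(s) without healthy controls: ",
         paste(no_ctrl, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a per-sample relative-abundance table
#'
#' Reads a tab-separated table with columns \code{cohort} (\code{"disease"} or
#' \code{"healthy"}), \code{disease_id}, \code{sample_id}, \code{species_id}
#' and \code{relative_abundance} (a fraction in \eqn{[0,1]}). Rows violating
#' the invariants (abundance out of range, duplicated keys, a disease cohort
#' without matching healthy controls) raise validation errors naming the
#' offending rows; nothing is silently dropped. Absent (species, sample)
#' combinations are interpreted downstream as abundance zero — sparse exports
#' that omit zero rows are therefore valid input.
#'
#' @param path Path to a tab-separated file.
#' @return A validated \code{data.frame} with the five columns above and
#'   numeric \code{relative_abundance}.
#' @seealso [summarize_medians()], [write_sample_abundances()]
#' @export
read_sample_abundances <- function(path) {
  df <- read_tsv_raw(path, c("cohort", "disease_id", "sample_id",
                             "species_id", "relative_abundance"))
  validate_sample_abundances(df)
}

#' @rdname read_sample_abundances
#' @param samples A validated sample-abundance table.
#' @export
write_sample_abundances <- function(samples, path) {
  write_tsv(validate_sample_abundances(samples), path)
}

#' Median relative abundance per cohort
#'
#' Collapses a per-sample abundance table to one row per (disease, species):
#' the median relative abundance across all samples of the disease cohort and
#' across all samples of the matched healthy cohort, together with the two
#' sample counts. A species absent from a given sample contributes abundance 0
#' to that sample's median — microbiome tables are sparse and routinely omit
#' zero rows, and the median is otherwise undefined over ragged supports. The
#' median of an even number of samples is the mean of the two central order
#' statistics.
#'
#' @param samples A per-sample table as returned by
#'   [read_sample_abundances()] (or any data.frame with the same columns).
#' @return A \code{data.frame} with columns \code{disease_id},
#'   \code{species_id}, \code{median_disease}, \code{median_healthy},
#'   \code{n_disease}, \code{n_healthy}, one row per (disease, species) pair
#'   seen in either cohort.
#' @examples
#' tab <- data.frame(
#'   cohort = c("disease", "disease", "disease", "healthy", "healthy"),
#'   disease_id = "d1", sample_id = c("s1", "s2", "s3", "c1", "c2"),
#'   species_id = "sp1",
#'   relative_abundance = c(0.1, 0.3, 0.2, 0.2, 0.2))
#' summarize_medians(tab)
#' @export
summarize_medians <- function(samples) {
  samples <- validate_sample_abundances(samples)
  if (!nrow(samples)) stop("sample table is empty", call. = FALSE)
  out <- lapply(sort(unique(samples$disease_id)), function(dz) {
    sub <- samples[samples$disease_id == dz, , drop = FALSE]
    dsub <- sub[sub$cohort == "disease", , drop = FALSE]
    hsub <- sub[sub$cohort == "healthy", , drop = FALSE]
    species <- sort(unique(sub$species_id))
    med <- function(csub) {
      n <- length(unique(csub$sample_id))
      if (n == 0L) {
        return(list(n = 0L, med = stats::setNames(rep(NA_real_,
                                                      length(species)),
                                                  species)))
      }
      m <- matrix(0, nrow = length(species), ncol = n,
                  dimnames = list(species, sort(unique(csub$sample_id))))
      m[cbind(match(csub$species_id, species),
              match(csub$sample_id, colnames(m)))] <- csub$relative_abundance
      list(n = n, med = apply(m, 1L, stats::median))
    }
    d <- med(dsub)
    h <- med(hsub)
    data.frame(disease_id = dz, species_id = species,
               median_disease = unname(d$med[species]),
               median_healthy = unname(h$med[species]),
               n_disease = d$n, n_healthy = h$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

validate_abundance_summary <- function(df) {
  required <- c("disease_id", "species_id", "median_disease",
                "median_healthy", "n_disease", "n_healthy")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("abundance summary missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  if (is.character(df$median_disease)) {
    df$median_disease <- parse_fraction(df$median_disease, "median_disease")
  }
  if (is.character(df$median_healthy)) {
    df$median_healthy <- parse_fraction(df$median_healthy, "median_healthy")
  }
  df$n_disease <- as.integer(df$n_disease)
  df$n_healthy <- as.integer(df$n_healthy)
  if (any(df$n_disease < 0L) || any(df$n_healthy < 0L)) {
    stop("validation error: negative sample count", call. = FALSE)
  }
  stop_if_duplicated(paste(df$disease_id, df$species_id, sep = "\r"),
                     "(disease_id, species_id)")
  rownames(df) <- NULL
  df
}

#' Read or write a cohort abundance summary
#'
#' The summary table holds, per (disease, species), the median relative
#' abundance in the disease and healthy cohorts and the two sample counts —
#' the quantities the association score is computed from. Pre-summarized
#' exports (e.g. repository downloads of per-phenotype medians) can be fed to
#' the scorer directly through this reader.
#'
#' @param path Path to a tab-separated file with columns \code{disease_id},
#'   \code{species_id}, \code{median_disease}, \code{median_healthy},
#'   \code{n_disease}, \code{n_healthy}.
#' @return A validated summary \code{data.frame}.
#' @export
read_abundance_summary <- function(path) {
  df <- read_tsv_raw(path, c("disease_id", "species_id", "median_disease",
                             "median_healthy", "n_disease", "n_healthy"))
  validate_abundance_summary(df)
}

#' @rdname read_abundance_summary
#' @param summary A validated summary table.
#' @export
write_abundance_summary <- function(summary, path) {
  write_tsv(validate_abundance_summary(summary), path)
}

validate_production_map <- function(df) {
  required <- c("taxon_id", "taxon_rank", "metabolite_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("production map missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- unique(df[required])
  bad <- which(!df$taxon_rank %in% c("strain", "species"))
  if (length(bad)) {
    stop("validation error: taxon_rank must be 'strain' or 'species' at row ",
         paste(bad[seq_len(min(5, length(bad)))], collapse = ", "),
         call. = FALSE)
  }
  ranks <- tapply(df$taxon_rank, df$taxon_id,
                  function(r) length(unique(r)))
  if (any(ranks > 1L)) {
    stop("validation error: inconsistent taxon_rank for taxon(s): ",
         paste(names(ranks)[ranks > 1L], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read or write a taxon-to-metabolite production map
#'
#' The production map is the binary relation behind the producer indicator of
#' the association score: a row \code{(taxon_id, taxon_rank, metabolite_id)}
#' states that the taxon produces the metabolite. Taxa may be recorded at
#' strain or species rank; [collapse_to_species()] folds strain-level rows to
#' species rank before scoring. Taxon identifiers are opaque strings (names or
#' taxonomy ids); no taxonomy service is consulted.
#'
#' @param path Path to a tab-separated file with columns \code{taxon_id},
#'   \code{taxon_rank} (\code{"strain"} or \code{"species"}) and
#'   \code{metabolite_id}.
#' @return A validated, de-duplicated \code{data.frame}.
#' @export
read_production_map <- function(path) {
  df <- read_tsv_raw(path, c("taxon_id", "taxon_rank", "metabolite_id"))
  validate_production_map(df)
}

#' @rdname read_production_map
#' @param map A validated production map.
#' @export
write_production_map <- function(map, path) {
  write_tsv(validate_production_map(map), path)
}

#' Collapse a strain-level production map to species rank
#'
#' Microbe-metabolite annotations are frequently curated at strain level while
#' abundance profiles are species-level; the score treats species abundance as
#' a proxy for its strains. This helper maps every strain to its species and
#' merges: a species produces a metabolite iff any of its strains does
#' (logical OR). Species-rank rows pass through unchanged, so re-collapsing is
#' a no-op.
#'
#' @param map A production map (see [read_production_map()]).
#' @param strain_to_species Named character vector (or two-column data.frame
#'   \code{strain_id}, \code{species_id}) mapping every strain-rank
#'   \code{taxon_id} in \code{map} to a species id.
#' @return A species-rank production map.
#' @examples
#' map <- data.frame(taxon_id = c("s1", "s2"), taxon_rank = "strain",
#'                   metabolite_id = c("M1", "M2"))
#' collapse_to_species(map, c(s1 = "SP", s2 = "SP"))
#' @export
collapse_to_species <- function(map, strain_to_species = NULL) {
  map <- validate_production_map(map)
  is_strain <- map$taxon_rank == "strain"
  if (!any(is_strain)) return(map)
  if (is.data.frame(strain_to_species)) {
    strain_to_species <- stats::setNames(
      as.character(strain_to_species[[2L]]),
      as.character(strain_to_species[[1L]]))
  }
  strains <- unique(map$taxon_id[is_strain])
  unmapped <- setdiff(strains, names(strain_to_species))
  if (length(unmapped)) {
    stop("unmapped strain taxon_id(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  map$taxon_id[is_strain] <- unname(strain_to_species[map$taxon_id[is_strain]])
  map$taxon_rank <- "species"
  out <- unique(map)
  out <- out[order(out$taxon_id, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a metabolite-gene association table
#'
#' @param path Tab-separated file with columns \code{metabolite_id},
#'   \code{gene_id}, \code{mode} (\code{activated}, \code{repressed} or
#'   \code{indeterminate}) and optional non-negative \code{strength}.
#' @return A validated \code{data.frame}; absent strengths are \code{NA}.
#' @export
read_gene_associations <- function(path) {
  df <- read_tsv_raw(path, c("metabolite_id", "gene_id", "mode", "strength"))
  validate_gene_associations(df)
}

validate_gene_associations <- function(df) {
  required <- c("metabolite_id", "gene_id", "mode")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("gene association table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$strength)) df$strength <- NA_real_
  df <- unique(df[c(required, "strength")])   # exact duplicate rows collapse
  bad <- which(!df$mode %in% c("activated", "repressed", "indeterminate"))
  if (length(bad)) {
    stop("validation error: mode must be activated/repressed/indeterminate",
         " at row ", paste(bad[seq_len(min(5, length(bad)))], collapse = ", "),
         call. = FALSE)
  }
  df$strength <- suppressWarnings(as.numeric(df$strength))
  if (any(df$strength < 0, na.rm = TRUE)) {
    stop("validation error: negative strength", call. = FALSE)
  }
  stop_if_duplicated(paste(df$metabolite_id, df$gene_id, sep = "\r"),
                     "(metabolite_id, gene_id)")
  rownames(df) <- NULL
  df
}

#' Read a literature direction-validation table
#'
#' Each row records the literature-reported change direction of a metabolite
#' in a disease, used by [direction_consistency()] to benchmark computed score
#' signs.
#'
#' @param path Tab-separated file with columns \code{disease_id},
#'   \code{metabolite_id}, \code{direction} (\code{increased} or
#'   \code{decreased}) and \code{evidence_id} (e.g. a PMID).
#' @return A validated \code{data.frame}.
#' @export
read_validation_set <- function(path) {
  df <- read_tsv_raw(path, c("disease_id", "metabolite_id", "direction",
                             "evidence_id"))
  validate_validation_set(df)
}

validate_validation_set <- function(df) {
  required <- c("disease_id", "metabolite_id", "direction", "evidence_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("validation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  bad <- which(!df$direction %in% c("increased", "decreased"))
  if (length(bad)) {
    stop("validation error: direction must be 'increased' or 'decreased'",
         " at row ", paste(bad[seq_len(min(5, length(bad)))], collapse = ", "),
         call. = FALSE)
  }
  stop_if_duplicated(paste(df$disease_id, df$metabolite_id, sep = "\r"),
                     "(disease_id, metabolite_id) in validation table")
  rownames(df) <- NULL
  df
}

#' Packaged reference set of literature-supported beneficial metabolites
#'
#' Loads the curated reference table shipped with the package: 48
#' disease-metabolite associations across 27 diseases for which published
#' animal or clinical intervention studies support a disease-ameliorating
#' role. Each row carries the association score, confidence p-value, FDR and
#' the supporting publication identifier. Every entry satisfies the beneficial
#' thresholds (score < 0, p < 0.05, FDR < 0.1); the loader verifies this and
#' the row count, and refuses to return a corrupted resource.
#'
#' @return A \code{data.frame} with columns \code{disease}, \code{metabolite},
#'   \code{score}, \code{p_value}, \code{fdr}, \code{pmid}.
#' @examples
#' ref <- load_beneficial_reference()
#' nrow(ref)
#' min(ref$score)
#' @export
load_beneficial_reference <- function() {
  path <- system.file("extdata", "beneficial_reference.tsv",
                      package = "micrometab", mustWork = TRUE)
  df <- read_tsv_raw(path, c("disease", "metabolite", "score", "p_value",
                             "fdr", "pmid"))
  df$score <- suppressWarnings(as.numeric(df$score))
  df$p_value <- suppressWarnings(as.numeric(df$p_value))
  df$fdr <- suppressWarnings(as.numeric(df$fdr))
  ok <- nrow(df) == 48L &&
    !anyNA(df$score) && !anyNA(df$p_value) && !anyNA(df$fdr) &&
    all(df$score < 0) && all(df$p_value < 0.05) && all(df$fdr < 0.1) &&
    !anyDuplicated(paste(df$disease, df$metabolite, sep = "\r"))
  if (!ok) {
    stop("integrity error: packaged beneficial reference table is corrupted",
         call. = FALSE)
  }
  df
}

validate_metabolite_annotations <- function(df) {
  required <- c("metabolite_id", "name")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metabolite annotation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (opt in c("formula", "smiles", "origins")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  }
  df <- df[c(required, "formula", "smiles", "origins")]
  stop_if_duplicated(df$metabolite_id, "metabolite_id in annotation table")
  known <- c("host", "microbiota", "food", "drug", "environment")
  origins <- strsplit(ifelse(is.na(df$origins), "", df$origins), ";",
                      fixed = TRUE)
  bad <- which(vapply(origins, function(o) any(!o %in% known), logical(1)))
  if (length(bad)) {
    stop("validation error: unknown origin category at row ",
         paste(bad[seq_len(min(5, length(bad)))], collapse = ", "),
         "; known categories: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a metabolite annotation table
#'
#' Pass-through annotations carried onto network nodes: identifier, display
#' name, optional molecular formula and SMILES string, and origin categories
#' (semicolon-separated subset of host, microbiota, food, drug, environment).
#'
#' @param path Tab-separated file with columns \code{metabolite_id},
#'   \code{name} and optionally \code{formula}, \code{smiles},
#'   \code{origins}.
#' @return A validated \code{data.frame}.
#' @export
read_metabolite_annotations <- function(path) {
  df <- read_tsv_raw(path, c("metabolite_id", "name"))
  full <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "", check.names = FALSE,
                            fileEncoding = "UTF-8")
  for (opt in intersect(c("formula", "smiles", "origins"), names(full))) {
    df[[opt]] <- full[[opt]]
  }
  validate_metabolite_annotations(df)
}
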