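sig_records <- function(disease, metabolite, score) {
  data.frame(disease_id = disease, metabolite_id = metabolite, score = score,
             p_value = 0.01, fdr = 0.02, stringsAsFactors = FALSE)
}

test_that("disease-metabolite network keeps top-|score| edges per disease", {
  r <- rbind(sig_records("d1", sprintf("a%d", 1:5), seq(-0.5, -0.1, 0.1)),
             sig_records("d2", sprintf("b%d", 1:5), seq(0.1, 0.5, 0.1)))
  net <- build_disease_metabolite_network(r, per_disease_top = 5)
  expect_equal(nrow(net$nodes), 12L)  # 2 diseases + 10 disjoint metabolites
  expect_equal(nrow(net$edges), 10L)
  expect_equal(net$edges$weight, abs(r$score[match(
    paste(net$edges$source, net$edges$target),
    paste(r$disease_id, r$metabolite_id))]))

  # shared metabolite gets degree 2
  r2 <- rbind(sig_records("d1", "shared", -0.3),
              sig_records("d2", "shared", 0.2))
  net2 <- build_disease_metabolite_network(r2)
  expect_equal(sum(net2$edges$target == "shared"), 2L)
  expect_equal(net2$edges$relation[order(net2$edges$source)], c("-", "+"))

  # records below the significance thresholds are excluded before topping
  r3 <- rbind(sig_records("d1", sprintf("m%d", 1:3), c(-0.5, -0.4, -0.3)),
              data.frame(disease_id = "d1", metabolite_id = "big",
                         score = -0.9, p_value = 0.2, fdr = 0.5))
  net3 <- build_disease_metabolite_network(r3, per_disease_top = 2)
  expect_equal(sort(net3$edges$target), c("m1", "m2"))
  expect_lte(nrow(net3$edges), 2 * 1)  # per_disease_top x retained diseases
})

test_that("metabolite node ranking uses mean incident |weight|", {
  r <- rbind(sig_records(c("d1", "d2"), "star", c(-0.3, 0.1)),
             sig_records("d3", "lone", -0.4))
  net <- build_disease_metabolite_network(r)
  rk <- rank_metabolite_nodes(net)
  expect_equal(rk$degree[rk$metabolite_id == "star"], 2L)
  expect_equal(rk$weighted_average_score[rk$metabolite_id == "star"], 0.2)
  # a low-degree node with strong edges can rank first
  expect_equal(rk$metabolite_id[1], "lone")

  # all weights equal: ranking falls back to degree then id
  r2 <- rbind(sig_records(c("d1", "d2"), "two", c(0.2, 0.2)),
              sig_records("d1", "one", -0.2))
  rk2 <- rank_metabolite_nodes(build_disease_metabolite_network(r2))
  expect_equal(rk2$metabolite_id, c("two", "one"))

  # insertion order does not matter
  shuffled <- r[c(3, 1, 2), ]
  expect_equal(rank_metabolite_nodes(
    build_disease_metabolite_network(shuffled)), rk)

  empty <- build_disease_metabolite_network(r[0, ])
  expect_equal(nrow(rank_metabolite_nodes(empty)), 0L)
})

test_that("metabolite-gene network flags genes shared by >= 2 metabolites", {
  assocs <- data.frame(
    metabolite_id = c("daidzein", "cholecalciferol", "daidzein"),
    gene_id = c("CASP3", "CASP3", "CYP2C9"),
    mode = c("repressed", "repressed", "activated"),
    strength = c(0.8, 0.6, NA))
  net <- build_metabolite_gene_network(assocs,
                                       c("daidzein", "cholecalciferol"))
  genes <- net$nodes[net$nodes$node_kind == "gene", ]
  expect_true(genes$shared_hub[genes$node_id == "CASP3"])
  expect_false(genes$shared_hub[genes$node_id == "CYP2C9"])
  expect_equal(sort(unique(net$edges$relation)), c("activated", "repressed"))

  # empty metabolite set -> empty network; duplicate rows collapse
  expect_equal(nrow(build_metabolite_gene_network(assocs,
                                                  character(0))$edges), 0L)
  dup <- rbind(assocs, assocs)
  expect_equal(nrow(build_metabolite_gene_network(dup[-6, ],
                                                  "daidzein")$edges), 2L)
})

test_that("network exports are deterministic and GraphML round-trips", {
  r <- rbind(sig_records("d1", c("m1", "m2"), c(-0.3, 0.2)),
             sig_records("d2", "m1", 0.15))
  net <- build_disease_metabolite_network(r)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_length(lines, 3L)
  expect_true(all(grepl("^\\S+\t[+-]\t\\S+$", lines)))

  one <- build_disease_metabolite_network(sig_records("d", "m", -0.1))
  one_sif <- withr::local_tempfile(fileext = ".sif")
  export_network(one, one_sif, format = "sif")
  expect_length(readLines(one_sif), 1L)

  gml1 <- withr::local_tempfile(fileext = ".graphml")
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml1, format = "graphml")
  export_network(net, gml2, format = "graphml")
  expect_identical(readLines(gml1), readLines(gml2))  # byte-identical

  back <- import_network(gml1)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$kind, net$kind)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, format = "tsv")
  df <- read.delim(tsv)
  expect_equal(nrow(df), nrow(net$edges))
  expect_true(all(c("source_kind", "target_kind", "weight") %in% names(df)))

  expect_error(export_network(net, tsv, format = "dot"))
})

test_that("metabolite annotations attach to network nodes and export", {
  ann <- data.frame(metabolite_id = c("m1", "m2"),
                    name = c("Alanine", "Butyrate"),
                    formula = c("C3H7NO2", NA),
                    smiles = c("CC(N)C(=O)O", NA),
                    origins = c("host;microbiota", "microbiota"))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_metabolite_annotations(path)
  expect_equal(back$origins, ann$origins)

  net <- build_disease_metabolite_network(
    sig_records("d1", c("m1", "m2"), c(-0.3, 0.2)))
  net <- annotate_metabolite_nodes(net, back)
  mets <- net$nodes[net$nodes$node_kind == "metabolite", ]
  expect_equal(mets$origins, c("host;microbiota", "microbiota"))
  expect_true(all(is.na(net$nodes$origins[net$nodes$node_kind == "disease"])))

  bad <- ann
  bad$origins[1] <- "mineral"
  expect_error(annotate_metabolite_nodes(net, bad), "unknown origin")
})
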