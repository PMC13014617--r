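# Weighted bipartite association networks (disease-metabolite and
# metabolite-gene) with Cytoscape-compatible export.

new_assoc_network <- function(nodes, edges, kind) {
  nodes <- nodes[order(nodes$node_kind, nodes$node_id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, kind = kind),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("Association network (%s): %d nodes, %d edges\n",
              x$kind, nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$node_kind))
  invisible(x)
}

#' Build the weighted disease-metabolite association network
#'
#' Keeps, per disease, the \code{per_disease_top} significant records with the
#' largest absolute score (either sign — the most strongly altered
#' metabolites, not only the depleted ones), and connects each retained
#' disease to its metabolites. Edge weight is the absolute score; edge sign
#' records the direction of the association ("+" enriched in disease, "-"
#' depleted). Ties in absolute score are broken by \code{metabolite_id}
#' ascending.
#'
#' @param x A \code{"gmassoc"} fit or a record data.frame with
#'   \code{disease_id}, \code{metabolite_id}, \code{score}, \code{p_value},
#'   \code{fdr}.
#' @param per_disease_top Edges retained per disease.
#' @param config A [scoring_config()] supplying the significance thresholds.
#' @return An object of class \code{"assoc_network"}: a list with a
#'   \code{nodes} table (\code{node_id}, \code{node_kind}) and an \code{edges}
#'   table (\code{source} = disease, \code{target} = metabolite,
#'   \code{weight}, \code{relation} = "+"/"-").
#' @export
build_disease_metabolite_network <- function(x, per_disease_top = 5L,
                                             config = scoring_config()) {
  r <- normalize_call_columns(records_from(x))
  r <- r[significant_idx(r, config), , drop = FALSE]
  kept <- lapply(split(r, r$disease_id), function(sub) {
    sub <- sub[order(-abs(sub$score), sub$metabolite_id), , drop = FALSE]
    sub[seq_len(min(nrow(sub), per_disease_top)), , drop = FALSE]
  })
  r <- do.call(rbind, kept)
  if (is.null(r) || !nrow(r)) {
    return(new_assoc_network(
      data.frame(node_id = character(0), node_kind = character(0)),
      data.frame(source = character(0), target = character(0),
                 weight = numeric(0), relation = character(0)),
      kind = "disease_metabolite"))
  }
  nodes <- rbind(
    data.frame(node_id = unique(r$disease_id), node_kind = "disease",
               stringsAsFactors = FALSE),
    data.frame(node_id = unique(r$metabolite_id), node_kind = "metabolite",
               stringsAsFactors = FALSE))
  edges <- data.frame(source = r$disease_id, target = r$metabolite_id,
                      weight = abs(r$score),
                      relation = ifelse(r$score >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  new_assoc_network(nodes, edges, kind = "disease_metabolite")
}

#' Rank metabolite nodes of a disease-metabolite network
#'
#' Summarizes each metabolite node by its connectivity (number of incident
#' disease edges) and its weighted average score — the mean of incident
#' absolute edge weights. The mean (rather than the sum) lets a low-degree
#' metabolite with strong associations outrank a high-degree one with weak
#' ones, while broadly connected metabolites with consistently strong edges
#' still rank highly. Sorted by weighted average score descending, ties broken
#' by degree descending then \code{metabolite_id}.
#'
#' @param net An \code{"assoc_network"} built by
#'   [build_disease_metabolite_network()].
#' @return A \code{data.frame} with columns \code{metabolite_id},
#'   \code{degree}, \code{mean_abs_weight} and \code{weighted_average_score}
#'   (the two statistics coincide under this definition and are both reported
#'   for clarity of downstream tables).
#' @export
rank_metabolite_nodes <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  e <- net$edges
  if (!nrow(e)) {
    return(data.frame(metabolite_id = character(0), degree = integer(0),
                      mean_abs_weight = numeric(0),
                      weighted_average_score = numeric(0)))
  }
  mets <- sort(unique(e$target))
  degree <- vapply(mets, function(m) sum(e$target == m), integer(1))
  meanw <- vapply(mets, function(m) mean(abs(e$weight[e$target == m])),
                  numeric(1))
  out <- data.frame(metabolite_id = mets, degree = unname(degree),
                    mean_abs_weight = unname(meanw),
                    weighted_average_score = unname(meanw),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weighted_average_score, -out$degree,
                   out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a metabolite-gene association network
#'
#' Restricts a metabolite-gene association table to a set of metabolites of
#' interest (typically candidates nominated for one disease group) and builds
#' the bipartite network. The interaction mode (activated, repressed,
#' indeterminate) is carried on edges; genes targeted by two or more of the
#' selected metabolites are flagged as shared hubs — convergence points where
#' several candidate metabolites may act on the same host gene.
#'
#' @param assocs Gene association table (see [read_gene_associations()]).
#' @param metabolites Character vector of metabolite ids to retain.
#' @return An \code{"assoc_network"} whose gene nodes carry a
#'   \code{shared_hub} flag.
#' @export
build_metabolite_gene_network <- function(assocs, metabolites) {
  assocs <- validate_gene_associations(assocs)
  a <- assocs[assocs$metabolite_id %in% metabolites, , drop = FALSE]
  if (!nrow(a)) {
    return(new_assoc_network(
      data.frame(node_id = character(0), node_kind = character(0),
                 shared_hub = logical(0)),
      data.frame(source = character(0), target = character(0),
                 weight = numeric(0), relation = character(0)),
      kind = "metabolite_gene"))
  }
  gene_deg <- table(a$gene_id)
  nodes <- rbind(
    data.frame(node_id = unique(a$metabolite_id), node_kind = "metabolite",
               shared_hub = FALSE, stringsAsFactors = FALSE),
    data.frame(node_id = names(gene_deg), node_kind = "gene",
               shared_hub = as.vector(gene_deg) >= 2L,
               stringsAsFactors = FALSE))
  edges <- data.frame(source = a$metabolite_id, target = a$gene_id,
                      weight = ifelse(is.na(a$strength), 1, a$strength),
                      relation = a$mode, stringsAsFactors = FALSE)
  new_assoc_network(nodes, edges, kind = "metabolite_gene")
}

#' Export an association network
#'
#' Writes a network in Cytoscape-compatible form. SIF emits one
#' \code{source TAB relation TAB target} line per edge; GraphML (via igraph)
#' carries node kinds and edge weight/relation as attributes and round-trips
#' losslessly through [import_network()]; TSV writes the edge list with node
#' kinds inline. Nodes and edges are written in sorted order, so two exports
#' of the same network are byte-identical.
#'
#' @param net An \code{"assoc_network"}.
#' @param path Output file path.
#' @param format One of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @return The path, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "assoc_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$relation,
                     net$edges$target)
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$nodes)
    igraph::graph_attr(g, "kind") <- net$kind
    igraph::write_graph(g, path, format = "graphml")
  } else {
    kind_of <- stats::setNames(net$nodes$node_kind, net$nodes$node_id)
    df <- data.frame(source = net$edges$source,
                     source_kind = unname(kind_of[net$edges$source]),
                     target = net$edges$target,
                     target_kind = unname(kind_of[net$edges$target]),
                     weight = net$edges$weight,
                     relation = net$edges$relation,
                     stringsAsFactors = FALSE)
    write_tsv(df, path)
  }
  invisible(path)
}

#' Import a GraphML network written by [export_network()]
#'
#' @param path Path to a GraphML file.
#' @return The reconstructed \code{"assoc_network"}.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(node_id = igraph::V(g)$name,
                      node_kind = igraph::V(g)$node_kind,
                      stringsAsFactors = FALSE)
  if ("shared_hub" %in% igraph::vertex_attr_names(g)) {
    nodes$shared_hub <- as.logical(igraph::V(g)$shared_hub)
  }
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(source = el$from, target = el$to,
                      weight = as.numeric(el$weight),
                      relation = el$relation, stringsAsFactors = FALSE)
  kind <- igraph::graph_attr(g, "kind")
  new_assoc_network(nodes, edges,
                    kind = if (is.null(kind)) "unknown" else kind)
}

#' Attach metabolite annotations to network nodes
#'
#' Carries the \code{name} and \code{origins} columns of an annotation table
#' onto the matching metabolite nodes, so exports (e.g. GraphML for
#' Cytoscape) can style nodes by origin. Unannotated metabolites keep
#' \code{NA}.
#'
#' @param net An \code{"assoc_network"}.
#' @param annotations Annotation table (see [read_metabolite_annotations()]).
#' @return The network with \code{name} and \code{origins} node columns.
#' @export
annotate_metabolite_nodes <- function(net, annotations) {
  stopifnot(inherits(net, "assoc_network"))
  annotations <- validate_metabolite_annotations(annotations)
  idx <- match(net$nodes$node_id, annotations$metabolite_id)
  idx[net$nodes$node_kind != "metabolite"] <- NA_integer_
  net$nodes$name <- annotations$name[idx]
  net$nodes$origins <- annotations$origins[idx]
  net
}
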