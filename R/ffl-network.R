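#' Assemble the typed tripartite regulatory network
#'
#' Combines calibrated TF-gene, miRNA-gene and miRNA-TF tables into one
#' directed network whose nodes are (role, id) pairs with roles `TF`, `mRNA`
#' and `miRNA`, and whose edges are typed `tf_mrna`, `mirna_mrna` and
#' `mirna_tf` by the table they came from. An identifier appearing under two
#' roles (e.g. a TF that is also in the mRNA list) is kept as two distinct
#' nodes — one per role — with a notice, so per-role node counts stay
#' additive.
#'
#' @param tf_gene data frame with columns `tf`, `gene`.
#' @param mir_gene data frame with columns `mirna`, `target` (mRNA arm).
#' @param mir_tf data frame with columns `mirna`, `target` (TF arm).
#' @return An object of class `regulatory_network`: a list with
#'   * `nodes`: data frame `role`, `id` (unique, sorted),
#'   * `edges`: data frame `source_role`, `source`, `target_role`, `target`,
#'     `edge_type`, deduplicated within each type.
#' @export
#' @examples
#' net <- assemble_network(
#'   tf_gene = data.frame(tf = "TF1", gene = "G1"),
#'   mir_gene = data.frame(mirna = "miR1", target = "G1"),
#'   mir_tf = data.frame(mirna = "miR1", target = "TF1"))
#' network_summary(net)
assemble_network <- function(tf_gene, mir_gene, mir_tf) {
  typed <- rbind(
    if (nrow(tf_gene)) data.frame(source_role = "TF", source = tf_gene$tf,
                                  target_role = "mRNA", target = tf_gene$gene,
                                  edge_type = "tf_mrna",
                                  stringsAsFactors = FALSE),
    if (nrow(mir_tf)) data.frame(source_role = "miRNA", source = mir_tf$mirna,
                                 target_role = "TF", target = mir_tf$target,
                                 edge_type = "mirna_tf",
                                 stringsAsFactors = FALSE),
    if (nrow(mir_gene)) data.frame(source_role = "miRNA",
                                   source = mir_gene$mirna,
                                   target_role = "mRNA",
                                   target = mir_gene$target,
                                   edge_type = "mirna_mrna",
                                   stringsAsFactors = FALSE)
  )
  if (is.null(typed)) {
    typed <- data.frame(source_role = character(0), source = character(0),
                        target_role = character(0), target = character(0),
                        edge_type = character(0), stringsAsFactors = FALSE)
  }
  typed <- unique(typed)
  typed <- typed[order(typed$edge_type, typed$source, typed$target), ,
                 drop = FALSE]
  rownames(typed) <- NULL

  nodes <- unique(rbind(
    data.frame(role = typed$source_role, id = typed$source,
               stringsAsFactors = FALSE),
    data.frame(role = typed$target_role, id = typed$target,
               stringsAsFactors = FALSE)
  ))
  nodes <- nodes[order(nodes$role, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  dual <- nodes$id[duplicated(nodes$id)]
  if (length(dual)) {
    message("ids appearing under more than one role kept as distinct nodes: ",
            paste(unique(dual), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = typed), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("regulatory_network: %d nodes ",
                     "(%d TF, %d mRNA, %d miRNA), %d edges ",
                     "(%d tf_mrna, %d mirna_tf, %d mirna_mrna)\n"),
              s$n_nodes, s$n_tf, s$n_mrna, s$n_mirna,
              s$n_edges, s$n_tf_mrna, s$n_mirna_tf, s$n_mirna_mrna))
  invisible(x)
}

#' Per-role and per-type network bookkeeping
#'
#' @param network a [assemble_network()] result.
#' @return A list of counts: `n_tf`, `n_mrna`, `n_mirna`, `n_nodes` (their
#'   sum), `n_tf_mrna`, `n_mirna_tf`, `n_mirna_mrna`, `n_edges` (their sum).
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  role <- function(r) sum(network$nodes$role == r)
  type <- function(t) sum(network$edges$edge_type == t)
  list(n_tf = role("TF"), n_mrna = role("mRNA"), n_mirna = role("miRNA"),
       n_nodes = nrow(network$nodes),
       n_tf_mrna = type("tf_mrna"), n_mirna_tf = type("mirna_tf"),
       n_mirna_mrna = type("mirna_mrna"), n_edges = nrow(network$edges))
}

#' Enumerate all three-node miRNA feed-forward loops
#'
#' A feed-forward loop is a triple (TF, gene, miRNA) whose three defining
#' edges — TF activates the gene, the miRNA represses the TF, the miRNA
#' represses the gene — are all present in the network. Enumeration joins the
#' miRNA-TF and miRNA-gene edge sets on the miRNA and intersects with the
#' TF-gene edge set, which is exactly the set of typed triangles of the
#' tripartite graph.
#'
#' @param network a [assemble_network()] result.
#' @return A data frame `tf`, `gene`, `mirna`, one row per motif, sorted by
#'   (tf, gene, mirna) with no duplicates.
#' @export
enumerate_ffls <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  tg <- e[e$edge_type == "tf_mrna", c("source", "target")]
  mt <- e[e$edge_type == "mirna_tf", c("source", "target")]
  mg <- e[e$edge_type == "mirna_mrna", c("source", "target")]
  names(tg) <- c("tf", "gene")
  names(mt) <- c("mirna", "tf")
  names(mg) <- c("mirna", "gene")
  if (!nrow(tg) || !nrow(mt) || !nrow(mg)) {
    return(data.frame(tf = character(0), gene = character(0),
                      mirna = character(0), stringsAsFactors = FALSE))
  }
  tri <- merge(merge(mt, mg, by = "mirna"), tg, by = c("tf", "gene"))
  tri <- unique(tri[c("tf", "gene", "mirna")])
  tri <- tri[order(tri$tf, tri$gene, tri$mirna), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

#' Degree centrality of every network node
#'
#' Degree is the number of incident edges (in-degree + out-degree over all
#' edge types, the raw degree a graph viewer would report). With
#' `normalized = TRUE`, degrees are divided by (total nodes - 1).
#'
#' @param network a [assemble_network()] result.
#' @param normalized divide by `n_nodes - 1`?
#' @return A named numeric vector over all nodes, names formatted
#'   `"<role>|<id>"`; isolated nodes score 0.
#' @export
degree_centrality <- function(network, normalized = FALSE) {
  stopifnot(inherits(network, "regulatory_network"))
  keys <- node_key(network$nodes$role, network$nodes$id)
  deg <- stats::setNames(numeric(length(keys)), keys)
  e <- network$edges
  endpoint_keys <- c(node_key(e$source_role, e$source),
                     node_key(e$target_role, e$target))
  counts <- table(endpoint_keys)
  deg[names(counts)] <- as.numeric(counts)
  if (normalized) {
    n <- nrow(network$nodes)
    if (n > 1L) deg <- deg / (n - 1L)
  }
  deg
}

#' Rank feed-forward loops by member degree centrality
#'
#' Each motif is scored by aggregating the degree centrality of its three
#' members — the sum by default (symmetric in the members and reducing to
#' node degree when motifs share members), or the maximum member degree with
#' `aggregate = "max"`. Motifs are sorted by descending score with
#' lexicographic (tf, gene, mirna) tie-breaking; the first row is the
#' predominant motif.
#'
#' @param ffls motif table from [enumerate_ffls()].
#' @param centrality named degree vector from [degree_centrality()]; every
#'   motif member must be present.
#' @param aggregate `"sum"` (default) or `"max"`.
#' @return `ffls` with added columns `deg_tf`, `deg_gene`, `deg_mirna`,
#'   `motif_score` and `rank`, sorted by rank.
#' @export
rank_motifs <- function(ffls, centrality, aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  if (!nrow(ffls)) {
    message("rank_motifs: no motifs to rank")
    return(cbind(ffls, deg_tf = numeric(0), deg_gene = numeric(0),
                 deg_mirna = numeric(0), motif_score = numeric(0),
                 rank = integer(0)))
  }
  need <- c(node_key("TF", ffls$tf), node_key("mRNA", ffls$gene),
            node_key("miRNA", ffls$mirna))
  if (!all(need %in% names(centrality))) {
    abort_invalid("centrality map is missing motif members")
  }
  out <- ffls
  out$deg_tf <- unname(centrality[node_key("TF", ffls$tf)])
  out$deg_gene <- unname(centrality[node_key("mRNA", ffls$gene)])
  out$deg_mirna <- unname(centrality[node_key("miRNA", ffls$mirna)])
  out$motif_score <- if (aggregate == "sum") {
    out$deg_tf + out$deg_gene + out$deg_mirna
  } else {
    pmax(out$deg_tf, out$deg_gene, out$deg_mirna)
  }
  out <- out[order(-out$motif_score, out$tf, out$gene, out$mirna), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export the network as an edge-list TSV
#'
#' Writes `source`, `target`, `edge_type` columns loadable by common graph
#' viewers (node roles are recoverable from the edge type).
#'
#' @param network a [assemble_network()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  utils::write.table(network$edges[c("source", "target", "edge_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
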