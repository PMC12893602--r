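#' Filter TF-gene interaction edges
#'
#' Keeps edges with a significance p-value strictly below `p_thresh` whose
#' target gene belongs to `allowed_genes` (typically the DE gene list). Both
#' conditions are read literally as strict inequalities / set membership.
#'
#' @param edges data frame `tf`, `gene`, `p_value`.
#' @param p_thresh strict significance threshold, default 0.05.
#' @param allowed_genes character vector of admissible target genes.
#' @return The retained rows; an empty result is allowed (a message is
#'   emitted).
#' @export
filter_tf_edges <- function(edges, p_thresh = 0.05, allowed_genes) {
  p_thresh <- check_prob(p_thresh, "p_thresh")
  out <- edges[edges$p_value < p_thresh & edges$gene %in% allowed_genes, ,
               drop = FALSE]
  if (!nrow(out)) message("filter_tf_edges: no edges retained")
  rownames(out) <- NULL
  out
}

# TRUE when the ;-joined region string denotes exactly the {3UTR} set
region_is_exclusive_3utr <- function(binding_region) {
  vapply(strsplit(binding_region, ";", fixed = TRUE),
         function(r) identical(sort(unique(trimws(r))), "3UTR"),
         logical(1))
}

#' Filter miRNA-target interaction edges
#'
#' Keeps edges whose prediction score is strictly above `score_thresh` and
#' whose binding-region set is exactly \{3'UTR\} — edges that additionally
#' bind the CDS or 5'UTR are dropped ("exclusively 3'UTR" is enforced as set
#' equality, not membership).
#'
#' @param edges data frame `mirna`, `target`, `target_role`, `score`,
#'   `binding_region` (`;`-joined region set).
#' @param score_thresh strict score threshold, default 0.95.
#' @param region_policy only `"exclusive_3utr"` is implemented.
#' @return The retained rows.
#' @export
filter_mir_edges <- function(edges, score_thresh = 0.95,
                             region_policy = "exclusive_3utr") {
  score_thresh <- check_prob(score_thresh, "score_thresh")
  region_policy <- match.arg(region_policy, "exclusive_3utr")
  out <- edges[edges$score > score_thresh &
                 region_is_exclusive_3utr(edges$binding_region), ,
               drop = FALSE]
  if (!nrow(out)) message("filter_mir_edges: no edges retained")
  rownames(out) <- NULL
  out
}

#' miRNAs repressing both an mRNA and a TF
#'
#' The feed-forward loop requires a miRNA that represses both arms; this
#' returns the miRNAs with at least one retained edge in each of the two
#' (already filtered) tables.
#'
#' @param mir_gene,mir_tf filtered miRNA-target tables restricted to
#'   `target_role == "mRNA"` and `"TF"` respectively.
#' @return Sorted character vector of common miRNA ids.
#' @export
common_mirnas <- function(mir_gene, mir_tf) {
  sort(intersect(unique(mir_gene$mirna), unique(mir_tf$mirna)))
}

#' Calibrate the three interaction tables to their mutually consistent core
#'
#' Iteratively restricts the TF-gene, miRNA-gene and miRNA-TF tables so that
#' every surviving edge can participate in at least one feed-forward loop
#' ingredient: miRNA edges are kept only for miRNAs hitting both arms
#' ([common_mirnas()]), miRNA-TF edges only for TFs still present in the
#' TF-gene table, and TF-gene edges only when both the TF and the gene are
#' repressed by at least one common miRNA. The restriction is repeated to a
#' fixed point (it is a monotone contraction, so at most one pass per removed
#' edge is needed); `single_pass = TRUE` stops after one round for
#' comparison. The full calibration ends with a triangle-support prune that
#' keeps exactly the edges participating in at least one feed-forward loop —
#' pruning to supported edges is stable after a single pass, because every
#' supporting triangle consists of supported edges. Outputs are sorted by
#' their key columns, so the result does not depend on input row order.
#'
#' @param tf_gene filtered TF-gene table (`tf`, `gene`, `p_value`).
#' @param mir_gene,mir_tf filtered miRNA-target tables (mRNA / TF arms).
#' @param single_pass if `TRUE`, perform one restriction round only.
#' @return A list `tf_gene`, `mir_gene`, `mir_tf` of calibrated tables
#'   (always subsets of the inputs; possibly empty, with a message).
#' @export
calibrate_pairs <- function(tf_gene, mir_gene, mir_tf, single_pass = FALSE) {
  repeat {
    sizes <- c(nrow(tf_gene), nrow(mir_gene), nrow(mir_tf))
    cm <- common_mirnas(mir_gene, mir_tf)
    mir_gene <- mir_gene[mir_gene$mirna %in% cm, , drop = FALSE]
    mir_tf <- mir_tf[mir_tf$mirna %in% cm &
                       mir_tf$target %in% tf_gene$tf, , drop = FALSE]
    tf_gene <- tf_gene[tf_gene$tf %in% mir_tf$target &
                         tf_gene$gene %in% mir_gene$target, , drop = FALSE]
    if (single_pass ||
        identical(c(nrow(tf_gene), nrow(mir_gene), nrow(mir_tf)), sizes)) {
      break
    }
  }
  if (!single_pass && nrow(tf_gene)) {
    # keep exactly the edges supported by >= 1 (tf, gene, mirna) triangle
    tri <- merge(merge(mir_tf[c("mirna", "target")],
                       stats::setNames(mir_gene[c("mirna", "target")],
                                       c("mirna", "gene")),
                       by = "mirna"),
                 stats::setNames(tf_gene[c("tf", "gene")], c("target", "gene")),
                 by = c("target", "gene"))
    names(tri)[names(tri) == "target"] <- "tf"
    tf_gene <- tf_gene[paste(tf_gene$tf, tf_gene$gene) %in%
                         paste(tri$tf, tri$gene), , drop = FALSE]
    mir_tf <- mir_tf[paste(mir_tf$mirna, mir_tf$target) %in%
                       paste(tri$mirna, tri$tf), , drop = FALSE]
    mir_gene <- mir_gene[paste(mir_gene$mirna, mir_gene$target) %in%
                           paste(tri$mirna, tri$gene), , drop = FALSE]
  }
  if (!nrow(tf_gene)) message("calibrate_pairs: empty fixed point")
  sort_by <- function(tab, cols) {
    out <- tab[do.call(order, tab[cols]), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(tf_gene = sort_by(tf_gene, c("tf", "gene")),
       mir_gene = sort_by(mir_gene, c("mirna", "target")),
       mir_tf = sort_by(mir_tf, c("mirna", "target")))
}
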