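minimal_net <- function() {
  assemble_network(
    tf_gene = data.frame(tf = "T1", gene = "G1", stringsAsFactors = FALSE),
    mir_gene = data.frame(mirna = "m1", target = "G1",
                          stringsAsFactors = FALSE),
    mir_tf = data.frame(mirna = "m1", target = "T1", stringsAsFactors = FALSE))
}

test_that("network assembly types nodes and edges and keeps counts additive", {
  net <- minimal_net()
  s <- network_summary(net)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$n_tf + s$n_mrna + s$n_mirna, s$n_nodes)
  expect_equal(s$n_tf_mrna + s$n_mirna_tf + s$n_mirna_mrna, s$n_edges)

  empty <- assemble_network(data.frame(tf = character(0), gene = character(0)),
                            data.frame(mirna = character(0),
                                       target = character(0)),
                            data.frame(mirna = character(0),
                                       target = character(0)))
  expect_equal(network_summary(empty)$n_nodes, 0L)
  expect_equal(network_summary(empty)$n_edges, 0L)
})

test_that("an id under two roles becomes two distinct nodes", {
  expect_message(
    net <- assemble_network(
      data.frame(tf = "X", gene = "G1"),
      data.frame(mirna = "m1", target = "X"),   # "X" also used as an mRNA id
      data.frame(mirna = "m1", target = "X")),
    "distinct nodes")
  s <- network_summary(net)
  expect_equal(s$n_tf, 1L)
  expect_equal(s$n_mrna, 2L)
  expect_equal(s$n_nodes, 4L)
})

test_that("duplicate input rows collapse to one edge", {
  net <- assemble_network(
    data.frame(tf = c("T1", "T1"), gene = c("G1", "G1")),
    data.frame(mirna = "m1", target = "G1"),
    data.frame(mirna = "m1", target = "T1"))
  expect_equal(network_summary(net)$n_tf_mrna, 1L)
})

test_that("FFL enumeration finds the minimal loop and loses it with any edge removed", {
  net <- minimal_net()
  ffls <- enumerate_ffls(net)
  expect_identical(ffls, data.frame(tf = "T1", gene = "G1", mirna = "m1",
                                    stringsAsFactors = FALSE))
  for (drop_type in c("tf_mrna", "mirna_tf", "mirna_mrna")) {
    broken <- net
    broken$edges <- net$edges[net$edges$edge_type != drop_type, , drop = FALSE]
    expect_equal(nrow(enumerate_ffls(broken)), 0L)
  }
})

test_that("complete tripartite input yields the full product of triples", {
  tabs <- generate_regulatory_tables(5, 10, 5, edge_prob = 1, planted = NULL,
                                     frac_passing = 1, seed = 13)
  mir <- filter_mir_edges(tabs$mir_targets)
  tg <- filter_tf_edges(tabs$tf_gene, allowed_genes = unique(tabs$tf_gene$gene))
  net <- assemble_network(tg, mir[mir$target_role == "mRNA", ],
                          mir[mir$target_role == "TF", ])
  expect_equal(nrow(enumerate_ffls(net)), 5L * 10L * 5L)
})

test_that("enumeration agrees with the brute-force triple loop on random instances", {
  for (s in 1:100) {
    draw <- withr::with_seed(s, list(size = sample(2:12, 3, replace = TRUE),
                                     p = runif(1, 0.1, 0.5)))
    tabs <- random_edge_tables(draw$size[1], draw$size[2], draw$size[3],
                               p = draw$p, seed = 3000 + s)
    net <- assemble_network(tabs$tf_gene, tabs$mir_gene, tabs$mir_tf)
    got <- enumerate_ffls(net)
    ref <- oracle_ffls(tabs$tf_gene, tabs$mir_gene, tabs$mir_tf)
    rownames(ref) <- NULL
    expect_equal(got, ref)
  }
})

test_that("degree centrality satisfies the handshake identity", {
  for (s in 1:10) {
    tabs <- random_edge_tables(6, 9, 7, p = 0.3, seed = 4000 + s)
    net <- assemble_network(tabs$tf_gene, tabs$mir_gene, tabs$mir_tf)
    deg <- degree_centrality(net)
    expect_equal(sum(deg), 2 * network_summary(net)$n_edges)
  }
  net <- minimal_net()
  deg <- degree_centrality(net)
  expect_equal(unname(deg["miRNA|m1"]), 2)
  # normalization divides by (n - 1)
  expect_equal(degree_centrality(net, normalized = TRUE),
               deg / (nrow(net$nodes) - 1))
  # isolated nodes score zero
  net$nodes <- rbind(net$nodes, data.frame(role = "mRNA", id = "lonely"))
  expect_equal(unname(degree_centrality(net)["mRNA|lonely"]), 0)
})

test_that("degree centrality matches igraph on a random network", {
  skip_if_not_installed("igraph")
  tabs <- random_edge_tables(8, 10, 9, p = 0.25, seed = 555)
  net <- assemble_network(tabs$tf_gene, tabs$mir_gene, tabs$mir_tf)
  e <- net$edges
  g <- igraph::graph_from_data_frame(data.frame(
    from = paste(e$source_role, e$source, sep = "|"),
    to = paste(e$target_role, e$target, sep = "|")))
  ig_deg <- igraph::degree(g, mode = "all")
  deg <- degree_centrality(net)
  expect_equal(deg[names(ig_deg)], ig_deg[names(ig_deg)])
})

test_that("motif ranking is deterministic and puts a single motif first", {
  net <- minimal_net()
  ffls <- enumerate_ffls(net)
  ranked <- rank_motifs(ffls, degree_centrality(net))
  expect_equal(ranked$rank, 1L)
  expect_equal(ranked$motif_score, 2 + 2 + 2)
  expect_equal(ranked$motif_score,
               ranked$deg_tf + ranked$deg_gene + ranked$deg_mirna)

  tabs <- random_edge_tables(6, 8, 7, p = 0.4, seed = 99)
  net2 <- assemble_network(tabs$tf_gene, tabs$mir_gene, tabs$mir_tf)
  ffls2 <- enumerate_ffls(net2)
  deg2 <- degree_centrality(net2)
  r1 <- rank_motifs(ffls2, deg2)
  shuffled <- withr::with_seed(1, ffls2[sample.int(nrow(ffls2)), ])
  r2 <- rank_motifs(shuffled, deg2)
  rownames(r2) <- NULL
  expect_equal(r1, r2)
  # max-member aggregation is exposed as a variant
  rmax <- rank_motifs(ffls2, deg2, aggregate = "max")
  expect_equal(rmax$motif_score,
               pmax(rmax$deg_tf, rmax$deg_gene, rmax$deg_mirna))
})

test_that("the planted hub motif is recovered as rank 1 in nearly all seeds", {
  hits <- 0L
  n_seeds <- 100L
  pl <- planted_motif("TF10", "G25", "miR15", extra_degree = 30)
  for (s in seq_len(n_seeds)) {
    tabs <- generate_regulatory_tables(40, 100, 50, edge_prob = 0.02,
                                       planted = pl, seed = 5000 + s)
    tg <- filter_tf_edges(tabs$tf_gene,
                          allowed_genes = unique(tabs$tf_gene$gene))
    mir <- filter_mir_edges(tabs$mir_targets)
    net <- assemble_network(tg, mir[mir$target_role == "mRNA", ],
                            mir[mir$target_role == "TF", ])
    ranked <- rank_motifs(enumerate_ffls(net), degree_centrality(net))
    if (nrow(ranked) &&
        identical(unlist(ranked[1, c("tf", "gene", "mirna")],
                         use.names = FALSE),
                  c("TF10", "G25", "miR15"))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("network edge lists round-trip through TSV export", {
  net <- minimal_net()
  path <- tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3L)
  expect_setequal(back$edge_type, c("tf_mrna", "mirna_tf", "mirna_mrna"))
})
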