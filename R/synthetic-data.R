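#' Generate a two-group log2 expression matrix with planted differential features
#'
#' Draws a features x samples matrix on the log2 scale as
#' `baseline + group shift + Gaussian noise`. A fraction `frac_de` of features
#' is planted as differentially expressed: their case-group mean is shifted by
#' `+effect` (up-regulated) or `-effect` (down-regulated), with the planted set
#' split as evenly as possible between the two directions. Per-feature
#' baselines are uniform on [4, 12], a typical dynamic range for log2
#' microarray intensities.
#'
#' @param n_features number of features (rows).
#' @param n_case,n_control samples per group; each must be at least 2.
#' @param frac_de fraction of features planted as differential, in [0, 1].
#' @param effect absolute planted shift in log2 units (case minus control).
#' @param sd standard deviation of the Gaussian noise (log2 units), > 0.
#' @param seed integer seed; identical parameters and seed give byte-identical
#'   output. The global RNG state is left untouched.
#' @param feature_prefix prefix for generated feature identifiers.
#' @param always_de optional character vector of feature ids forced into the
#'   planted (up-regulated) set regardless of the random draw.
#'
#' @return A list with
#'   * `matrix`: an [expression_matrix()] with case columns first,
#'   * `truth`: a data frame with one row per feature and columns
#'     `feature_id`, `is_de`, `true_log2fc`, `direction`
#'     (`"up"`, `"down"` or `"null"`).
#' @export
#' @examples
#' sim <- generate_expression(50, 5, 5, frac_de = 0.2, effect = 1, sd = 0.4,
#'                            seed = 7)
#' table(sim$truth$direction)
generate_expression <- function(n_features, n_case, n_control,
                                frac_de = 0.1, effect = 1, sd = 0.5, seed,
                                feature_prefix = "F", always_de = NULL) {
  n_features <- check_count(n_features, "n_features")
  n_case <- check_count(n_case, "n_case", min = 2L)
  n_control <- check_count(n_control, "n_control", min = 2L)
  frac_de <- check_prob(frac_de, "frac_de")
  sd <- check_positive(sd, "sd")
  seed <- check_seed(seed)
  if (!is.numeric(effect) || length(effect) != 1L || is.na(effect)) {
    abort_invalid("`effect` must be a single number (log2 units)")
  }

  ids <- paste0(feature_prefix, seq_len(n_features))
  if (!is.null(always_de) && !all(always_de %in% ids)) {
    abort_invalid("`always_de` contains ids outside the generated namespace")
  }

  withr::with_seed(seed, {
    n_de <- round(n_features * frac_de)
    de_idx <- if (n_de > 0L) sort(sample.int(n_features, n_de)) else integer(0)
    # forced features join the planted set (direction up)
    forced <- match(always_de, ids)
    de_idx <- sort(union(de_idx, forced))
    n_up <- ceiling(length(de_idx) / 2)
    up_pool <- setdiff(de_idx, forced)
    n_up_random <- max(0L, n_up - length(forced))
    up_idx <- sort(c(forced,
                     if (n_up_random > 0L && length(up_pool) > 0L)
                       sample_from(up_pool, min(n_up_random, length(up_pool)))
                     else integer(0)))
    down_idx <- setdiff(de_idx, up_idx)

    true_fc <- numeric(n_features)
    true_fc[up_idx] <- effect
    true_fc[down_idx] <- -effect

    baseline <- stats::runif(n_features, 4, 12)
    n <- n_case + n_control
    values <- matrix(stats::rnorm(n_features * n, sd = sd), n_features, n) +
      baseline
    values[, seq_len(n_case)] <- values[, seq_len(n_case)] + true_fc
    dimnames(values) <- list(ids, sprintf("S%04d", seq_len(n)))
    group <- rep(c("case", "control"), c(n_case, n_control))

    truth <- data.frame(
      feature_id = ids,
      is_de = seq_len(n_features) %in% de_idx,
      true_log2fc = true_fc,
      direction = ifelse(true_fc > 0, "up", ifelse(true_fc < 0, "down", "null")),
      stringsAsFactors = FALSE
    )
    list(matrix = expression_matrix(values, group), truth = truth)
  })
}

#' Describe a planted feed-forward-loop motif
#'
#' The planted motif is the ground truth for motif-recovery simulations: its
#' three defining edges (TF activates gene, miRNA represses TF, miRNA
#' represses gene) are always emitted with filter-passing scores, and each of
#' the three members receives `extra_degree` additional passing edges so that
#' its degree exceeds the background expectation.
#'
#' @param tf_id,gene_id,mirna_id identifiers inside the namespaces generated
#'   by [generate_regulatory_tables()].
#' @param extra_degree non-negative count of additional passing edges attached
#'   to each member.
#' @return An object of class `planted_motif`.
#' @export
planted_motif <- function(tf_id, gene_id, mirna_id, extra_degree = 0L) {
  extra_degree <- check_count(extra_degree, "extra_degree", min = 0L)
  stopifnot(is.character(tf_id), is.character(gene_id), is.character(mirna_id),
            length(tf_id) == 1L, length(gene_id) == 1L, length(mirna_id) == 1L)
  structure(list(tf_id = tf_id, gene_id = gene_id, mirna_id = mirna_id,
                 extra_degree = extra_degree),
            class = "planted_motif")
}

# sample k unique (a, b) index pairs from the n_a x n_b grid, excluding the
# pairs listed in `exclude` (a data frame with columns a, b)
sample_pairs <- function(n_a, n_b, k, exclude = NULL) {
  total <- n_a * n_b
  cells <- seq_len(total)
  if (!is.null(exclude) && nrow(exclude)) {
    cells <- setdiff(cells, (exclude$b - 1L) * n_a + exclude$a)
  }
  if (k > length(cells)) abort_invalid("not enough free pairs to sample")
  pick <- if (k > 0L) sample_from(cells, k) else integer(0)
  data.frame(a = ((pick - 1L) %% n_a) + 1L, b = ((pick - 1L) %/% n_a) + 1L)
}

# passing / failing score draws for the two edge families; strict thresholds
# are p < 0.05 and score > 0.95 with exclusive-3'UTR binding
draw_tf_p <- function(n, pass) {
  ifelse(pass, stats::runif(n, 0, 0.0499), stats::runif(n, 0.05, 1))
}
draw_mir_score <- function(n, pass) {
  ifelse(pass, stats::runif(n, 0.9501, 1), stats::runif(n, 0, 0.95))
}
draw_mir_region <- function(n, pass) {
  fail_regions <- c("5UTR", "CDS", "3UTR;CDS", "3UTR;5UTR")
  out <- rep("3UTR", n)
  # a failing edge fails through its score, its region, or both
  mode <- sample(c("score", "region", "both"), n, replace = TRUE)
  region_fail <- !pass & mode != "score"
  out[region_fail] <- sample(fail_regions, sum(region_fail), replace = TRUE)
  list(region = out, score_must_fail = !pass & mode != "region")
}

#' Generate TF-gene and miRNA-target interaction tables with a planted motif
#'
#' Emulates the shape of curated interaction resources: a TF-gene table with a
#' per-edge significance p-value (ChEA-style) and a single miRNA-target table
#' with a prediction score and binding region (miRWalk-style) covering both
#' miRNA-TF and miRNA-mRNA pairs, distinguished by `target_role`. Background
#' edges are sampled independently per pair type with probability `edge_prob`;
#' a fraction `frac_passing` of them receives filter-passing scores
#' (p < 0.05; score > 0.95 with exclusive 3'UTR binding) and the rest fail at
#' least one filter. The planted motif's defining and extra-degree edges are
#' always emitted and always pass.
#'
#' Namespaces are `TF1..TFn`, `G1..Gn`, `miR1..miRn`.
#'
#' @param n_tf,n_gene,n_mirna node counts per role.
#' @param edge_prob background edge probability per pair, in [0, 1].
#' @param planted a [planted_motif()] or `NULL` for pure background.
#' @param frac_passing fraction of background edges drawn with passing scores.
#' @param seed integer seed (global RNG state untouched).
#'
#' @return A list with
#'   * `tf_gene`: data frame `tf`, `gene`, `p_value`,
#'   * `mir_targets`: data frame `mirna`, `target`, `target_role`
#'     (`"TF"`/`"mRNA"`), `score`, `binding_region` (`;`-joined region set),
#'   * `planted`: the `planted_motif` (or `NULL`).
#'   Tables contain no duplicate (source, target) pairs within a type.
#' @export
generate_regulatory_tables <- function(n_tf, n_gene, n_mirna, edge_prob,
                                       planted = NULL, frac_passing = 0.9,
                                       seed) {
  n_tf <- check_count(n_tf, "n_tf")
  n_gene <- check_count(n_gene, "n_gene")
  n_mirna <- check_count(n_mirna, "n_mirna")
  edge_prob <- check_prob(edge_prob, "edge_prob")
  frac_passing <- check_prob(frac_passing, "frac_passing")
  seed <- check_seed(seed)

  tfs <- paste0("TF", seq_len(n_tf))
  genes <- paste0("G", seq_len(n_gene))
  mirnas <- paste0("miR", seq_len(n_mirna))

  p_i <- g_i <- m_i <- NULL
  if (!is.null(planted)) {
    stopifnot(inherits(planted, "planted_motif"))
    p_i <- match(planted$tf_id, tfs)
    g_i <- match(planted$gene_id, genes)
    m_i <- match(planted$mirna_id, mirnas)
    if (anyNA(c(p_i, g_i, m_i))) {
      abort_invalid("planted ids fall outside the generated namespaces")
    }
  }

  withr::with_seed(seed, {
    # forced edges: always emitted, always passing
    forced_tg <- forced_mg <- forced_mt <- data.frame(a = integer(0), b = integer(0))
    if (!is.null(planted)) {
      forced_tg <- data.frame(a = p_i, b = g_i)       # tf -> gene
      forced_mt <- data.frame(a = m_i, b = p_i)       # mirna -| tf
      forced_mg <- data.frame(a = m_i, b = g_i)       # mirna -| gene
      k <- planted$extra_degree
      if (k > 0L) {
        if (k > n_gene - 1L || k > n_tf - 1L || k > n_mirna - 1L) {
          abort_invalid("`extra_degree` exceeds the available counterpart nodes")
        }
        # TF member: extra targets among the other genes
        forced_tg <- rbind(forced_tg,
                           data.frame(a = p_i,
                                      b = sample_from(setdiff(seq_len(n_gene), g_i), k)))
        # gene member: extra incoming repressors among the other miRNAs
        forced_mg <- rbind(forced_mg,
                           data.frame(a = sample_from(setdiff(seq_len(n_mirna), m_i), k),
                                      b = g_i))
        # miRNA member: extra repressed TF targets among the other TFs
        forced_mt <- rbind(forced_mt,
                           data.frame(a = m_i,
                                      b = sample_from(setdiff(seq_len(n_tf), p_i), k)))
      }
    }

    sample_background <- function(n_a, n_b, forced) {
      free <- n_a * n_b - nrow(forced)
      k <- stats::rbinom(1L, free, edge_prob)
      sample_pairs(n_a, n_b, k, exclude = forced)
    }
    bg_tg <- sample_background(n_tf, n_gene, forced_tg)
    bg_mt <- sample_background(n_mirna, n_tf, forced_mt)
    bg_mg <- sample_background(n_mirna, n_gene, forced_mg)

    build_tf_gene <- function(forced, bg) {
      pass <- c(rep(TRUE, nrow(forced)),
                stats::runif(nrow(bg)) < frac_passing)
      all <- rbind(forced, bg)
      data.frame(tf = tfs[all$a], gene = genes[all$b],
                 p_value = draw_tf_p(nrow(all), pass),
                 stringsAsFactors = FALSE)
    }
    build_mir <- function(forced, bg, targets, role) {
      pass <- c(rep(TRUE, nrow(forced)),
                stats::runif(nrow(bg)) < frac_passing)
      all <- rbind(forced, bg)
      reg <- draw_mir_region(nrow(all), pass)
      score_pass <- pass | (!pass & !reg$score_must_fail & stats::runif(nrow(all)) < 0.5)
      data.frame(mirna = mirnas[all$a], target = targets[all$b],
                 target_role = role,
                 score = draw_mir_score(nrow(all), score_pass),
                 binding_region = reg$region,
                 stringsAsFactors = FALSE)
    }

    tf_gene <- build_tf_gene(forced_tg, bg_tg)
    mir_targets <- rbind(build_mir(forced_mt, bg_mt, tfs, "TF"),
                         build_mir(forced_mg, bg_mg, genes, "mRNA"))
    rownames(tf_gene) <- rownames(mir_targets) <- NULL
    list(tf_gene = tf_gene, mir_targets = mir_targets, planted = planted)
  })
}

#' Generate survival records with an expression-dependent hazard
#'
#' Event times are exponential with subject-specific rate
#' `baseline_rate * exp(log_hr * z)`, where `z` is the standardised covariate
#' (mean 0, unit variance; a constant covariate maps to z = 0). Censoring
#' times are independent exponential with rate `censor_rate`; the recorded
#' time is the minimum and the event flag marks whether the event came first.
#'
#' @param n number of subjects (>= 10).
#' @param baseline_rate baseline event rate per time unit (months by
#'   convention), > 0.
#' @param log_hr log hazard ratio per standard deviation of the covariate.
#' @param covariate numeric vector of length `n` (e.g. log2 expression or a
#'   methylation beta value).
#' @param censor_rate censoring rate per time unit, > 0.
#' @param seed integer seed.
#' @return A data frame `sample`, `time`, `event` (1 = death, 0 = censored),
#'   `covariate`.
#' @export
generate_survival <- function(n, baseline_rate, log_hr, covariate,
                              censor_rate, seed) {
  n <- check_count(n, "n", min = 10L)
  baseline_rate <- check_positive(baseline_rate, "baseline_rate")
  censor_rate <- check_positive(censor_rate, "censor_rate")
  seed <- check_seed(seed)
  if (!is.numeric(covariate)) abort_invalid("`covariate` must be numeric")
  if (length(covariate) != n) {
    stop(errorCondition(
      sprintf("`covariate` has length %d but n = %d", length(covariate), n),
      class = c("fflmotif_shape_error", "fflmotif_invalid_parameter")))
  }

  s <- stats::sd(covariate)
  z <- if (is.na(s) || s == 0) rep(0, n) else (covariate - mean(covariate)) / s

  withr::with_seed(seed, {
    event_time <- stats::rexp(n, rate = baseline_rate * exp(log_hr * z))
    censor_time <- stats::rexp(n, rate = censor_rate)
    data.frame(
      sample = sprintf("S%04d", seq_len(n)),
      time = pmin(event_time, censor_time),
      event = as.integer(event_time <= censor_time),
      covariate = covariate,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a CpG methylation beta-value matrix
#'
#' Entries are i.i.d. Beta(`alpha`, `beta`), so all values lie in [0, 1] as
#' methylation beta values do.
#'
#' @param n_cpg,n_samples matrix dimensions.
#' @param alpha,beta Beta shape parameters, > 0.
#' @param seed integer seed.
#' @param sample_ids optional column names (defaults to `S0001..`), e.g. to
#'   align with a survival table.
#' @return A numeric matrix with CpG ids (`cg<...>`) as row names.
#' @export
generate_methylation <- function(n_cpg, n_samples, alpha = 2, beta = 2, seed,
                                 sample_ids = NULL) {
  n_cpg <- check_count(n_cpg, "n_cpg")
  n_samples <- check_count(n_samples, "n_samples")
  alpha <- check_positive(alpha, "alpha")
  beta <- check_positive(beta, "beta")
  seed <- check_seed(seed)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  if (length(sample_ids) != n_samples) {
    abort_invalid("`sample_ids` must have length `n_samples`")
  }
  withr::with_seed(seed, {
    m <- matrix(stats::rbeta(n_cpg * n_samples, alpha, beta),
                n_cpg, n_samples,
                dimnames = list(sprintf("cg%08d", seq_len(n_cpg)), sample_ids))
    m
  })
}

#' Generate gene-set collections over a feature universe
#'
#' Draws `n_sets` random sets by uniform sampling from `universe` and
#' optionally spikes the first set with members of `enrich_with` (e.g. a DE
#' gene list) so over-representation is planted and recoverable.
#'
#' @param universe character vector of feature ids.
#' @param n_sets number of sets.
#' @param set_size integer range `c(min, max)` for set sizes.
#' @param enrich_with optional character vector; the first set draws
#'   `enrich_frac` of its members from it.
#' @param enrich_frac fraction of the spiked set taken from `enrich_with`.
#' @param seed integer seed.
#' @return A named list of character vectors (the GMT in-memory form).
#' @export
generate_gene_sets <- function(universe, n_sets = 20, set_size = c(20, 100),
                               enrich_with = NULL, enrich_frac = 0.5, seed) {
  n_sets <- check_count(n_sets, "n_sets")
  seed <- check_seed(seed)
  enrich_frac <- check_prob(enrich_frac, "enrich_frac")
  withr::with_seed(seed, {
    sizes <- sample(set_size[1]:set_size[2], n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample_from(universe, min(k, length(universe))))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    if (!is.null(enrich_with) && length(enrich_with)) {
      k <- length(sets[[1L]])
      n_spike <- min(round(k * enrich_frac), length(enrich_with))
      sets[[1L]] <- unique(c(sample_from(enrich_with, n_spike),
                             sample_from(universe, k - n_spike)))
      names(sets)[1L] <- "SET_SPIKED"
    }
    sets
  })
}

#' Write / read interaction and survival tables
#'
#' Thin CSV round-trips for the schemas produced by the generators:
#' `tf,gene,p_value` / `mirna,target,target_role,score,binding_region` /
#' `sample,time,event,covariate`, and a TSV matrix for methylation.
#'
#' @param x table or matrix to write.
#' @param path file path.
#' @return The written path (writers, invisibly) or the parsed object
#'   (readers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_interaction_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_interaction_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
write_methylation_tsv <- function(x, path) {
  utils::write.table(cbind(cpg = rownames(x), as.data.frame(x)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_methylation_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}

#' Generate interaction tables with exact node and edge counts
#'
#' Produces TF-gene, miRNA-TF and miRNA-gene tables containing exactly the
#' requested numbers of distinct nodes per role and unique edges per type,
#' with all scores passing the regulatory filters. Useful for verifying the
#' network assembly bookkeeping against published per-role / per-type counts.
#' Coverage of every node is guaranteed by a deterministic first block of
#' edges (gene i paired with TF i mod n_tf, miRNA i with TF i mod n_tf); the
#' remaining edges are sampled uniformly without replacement.
#'
#' @param n_tf,n_gene,n_mirna distinct node counts per role.
#' @param n_tf_gene,n_mir_tf,n_mir_gene unique edge counts per type;
#'   `n_tf_gene >= max(n_tf, n_gene)` and `n_mir_tf >= max(n_mirna, n_tf)`
#'   so that every node can be covered.
#' @param seed integer seed.
#' @return A list `tf_gene`, `mir_gene`, `mir_tf` of edge tables using the
#'   generator namespaces, every edge filter-passing.
#' @export
generate_exact_tables <- function(n_tf, n_gene, n_mirna,
                                  n_tf_gene, n_mir_tf, n_mir_gene, seed) {
  n_tf <- check_count(n_tf, "n_tf")
  n_gene <- check_count(n_gene, "n_gene")
  n_mirna <- check_count(n_mirna, "n_mirna")
  seed <- check_seed(seed)
  if (n_tf_gene < max(n_tf, n_gene) || n_tf_gene > n_tf * n_gene ||
      n_mir_tf < max(n_mirna, n_tf) || n_mir_tf > n_mirna * n_tf ||
      n_mir_gene < 1 || n_mir_gene > n_mirna * n_gene) {
    abort_invalid("edge counts incompatible with the requested node counts")
  }
  tfs <- paste0("TF", seq_len(n_tf))
  genes <- paste0("G", seq_len(n_gene))
  mirnas <- paste0("miR", seq_len(n_mirna))
  withr::with_seed(seed, {
    cover_tg <- data.frame(a = rep_len(seq_len(n_tf), n_gene),
                           b = seq_len(n_gene))
    tg <- rbind(cover_tg,
                sample_pairs(n_tf, n_gene, n_tf_gene - nrow(cover_tg),
                             exclude = cover_tg))
    cover_mt <- data.frame(a = seq_len(n_mirna),
                           b = rep_len(seq_len(n_tf), n_mirna))
    mt <- rbind(cover_mt,
                sample_pairs(n_mirna, n_tf, n_mir_tf - nrow(cover_mt),
                             exclude = cover_mt))
    mg <- sample_pairs(n_mirna, n_gene, n_mir_gene)
    list(
      tf_gene = data.frame(tf = tfs[tg$a], gene = genes[tg$b],
                           p_value = stats::runif(nrow(tg), 0, 0.0499),
                           stringsAsFactors = FALSE),
      mir_gene = data.frame(mirna = mirnas[mg$a], target = genes[mg$b],
                            target_role = "mRNA",
                            score = stats::runif(nrow(mg), 0.9501, 1),
                            binding_region = "3UTR",
                            stringsAsFactors = FALSE),
      mir_tf = data.frame(mirna = mirnas[mt$a], target = tfs[mt$b],
                          target_role = "TF",
                          score = stats::runif(nrow(mt), 0.9501, 1),
                          binding_region = "3UTR",
                          stringsAsFactors = FALSE)
    )
  })
}
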