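#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]. The defaults
#' encode the screening thresholds used throughout the package (p < 0.05 with
#' a 0.5-1.0 absolute log2-fold-change band; interaction score > 0.95 with
#' exclusive 3'UTR binding) and desk-scale synthetic study conditions: a
#' miRNA cohort of 397 case / 151 control samples and an mRNA cohort of
#' 31 case / 20 control samples, with a planted high-degree feed-forward
#' loop (background edge probability 0.02, 30 extra passing edges per
#' member), expression-linked exponential survival and Beta-distributed
#' methylation.
#'
#' @param seed integer seed driving every synthetic stage.
#' @param output_dir directory for intermediate tables and the JSON manifest.
#' @param ... named overrides merged (recursively for nested lists) into the
#'   defaults, e.g. `de = list(p_thresh = 0.01)`.
#' @return A nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, output_dir = tempfile("fflmotif_run_"),
                            ...) {
  seed <- check_seed(seed)
  cfg <- list(
    seed = seed,
    output_dir = output_dir,
    stages = list(simulate = TRUE, de = TRUE, filter = TRUE, network = TRUE,
                  survival = TRUE, enrich = TRUE),
    sim = list(
      mirna = list(n_features = 800, n_case = 397, n_control = 151,
                   frac_de = 0.15, effect = 0.8, sd = 0.5),
      mrna = list(n_features = 2000, n_case = 31, n_control = 20,
                  frac_de = 0.15, effect = 0.8, sd = 0.5),
      regulatory = list(n_tf = 40, n_gene = 2000, n_mirna = 800,
                        edge_prob = 0.02, frac_passing = 0.9,
                        extra_degree = 30),
      survival = list(n = 300, baseline_rate = 1 / 40, log_hr = 0.6,
                      censor_rate = 1 / 60),
      methylation = list(n_cpg = 30, alpha = 2, beta = 5)
    ),
    de = list(p_thresh = 0.05, fc_lo = 0.5, fc_hi = 1.0, fc_rule = "band",
              adjust = "none"),
    filter = list(p_thresh = 0.05, score_thresh = 0.95),
    enrich = list(p_thresh = 0.05, top_k = 10, n_sets = 20)
  )
  overrides <- list(...)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_into(cfg, overrides), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds any subset of the [pipeline_config()] fields; missing
#' fields take their defaults. `seed` must be present in the file or given
#' explicitly.
#'
#' @param path YAML file path.
#' @param seed overrides any seed in the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  if (is.null(raw$seed)) abort_invalid("config must provide `seed`")
  s <- raw$seed
  raw$seed <- NULL
  out_dir <- raw$output_dir
  raw$output_dir <- NULL
  args <- c(list(seed = s), raw)
  if (!is.null(out_dir)) args$output_dir <- out_dir
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()] (or plain list with the same shape).
#' @return A character vector of diagnostics, one per out-of-domain
#'   parameter, each naming the parameter and its documented domain; empty
#'   when the configuration is valid.
#' @export
validate_config <- function(config) {
  diag <- character(0)
  bad <- function(msg) diag <<- c(diag, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 0 && x <= 1
  if (!in01(config$de$p_thresh)) {
    bad("de$p_thresh: must lie in [0, 1]")
  }
  if (!in01(config$filter$p_thresh)) {
    bad("filter$p_thresh: must lie in [0, 1]")
  }
  if (!in01(config$filter$score_thresh)) {
    bad("filter$score_thresh: must lie in [0, 1]")
  }
  if (!in01(config$enrich$p_thresh)) {
    bad("enrich$p_thresh: must lie in [0, 1]")
  }
  if (!is.numeric(config$de$fc_lo) || !is.numeric(config$de$fc_hi) ||
      config$de$fc_lo < 0 || config$de$fc_lo > config$de$fc_hi) {
    bad("de$fc_lo/fc_hi: need 0 <= fc_lo <= fc_hi")
  }
  if (!in01(config$sim$regulatory$edge_prob)) {
    bad("sim$regulatory$edge_prob: must lie in [0, 1]")
  }
  if (!in01(config$sim$mirna$frac_de) || !in01(config$sim$mrna$frac_de)) {
    bad("sim$*$frac_de: must lie in [0, 1]")
  }
  if (any(unlist(config$stages)) &&
      (is.null(config$seed) || is.na(config$seed))) {
    bad("seed: required when any synthetic stage is enabled")
  }
  diag
}

#' Run the full motif-discovery pipeline on synthetic data
#'
#' Executes the enabled stages in order — simulate the two expression
#' cohorts, interaction tables, survival and methylation data; screen genes
#' and miRNAs for differential expression; filter and calibrate the
#' interaction tables (TF-gene edges are restricted to the DE gene list);
#' assemble the tripartite network, enumerate feed-forward loops and rank
#' them by summed member degree; test the planted gene's expression and each
#' CpG for survival association; and run over-representation analysis of the
#' DE genes against generated gene sets. Every intermediate table is written
#' to `config$output_dir` and a JSON manifest records the seed, per-stage
#' row counts and the top-ranked motif.
#'
#' @param config a valid [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `file.path(output_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  diag <- validate_config(config)
  if (length(diag)) {
    abort_invalid(paste(c("invalid config:", diag), collapse = "\n  "))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(package_version = as.character(utils::packageVersion("fflmotif")),
                   seed = seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_csv <- function(tab, name) {
    utils::write.csv(tab, file.path(config$output_dir, name),
                     row.names = FALSE)
  }

  sim <- NULL
  if (config$stages$simulate) {
    sim <- stage("simulate", {
      rg <- config$sim$regulatory
      planted <- planted_motif(
        tf_id = paste0("TF", max(1L, rg$n_tf %/% 2L)),
        gene_id = paste0("G", max(1L, rg$n_gene %/% 2L)),
        mirna_id = paste0("miR", max(1L, rg$n_mirna %/% 2L)),
        extra_degree = rg$extra_degree)
      mrna <- do.call(generate_expression,
                      c(config$sim$mrna,
                        list(seed = seed + 1L, feature_prefix = "G",
                             always_de = planted$gene_id)))
      mirna <- do.call(generate_expression,
                       c(config$sim$mirna,
                         list(seed = seed + 2L, feature_prefix = "miR")))
      tables <- generate_regulatory_tables(
        n_tf = rg$n_tf, n_gene = rg$n_gene, n_mirna = rg$n_mirna,
        edge_prob = rg$edge_prob, planted = planted,
        frac_passing = rg$frac_passing, seed = seed + 3L)
      sv <- config$sim$survival
      # covariate: standardised expression surrogate for the motif gene
      surv <- generate_survival(sv$n, sv$baseline_rate, sv$log_hr,
                                covariate = withr::with_seed(seed + 4L,
                                                             stats::rnorm(sv$n)),
                                censor_rate = sv$censor_rate, seed = seed + 5L)
      meth <- generate_methylation(config$sim$methylation$n_cpg, sv$n,
                                   alpha = config$sim$methylation$alpha,
                                   beta = config$sim$methylation$beta,
                                   seed = seed + 6L,
                                   sample_ids = surv$sample)
      write_expression_tsv(mrna$matrix,
                           file.path(config$output_dir, "mrna_expression.tsv"))
      write_expression_tsv(mirna$matrix,
                           file.path(config$output_dir, "mirna_expression.tsv"))
      out_csv(tables$tf_gene, "tf_gene_edges.csv")
      out_csv(tables$mir_targets, "mir_target_edges.csv")
      out_csv(surv, "survival.csv")
      write_methylation_tsv(meth,
                            file.path(config$output_dir, "methylation.tsv"))
      list(mrna = mrna, mirna = mirna, tables = tables, planted = planted,
           survival = surv, methylation = meth)
    })
    manifest$stages$simulate <- list(
      mrna_features = nrow(sim$mrna$matrix$values),
      mirna_features = nrow(sim$mirna$matrix$values),
      tf_gene_edges = nrow(sim$tables$tf_gene),
      mir_target_edges = nrow(sim$tables$mir_targets),
      planted_motif = unclass(sim$planted)[c("tf_id", "gene_id", "mirna_id")])
  }

  de_gene <- de_mirna <- NULL
  if (config$stages$de) {
    if (is.null(sim)) stop("pipeline stage 'de' requires the simulate stage")
    rule <- if (config$de$fc_rule == "band") {
      fc_band(config$de$fc_lo, config$de$fc_hi)
    } else {
      fc_min(config$de$fc_lo)
    }
    de_gene <- stage("de", run_de(sim$mrna$matrix, config$de$p_thresh, rule,
                                  adjust = config$de$adjust))
    de_mirna <- stage("de", run_de(sim$mirna$matrix, config$de$p_thresh, rule,
                                   adjust = config$de$adjust))
    out_csv(de_gene, "de_genes.csv")
    out_csv(de_mirna, "de_mirnas.csv")
    out_csv(volcano_table(de_gene), "volcano_genes.csv")
    out_csv(top_k_table(de_mirna), "top10_mirnas.csv")
    sg <- de_summary(de_gene)
    sm <- de_summary(de_mirna)
    manifest$stages$de <- list(deg = sg, dem = sm)
  }

  calibrated <- NULL
  if (config$stages$filter) {
    if (is.null(de_gene)) stop("pipeline stage 'filter' requires the de stage")
    calibrated <- stage("filter", {
      de_ids <- de_gene$feature_id[de_gene$is_de]
      tg <- filter_tf_edges(sim$tables$tf_gene, config$filter$p_thresh, de_ids)
      mir <- filter_mir_edges(sim$tables$mir_targets,
                              config$filter$score_thresh)
      calibrate_pairs(tf_gene = tg,
                      mir_gene = mir[mir$target_role == "mRNA", , drop = FALSE],
                      mir_tf = mir[mir$target_role == "TF", , drop = FALSE])
    })
    out_csv(calibrated$tf_gene, "calibrated_tf_gene.csv")
    out_csv(calibrated$mir_gene, "calibrated_mir_gene.csv")
    out_csv(calibrated$mir_tf, "calibrated_mir_tf.csv")
    manifest$stages$filter <- list(
      tf_gene = nrow(calibrated$tf_gene),
      mir_gene = nrow(calibrated$mir_gene),
      mir_tf = nrow(calibrated$mir_tf))
  }

  if (config$stages$network) {
    if (is.null(calibrated)) {
      stop("pipeline stage 'network' requires the filter stage")
    }
    ranked <- stage("network", {
      net <- assemble_network(calibrated$tf_gene, calibrated$mir_gene,
                              calibrated$mir_tf)
      write_network_tsv(net, file.path(config$output_dir, "network_edges.tsv"))
      ffls <- enumerate_ffls(net)
      rk <- rank_motifs(ffls, degree_centrality(net))
      out_csv(rk, "ranked_motifs.csv")
      list(net = net, ranked = rk)
    })
    top <- if (nrow(ranked$ranked)) ranked$ranked[1L, ] else NULL
    manifest$stages$network <- list(
      summary = network_summary(ranked$net),
      n_ffls = nrow(ranked$ranked),
      top_motif = if (is.null(top)) NULL else
        list(tf = top$tf, gene = top$gene, mirna = top$mirna,
             score = top$motif_score),
      planted_recovered = if (is.null(top) || is.null(sim$planted)) FALSE else
        identical(c(top$tf, top$gene, top$mirna),
                  c(sim$planted$tf_id, sim$planted$gene_id,
                    sim$planted$mirna_id)))
  }

  if (config$stages$survival) {
    if (is.null(sim)) {
      stop("pipeline stage 'survival' requires the simulate stage")
    }
    surv_res <- stage("survival", {
      grp <- median_split(sim$survival)
      lr <- log_rank(sim$survival, grp)
      scan <- covariate_scan(sim$methylation, sim$survival)
      out_csv(scan, "cpg_survival_scan.csv")
      km <- km_estimate(sim$survival)
      utils::write.csv(data.frame(time = km$times, survival = km$survival,
                                  at_risk = km$at_risk),
                       file.path(config$output_dir, "km_curve.csv"),
                       row.names = FALSE)
      list(lr = lr, scan = scan)
    })
    manifest$stages$survival <- list(
      expression_logrank = unclass(surv_res$lr),
      top_cpg = if (nrow(surv_res$scan)) as.list(surv_res$scan[1L, ]) else NULL)
  }

  if (config$stages$enrich) {
    if (is.null(de_gene)) stop("pipeline stage 'enrich' requires the de stage")
    enr <- stage("enrich", {
      universe <- de_gene$feature_id
      de_ids <- de_gene$feature_id[de_gene$is_de]
      sets <- generate_gene_sets(universe, n_sets = config$enrich$n_sets,
                                 enrich_with = de_ids, seed = seed + 7L)
      write_gmt(sets, file.path(config$output_dir, "gene_sets.gmt"))
      ora(de_ids, universe, sets, p_thresh = config$enrich$p_thresh,
          top_k = config$enrich$top_k)
    })
    out_csv(enr, "enrichment.csv")
    manifest$stages$enrich <- list(
      n_reported = nrow(enr),
      top_set = if (nrow(enr)) enr$set_name[1L] else NULL)
  }

  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
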