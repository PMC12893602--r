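# fflmotif

Identifying a regulatory *driver motif* — a transcription factor, an mRNA and
a microRNA locked in a three-node feed-forward loop (FFL) — is a common goal
of integrative expression studies in cancer, notably non-small cell lung
carcinoma (NSCLC), where composite miRNA-TF loops such as NRG1-SMAD4-miR-5010
have been proposed as prognostic axes. `fflmotif` implements that discovery
pipeline as a tested, reusable R package:

1. **Differential screening** of genes (DEGs) and miRNAs (DEMs) from
   two-group log2 expression matrices with a t-test (Welch by default) at
   p < 0.05 and a fold-change *band* filter 0.5 ≤ |log2FC| ≤ 1.0 (a
   conventional minimum-threshold rule is also available);
2. **Interaction filtering**: TF→gene edges kept at p < 0.05 when the gene is
   differentially expressed; miRNA⊣target edges kept at score > 0.95 with
   binding *exclusively* in the 3'UTR;
3. **Calibration** of the three edge tables (TF-gene, miRNA-gene, miRNA-TF)
   to the shared miRNAs and consistent TFs, so every surviving edge can close
   a loop;
4. **Network assembly and motif ranking**: a typed tripartite directed graph
   is built, every FFL — a triple (TF, gene, miRNA) with edges TF→gene,
   miRNA⊣TF, miRNA⊣gene — is enumerated, and motifs are ranked by the summed
   degree centrality of their members; the top-ranked triple is the
   predominant motif;
5. **Survival analysis**: Kaplan-Meier curves and log-rank tests on
   cohort-median expression splits (with the "invert HR below 1" reporting
   convention and the O/E hazard-ratio approximation), including a per-CpG
   methylation scan;
6. **Over-representation analysis** (one-sided hypergeometric with BH
   adjustment) of the DE gene list against GMT gene-set collections.

Because the original data sources are external (GEO series, curated
interaction databases, clinical cohorts), the package ships fully seeded
synthetic-data generators with *planted ground truth* — shifted-mean DE
features, a high-degree planted FFL, expression-dependent exponential
survival, Beta-distributed methylation — so the whole chain is verifiable
offline, and `run_pipeline()` executes it end to end from one configuration.

## Worked example

Plant a hub motif in a small interaction background, filter, calibrate,
assemble and rank:

```r
library(fflmotif)

pl   <- planted_motif("TF5", "G20", "miR8", extra_degree = 12)
tabs <- generate_regulatory_tables(n_tf = 15, n_gene = 60, n_mirna = 25,
                                   edge_prob = 0.03, planted = pl, seed = 11)
tg  <- filter_tf_edges(tabs$tf_gene, allowed_genes = unique(tabs$tf_gene$gene))
mir <- filter_mir_edges(tabs$mir_targets)
cal <- calibrate_pairs(tg, mir[mir$target_role == "mRNA", ],
                       mir[mir$target_role == "TF", ])
net <- assemble_network(cal$tf_gene, cal$mir_gene, cal$mir_tf)
net
#> regulatory_network: 7 nodes (3 TF, 2 mRNA, 2 miRNA), 11 edges (4 tf_mrna, 4 mirna_tf, 3 mirna_mrna)

ranked <- rank_motifs(enumerate_ffls(net), degree_centrality(net))
head(ranked, 3)
#>     tf gene mirna deg_tf deg_gene deg_mirna motif_score rank
#> 1  TF5  G20  miR8      4        5         5          14    1
#> 2  TF1  G20  miR8      2        5         5          12    2
#> 3 TF12  G20  miR8      2        5         5          12    3
```

The planted triple TF5-G20-miR8 is ranked first: after filtering, only edges
able to participate in a loop survive calibration, and the planted members'
extra passing edges give them the highest degrees (`motif_score` is the sum
of the three member degrees).

Differential screening and survival on synthetic cohorts:

```r
sim <- generate_expression(n_features = 500, n_case = 30, n_control = 30,
                           frac_de = 0.2, effect = 0.8, sd = 0.5, seed = 1)
res <- run_de(sim$matrix)          # p < 0.05 and 0.5 <= |log2FC| <= 1.0
str(de_summary(res))
#> List of 5
#>  $ up      : int 50
#>  $ down    : int 48
#>  $ de_total: int 98
#>  $ none    : int 402
#>  $ total   : int 500

rec <- generate_survival(n = 200, baseline_rate = 1/40, log_hr = 0.8,
                         covariate = rnorm(200), censor_rate = 1/60, seed = 2)
log_rank(rec, median_split(rec))
#> log-rank: chi2 = 42.123, p = 8.573e-11, HR = 3.134 (100 high / 100 low)
```

Here 98 of the 100 planted DE features are recovered (up + down), the other
402 stay unflagged, and a strong planted hazard effect yields a highly
significant log-rank split with HR oriented above 1.

The full chain runs from one config:

```r
manifest <- run_pipeline(pipeline_config(seed = 42, output_dir = "run1"))
manifest$stages$network$top_motif
```

A YAML-driven command-line wrapper is installed at
`inst/scripts/run_pipeline.R`.

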