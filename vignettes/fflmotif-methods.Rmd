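---
title: "Methods: feed-forward-loop motif discovery and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feed-forward-loop motif discovery and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflmotif)
```

## The analysis in one paragraph

`fflmotif` searches for a *composite miRNA feed-forward loop*: a triple
(TF, gene, miRNA) in which the transcription factor activates the gene while
the microRNA represses both the TF and the gene. Candidate genes and miRNAs
come from a two-group differential-expression screen; candidate edges come
from scored interaction tables (TF-gene with a significance p-value,
miRNA-target with a prediction score and binding region); filtering,
mutual calibration, triangle enumeration and degree-centrality ranking then
reduce tens of thousands of edges to a single *predominant* motif.
Companion modules quantify the prognostic value of candidate members via
Kaplan-Meier / log-rank analysis of median-split cohorts and the functional
context of the DE gene list via over-representation analysis.

## Differential screening

For each feature the case/control contrast is tested with a two-sample
t-test — Welch by default, because equal group variances are not assumed on
array data; a pooled-variance variant is available. The effect size is the
difference of group means on the log2 scale (case minus control), so it is a
log2 fold change directly.

A feature is flagged when `p < p_thresh` (default 0.05, raw p-values;
Benjamini-Hochberg adjustment is available but off by default, matching the
common reporting practice for screens of this kind) **and** the absolute
log2 fold change satisfies the fold-change rule. Two rules are exposed:

* `fc_band(0.5, 1.0)` — the default *band* rule, `0.5 <= |log2FC| <= 1.0`.
  A band deliberately targets moderate, reproducible shifts and excludes
  extreme fold changes (which on arrays are often saturation or annotation
  artifacts). Because a pure band is unusual, the conventional
* `fc_min(0.5)` — `|log2FC| >= 0.5` — is offered alongside, and both are
  selectable in the pipeline configuration.

Numerical conventions: a feature constant and equal in both groups yields
`t = 0, p = 1` (no evidence); constant but unequal yields infinite `t` and
`p = 0`; `-log10(p)` for volcano output clamps `p = 0` to the smallest
positive double with a logged message. Duplicate probe ids must be collapsed
first (`collapse_duplicates()`, keeping the most-expressed probe by default);
quantile normalisation is provided as a convenience via
`limma::normalizeQuantiles` but inputs are assumed pre-normalised.

## Interaction filtering and calibration

Thresholds are read strictly: TF-gene edges need `p_value < 0.05` *and* a
differentially expressed target gene; miRNA-target edges need
`score > 0.95` and a binding-region set exactly equal to {3'UTR} — an edge
that also binds the CDS or 5'UTR is rejected. TFs themselves are *not*
required to be differentially expressed (they enter through the genes they
regulate); requiring it would only shrink the TF namespace and can be
emulated by pre-filtering the TF table.

Calibration then restricts the three tables to their mutually consistent
core. The node-level restriction (keep miRNAs hitting both arms, keep
miRNA-TF edges whose TF still regulates some retained gene, keep TF-gene
edges whose TF and gene are each repressed by a shared miRNA) is iterated to
a fixed point; because each pass only removes rows, at most one pass per
removed edge is needed. Node-level consistency alone, however, does not
guarantee that every surviving edge closes a loop — a miRNA-gene edge can
point at a gene whose TF partners are repressed only by *other* miRNAs. The
calibration therefore finishes with a *triangle-support prune*: exactly the
edges participating in at least one enumerable loop are kept. This prune is
stable after a single pass (every supporting triangle is made of supported
edges), and it is what makes the advertised invariant — every calibrated
edge appears in at least one FFL — true by construction. A literal
single-round node-level variant is kept behind `single_pass = TRUE` for
comparison.

## Network, enumeration, ranking

Nodes are (role, id) pairs. An identifier appearing as both TF and mRNA is
deliberately kept as two distinct nodes: biologically the two rows describe
different molecules' roles, and practically it keeps per-role node counts
additive to the total, so published per-role/per-type bookkeeping can be
checked by exact arithmetic.

FFL enumeration is a relational join (miRNA-TF ⋈ miRNA-gene on the miRNA,
intersected with TF-gene), which is exactly the typed-triangle set of the
tripartite graph; the unit tests verify it against a brute-force triple loop
over all instances.

Degree centrality is the raw incident-edge count (in + out over all edge
types), computed on the full assembled network rather than per component —
this matches what a network viewer reports and keeps hub scores comparable
across components. Normalisation by (n − 1) is available but off by default.
The ranking rule aggregates member centralities by *sum* (symmetric in the
three members; a max-member variant is exposed behind `aggregate = "max"`),
with deterministic lexicographic tie-breaking, so rankings are reproducible
under input permutation.

## Survival analysis

Groups are formed by the cohort-wide median of the covariate (expression or
methylation beta), ties going to the *low* group — the documented, if
arbitrary, convention; an all-constant covariate is a degenerate-split
error. Kaplan-Meier estimation and the two-group log-rank test are delegated
to the `survival` package (`survfit`, `survdiff`) and repackaged to the
module's containers; independent hand-computed product-limit and O/E/V
oracles in the test suite guard the wiring.

The hazard ratio is reported in the log-rank O/E form
`(O_high/E_high)/(O_low/E_low)` rather than from a Cox fit: the claims this
pipeline supports are *direction and significance* of a split, for which the
O/E approximation suffices, and it avoids an iterative model fit. With
`invert_hr = TRUE` (default) a ratio below 1 is reported as its reciprocal
with an `inverted` flag, mirroring the "invert HR values below 1" reporting
convention of popular survival portals; inversion is an involution and does
not touch the chi-square. The per-CpG methylation scan is the same
median-split + log-rank applied to each matrix row, skipping degenerate rows
with a logged message.

## Over-representation analysis

One-sided hypergeometric upper tail per gene set, after intersecting each
set with the universe; BH adjustment across tested sets; report sorted by p,
truncated to the top 10 below p < 0.05 by default. The universe defaults to
*all tested features* (every gene that entered the DE screen) — the least
biased choice available offline; a hosted enrichment service's combined
score (p-value blended with a rank-based z-score against its own background)
is deliberately not reproduced, since it is tied to that service's
background ensembles.

## What the synthetic generators emulate — and what they do not

* `generate_expression()`: Gaussian noise around per-feature baselines
  (uniform on log2 4–12, a typical array dynamic range), with a planted
  fraction of features shifted by ±`effect` in the case group, split evenly
  up/down. This is the minimal model under which t-test + fold-change
  thresholds are meaningful. It does **not** simulate probe effects,
  background correction, batch structure, or correlated features, so passing
  tests demonstrate correctness of the screen's decision rules, not
  robustness to array artifacts. No batch structure is simulated and no
  batch correction is implemented.
* `generate_regulatory_tables()`: independent Bernoulli background edges per
  pair type (default density 0.02), a `frac_passing` fraction (default 0.9)
  drawn with filter-passing scores and the rest failing at least one filter;
  the planted motif's three defining edges always pass, and each member
  receives `extra_degree` additional passing edges (the TF gains targets,
  the gene gains miRNA repressors, the miRNA gains TF targets — which
  requires `n_tf > extra_degree`). Real interaction databases are neither
  independent nor uniform; the generator only guarantees that degree-based
  recovery is well-posed.
* `generate_survival()`: exponential event times with rate
  `baseline_rate · exp(log_hr · z)` on the standardised covariate, and
  independent exponential censoring — proportional hazards by construction.
* `generate_methylation()`: i.i.d. Beta(α, β) beta-values (defaults 2 and 5,
  a typical low-methylation promoter profile); no CpG-island correlation
  structure.
* `generate_exact_tables()` builds interaction tables with *exact* distinct
  node counts and unique edge counts (deterministic coverage block plus
  uniform sampling) for bookkeeping verification.

All generators take a mandatory seed, restore the global RNG state, and are
byte-reproducible; the pipeline manifest echoes the seed.

## Study conditions and problem sizes

The default pipeline configuration emulates cohorts of 397 case / 151
control samples for miRNAs and 31 / 20 for mRNAs, with 800 and 2000
features, 15% planted DE at effect 0.8 (inside the fold-change band) and
noise SD 0.5; a regulatory layer of 40 TFs, 2000 genes and 800 miRNAs at
background density 0.02 with a planted motif carrying 30 extra edges per
member; a 300-subject survival cohort at baseline rate 1/40 per month,
log-HR 0.6 and censoring rate 1/60; and 30 CpGs. Tests and the acceptance
script scale some replicated simulations down (e.g. 120–300 features,
100-seed recovery runs, 2000-replicate null calibrations) — sizes chosen so
the Monte-Carlo tolerances stated with each check are comfortably within
reach of the replicate counts.

## Known limitations

* The t-test is unmoderated; no empirical-Bayes variance shrinkage, so very
  small cohorts (n per group near 2–3) are underpowered relative to
  moderated screens.
* The O/E hazard ratio is biased away from 1 relative to a Cox estimate when
  censoring differs between groups; interpret its magnitude qualitatively.
* Whether the fold-change band applies to the log2 or raw scale is a genuine
  reading ambiguity in screens that report a "0.5 to 1.0" range; this
  package applies it to |log2FC| and exposes `fc_min()` for the
  conventional alternative.
* Degree centrality is the only motif-ranking signal; betweenness or
  eigenvector centrality, and visualisation layouts, are out of scope.
* Enrichment requires user-supplied GMT collections; no pathway databases
  are bundled or fetched.
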