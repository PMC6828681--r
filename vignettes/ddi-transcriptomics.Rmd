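---
title: "Dissecting drug-drug interactions from transcriptome data with ddixome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting drug-drug interactions from transcriptome data with ddixome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddixome)
```

## The problem

When two drugs are given together, one can enhance (synergy) or blunt
(antagonism) the other's effect. Pharmacokinetic assays rarely explain *why*.
`ddixome` implements a transcriptome-based strategy: treat cells with nothing,
with the primary drug alone, and with the primary drug plus the interacting
agent; sequence all three; and ask, gene by gene, whether the interacting
agent pushes expression further in the direction the primary drug set, or
pulls it back.

The design has two treatment *arms* (a cell line paired with a primary
chemotherapy drug), three *conditions* per arm (`untreated`, `single`,
`combined`) and replicated RNA-seq counts. Two contrasts per arm are tested:
single vs untreated, and combined vs single — the baseline for the
interaction contrast is deliberately the primary-drug treatment, because the
question is what the *second* drug changes.

## The interaction calculus

For a gene significant in all four contrasts, let $L_1$ be its log2 fold
change for single vs untreated and $L_2$ for combined vs single.

* **positive interaction** (synergistic regulation):
  $\operatorname{sign}(L_1) = \operatorname{sign}(L_2)$. Equivalently, the
  single-treatment expression lies strictly between the untreated and
  combined levels.
* **negative interaction** (antagonistic regulation): opposite signs; the
  single-treatment level is the extreme.

The two formulations are exactly equivalent for non-degenerate values, and
the test suite checks this on random triples. An exact zero log fold change
is indeterminate: `classify_interaction()` refuses it rather than guessing,
and `interaction_table()` excludes such genes with a logged count. (Zero is a
measure-zero event for FDR-significant genes, but must not crash or silently
misclassify.)

With the three condition values exchangeable (no real interaction
structure), the single-treatment value is the middle order statistic with
probability exactly 1/3, so one third of genes land in the positive class by
chance. This analytic null anchors two downstream rules:

* a pathway is labelled a *positive-interaction pathway* only when its
  positive fraction is **strictly** above one third (the default cutoff is
  stored as `100/3`, with a $10^{-9}$ tie tolerance, so a pathway at exactly
  3/9 positive is *not* called positive);
* the Monte-Carlo acceptance check verifies the 33.33% null rate.

Genes are then partitioned across arms: group **A** (positive in arm 1,
negative in arm 2), **B** (negative, positive), **C** (negative in both),
**D** (positive in both). Arm 1 is the positive-reference arm, recorded in
the run summary so the letters are unambiguous.

## Differential expression

The DE stage re-implements the classic negative-binomial exact-test pipeline
(the one popularised by edgeR), with deliberately simple, verifiable
components:

* **Filter**: keep genes with count strictly greater than `min_count`
  (default 2) in *every* sample, applied once to the full matrix.
* **TMM normalization**: reference sample = the one whose upper-quartile
  statistic is closest to the mean; per-sample factors from a doubly-trimmed
  (30% on log-ratios, 5% on abundance) precision-weighted mean of log2
  ratios over genes expressed in both samples; factors rescaled to geometric
  mean 1. The implementation matches edgeR's `calcNormFactors` to ~1% on
  simulated data (checked in the suite).
* **Dispersion**: per-gene method-of-moments estimate
  $\hat\phi_g = (s^2 - m)/m^2$ on counts rescaled to a common effective
  library size, pooling within-group residual variance; per-gene values are
  shrunk toward the common mean with weight 0.7 by default, mimicking
  empirical-Bayes pooling without its machinery. The common value is the
  mean of the *untruncated* per-gene estimates (then clamped at zero):
  truncating before averaging would bias the common dispersion upward and
  make the test conservative; the untruncated mean keeps the global-null
  type-I error calibrated, which the suite verifies at $\alpha \in
  \{0.01, 0.05\}$.
* **Exact test**: counts are rescaled to the geometric-mean effective
  library size and summed within groups; conditional on the total, the split
  follows a beta-binomial-type law with sizes $n_g/\phi$, which reduces to
  Binomial($n$, 1/2) at $\phi = 0$ for balanced groups — the verifiable
  anchor (agreement with the exact binomial to $10^{-9}$ for all totals up
  to 200). Two-sided p-values sum the probabilities of all splits no more
  likely than the observed one, counting tie mass once. This conditioning is
  a simplification of edgeR's quantile-adjusted scheme; on real data,
  results may differ from edgeR in the marginal-significance band, which is
  why we describe the test as *edgeR-approximating*.
* **logFC**: $\log_2((s_b + 0.5)/(s_a + 0.5))$ on the depth-equalized group
  sums; the 0.5 pseudo-count handles zero sums. Supported designs are
  balanced, so the sum ratio equals the mean ratio.
* **FDR**: Benjamini-Hochberg step-up (via `stats::p.adjust`), significance
  at `fdr < 0.05` with **no fold-change cutoff**.

## Enrichment and pathway direction

Over-representation uses the right-tailed hypergeometric test,
$p = P(X \ge k)$, with BH correction within each collection. The universe is
the set of genes surviving the low-count filter — the population actually
testable — not the whole genome. Gene sets arrive as standard GMT files,
already flattened; ontology-hierarchy traversal is intentionally out of
scope. By default only sets enriched at FDR < 0.05 receive directionality
labels (`collection_direction(enriched_only = FALSE)` scores all sets); the
per-arm positive fraction among called member genes is compared against the
one-third cutoff described above, and single-drug up/down percentages are
reported per set.

## Co-expression and hub ranking

The module stage follows WGCNA's construction at desk scale. Expression
profiles are $\log_2(\mathrm{CPM}+1)$ averaged over replicates within each
(arm, treatment) condition group — six groups for the standard two-arm,
three-condition design. The supported design enumerates exactly these three
treatment levels, so condition-group count follows the design rather than
being a separate parameter. Cross-arm values are concatenated after per-sample
CPM normalization; no additional cross-line normalization is attempted, and
module-trait correlations should be read accordingly.

* adjacency $a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$ with $\beta = 16$
  (unsigned by default; a signed variant is available). The high power is
  what makes the next step work with few observations: it drives
  noise-level correlations to numerical zero while preserving real
  co-expression.
* topological overlap
  $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
  (\min(k_i,k_j) + 1 - a_{ij})$, a neighbourhood-sharing similarity.
* average-linkage clustering on $1 - \mathrm{TOM}$ with a **static** cut at
  0.99 of the maximum merge height; clusters below `min_size = 5` genes
  become `grey`. The static cut replaces WGCNA's dynamic hybrid cut: it is
  deterministic, order-invariant and adequate for the few-hundred-gene
  inputs this stage receives (one interaction group, as in the motivating
  workflow, which ran modules on group A). It is *not* recommended for
  whole-transcriptome matrices.
* module eigengene = first principal component of the z-scored module
  submatrix, unit norm, oriented to correlate non-negatively with the mean
  module profile.
* module-trait association = Pearson correlation of eigengenes with
  phenotype traits (viability and apoptosis percentages per condition
  group), with $t$-distribution p-values ($df = n - 2$). With six condition
  groups these p-values are descriptive and deliberately unadjusted — they
  rank modules, they do not test hypotheses.
* the top module maximizes the *minimum* absolute correlation over traits
  ("strong with both traits"), ties going to the larger module, then the
  lexicographically smaller label.

Hub ranking builds the protein-interaction subgraph induced on the top
module (STRING-style edge list, combined score $\ge$ 0.4, the usual
medium-confidence threshold; 0-1000 integer scores are auto-detected and
rescaled) and sorts genes by degree, then by the number of annotation terms
containing them, then by identifier. Isolated module genes are kept with
degree 0 so the report covers the whole module. Degree is the only
centrality used — the selection logic is "most connected protein", not a
network-science exercise.

## The synthetic experiment

`simulate_ddi_experiment()` generates a complete, fully-labelled experiment
emulating the motivating study's structure: 2 arms x 3 conditions x 3
replicates. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | desk-scale transcriptome |
| `n_reps` | 3 | the study's replication level |
| `dispersion` | 0.05 | BCV ~0.22, typical for cell-line RNA-seq |
| `baseline_meanlog`, `baseline_sdlog` | log(150), 1.2 | log-normal means spanning low to high expression |
| `libsize_sdlog` | 0.2 | realistic depth variation, so TMM has work to do |
| `fraction_de` | 0.15 | planted DE genes, active in all four contrasts |
| `logfc_min`, `logfc_max` | 1, 2 | moderate-to-strong planted effects |
| `p_positive` | 0.309, 0.129 | per-arm positive-interaction probabilities, the arm-level fractions the motivating study observed |
| `module_sizes` | 30, 20 | planted co-expression modules |
| `phenotype_noise` | 2 | percent-scale noise on viability/apoptosis |

DE genes get per-arm fold changes $L_1, L_2$ with
$\operatorname{sign}(L_2)$ set by a Bernoulli draw of the arm's positive
probability — interaction is planted on the combined-vs-single scale,
mirroring the pipeline's baseline choice. Planted modules are sets of DE
genes sharing one treatment-response profile (scaled per gene by a factor in
[0.8, 1.2], plus small log-scale noise controlled by `module_loading`); the
shared profile carries the group-A signature, and the first module's profile
drives the phenotype traits linearly. Counts are NB with log-normal library
factors; the whole simulation is a pure function of the configuration,
including its mandatory seed.

What the generator does *not* emulate: batch effects, gene-gene count
correlation beyond the planted modules, length/GC biases, isoforms, and
outlier samples. Passing recovery tests therefore demonstrates correctness
of the calculus and reasonable statistical behaviour, not robustness to
every artefact of real data.

A separate expression-level generator, `simulate_coexpression_profile()`,
plants modules directly in a gene-by-observation matrix
(member = $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$) and is used to
measure module recovery in isolation; those checks use 20 observation
columns so that empirical correlations estimate $\rho$ faithfully —
with only six columns, correlation noise, not the algorithm, dominates.

## Numerical choices and degenerate inputs

* Exact-zero logFC: indeterminate, excluded with a count (never silently
  classified).
* Tie tolerance $10^{-9}$ at the one-third pathway cutoff; tie mass in the
  exact test counted once via a $10^{-10}$ log-probability tolerance.
* $\phi < 10^{-10}$ switches the conditional law to its binomial limit.
* Constant genes: zero-variance profiles are an error in `adjacency_matrix`
  (correlation undefined); a constant gene's raw dispersion is 0.
* Empty intersections and unscoreable gene sets warn or log and return
  empty, rather than erroring, so batch runs survive sparse inputs.
* All tie-breaks (module naming by size, hub ordering, top-module
  selection) end in lexicographic order, making every output deterministic
  and rerun-identical, which the suite asserts byte-for-byte.

## Problem sizes

The test and acceptance workloads use 2000-gene simulations with 3
replicates (the study's design), 100,000 Monte-Carlo draws for the analytic
null, 200-gene/20-observation profiles for module recovery, and 20 seeded
runs for hub recovery. These sizes give tight Monte-Carlo error (the null
check resolves 0.45 percentage points) while keeping a full run in minutes
on one core.

## Known limitations

* The exact test approximates edgeR's conditioning; marginal calls can
  differ from edgeR on real data.
* The static tree cut under-performs dynamic cutting on large,
  heterogeneous matrices; this stage expects a few hundred pre-selected
  genes.
* Module-trait correlation over six condition groups has very low power;
  it ranks modules, nothing more.
* Gene identifiers are opaque strings; symbol/ID mapping belongs upstream.
* GO hierarchy handling is out of scope — supply pre-flattened GMT
  collections.
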