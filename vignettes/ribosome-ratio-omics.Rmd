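---
title: "Ribosome ratio-omics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosome ratio-omics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboratio)
```

## The stoichiometry barcode

The eukaryotic 80S ribosome is built from roughly 80 conserved ribosomal
proteins (RPs) plus context-restricted paralogs such as RPL10L and RPL39L.
Growing evidence indicates that ribosomes are not a single fixed machine:
the relative proportions of RPs in the ribosome pool differ between
tissues, developmental stages and disease states. `riboratio` quantifies
that heterogeneity from ordinary protein-level quantifications.

Given iBAQ-style intensities — which are proportional to the molar amount
of each protein — the package computes, per sample,

$$
r_{is} \;=\; \frac{x_{is}}{\sum_{j \in D_s} x_{js}},
$$

where $x_{is}$ is the intensity of RP $i$ in sample $s$ and $D_s$ is the
set of RPs *detected in that sample*. The vector $r_{\cdot s}$ lives on the
simplex and is the sample's stoichiometry "barcode". It is invariant to any
per-sample scale factor (loading, instrument response, cell count), which
is the property that makes barcodes comparable across samples without
cross-run normalization.

Two consequences of working on the simplex deserve emphasis:

* **Detection-dependent denominators.** Because $D_s$ is recomputed per
  sample, the ratio of a shared RP shifts when *other* RPs drop in or out
  of detection. We deliberately do not impute or pseudocount at the ratio
  stage; missing stays missing, and the per-sample detected-RP count is
  reported (`detected_rp_counts()`) so that sparsely covered samples can be
  gated (the conventional single-cell gate is >50 detected RPs).
* **Subcompositional closure.** Removing an RP from the catalog rescales
  the remaining ratios of each sample by a common factor. Tests assert this
  proportionality exactly.

Exact zeros are treated as "not detected" rather than as measured
abundances, since the ratio is defined over detected RPs; a flag restores
literal zeros for sensitivity analyses. Duplicate gene symbols are an error
by default — there is no universally correct aggregation over protein
groups — with an opt-in, logged summation mode.

The RP catalog bundled with the package is the union of standard human and
mouse cytosolic RP gene symbols (~80 core proteins, upper-cased for
cross-species matching) plus known paralogs. RACK1, a 40S-associated
scaffold rather than a core RP, is excluded by default and available via
`include_rack1 = TRUE`. Mitochondrial RPs (`MRPL*`/`MRPS*`) are always
rejected from the cytosolic catalog. The number of RPs actually *detected*
is a property of each dataset (published RP proteomes typically report
71–86), so the package reports the count rather than hard-coding a panel.

## Downstream inference

### Scaling

For PCA and heatmap clustering, rows (RPs) are centered and unit-variance
scaled on their non-missing values, so every RP contributes equally
regardless of its absolute share. Rows with fewer than two observations or
zero variance carry no signal at all; they are dropped with a warning and
listed in the `scaling_record` attribute rather than silently padded.

### PCA with SVD imputation

`pca_svd_impute()` performs PCA of the samples with missing values handled
by iterative SVD imputation: missing cells start at their row means; each
iteration computes the $k$ leading right singular vectors of the current
matrix and re-estimates every incomplete row by regressing its *observed*
coordinates on those vectors, the fitted model supplying the row's missing
values. Iteration stops when the imputed entries change by less than `tol`
(relative Frobenius norm, default `1e-6`) or after `max_iter` (default
200) iterations; non-convergence is a warning plus a `converged = FALSE`
flag, never an error, so partial results remain inspectable.

The regression form matters. A naive variant that replaces missing cells
with the rank-$k$ reconstruction of the full matrix has self-consistent
wrong fixed points: a single badly imputed cell is itself a rank-one
perturbation that a rank-2 SVD happily reproduces, so exact low-rank
matrices are *not* recovered. Regressing on observed coordinates only
breaks that feedback; the suite verifies that masked entries of exact
rank-1 matrices are recovered to within `1e-6`, that the masked-entry
error is non-increasing over iterations, and that on complete matrices the
whole procedure collapses to direct SVD PCA (sign-invariant agreement with
`prcomp`).

### Prediction ellipses

Group ellipses in PC1/PC2 are *prediction* ellipses: the region expected
to contain a new observation from the same group with probability 0.95.
With groups as small as $n = 3$ — common in tissue designs — the correct
quantile is the Hotelling-type F form

$$
r^2 \;=\; \frac{2\,(n-1)(n+1)}{n\,(n-2)}\; F_{0.95}(2,\, n-2),
$$

which is noticeably wider than the large-$n$ chi-square(2) limit; both
modes are exposed (`method = "f"` default, `"chisq"` for the asymptotic
form). A Monte-Carlo check at $n = 10{,}000$ fresh draws verifies coverage
within ±0.01. Singular covariances (collinear samples) are an explicit
error, never a silently degenerate ellipse.

### Correlation and clustering

Sample–sample similarity uses the Pearson correlation over pairwise-
complete RP ratios, with the number of shared RPs recorded per pair;
coefficients resting on fewer than three shared RPs are set to missing.
Clustering uses correlation distance $d = 1 - r$ (range $[0, 2]$) with
unweighted average linkage (UPGMA), on rows and columns of the scaled
matrix. The implementation delegates to `stats::hclust`; the test suite
checks it against an independently written $O(n^3)$ UPGMA that follows the
textbook definition merge by merge, on batches of random distance matrices
with up to six leaves, comparing both merge heights and the partition at
every level. `cut_tree()` returns flat cluster labels plus the per-cluster
group composition, and `cluster_purity()` summarizes agreement with known
groups.

### Differential stoichiometry

`differential_ratio()` runs per-RP two-tailed two-sample t tests between
two groups — Student's pooled-variance form by default (Welch by flag; the
variant is recorded in the output attributes) — followed by
Benjamini–Hochberg adjustment across all RPs tested *within the
comparison*. Conventions, each of which is tested:

* an RP is tested only with ≥2 non-missing values per group
  (`tested = FALSE` otherwise, with no fabricated p value);
* identical constant groups give $t = 0, p = 1$; zero variance with
  unequal means is flagged untestable;
* the fold change is `log2(mean_A / mean_B)` of linear-space ratio means —
  ratios are what the method measures, so effects are reported on that
  scale (a per-sample log-ratio mean is a possible alternative; we report
  the ratio of means because group stoichiometries, not per-sample
  logs, are the estimand);
* significance is strict, `p_adj < alpha` (default 0.05), so an adjusted p
  exactly at the threshold is not significant;
* `direction` is `up`/`down` only with both significance and a nonzero
  fold change.

In `"level"` mode the same machinery runs on raw intensities instead of
ratios, which answers a different question (overall ribosome abundance
rather than composition); the mode is recorded in the result.

## The synthetic-data generator

Real RP proteomes of the published study designs are not redistributable
inputs, so every pipeline stage is validated against a seeded generator
(`ribor_spec()`, `generate_dataset()`) with planted ground truth. The
model composes:

1. a baseline stoichiometry on the simplex (deterministic lognormal spread,
   `sdlog = 1.2`, matching the 2–3 orders of magnitude typical of RP iBAQ
   values; or user-supplied; or a Dirichlet draw);
2. per-group planted fold effects on that composition, renormalized;
3. optional Dirichlet resampling per sample (between-sample biological
   variability, concentration `bio_concentration`);
4. a lognormal per-sample total abundance (cell size / loading);
5. multiplicative lognormal measurement noise with coefficient of
   variation `noise_cv`;
6. optional abundance-dependent dropout: detection probability
   `plogis(steepness * (log10(intensity) - midpoint))`, plus optional
   missing-at-random cells for bulk designs.

All randomness flows from the single spec seed through an isolated RNG
scope, so identical specs give bit-identical datasets and interleaved
generators cannot interfere.

**Mass-balanced planting.** Preset fold effects are chosen so that
`sum(baseline * fold) = 1`: the planted mass gained by up-shifted RPs
equals the mass lost by down-shifted ones. Under compositional closure
this is what makes "unchanged" well-defined — without the balance, *every*
unplanted RP's true ratio shifts by the renormalization factor and the
null hypothesis is false for all of them. The suite asserts that unplanted
RPs have identical true ratios across groups in the presets.

The five presets mirror the structure of published ratio-omics study
designs — group sizes, RP counts, and (for single cells) detection depth:

| preset | design | RPs | planted effects |
|---|---|---|---|
| `tissues6` | 6 tissues × 3 | 82 | one 1.8× block per tissue |
| `testis4` | 4 stages × 3 | 81 | RPL10L 1→8→40→80×, RPL39L 1→10× |
| `neuron2` | 2 stages × 3 | 81 | 4 up (2.5×), 3 down |
| `gastric_cohort` | 82 vs 58 | 86 | 34 up, 23 down (1.6×) |
| `macrophage_sc` | 10 vs 38 cells | 71 | 9 up (2×), 9 down (0.5×) |

Effect sizes are didactic defaults, not estimates of the real datasets'
effects (no variance or effect-size estimates are published for them). Two
of them have a biological rationale worth noting: the testis paralogs are
modeled as nearly absent at the earliest stage (baseline share
$5\times10^{-4}$) and switching on with large folds, because
RPL10L/RPL39L are known to be essentially testis-restricted and rise to
substantial shares during spermatogenesis — a 2× effect on an
always-present protein would misrepresent that biology and, at $n = 3$
with BH correction over 81 RPs, would also be statistically invisible.
Each stage's paralog gain is balanced against a sink of high-abundance
RPs. The single-cell preset plants exact 2-fold shifts both ways by
giving the down-set twice the baseline share of the up-set
(9 × 0.016 vs 9 × 0.008), which is the unique way to keep 2× and 0.5×
folds mass-balanced simultaneously.

The single-cell dropout midpoint (3.9 on log10 intensity, steepness 1.5
per decade) was calibrated by Monte-Carlo so that cells retain a median of
about 55 of 71 RPs, reproducing the ">50 RPs per cell" detection depth of
single-cell ribosome proteomes. Its measurement noise is the lognormal
CV-20% term alone (`bio_concentration = Inf`): that is the stated noise
model of the recovery design this preset implements, and the Dirichlet
layer remains available as a knob for sensitivity analyses. Bulk presets
use a tight Dirichlet layer (concentration 20,000; 1,500 for the
heterogeneous tumor cohort) plus 10–20% measurement noise and a small
missing-at-random rate to exercise missing-data paths.

What the generator does **not** emulate: peptide-level identification and
inference, chromatographic or batch effects, correlated noise between RPs
beyond compositional closure, and real biological effect sizes. Passing
recovery tests therefore demonstrates that the pipeline's inference is
correct *under its stated model*, not that any particular real dataset
will show the same power.

## Numerical and design choices

* **Imputation happens only inside PCA.** Ratios, correlations and t tests
  use observed values (pairwise-complete where applicable); only the PCA
  step, whose algorithm is defined with imputation, fills missing cells.
* **Tie-breaks.** UPGMA ties are resolved by `stats::hclust`'s
  deterministic ordering; all outputs are byte-reproducible for identical
  inputs (asserted by rerun tests). Random continuous distances make ties
  measure-zero in the oracle comparisons.
* **BH family.** All RPs tested within one comparison form the family;
  untested RPs are excluded from the family size. Adjusted p values are
  computed by `stats::p.adjust` and checked exactly (to floating-point
  association order) against a brute-force step-up enumeration.
* **Degenerate inputs.** Samples with zero detected RPs, all-constant
  matrices, singular group covariances, out-of-range p values and
  asymmetric distance matrices are all explicit, named errors.
* **Problem sizes in the suite.** The test suite validates the simplex and
  scale-invariance properties on 1,000 random tables, oracle agreement on
  1,000 random p-vectors and 200 random dendrogram instances, ellipse
  coverage on 10,000 Monte-Carlo draws, and BH null control on 200
  simulated null datasets — sizes chosen to give tight empirical checks
  while keeping the default run around a minute.

## A worked run

```{r example, eval = FALSE}
sim <- generate_dataset(ribor_preset("macrophage_sc", seed = 1))
run <- run_pipeline(
  sim$quant, sim$groups,
  contrast = c("LPS", "control"), k = 2
)
glance(run$diff)
evaluate_recovery(run$diff, sim$truth)
autoplot(run$pca, groups = sim$groups)  # scores + 95% ellipses
autoplot(run$diff)                      # volcano
```

## Limitations

* Barcodes from whole-cell lysates reflect the RP *pool*, not necessarily
  assembled ribosomes; interpretation as ribosome composition is strongest
  for purified-monosome inputs.
* The per-sample detected-RP denominator means barcodes are only strictly
  comparable between samples of similar detection depth; the QC gate
  exists precisely to enforce that.
* Compositional effects make single-RP fold changes partly relative
  statements; mass-balanced simulations quantify pipeline behavior, but
  real perturbations are rarely balanced, so genuine global shifts will
  distribute small opposite-signed effects across all other RPs.
* No GO enrichment or protein-interaction analysis is included; those are
  external-database services outside the package's scope.
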