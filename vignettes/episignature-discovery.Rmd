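---
title: "Deriving and validating DNA methylation episignatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating DNA methylation episignatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many Mendelian neurodevelopmental disorders — Pitt-Hopkins syndrome among
them — leave a reproducible genome-wide DNA methylation pattern in
peripheral blood, an *episignature*, that can serve as a diagnostic
biomarker and as functional evidence for reclassifying variants of
uncertain significance. episignr implements the full derivation loop for
such a classifier from an Infinium EPIC-style beta-value matrix: per-probe
differential methylation statistics, signature probe selection with
iterative removal of signature-negative cases, a calibrated support vector
machine producing a methylation variant pathogenicity (MVP) score, and the
three standard robustness views (cross-validation, hierarchical
clustering, multidimensional scaling), plus cross-cohort comparative
tooling.

Because real patient cohorts of this kind are not publicly distributable,
the package ships a seeded synthetic cohort generator whose defaults stand
in for the study conditions, with machine-readable ground truth so every
stage can be benchmarked against what was planted.

## The statistical model

Beta values `b` (methylated fraction, in `[0, 1]`) are heteroskedastic and
bounded, so hypothesis testing happens on the logit-2 M-value scale,
`M = log2(b / (1 - b))`, after clipping `b` to `[0.01, 0.99]`; effect
sizes are reported back on the interpretable beta scale as
`delta-beta = mean_beta(cases) - mean_beta(controls)`. The clipping
epsilon of 0.01 bounds `|M|` by about 6.6 and keeps extreme probes from
dominating the variance model.

For each probe, ordinary least squares fits `M ~ intercept + group
(+ covariates such as age and sex)`. With tens of thousands of probes and
modest cohorts, per-probe variance estimates are noisy; they are shrunk by
an empirical-Bayes scheme that models the true variances as scaled
inverse-chi-square with prior degrees of freedom `d0` and scale `s0^2`,
estimated by the method of moments on `log(s2)`. The moderated statistic

```
s2_post = (d0 * s0^2 + df * s2) / (d0 + df)
t_mod   = coef / (sqrt(s2_post) * se_unit)
```

is referred to a t-distribution with `d0 + df` degrees of freedom. At
`d0 = 0` this reduces to the ordinary t-test; as `d0 -> Inf` every probe
is tested at the pooled variance. The test suite verifies both limits
numerically and checks the whole moderation path against an independent
reference implementation. Multiple testing uses Benjamini-Hochberg
step-up q-values.

## Probe selection

Signature probes must be individually significant, biologically
meaningful in effect size, and jointly non-redundant. `select_probes()`
applies, in order:

1. `q <= q_max` (default 0.01);
2. `|delta-beta| >= min_abs_delta` (default 0.05);
3. rank by `|delta-beta| * (-log10 p)`, ties broken by probe id, truncate
   to `top_n` (default 500);
4. greedy correlation pruning: walking down the ranking, drop any probe
   whose Pearson correlation with an already-kept probe exceeds
   `corr_max` (default 0.85).

The effect-size floor is deliberately set at 0.05, the conventional
minimum methylation difference considered reliable on blood arrays,
rather than at the centre of the plausible effect-size range: sampling
noise in a realized delta-beta is a few percentage points at these cohort
sizes, so a floor placed at the typical effect magnitude (around 0.10)
would reject roughly half of the genuinely differential probes and halve
recall for no gain in precision. The q-value filter carries the burden of
type-I control; the delta filter only removes statistically significant
but biologically negligible differences. All four parameters are exposed.

## The MVP classifier

The classifier is a linear-kernel soft-margin SVM (`C = 1`, balanced class
weights) on the beta values of the signature probes — bounded features
that mirror what the heatmap and MDS views display; an M-value feature
space is available behind a flag. Cases form the positive class; the
negative class is controls plus any other-disorder samples, which trains
specificity against unrelated phenotypes when such cohorts are present.

Raw decision values are mapped to the MVP score by Platt scaling,
`mvp = 1 / (1 + exp(A * d + B))`, with `(A, B)` fitted by
prior-corrected maximum likelihood on decision values from an internal
stratified 3-fold cross-validation, so calibration is not inflated by the
training fit. Clinical calls follow the strict cutoffs used in
episignature practice: *positive* above 0.5, *negative* below 0.25,
*inconclusive* in between (the boundary values themselves are
inconclusive, since the conventions are stated as strict inequalities).

Cohorts often contain cases that genuinely lack the episignature —
mosaicism diluting the bulk signal, hypomorphic alleles, or phenocopies.
`iterative_case_pruning()` scores every discovery case with a classifier
derived with that case held out, removes cases below the 0.25 cutoff, and
repeats (up to 3 rounds) until stable. If more than half the cases are
flagged in one round, the signature is declared untrustworthy and the run
aborts rather than silently discarding the cohort.

## Validation views

`cross_validate()` performs leave-25%-out cross-validation (default 20
rounds): each round holds out a stratified quarter of cases and of
controls and re-derives *everything* — probe selection included — on the
remainder before scoring the held-out samples. Re-deriving inside the
loop is what makes the exercise honest; reusing globally selected probes
would leak the held-out samples into selection. A master seed spawns
per-round seeds by fixed arithmetic, so rounds are independent but
reproducible.

Hierarchical clustering uses Euclidean distance and Ward linkage
(`ward.D2`). The linkage is a design choice — "Euclidean clustering" does
not pin one down — made for its compact, balanced clusters; it is
config-exposed at the function level. Columns are sorted by sample id
before clustering, which fixes the leaf order deterministically.
`mds_embed()` implements classical (Torgerson) metric MDS via the
double-centered Gram matrix, with a deterministic sign convention (first
nonzero loading positive). Whether the original analyses used metric or
non-metric MDS is unknowable from the description; classical metric MDS
is implemented and labeled as such.

## Comparative epigenomics

`build_cohort_signature()` applies the published convention for
cross-disorder comparison: all DMPs at FDR < 0.05, capped at the top 500
by ascending p (cohorts with fewer keep all). `overlap_matrix()` reports
the directional percentage of row-cohort probes present in the
column-cohort signature, and `cohort_tree()` clusters cohorts in the
union feature space, where a probe absent from a cohort's signature
contributes 0 — the natural neutral value for "no differential
methylation"; the tree's leaf attributes carry signature size and mean
methylation difference, the node size and color of a tree-and-leaf plot.

CpG-island context follows the standard distance bins: *island* inside an
island, *shore* within 0–2 kb of a boundary, *shelf* within 2–4 kb, *open
sea* beyond; the shelf bin extends the printed 0–2 kb shore definition
symmetrically. Gene-region labels (promoter, promoter+, gene body,
intergenic) are taken from the supplied annotation rather than recomputed
from transcription start sites. Enrichment uses Fisher's exact test per
category with BH adjustment across categories and a Haldane 0.5
correction for zero cells.

## The synthetic cohort generator

`simulate_cohort()` emulates the features of an EPIC discovery study that
matter to the pipeline:

* **Baseline bimodality** — probe means drawn from a 45% low (≈0.1) /
  45% high (≈0.9) / 10% intermediate beta mixture, the characteristic
  two-humped distribution of array betas.
* **Planted episignature** — default 200 probes (of 20,000) shifted in
  cases by per-probe deltas drawn uniformly from 0.05–0.15 (mean 0.10),
  70% towards hypermethylation, planted on probes with headroom so
  clipping never truncates the effect.
* **Noise** — each observation is `Beta(mu * k, (1 - mu) * k)` with
  concentration `k = 100`, giving bounded, heteroskedastic noise whose
  spread peaks at intermediate means, as on real arrays.
* **Covariates** — 1% of non-planted probes drift linearly with age on
  the M scale; a 0.5% block responds to sex. These exercise covariate
  adjustment without modeling chromosome X explicitly.
* **Negative and mosaic cases** — a case's planted effect is diluted
  linearly by its mosaic cell fraction `m` (a bulk mixture of affected
  and unaffected cells); episignature-negative cases are simply `m = 0`.
* **Related cohorts** — `simulate_multi_cohort()` plants controlled
  signature overlap between cohorts sharing one probe universe and
  baseline, so directional overlap recovery can be tested exactly.

Default cohort sizes (60 cases, 85 controls, 11 validation cases) mirror
the discovery study the pipeline is modeled on. What the generator does
*not* emulate — probe-type chemistry, cell-composition heterogeneity
beyond the scalar dilution, batch structure, genuine chromosomal dosage —
bounds what passing tests show: they demonstrate that the pipeline
recovers what was planted under realistic noise, not that any particular
clinical cohort would behave as cleanly.

## Numerical and degenerate-input choices

* p-values are floored at the smallest positive double so ranking scores
  stay finite.
* When observed variances are under-dispersed relative to chi-square
  sampling noise, the moments estimator returns `d0 = Inf` and all
  probes are tested at the pooled variance (normal reference).
* Probe selection with no passing probe raises an error reporting the
  strictest attained thresholds; the comparative signature builder,
  whose downstream tolerates empty sets, warns instead.
* Ties are broken lexicographically everywhere (probe ids in ranking,
  control ids in matching, sample ids in clustering leaf order), which
  makes every output order-invariant to input permutations.
* Greedy nearest-age matching is used rather than optimal matching:
  deterministic, transparent, and adequate at these cohort sizes.

## Problem sizes in the test suite

The shipped tests benchmark parameter recovery at the full default scale
(20,000 probes, 60/85 cohorts) for the headline checks, and at reduced
scales (2,000–10,000 probes, 20–30 samples per arm) for per-module
properties, chosen so the whole suite completes in a couple of minutes
while keeping every planted-truth comparison well-powered. Null
calibration of the discovery p-values is checked at 20,000 probes over
10 seeds (mean Kolmogorov-Smirnov statistic below 0.02).

## Known limitations

* Raw IDAT processing, normalization, probe QC and cell-type
  deconvolution are out of scope; the pipeline starts from a clean beta
  matrix.
* The iterative pruning loop retrains one classifier per case per round;
  at very large cohort sizes a screened or cached variant would be
  needed.
* The generator's linear mosaic dilution is the simplest defensible bulk
  model; real mosaicism can be tissue- and locus-heterogeneous.
* Specificity against *unresolved clinical cases* (as opposed to healthy
  controls) requires a population the generator does not model; only the
  on-controls analog is reproduced here.
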