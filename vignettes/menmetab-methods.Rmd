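---
title: "Metabolomic subtyping with menmetab: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic subtyping with menmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menmetab)
```

## Overview

menmetab implements an end-to-end subtyping workflow for 1D ^1H-NMR
metabolite profiles of small tumour cohorts: normalisation, unsupervised
clustering with silhouette-guided model selection, cluster signatures,
weighted correlation network analysis (WCNA), metabolite-set enrichment,
and clinical/survival statistics. This vignette documents the models and
their assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## The processing chain and its assumptions

### Normalisation

`pq_normalize()` performs pseudo-counted quantile normalisation: a
pseudocount (default 1.0, on the raw intensity scale) is added to every
entry, then each sample's sorted intensity vector is replaced by the
across-sample mean of order statistics, re-inserted in the sample's rank
order. Runs of ties receive the mean of their reference quantiles. The
assumption is the usual one for quantile methods: samples share a common
intensity distribution and between-sample distributional differences are
technical. After normalisation every sample has literally the same sorted
value multiset (exactly so in continuous data). `log2_median_center()`
then moves to log2 scale and subtracts each metabolite's median across
samples, so that per-metabolite location differences cancel and fold
changes are additive. `top_variable()` keeps the `n` metabolites of
largest unbiased sample variance (default 100), ties broken by name so
the selection is reproducible.

The pseudocount magnitude and the mean-of-order-statistics reference are
conventions, not estimates; both are configurable, and the pipeline's
state flags (`raw` → `normalized` → `log2_centered`) prevent stages from
being applied out of order.

### PAM clustering and silhouette model selection

`select_k()` runs classic BUILD+SWAP k-medoids on Euclidean distances
between sample profiles for every k in 2–12 and keeps the k with the
largest mean silhouette width, breaking ties toward the smaller k
(parsimony). The SWAP phase applies the best single medoid/non-medoid
exchange until no exchange lowers the total cost; the cost trace is
asserted non-increasing. The algorithm is deterministic: the seed only
randomises the candidate ordering used to break exact cost ties.
Euclidean distance on the top-100 log2-centred matrix is the default
(correlation distance `1 − r` is available via `metric`). Samples with
negative silhouette width are flagged non-core; signature extraction
downstream uses core samples only. All-identical samples are rejected
with an explicit error rather than returning an arbitrary k.

### Signatures

Two complementary routes are provided and reported side by side, since
either could plausibly generate a published signature list:

* `shrunken_centroid_signature()` — nearest shrunken centroids. The
  class contrasts `d_ik = (x̄_ik − x̄_i)/(m_k (s_i + s0))` use the pooled
  within-class SD `s_i` and the offset `s0 = median(s_i)` (the standard
  stabilisation against near-zero variances). The shrinkage threshold Δ
  is chosen by stratified cross-validation as the **largest** Δ within
  one standard error of the minimal misclassification rate. Note the
  consequence: when classes separate easily, CV error is zero over a wide
  Δ range and the rule deliberately returns a *sparse* sufficient
  signature, not an exhaustive list of every differential metabolite.
  Analysts wanting the dense list should read it off `fit$cv` at the
  smallest Δ attaining the minimum, or use the linear-model route.
* `glm_signature()` — per-metabolite ordinary least squares of centred
  log2 intensity on a class indicator, two-sided slope p-values,
  Benjamini–Hochberg adjustment across metabolites (default α = 0.05).
  Zero-variance metabolites get p = 1 with a flag instead of an error.

### WCNA

`run_wcna()` builds the unsigned weighted adjacency
`a_ij = |cor(x_i, x_j)|^β`. The power β is the smallest value whose
signed scale-free fit index reaches 0.8 — the index is the R² of
`log10 p(k)` on `log10 k` over ten connectivity bins, negated when the
slope is positive, since a scale-free degree law must decay — subject to
a floor `beta_min = 5`. The floor is a deliberate design decision: on
cohorts of a few dozen samples the background correlation level
(`|r| ≈ n^{-1/2}`) lets the scale-free criterion pass already at β = 1–2,
where the adjacency retains almost no contrast between genuinely
co-regulated metabolites and sampling noise and the topological overlap
landscape is too flat for stable module separation.

Topological overlap follows the standard formula, modules come from
average-linkage clustering of `1 − TOM` with a **static cut at height
0.975** (configurable), clusters below `min_size = 5` fall into the grey
pool, and modules whose eigengenes correlate above 0.9 are merged
iteratively. The cut height deserves explanation: with ~43 samples and
within-module correlations around 0.6, TOM values between true module
members are only ~0.05–0.15, so real branches join the tree at heights
0.85–0.97 while unrelated metabolites join close to 1. A traditional cut
at 0.7–0.8 — appropriate for large expression datasets with stronger
correlations — returns an all-grey solution on every cohort this
package's own generator produces, which is why the default sits high.
Both the height and the minimum size remain user-settable.

Eigengenes are first principal components of the standardized member
submatrices, unit-variance, sign-oriented so the mean correlation with
members is positive (so negating all member profiles leaves the oriented
eigengene invariant). kME is the Pearson correlation of each metabolite
with each eigengene. `module_trait_stats()` correlates eigengenes with
clinical traits (binary indicators for WHO grade I/II/III, high edema,
male sex and each location; continuous age, volume, MIB-1, KPS), with p
from the t transform at n − 2 df and BH adjustment over the full
module × trait grid — the widest, most conservative family. For binary
traits a single-predictor logistic regression is reported alongside,
because published module–trait "R" values are sometimes point-biserial
correlations and sometimes logistic-model statistics; emitting both
removes the ambiguity. The network itself is unsigned while kME keeps
its sign, which reproduces the common reporting style of negative
module–trait correlations over an unsigned network.

`cluster_of_clusters()` jointly clusters module eigengenes and
standardized metabolite profiles under correlation distance with average
linkage. The originating description of this analysis is terse; this
joint-clustering reading — modules and metabolites co-cluster when their
sample patterns (equivalently their kME fingerprints) agree — is a
declared design choice.

### Enrichment

`ora()` is the hypergeometric over-representation test with enrichment
score `ES = (k/n)/(K/N)`, the observed-over-expected hit ratio. Published
"enrichment scores" in this field rarely state their definition; this
ratio is the convention adopted here and is documented as such rather
than matched to any printed value. The universe is all quantified
metabolites. `qea()` is the quantitative counterpart — per-set mean
absolute Welch t between two clusters, label-permutation p with +1
smoothing (so p is never exactly zero), BH across sets — and needs no
hard signature cut.

### Clinical statistics

The 2×2 tests follow the conventions that reproduce standard printed
cohort tables: Fisher's two-sided p sums hypergeometric point
probabilities no larger than the observed one (relative tolerance
1 + 1e−7, log-space computation); the chi-squared test applies **no**
Yates continuity correction by default (the correction is available
behind a flag — with it, the edema-style tables in reference cohorts no
longer match their printed two-decimal p-values); the Welch (not pooled)
t statistic is computed directly from printed group summaries with
Welch–Satterthwaite degrees of freedom. Wilcoxon uses exact enumeration
for `n1 + n2 ≤ 12` without ties and the tie- and continuity-corrected
normal approximation otherwise. Kaplan–Meier estimation is delegated to
the survival package; the log-rank statistic is computed explicitly from
the per-event-time `O/E/V` table (which the result object exposes) and
cross-checked against `survival::survdiff` in the test suite.
`cohort_table()` assigns tests per row: Fisher for sparse categoricals,
chi-squared for the edema 2×2 (expected counts ≥ 5), Welch for age and
volume, Wilcoxon for KPS; p-values are kept at full precision with a
two-decimal display column.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the analysis assumes: 43
samples and 270 metabolites, subtype sizes 15 / 13 / 15 (subtype I =
cluster 1; II-a and II-b form cluster 2 — the 13/15 split is chosen so
the cluster-2 WHO-grade composition, 13 grade I and 15 grade II+III, can
be mirrored), a log2-scale generative model

> x = baseline + subtype effect (1.0 on that subtype's signature set) +
> module loading (0.6) × latent factor + N(0, 0.5²) noise,

with intensities `2^x`. Baselines are N(0, 1) per metabolite, i.e.
log-normal abundances. The three signature pathways (glycine/serine for
subtype I; choline/phosphocholine/sphingosine for II-a;
tryptophan/kynurenine for II-b, with choline shared) seed the first
three of five 12-metabolite modules.

The module latent factors are where the generator takes its one
substantive stand. Real subtype-defining pathways are not independent of
the subtypes — the grade-associated modules of a real cohort carry the
subtype contrast. The factors are therefore mixed: factor 1 is the
standardized cluster-1 indicator (a grade-I module), factors 2 and 3
load `sqrt(0.20)` on the standardized II-a and II-b indicators
respectively, and factors 4 and 5 carry only a faint (`sqrt(0.10)`,
opposite-sign) cluster trace, leaving them effectively grade-neutral.
These weights were fixed once, at design time, as the balance point of
two opposing requirements: strong enough subtype linkage that the
two-cluster structure dominates the top-100 variance landscape, and weak
enough inter-factor correlation that the five modules remain mutually
distinguishable in the topological-overlap tree. Pushing linkage up
merges modules; removing it dissolves the clusters. `link_modules =
FALSE` yields fully independent factors for null experiments.

Clinical covariates are drawn with per-cluster margins matching the
reference cohort (sex, edema, location, Simpson grade, KPS levels, MIB-1
log-normal around per-subtype means 1.2 / 2.1 / 11.7%), and
`exact_margins = TRUE` reproduces the reference contingency counts
deterministically — the mode used to validate the cohort-table stage.
Progression-free survival is exponential per cluster (0.01 and 0.05
events/month) with administrative censoring at 60 months.

What the generator does **not** emulate: realistic NMR artifacts
(phasing, baseline roll, water residual), metabolite-specific abundance
distributions, dependence between clinical covariates beyond their
cluster linkage, non-exponential hazards, or annotation error in
metabolite identification. Tests passing on this design therefore
demonstrate algorithmic correctness and statistical behaviour under a
clean factor model — not robustness to spectral artifacts or real
biological covariance structure.

`simulate_spectra()` renders per-sample toy spectra as sums of Lorentzian
templates on a fixed 2^14-point grid spanning a 16.02 ppm sweep centred
at 4.691 ppm — desk-scale resolution standing in for 64k acquisition
points — with a lactate doublet whose taller line sits exactly at
1.310 ppm, and per-sample chemical-shift offsets up to ±0.02 ppm applied
as whole-spectrum translations by an integer number of grid steps.
Alignment therefore recovers shifts to within one grid step by
construction; the apex rule is a plain argmax in the search window (no
quadratic interpolation), the simplest contract consistent with setting
a reference peak manually.

## Numerical choices and degenerate inputs

* Tie-breaks: smallest k in model selection; metabolite name order in
  variance ranking and hub ranking; seed-permuted candidate order for
  exact cost ties in PAM.
* Degenerate inputs fail loudly: all-identical samples (clustering),
  flat alignment windows, non-symmetric adjacencies, single-cluster
  cohort tables, zero-margin chi-squared. Soft degeneracies are flagged,
  not fatal: singleton silhouette clusters get width 0, zero-variance
  metabolites get kME 0 and linear-model p = 1, rank-deficient template
  bases warn and return the NNLS minimum-norm solution.
* The QEA permutation p uses +1 smoothing; the Fisher p is clamped at 1.
* One master seed drives `run_all()`, forked deterministically per stage
  by a small string hash, so individual stages can be re-run stably.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
43 × 270 cohorts over 20 seeds, CV-based signature selection at 30-point
Δ grids, permutation tests at 99–1000 permutations, and oracle
equivalence checks on 8-sample / 8-node instances plus full Fisher
enumeration for all margins with N ≤ 20 — sizes chosen so a complete run
of everything stays in the minutes range on a single core while keeping
every recovery experiment at the cohort scale the design describes.

## Known limitations

* The module-recovery and cluster-recovery regimes genuinely compete at
  this sample size (see the generator section); both are near their
  feasibility boundary at the default effect size and noise level, and
  single-seed results fluctuate.
* The shrunken-centroid one-SE rule yields sparse signatures by design;
  it should not be expected to return every planted differential
  metabolite (use `glm_signature()` for exhaustive lists).
* The built-in template library is stylised (a handful of Lorentzian
  lines per metabolite), suitable for validating alignment and NNLS
  quantification, not for fitting real spectra.
* No Cox regression or multivariable survival modelling; no consensus
  clustering; no KEGG map rendering or online pathway retrieval.
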