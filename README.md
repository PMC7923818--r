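# menmetab

Metabolomic subtyping of tumour cohorts from 1D ^1H-NMR metabolite
profiles, built around the analysis workflow used to stratify meningiomas
into metabolic subgroups: quantified metabolite intensities are
quantile-normalised, the most variable metabolites are clustered by
partitioning around medoids (PAM) with the cluster number chosen by mean
silhouette width, cluster signatures are extracted by nearest shrunken
centroids and per-metabolite linear models, co-abundance structure is
mapped by weighted correlation network analysis (WCNA), and the resulting
subgroups are compared on clinical covariates and progression-free
survival.

The package is aimed at analysts working with modest tumour cohorts
(tens of samples, a few hundred quantified metabolites) who want the
whole chain — simulation, normalisation, clustering, networks,
enrichment, survival — as composable, pipe-friendly functions with tidy
outputs.

## The methods in brief

* **PAM + silhouette model selection.** For each candidate k in 2–12,
  BUILD+SWAP k-medoids minimises the total distance
  `cost = Σᵢ d(xᵢ, medoid(xᵢ))`; the chosen k maximises the mean
  silhouette width `s(i) = (b(i) − a(i)) / max(a(i), b(i))`. Samples with
  `s(i) < 0` are flagged non-core and excluded from signature extraction.
* **Nearest shrunken centroids.** Class contrasts
  `d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s0))` are soft-thresholded by Δ,
  with Δ chosen as the largest value within one standard error of the
  minimal cross-validated misclassification rate.
* **WCNA.** Unsigned adjacency `a_ij = |cor(x_i, x_j)|^β` with β selected
  by approximate scale-free topology, topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  average-linkage modules from `1 − TOM`, module eigengenes (first
  principal components), kME module membership, and module–trait
  correlation/logistic statistics with Benjamini–Hochberg adjustment.
* **Enrichment.** Over-representation (hypergeometric upper tail,
  `ES = (k/n)/(K/N)`) and a quantitative permutation test (mean |Welch t|
  of set members) against a built-in pathway library.
* **Cohort statistics.** Fisher's exact and Pearson chi-squared 2×2
  tests, Welch's t from group summaries, Wilcoxon rank-sum, Kaplan–Meier
  curves and the log-rank test, assembled into a clinical
  characteristics table.

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates the
study design — 43 samples × 270 metabolites, a benign cluster of 15 and
a second cluster of 28 that splits into two subclusters, five correlated
metabolite modules (three of them subtype-linked), cluster-linked
clinical covariates and exponential progression-free survival — so the
entire pipeline is testable without patient data. A toy spectral stage
(`simulate_spectra()`, `align_to_lactate()`, `quantify_spectrum()`)
renders Lorentzian template spectra on the acquisition grid, aligns them
to the lactate reference at 1.310 ppm and quantifies them by
non-negative least squares.

## Worked example

```r
library(menmetab)

cohort <- simulate_cohort(sim_config(), seed = 1)

clust <- cohort$metabolites |>
  pq_normalize() |>
  log2_median_center() |>
  top_variable(100) |>
  select_k(seed = 1)
clust
#> <metab_clust> k = 2, mean silhouette 0.181, 43/43 core samples
#> cluster
#>  1  2
#> 28 15
```

The silhouette-optimal partition is k = 2 and recovers the planted
15/28 split (cluster ids are arbitrary). Network analysis finds the five
planted modules and their clinical associations:

```r
net <- run_wcna(cohort$metabolites |> pq_normalize() |> log2_median_center(),
                clinical = cohort$clinical)
glance(net)
#> # A tibble: 1 × 4
#>    beta n_modules n_grey max_scale_free_r2
#> 1     5         5    213             0.974

head(dplyr::arrange(net$trait_stats, p_adj), 3)
#> # A tibble: 3 × 7
#>   module trait        r    p_value    p_adj logistic_beta logistic_p
#> 1 M2     grade_I -0.635 0.00000477 0.000406         -2.01    0.00104
#> 2 M1     grade_I  0.532 0.000238   0.00506           2.48    0.0654
#> 3 M1     mib1    -0.533 0.000236   0.00506          NA      NA
```

Here module M1 (the glycine/serine module) tracks benign WHO grade I
histology and low proliferation, while M2 is anti-correlated with grade
I — the module–grade association structure the generator plants. The
subgroups differ strongly in progression-free survival:

```r
surv <- log_rank(cohort$clinical$pfs_time, cohort$clinical$pfs_event,
                 tidy(clust)$cluster)
surv
#> <metab_logrank> chisq = 8.260 (1 df), p = 0.004054
autoplot(surv)   # Kaplan-Meier curves per cluster
```

`cohort_table()` produces the clinical characteristics table (counts,
means, the appropriate test and its p-value per row), and `run_all()`
chains every stage — normalisation, clustering, subclustering,
signatures, WCNA, enrichment, cohort statistics and survival — into one
reproducible, seeded report bundle.

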