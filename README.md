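# riskclust

Unsupervised stratification of palliative oncology cohorts from
survival-linked biomarker panels.

## The problem

Patients with advanced liver malignancies under palliative treatment (SIRT —
selective internal radiation therapy — or TACE — trans-arterial
chemo-embolisation) are clinically heterogeneous, and single biomarkers
rarely separate good from poor survivors. A practical alternative is to let a
panel of candidate biomarkers speak jointly: score each patient's risk under
each biomarker separately, adjusted for clinical confounders, and then look
for groups of patients whose *risk profiles* — not their raw measurements —
are stable under resampling.

`riskclust` implements that workflow end to end for biostatisticians working
with cohort tables (one row per patient: survival time in months, death/censor
indicator, confounders, a continuous biomarker panel):

1. **Per-biomarker Cox models.** For each biomarker \(b\) a proportional-
   hazards model \(\lambda_i(t) = \lambda_0(t)\exp(x_i\beta)\) is fitted by
   Newton–Raphson maximisation of the partial likelihood (Efron tie
   correction), with the confounders age, gender, therapy and primary-tumour
   diagnosis as candidate terms and biomarker-by-therapy /
   biomarker-by-diagnosis interactions in scope. Terms are selected by
   bidirectional stepwise search on the Akaike Information Criterion, the
   biomarker itself is never dropped, and the proportional-hazards assumption
   can be checked with the Grambsch–Therneau scaled-Schoenfeld score test.
2. **Risk profiles.** The centred linear predictors \(\eta_i = x_i\hat\beta\)
   of the per-biomarker models are concatenated into a patients × biomarkers
   matrix (z-scored per column by default) — each patient's
   confounder-adjusted risk profile.
3. **Consensus clustering.** The profiles are clustered by resampling-based
   consensus hierarchical clustering (average linkage, Euclidean distance,
   100 resamples of 80% of patients, k = 2…5). The consensus matrix entry
   \(M_k(i,j)\) is the fraction of resamples containing both patients in which
   they co-clustered; the number of clusters is chosen by the delta-area
   criterion on the consensus CDF: \(\Delta(k) = (A(k)-A(k-1))/A(k-1)\), with
   the largest gain for k ≥ 3 selected when it exceeds τ = 0.1, else k = 2.
4. **Cluster characterisation.** Kaplan–Meier curves and the log-rank test
   across clusters; χ²/ANOVA confounder-association tests; all cluster-pair ×
   biomarker Wilcoxon rank-sum tests under a joint Benjamini–Hochberg
   correction; min-max normalised biomarker patterns and per-cluster /
   per-subgroup median–IQR summaries.

Because cohorts of this kind are rarely shareable, the package ships a seeded
synthetic-cohort generator (`simulation_config()`, `generate_cohort()`) with
planted subgroups, subgroup-shifted biomarkers (including Dirichlet-drawn
comet-assay class fractions that sum to one), Weibull-baseline proportional
hazards and calibrated right censoring, so every stage is testable.

## Worked example

```r
library(riskclust)

cohort <- generate_cohort(simulation_config(seed = 5))   # 108 patients
result <- run_pipeline(cohort, pipeline_config(seed = 5))
result$consensus
#> <consensus_result> n = 108 patients, k in {2, 3, 4, 5}, 100 resamples (fraction 0.80)
#> # A tibble: 4 × 3
#>       k     A  delta
#>   <int> <dbl>  <dbl>
#> 1     2 0.450 0.450
#> 2     3 0.665 0.478
#> 3     4 0.685 0.0293
#> 4     5 0.700 0.0225
#> selected k = 3 (delta-area rule, tau = 0.10)
```

The area under the consensus CDF grows strongly up to k = 3 (Δ(3) = 0.478)
and barely afterwards, so three stable patient subgroups are selected.

```r
result$report
#> <characterization_report> 3 clusters, BH family = global
#> log-rank: chi2 = 33.470, df = 2, p = 5.4e-08
#> # A tibble: 3 × 4
#>   cluster     n n_events median_survival
#>     <int> <int>    <int>           <dbl>
#> 1       1    35       31            3.80
#> 2       2    35       28            6.25
#> 3       3    38       15           22.4
#> 29 of 36 pairwise biomarker tests significant after BH (q < 0.05)
```

Clusters are labelled by increasing median survival (cluster 1 = worst,
cluster 3 = best; here 3.8 vs 22.4 months, log-rank p = 5.4e-08), and the
planted prognostic markers (comet classes, S100, SOD-2, profilin, RhoA,
thioredoxin, MMP-9) all separate the extreme clusters after
Benjamini–Hochberg correction, while the confounder-association tests stay
non-significant (age p = 0.38, gender 0.23, therapy 0.44, diagnosis 0.14,
comorbidities 0.95) — the confounders are generated independently of the
planted subgroups.

Useful entry points: `kaplan_meier()` + `autoplot()` for survival curves,
`fit_cox()` / `stepwise_aic()` / `test_ph()` for individual models,
`consensus_cluster()` for clustering arbitrary profile matrices,
`characterize()` for the statistics, and `tidy()` / `glance()` on every
fitted object. `run_pipeline(..., pipeline_config(out_dir = "..."))` writes
all artifacts (`profiles/`, `consensus/`, `report/`, `manifest.json`) as
CSV/JSON with no timestamps, so runs are byte-reproducible. A thin CLI lives
in `inst/cli/riskclust-cli.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the number of stable
patient subgroups selected by the delta-area criterion on the default
validation scenario: 50 synthetic cohorts (n = 108, 12-biomarker panel,
planted subgroup structure, ~30% censoring) are run through the full
pipeline — stepwise Cox risk profiles, consensus clustering with 100
resamples over k = 2…5, delta-area selection — and the modal selected k is
written as JSON.
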