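# dcnet — disease correlation networks from longitudinal medical records

Longitudinal electronic medical records contain, per patient, the dates on
which diseases were first diagnosed. `dcnet` screens such a table for
directional temporal correlations between disease states: for every
ordered pair X → Y it asks whether an earlier diagnosis of X is associated
with a sooner later diagnosis of Y, and assembles the significant pairs
into a directed, explorable disease-correlation network. It is written for
epidemiologists and biomedical-informatics researchers who want to mine
their own EMR extracts for hypothesis-generating comorbidity structure.

For each ordered pair the package

1. builds a **matched retrospective cohort**: exposed = patients diagnosed
   with X (index date = first X diagnosis); each is 1:1 matched to a
   random comparison subject never diagnosed with X, with the same gender
   and ethnicity, age at index within 5 years, and an index date — the
   date of a randomly chosen non-X diagnosis — within 7 days of the
   case's (all defaults configurable). The event is the first Y diagnosis
   after index within a 3650-day window; records ending earlier are
   dropouts (censored);
2. fits a **Cox proportional-hazards model**
   ln h(t)/h₀(t) = b₁P₁ + … + bₙPₙ, where the predictors are the exposure
   indicator plus confounders (age, gender, ethnicity, any extra
   columns); exp(b_exposed) is the adjusted hazard ratio for X → Y;
3. independently fits a **random survival forest** (log-rank splitting,
   terminal-node Nelson–Aalen estimates), reduces each subject's predicted
   curve to its restricted mean survival time (the integral of S(t) up to
   the window), and compares groups with Wilcoxon rank-sum and t tests;
4. runs **quality controls**: a Schoenfeld-residual proportional-hazards
   test, Cox–Snell residual plot data, and a two-sample Kolmogorov–Smirnov
   comparison of dropout timing between groups;
5. applies **Benjamini–Hochberg correction** across all pairs of the run
   (per arm) and keeps pairs with adjusted p ≤ 0.05 — by default those
   significant in *both* arms and in the positive (accelerating)
   direction — as network edges with degree summaries, filtering,
   shortest-path trajectories, and CSV / GraphML / Cytoscape-JSON export.

Because real hospital extracts are rarely shareable, `simulate_emr()`
generates synthetic first-diagnosis tables with planted hazard-ratio
effects and known ground truth; the test suite validates the whole
pipeline against it. See the vignette
(`vignettes/disease-correlation-networks.Rmd`) for the model details,
assumptions and design choices.

## Worked example

```r
library(dcnet)

# simulate records for 8000 patients with one planted effect: a diagnosis
# of D01 triples the hazard of a later D02 diagnosis
cfg <- simulation_config(
  n_patients = 8000,
  planted_effects = data.frame(from = "D01", to = "D02", hazard_ratio = 3),
  seed = 7)
sim <- simulate_emr(cfg)
sim$dataset
#> <emr_dataset> 9049 first-diagnosis records, 5101 patients, 15 diseases
#>   validation: 9049 rows read, 0 bad dates, 0 incomplete, 0 duplicates collapsed

cohort <- build_matched_cohort(sim$dataset, "D01", "D02", match_params(seed = 7))
cohort
#> <matched_cohort> D01 -> D02: 344 exposed + 344 comparison (258 cases unmatched)
#>   events: 38 exposed / 15 comparison; window 3650 days

fit_cox_pair(cohort)
#> <cox_pair_fit> D01 -> D02 (n = 688, events = 53)
#>   exposure: coef 1.0468, HR 2.849, Wald p 0.00108; PH-test p 0.785

ks_dropout_test(cohort)
#> <dropout_test> D01 -> D02
#>   KS D = 0.052, p = 0.784 (306 vs 329 dropouts)

curves <- fit_rsf(cohort, rsf_params(n_trees = 100, seed = 7))
compare_mean_survival(cohort, curves)
#> <rsf_pair_result> D01 -> D02
#>   restricted mean survival (tau = 3650 d): 2762 exposed vs 3126 comparison
#>   Wilcoxon p 4.42e-34; t-test p 3.76e-38
```

Reading the output: the Cox arm estimates an adjusted hazard ratio of 2.85
(true planted value 3) with raw Wald p ≈ 0.001, and the proportional-
hazards test (p = 0.785) gives no reason to distrust the model. The KS
check (p = 0.784) shows dropout timing is balanced between the groups. The
forest arm agrees: exposed subjects' restricted mean time to D02 is about
364 days shorter than their matched comparisons'. In a full run these
p-values would be BH-adjusted across all pairs before any edge is drawn.

The whole screen is one call (or one shell command via
`inst/cli/dcn.R`, which also exposes the `simulate` / `cohorts` / `cox` /
`rsf` / `network` stages separately):

```r
res <- run_pipeline(sim$dataset, "results/", seed = 7)
res$network        # disease_network object; CSVs + GraphML + JSON in results/
```

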