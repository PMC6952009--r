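---
title: "Screening longitudinal medical records for temporal disease correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening longitudinal medical records for temporal disease correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Longitudinal electronic medical records hold, for each patient, the dates on
which diseases were first diagnosed. `dcnet` screens such a table for
*directional temporal correlations*: for an ordered pair of diseases X → Y,
does an earlier diagnosis of X correlate with a sooner later diagnosis of Y?

The design is a matched retrospective cohort per ordered pair, in the
tradition of registry-wide comorbidity screens. The **exposed group** is
every patient diagnosed with X; the first X diagnosis is that subject's
index date. For each exposed subject a **comparison subject** is drawn at
random from the patients never diagnosed with X, under the matching rules:

* identical gender and ethnicity,
* the comparison subject's index date is the date of a randomly chosen
  non-X diagnosis within `max_date_diff` days (default 7) of the case's
  index date,
* age at index within `max_age_diff` years (default 5),
* matching is 1:1 and without replacement within the pair; exposed subjects
  with no eligible control are dropped, and the exposed group is capped at
  `max_group_size` (default 10 000) by uniform subsampling.

Anchoring the comparison subject's time origin at one of its own diagnoses
keeps both groups "in care" at the index date, so follow-up is comparable.
Treating time-to-Y as a continuous outcome rather than a within-window
yes/no is what distinguishes this design from purely binomial registry
screens: a Y diagnosis after one year and one after four years carry
different information, and continuous and categorical confounders enter the
models directly instead of through stratification.

The **event** is the first Y diagnosis after the index date within the
follow-up window (default 3650 days). Subjects whose first Y falls on or
before their index date are *prevalent cases* and are excluded from either
group before matching — the event must be a later diagnosis. Everyone else
is censored at the end of their record (their last recorded diagnosis — a
drop-out) or administratively at the window, whichever comes first. A
censoring time of zero is floored to one day.

### Interpretation choices the data forced

Three points are genuinely underdetermined by the design brief and were
fixed as follows:

* *Control exposure*: a comparison subject must be free of X anywhere in
  its record, not merely before its index date. The stricter reading is
  deterministic and avoids crossover subjects appearing in both roles.
* *Age at index*: records carry an age per diagnosis row, so a birth-date
  equivalent is derived from (age, date) of the earliest row and ages are
  evaluated at the index date. If ages were recorded only once, the static
  value would be used unchanged.
* *Order of operations*: prevalent-Y exclusion is applied first, then the
  exposure cap, then matching. Subsampling after exclusion keeps the cap
  meaningful as a bound on analysable subjects.

## The regression arm

Per pair, a Cox proportional-hazards model is fitted to the matched cohort:

$$\ln \frac{h(t)}{h_0(t)} = b_1 P_1 + b_2 P_2 + \dots + b_n P_n,$$

where $h(t)$ is the hazard of the Y diagnosis at time $t$ since index,
$h_0(t)$ the baseline hazard, and the predictors $P_i$ are the binary
exposure indicator plus any confounders (age at index, gender, ethnicity by
default; further columns of the input table may be added). The headline
statistic is the exposure coefficient $b_\text{exposed}$; its exponential is
the adjusted hazard ratio of Y after X. Ties are handled with the Efron
approximation by default (diagnosis dates have day resolution, so ties are
routine); Breslow is selectable. Wald p-values for the exposure term are
Benjamini–Hochberg adjusted *across all pairs of one run* — the
multiplicity family is the whole screen, one p-value per pair — and
adjusted p ≤ 0.05 is called significant. Covariate coefficients are
reported but never multiplicity-adjusted; they are nuisance estimates, not
hypotheses. The model fit itself is delegated to `survival::coxph()`; what
`dcnet` owns is the cohort construction around it and the per-pair
bookkeeping.

### Quality controls

* **Proportional hazards** — a score test of the scaled Schoenfeld
  residuals of the exposure term against the Kaplan–Meier transform of
  event time (`survival::cox.zph`); p < 0.05 flags a hazard ratio that
  drifts over follow-up. Cohorts with fewer than three distinct event
  times are reported "not testable" rather than tested on noise.
* **Model fit** — Cox–Snell residuals (the estimated cumulative hazard at
  each subject's observed time). Under a well-fitting model they behave
  like censored unit-exponential variates, so their Nelson–Aalen cumulative
  hazard plotted against the residuals should hug the 45° diagonal;
  `coxsnell_plot_data()` exports exactly those points.
* **Dropout balance** — records end early, and if the *timing* of those
  drop-outs differs between exposed and comparison groups, censoring may be
  informative and differential. `ks_dropout_test()` compares the two
  censoring-time samples with a two-sample Kolmogorov–Smirnov test.
  Subjects censored administratively at the full window are *not*
  drop-outs — they completed follow-up — so the tally per group is a
  three-way split into drop-off / event / survival, and only the first
  slice enters the test. The exact p-value is used when the combined
  sample is under 40 (day-resolution ties make it approximate), the
  asymptotic one otherwise. A failing test does not remove the pair; it
  attaches a caution flag.

## The machine-learning arm

Cox regression assumes proportional hazards and linear predictor effects. As
an independent check, each pair is also analysed with a random survival
forest: bootstrap survival trees split by the log-rank statistic, terminal
nodes carrying Nelson–Aalen cumulative-hazard estimates, averaged over
trees into a per-subject curve $S(t) = \exp(-H(t))$.

Tree growing is delegated to `ranger` (log-rank splitting, n-out-of-n
bootstrap). The terminal-node estimates, however, are computed in-package
from the per-tree bootstrap multiplicities and terminal-node assignments,
because the backend's built-in cumulative-hazard predictor evaluates the
risk set only at event times — censorings falling strictly between two
event times do not reduce it until the next event — which is not the
standard Nelson–Aalen estimator. Computing the estimator directly makes the
degenerate case exact: a single unbootstrapped, root-only tree
(`rsf_params(n_trees = 1, bootstrap = FALSE, min_node_size = n + 1)`)
reproduces the cohort-wide Nelson–Aalen estimator to machine precision,
which is both a unit-test oracle and a sanity anchor for the ensemble.
`rsf_params()` exposes tree count (default 500), `mtry` (default
⌈√p⌉) and the minimal node size to attempt a split (default 15); the
backend offers no separate per-node event-count control.

A forest predicts one curve per subject, so the standard two-cohort
log-rank test does not apply directly. Each curve is instead reduced to its
**restricted mean survival time** — the integral of the survival step
function up to τ = the follow-up window, computed exactly as Σ step width ×
step height. Curves are undefined beyond the window, so the mean is always
the restricted mean. The exposed and comparison groups' per-subject means
are compared with the two-sided Wilcoxon rank-sum test (primary, chosen as
the conservative non-parametric option) and the two-sample t-test; both are
BH-adjusted across pairs, and the RSF arm calls a pair significant only
when *both* adjusted p-values pass.

### A caveat that matters

Treating per-subject restricted means as independent draws is an
approximation, and not a harmless one: all subjects in a group share the
same forest, and a noise split on the exposure indicator shifts every
exposed subject's curve together. Under a pure null this correlation makes
the rank-sum test reject far above its nominal level (in our null
simulations the majority of null pairs reach p < 0.05). The RSF arm is
therefore *not* a calibrated test on its own; it is a concordance screen,
and false-positive control of the default **overlap** network rests on the
Cox arm, whose raw p-values are calibrated (see below). This is a property
of the published method, reproduced deliberately; users wanting a single
calibrated arm should use `mode = "cox"`.

## The network

An edge X → Y asserts that an earlier X diagnosis *accelerates* the Y
diagnosis. The design descends from registry methods that test whether the
outcome proportion is significantly *higher* in the exposed group, so by
default a pair must be both significant and in the positive direction
(Cox hazard ratio above 1; RSF exposed restricted mean below the
comparison mean) to become an edge; `require_positive = FALSE` restores
the purely two-sided reading. The direction gate matters in practice:
control selection requires a diagnosis inside the ±7-day index window,
which in sparse records enriches the comparison group in diagnosis-dense,
long-record patients — more of their later Y diagnoses are observed, and
their last-diagnosis censoring comes relatively sooner — tilting null
pairs toward *protective* (hazard ratio < 1) artifacts. Those artifacts
are exactly the direction the gate removes; genuinely protective
relationships are outside this tool's claim.

Pairs significant under the chosen mode — `"overlap"` (both arms, the
default display set), `"cox"`, or `"rsf"` — become directed edges X → Y
carrying the full per-pair statistics (coefficient, hazard ratio, cohort
size, raw/adjusted Cox p, proportional-hazards p, KS p, both RSF adjusted
p-values, and which arms flagged the pair). Self-loops cannot arise (X ≠ Y
by construction) and each ordered pair yields at most one edge. On top of
the network:

* `degrees()` — in/out/total degree per disease, sorted; in-degree is the
  conventional node-size driver in renderings.
* `shortest_path()` — minimum-hop trajectories by breadth-first search.
  Edges are unweighted (hop count defines "shortest"); neighbours are
  explored in lexicographic order so tie-breaks are reproducible; paths
  follow edge direction by default with an undirected option.
* `filter_network()` — thresholds on cohort size, adjusted p and
  coefficient; idempotent and monotone by construction.
* `export_network()` / `import_network()` — CSV edge list and GraphML
  round-trip losslessly; Cytoscape JSON follows the
  `elements: {nodes: [{data: {id}}], edges: [{data: {source, target, …}}]}`
  convention consumed by browser viewers, with in-degree and coefficient as
  numeric attributes (rendering style is the viewer's business, not ours).

## The synthetic-record generator

Real hospital extracts of this kind are not redistributable, so validation
rests on `simulate_emr()`, which generates first-diagnosis tables with
known ground truth. Each patient draws demographics (gender 50/50;
ethnicity 60/20/15/5 across four categories; age normal with mean 50, SD
15, truncated to 18–90) and an independent exponential first-diagnosis
clock per disease. The defaults — 15 diseases at 3 × 10⁻⁵/day (≈ 10%
ten-year cumulative incidence), a 3650-day observation span, exponential
record truncation at 2 × 10⁻⁴/day (roughly half of records end before ten
years) — sketch a mid-size hospital registry at configurable scale. A
planted effect (X, Y, HR) multiplies Y's clock rate by HR from the
patient's X onset onward (a Markov illness process with a multiplicative
hazard jump), so the true exposure hazard ratio of the matched design is
known and recoverable; the planted-effect graph must be acyclic so onset
times are well-defined. An optional log-linear age effect on all clocks
exercises covariate adjustment. Each patient consumes an RNG substream
derived from the master seed, so enlarging the population or switching off
dropout extends the data without reshuffling existing patients.

What the generator does **not** emulate: coding realism (labels are
opaque), visit-level structure, staggered calendar entry, secular trends,
and correlated comorbidity beyond the planted edges. Passing tests
demonstrate that the machinery recovers what it is pointed at under its own
assumptions, not that any particular clinical dataset satisfies those
assumptions.

## Numerical and validation choices

* Dates are stored as integer days (days since 1970-01-01 internally); all
  durations are reported in days. Disease labels match case-sensitively
  after whitespace trimming; duplicate (patient, disease) rows keep the
  earliest date; rows with unparseable dates or missing mandatory fields
  are dropped and counted in the validation report; subjects missing a
  modelled covariate are dropped from that model and counted.
* Per-pair seeds are derived by hashing the master seed with the pair
  labels, so a pair's cohort does not depend on the order in which pairs
  are processed, and reruns are byte-identical.
* Candidate split points in the forest are the backend's midpoints of
  sorted unique predictor values; log-rank splitting uses the standard
  hypergeometric variance.
* Expected analysis failures (no exposed patients, no eligible matches, no
  events, separation, non-convergence) are typed conditions; the pipeline
  records them in a per-pair status column and continues.

The test suite validates the pipeline property-wise, at sizes chosen for a
single CPU: exact agreement of the Cox exposure coefficient with a
brute-force maximization of the hand-written partial likelihood on tie-free
toy cohorts (10⁻⁶); ≥ 90% Wald-interval coverage of a true hazard ratio of
2 over 100 cohorts of 2000 per arm; raw Cox p calibration in [0.02, 0.09]
over 500 matched null pairs built by the full pipeline, with BH discoveries
≤ 5%; nominal-level calibration of the KS and proportional-hazards checks
over 500 replicates each; an exhaustive-enumeration audit of the matching
constraints; exact restricted-mean integration against the exponential
closed form ((1 − e^{−λτ})/λ ≈ 974.0 days at λ = 0.001/day, τ = 3650); and
end-to-end recovery of three planted HR = 3 effects among 15 diseases in
20 000 patients (overlap mode, cohort cap 1000, 20 trees — caps chosen as
runtime scaling, the statistical margins being large) in at least 8 of 10
seeded runs with at most one false edge.

## Known limitations

* The RSF arm's rank-sum test is anticonservative (see above); overlap
  mode inherits its error control from the Cox arm.
* The window requirement on controls makes comparison groups
  diagnosis-dense relative to exposed groups; with the direction gate this
  surfaces as conservatism rather than false edges, but hazard-ratio
  estimates for true effects are mildly attenuated in sparse data.
* Matching requires a reasonably dense diagnosis stream: in sparse data the
  ±7-day index window finds few eligible controls and unmatched cases are
  dropped, shrinking cohorts (the per-pair `n_unmatched` count makes this
  visible).
* The end of a patient's record is proxied by the last recorded diagnosis;
  a patient who remains enrolled but undiagnosed after the index date
  contributes a shorter censoring time than truth.
* No stratified, frailty or time-varying-coefficient Cox variants, no
  propensity or many-to-one matching, no competing-risks trees, and no
  ICD-hierarchy handling: diseases are opaque labels.
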