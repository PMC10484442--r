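---
title: "Modelling dosage adjustments under co-medication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dosage adjustments under co-medication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosepair)
```

## The question

When a hospitalised patient receives two drugs at once, clinicians sometimes
react by adjusting the dose of one of them — because of a known interaction,
an altered clinical state, or practical experience. `dosepair` turns
timestamped inpatient prescription data into, for every ordered pair
(index drug, co-medication), a posterior odds ratio for the probability that
the index drug's prescribed dosage is modified while the co-medication is
active, relative to periods when the index drug is given alone. Pairs with a
credibly elevated odds ratio are then characterised clinically
(discontinuation, 30-day mortality, 30-day readmission, length of stay,
diagnosis and blood-test enrichment on propensity-matched groups) and
cross-referenced against drug–drug-interaction (DDI) and pharmacokinetic
annotation tables.

## Prescribed average daily dose

The unit of observation is the *prescribed* regimen, not administration
records. For a regimen with components $(d_i, f_i)$ — a dose $d_i$ given
$f_i$ times per dose interval of $t$ days — the average daily dose is

$$\mathrm{ADD} = \frac{1}{t}\sum_{i=1}^{n} d_i f_i .$$

Missing fields are filled by a fixed default cascade (dose from package
strength × volume; volume assumed 1; interval derived from a stated
frequency, otherwise daily; frequency assumed 1), and each applied default is
recorded so that imputed regimens remain auditable. "As needed" (PN) and
variable-dose (VAO) prescriptions receive a categorical ADD; one-time
prescriptions and regimens that remain incomputable are excluded. Sequences
mixing convertible mass units (g/mg/mcg) are converted to a common unit;
anything else (e.g. mg vs IU) makes the sequence incomplete rather than
risking a spurious "change". Two ADDs count as different only when they
differ after rounding to 6 significant digits — dosage values are
human-entered decimals, and float noise must not create modifications.

```{r add}
compute_add(regimen(dose = 200, freq = 3, interval_hours = 24))$value
compute_add(regimen(dose = c(50, 100), freq = c(3, 4),
                    interval_hours = 7 * 24, unit = "mcg"))$value
```

## Treatment episodes

Within an admission, a drug's *active timeline* is the union of its
prescription validity intervals (half-open `[start, end)`, minutes;
abutting prescriptions chain into continuous treatment). That timeline is
partitioned into maximal sub-intervals over which the set of *other* active
drugs is constant: an empty set gives a monotherapy episode (the model's
reference condition), a non-empty set gives one concomitant episode per
co-medication active there. Each episode carries the index drug's
prescriptions whose validity intersects it, in time order; $N$ is the
prescription count and $y$ the number of adjacent prescription pairs with
unequal ADDs ("lagged changes"). Episodes whose ADD sequence cannot be
completed numerically are excluded.

Decisions worth making explicit:

* **Half-open intervals.** All overlap tests use `[start, end)`, so abutting
  intervals neither overlap nor leave gaps, and episode partitions are exact.
* **Change counting.** The verbal definition — the number of times the
  prescribed dosage changes between consecutive prescriptions — is
  implemented. (A literal telescoping sum of differences would collapse to
  $\mathrm{ADD}_N - \mathrm{ADD}_1$, which contradicts the verbal
  definition; the verbal form is used.)
* **Single-prescription episodes** ($N = 1$, $y = 0$) are retained; they
  carry trial information but no possible change.
* **Discontinuation** is cessation of the index drug *strictly inside* the
  co-medication's active interval, with no later index prescription in the
  admission; a simultaneous end of both drugs does not count.
* **Re-admissions within 24 hours** of discharge are combined with the
  previous admission before episode construction, and all admission-keyed
  tables are re-pointed at the surviving record.

Cohort-level selection filters retain index drugs with a monotherapy episode
in ≥ 50 patients and pairs present in ≥ 50 patients, and remove drugs that
are one-time prescriptions in > 70% of their orders from the co-medication
side only. All thresholds are configurable; defaults match the stated study
design.

## The hierarchical model

For every episode $e$ of one index drug, $y_e \sim
\mathrm{Binomial}(N_e, p_e)$ with

$$\mathrm{logit}(p_e) = \beta_0 + \beta_{\mathrm{co}[e]} +
\beta_{\mathrm{age}} x_e + \beta_{\mathrm{sex}} s_e +
\beta_{\mathrm{hosp}[e]} + \beta_{\mathrm{diag}[e]} +
\beta_{\mathrm{year}[e]} + \gamma_{\mathrm{patient}[e]},$$

where monotherapy is the reference level of the concomitant-drug factor and
$\gamma$ is a patient random intercept. One joint model is fitted per index
drug, so all of that drug's co-medication coefficients share the adjustment
covariates and patient effects. Coefficients have zero-mean normal priors
whose scales are half-normal(0, 1) hyperpriors (sex: half-normal(0, 0.5));
a fixed-scale mode (`prior_mode = "fixed"`) is available for sensitivity
analysis. The reported odds ratio is the exponentiated posterior median of
the pair coefficient.

Sampling uses JAGS (Gibbs/auxiliary-variable MCMC, with the `glm` module's
block samplers), 4 chains × 2000 iterations with the first 1000 as warmup by
default. Convergence is declared when the largest split R-hat across
monitored parameters is ≤ 1.1; minimal effective sample size is reported.
This sampler family has no divergence or tree-depth diagnostic, so the
`divergences` field is always 0 and R-hat/ESS are the operative gates. The
raw intercept trades off freely against the mean of the patient effects, so
the monitored intercept is the identified sum $\beta_0 + \bar\gamma$; pair
coefficients are unaffected. Fits are deterministic given a seed (each chain
gets a derived RNG seed), and per-index-drug fits are independent, so results
do not depend on fit order.

**Decision rule.** Posteriors are summarised by the 89% highest-density
interval — the shortest sample interval holding 89% of draws, preferred over
95% for stability at moderate effective sample sizes. A region of practical
equivalence (ROPE) of (−0.05, 0.05) on the log-odds scale brackets zero; the
null is rejected when the HDI lies entirely outside the ROPE, accepted when
entirely inside, and withheld otherwise. The ROPE is applied on the
coefficient scale (a null region around zero is only meaningful there); the
OR-scale interval is its exponential. A pair is *significant* when the fit
converged, the null is rejected, and OR > 1; pairs credibly *below* 1 are
reported but not flagged.

**Trials.** The binomial trial count defaults to the episode's prescription
count $N$, as the model is written. Since $y$ counts transitions between
consecutive prescriptions, at most $N-1$ changes can occur, and using $N$
trials attenuates coefficients slightly when $N$ is small. A
`trials = "transitions"` switch uses $N-1$; the simulation-based tests use it
because the synthetic generator's change process is defined per renewal
transition, making the planted coefficient the estimand under transition
trials exactly.

**Down-sampling.** Index drugs with more than 500,000 episodes are reduced by
keeping the 300 most frequent co-medications and then sampling down to the
threshold proportionally within the joint strata of age bin, sex, year,
hospital, diagnosis chapter and co-medication (largest-remainder allocation,
so the total is exact). Age bins follow Rice's rule,
$k = \lceil 2 n^{1/3}\rceil + 1$, computed with a $10^{-9}$ guard against
binary floating-point error in the cube root. Co-medications left with fewer
than 50 patients afterwards are dropped.

## The synthetic cohort

No inpatient EHR extract can ship with a package, so the generator emulates
one with known ground truth: it runs the change model *forward*. Within each
admission, scheduled prescriptions renew at a daily cadence; at each renewal
the regimen is resampled to a guaranteed-different menu entry with
probability $\mathrm{logit}^{-1}(\eta)$, where $\eta$ is the baseline change
logit plus the planted log-odds effect of any co-medication active at the
renewal instant, covariate terms, and a patient intercept. Change indicators
are therefore exactly Bernoulli given $\eta$, episode change counts are
binomial, and the downstream model's estimand equals the planted
coefficient.

Defaults — chosen once as the simulated study's conditions: lognormal length
of stay (median 5 days, sdlog 0.5), baseline change logit −1.7 (≈ 15% per
renewal), patient intercept SD 0.5, 60% of admissions carrying a drug pair
whose second drug overlaps the middle of the first drug's stay (single-drug
stays supply the monotherapy reference), 2% PN/VAO series, and occasional
one-time prescriptions of otherwise-inactive drugs. Admission covariates
(hospital, diagnosis chapter, year) are categorical-uniform; Charlson score
and medication burden are emitted directly as integers. Outcome effects
(mortality and readmission log-hazards, LOS log-rate, discontinuation and
enrichment log-odds) can be planted on pair-exposed admissions for the
post-hoc analyses. Blood tests are binary in/out-of-range and untaken tests
are simply absent rows — the pipeline reads absence as within range.

What the generator does *not* emulate: realistic ATC marginal frequencies,
ICD-10 structure beyond chapter labels, out-of-hospital prescriptions,
informative censoring, or correlation between regimen menus and drug
identity. Passing recovery tests therefore demonstrates the pipeline's
statistical correctness under its own assumptions, not robustness to every
real-EHR pathology.

## Post-hoc clinical characterisation

For each significant pair, exposed admissions (a patient's first exposure)
are matched 1:1 to controls on the same index drug with a different
co-medication, by greedy nearest-neighbour matching on the propensity-score
difference (logistic model of exposure on age, sex, diagnosis chapter,
Charlson score and medication burden). Exposed units are processed in a
seeded random order and ties break on the lowest admission id — the method
names the metric but not the order, so the order is fixed and documented.
Endpoints:

* mortality within 30 days of admission and readmission within 30 days of
  discharge: Cox partial likelihood stratified by matched pair, Breslow
  ties, exposure plus the adjustment set;
* length of stay: Poisson regression stratified by matched pair, fitted by
  the exact conditional likelihood given each pair's total — which reduces
  to a binomial logistic model on the exposed share and equals the fixed-
  effects estimate without thousands of nuisance parameters (verified
  against the dummy-variable fit in the tests);
* index-drug discontinuation and diagnosis/blood-test enrichment: logistic
  regressions with the same adjustment; codes present in < 50 patients are
  skipped, missing blood tests impute "within range".

Bonferroni correction is applied within one family per endpoint type across
pairs (family sizes are reported); LOS is taken from the admission containing
the exposure. Adjustment covariates observed at a single level are dropped
from model matrices rather than crashing the fit; inestimable endpoints
(separation, no events) are flagged, not silently omitted.

## Annotation and group comparison

Significant pairs are cross-referenced, as unordered pairs, against a binary
DDI evidence table, a pharmacokinetic table restricted to the
regulatory-listed CYP enzymes and transporters, and a literature co-mention
count table (absent pair → 0). "Shared activity" requires identity of the
protein, not of the role — an inducer and a substrate of the same CYP
qualify. Known-DDI and unknown-DDI groups are compared on patient volume,
co-mentions and posterior OR with the two-sided Mann–Whitney U test (exact
when $n_1 n_2 \le 400$ and tie-free, otherwise normal approximation with
continuity and tie correction) and effect size $r = |z|/\sqrt{n}$ with the
conventional 0.1/0.3/0.5 small/moderate/large cut-offs, which the source
analyses leave unnumbered.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise every claim on one
CPU: oracle equivalence of the interval algebra runs 100 random admissions
against a per-minute active-set scan; HDI minimality is brute-forced on
samples up to n = 2000; parameter recovery uses 20 cohorts of 5000 patients
with a planted log(2) effect at reduced MCMC settings (2 chains × 1000
iterations), checking 89% HDI coverage in ≥ 16/20 replicates and median
absolute bias < 0.15 on the log scale; null calibration uses 20 null cohorts
plus 200 simulated matched pairs whose pooled type-I error must be
binomially compatible with 5%. The end-to-end pipeline test checks
byte-identical replay of every table under a fixed seed.

## Known limitations

Only pairwise co-exposure is modelled — an index drug under two simultaneous
co-medications contributes to both pairs, and higher-order combinations are
out of scope. DDI evidence is consumed as a single binary flag; source
provenance is carried but unused. Kidney/liver function is not adjusted for.
Cross-admission treatment continuity beyond the 24-hour re-admission merge is
not modelled, and transitions that straddle an episode boundary are counted
in neither episode, mirroring episode-wise change counting.
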