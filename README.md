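# dosepair

Population-scale analysis of **dosage adjustments under co-medication** in
inpatient prescription data. Given timestamped prescriptions with dosing
regimens, `dosepair` estimates, for every ordered pair *(index drug,
co-medication)*, how much more likely the index drug's prescribed dosage is
to be modified while the co-medication is active than during monotherapy —
and then characterises the flagged pairs clinically and pharmacologically.

The pipeline:

1. **Prescribed average daily dose (ADD).** For a regimen with components
   $(d_i, f_i)$ over an interval of $t$ days,
   $\mathrm{ADD} = \tfrac{1}{t}\sum_i d_i f_i$, with a fixed, audited default
   cascade for missing fields; "as needed"/variable-dose prescriptions get a
   categorical ADD, one-time prescriptions are excluded.
2. **Treatment episodes.** Each drug's active timeline within an admission is
   partitioned into maximal intervals with a constant set of other active
   drugs: monotherapy episodes (reference) and concomitant episodes per
   co-medication, each carrying the count of prescriptions $N$ and of lagged
   dosage changes $y$. Selection filters: index drugs with monotherapy in
   ≥ 50 patients, pairs in ≥ 50 patients, >70%-one-time drugs dropped as
   co-medications.
3. **Hierarchical Bayesian model.** Per index drug,
   $y_e \sim \mathrm{Binomial}(N_e, p_e)$ with
   $\mathrm{logit}(p_e)$ = intercept + concomitant-drug coefficient
   (monotherapy reference) + age + sex + hospital + diagnosis chapter +
   calendar year + patient random intercept; half-normal(0, 1) hyperpriors on
   coefficient scales (sex: 0.5). MCMC via JAGS. Each pair is summarised by
   the posterior-median odds ratio, its 89% highest-density interval, and a
   ROPE decision on (−0.05, 0.05) log-odds: *significant* = converged ∧ HDI
   outside the ROPE ∧ OR > 1. Oversized index drugs are stratified
   down-sampled (500,000 episode cap, top 300 co-medications, Rice's-rule age
   bins).
4. **Post-hoc clinical analyses** on 1:1 propensity-matched exposed/control
   admissions: discontinuation, 30-day mortality, 30-day readmission
   (stratified Cox), length of stay (stratified Poisson via exact conditional
   likelihood), diagnosis and blood-test enrichment; Bonferroni per endpoint
   family.
5. **Annotation**: binary DDI evidence, shared CYP/transporter activity,
   gene-variant links, patient volume, literature co-mentions; known- vs
   unknown-DDI groups compared by two-sided Mann–Whitney U with effect size
   $r = |z|/\sqrt{n}$.

Because real inpatient EHR extracts cannot be redistributed, the package
ships a **synthetic cohort generator** that runs the change model forward
with planted log-odds effects, so every stage is testable end to end against
known ground truth.

## Worked example

Generate an 800-patient cohort over 4 drugs with one planted effect — the
dosage-change odds of drug `A01AA01` are tripled while `B01AA02` is
co-administered — then run every stage:

```r
library(dosepair)
drugs <- synthetic_drugs(4)
cfg <- pipeline_config(
  out_dir = "demo_run",
  cohort = cohort_config(
    n_patients = 800, n_drugs = 4,
    planted_effects = data.frame(index_drug = drugs[1], co_med = drugs[2],
                                 log_odds_effect = log(3)),
    seed = 2024),
  min_mono_patients = 25, min_pair_patients = 25,
  spec = model_spec(chains = 2, iter = 1200, warmup = 700,
                    trials = "transitions"),
  seed = 7)
res <- run_pipeline(cfg)
head(res$posteriors[order(-res$posteriors$or_median), ], 5)
```

```
  index_drug  co_med or_median hdi_low hdi_high rope_decision significant n_patients
1    A01AA01 B01AA02      2.84   2.193     3.66   reject_null        TRUE        118
2    B01AA02 A01AA01      1.32   0.995     1.66     undecided       FALSE        118
3    C01AA03 B01AA02      1.22   0.937     1.60     undecided       FALSE         93
4    A01AA01 C01AA03      1.03   0.764     1.34     undecided       FALSE        120
5    J01AA04 B01AA02      1.01   0.890     1.27     undecided       FALSE        106
```

The planted pair is recovered (posterior median OR 2.84 against a true 3.0,
89% HDI entirely above the ROPE) and flagged significant; unplanted pairs
stay undecided around OR 1. The direction matters: the model sees elevated
change odds for `A01AA01` under `B01AA02`, but not the reverse. Post-hoc
association results for the significant pair are near-null, as planted:

```
          pair_id        endpoint  effect p_raw p_bonferroni
1 A01AA01|B01AA02 discontinuation -0.0345 0.890        0.890
2 A01AA01|B01AA02   mortality_30d  0.0624 0.913        0.913
3 A01AA01|B01AA02             LOS -0.0693 0.183        0.183
```

and the annotation stage reports the pair's DDI evidence flag, shared
cytochrome activity (both drugs act on a common CYP in this synthetic
reference), patient volume and literature co-mentions. All stage outputs are
also written as TSV under `demo_run/`, with a manifest of seeds, row counts
and file digests; re-running the same config reproduces them byte-for-byte.

A shell wrapper with the same stages is provided at
`inst/scripts/run_pipeline.R`.

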