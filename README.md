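# roughpd

Rough-set analysis of reflexive-saccade and clinical attributes in
Parkinson's disease (PD).

## What this is for

Neurological PD scores — UPDRS total and its parts II/III/IV, Hoehn–Yahr,
Schwab–England, PDQ-39, AIMS, Epworth — are partly subjective, while
reflexive-saccade (RS) parameters (latency, amplitude, duration, peak
velocity) are objective and cheap to measure. For patients with a
deep-brain-stimulation (DBS) implant, the standard four-session protocol
crosses medication and stimulation (S1 both off, S2 DBS on, S3 medication
on, S4 both on), so the session number encodes the treatment condition.
`roughpd` answers, with rough-set theory, how well saccade and clinical
condition attributes predict a binned UPDRS score or the session — as
explicit decision rules with support/confidence, plus cross-validated
accuracy and coverage.

The machinery, for a decision table S = (U, C, D): the indiscernibility
relation IND(B) partitions records into B-elementary granules; a concept
X ⊆ U gets lower/upper approximations (granules inside / touching X) whose
difference is the boundary region; the dependency γ(B) is the share of
records in decision-pure granules; reducts are minimal attribute subsets
preserving γ. Numeric attributes are discretized by decision-aware
maximal-discernibility cuts (attributes receiving no cuts are starred `*`
and dropped as non-significant); rules like

```
('Pat' = 38) & ('age' = "(55.0, Inf)") & ('Sess' = 4) & ('SccDur' = "(-Inf, 45.5)")
  & ('SccLat' = "(-Inf, 260.0)") & ('SccAmp' = "(-Inf, 10.5)")
  => ('UPDRS' = "(-Inf, 14.0)")
```

are induced and vote with weight support × confidence; a decomposition tree
(binary, template-labelled nodes, rule-bearing leaves) is the main
classifier. Uncovered records abstain, so accuracy (correct/covered) and
coverage (covered/tested) are reported separately. Confusion matrices are
fold-averaged: accumulated integer counts divided by k. Baselines (naive
Bayes, gini decision tree, majority decision table, bagged tree ensemble),
SMOTE oversampling, MCC and Cohen's kappa round out the evaluation. A seeded
synthetic-cohort generator (10 patients × 4 sessions, session-dependent
score/latency moments, shared patient random effect) makes every stage
testable; `inst/extdata/synthetic_cohort.csv` is a calibrated synthetic
stand-in for the study table.

## Worked example

```r
library(roughpd)
cohort <- load_table(system.file("extdata", "synthetic_cohort.csv",
                                 package = "roughpd"),
                     cohort_schema())
res <- run_experiment(cohort, "E1", folds = 6, seeds = 1:10)
round(res$metrics, 3)
#> accuracy coverage      mcc    kappa
#>    0.383    0.647    0.172    0.169
res$cuts
#> <cutset>
#>   age : 51.5
#>   SccDur : 42.5, 44.5
#>   SccLat : 137.6, 182.35, 216.95, 292.15
#>   SccAmp : 9.5, 10.5
#>   kept nominal: Pat, Sess
#>   decision cuts: 27.5, 43.5, 63
format_rule(res$rules[[1]])
#> ('Pat' = 11) & ('age' = "(-Inf, 51.5)") & ('Sess' = 1) & ('SccDur' = "(42.5, 44.5)")
#>   & ('SccLat' = "(216.95, 292.15)") & ('SccAmp' = "(9.5, 10.5)") => ('UPDRS' = "(63.0, Inf)")
```

Preset `E1` predicts four-bin total UPDRS from patient, age, session and
saccade duration/latency/amplitude. The metrics are means over ten fold
seeds: on 64.7% of held-out records some rule fired (coverage), and 38.3% of
those were assigned the correct UPDRS bin (accuracy on covered records;
chance is 25%). The cut set shows which attributes the supervised
discretizer found informative — here every numeric attribute received cuts;
in other presets non-significant attributes come back starred. The first
rule reads: patient 11, aged under 51.5, in session 1 (everything off), with
mid-range duration and latency, had total UPDRS above 63.

Per-seed confusion matrices are in `res$cms` (printed in the standard
layout: predicted columns, actual rows, a TPR row and an ACC column).
Other presets: `E2` (session from clinical attributes only), `E3` (session
with eye movements), `E4a`/`E4b` (adding PDQ-39/AIMS/Epworth), `E5_II`/
`E5_III` (UPDRS subscale models). See `?run_experiment` for classifiers,
SMOTE, fold counts, leave-one-out, and leakage-free per-fold cuts.

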