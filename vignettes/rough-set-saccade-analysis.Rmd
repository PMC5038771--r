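---
title: "Rough-set analysis of saccade and clinical attributes in Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-set analysis of saccade and clinical attributes in Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease (PD) symptoms are scored with the Unified Parkinson's
Disease Rating Scale (UPDRS: total plus parts II, III, IV), Hoehn–Yahr
staging, Schwab–England daily-living percentages and quality-of-life scales
(PDQ-39, AIMS, Epworth). These scores are partly subjective. Reflexive
saccades (RS) — fast eye movements toward a suddenly appearing target — offer
an objective, automatable biomarker: their latency, amplitude, duration and
peak velocity change with disease state and treatment. For patients carrying
a deep-brain-stimulation (DBS) implant, a standard four-session protocol
crosses medication and stimulation states (S1 both off, S2 DBS on, S3
medication on, S4 both on), so the "session number" encodes the treatment
condition.

`roughpd` asks, with rough-set machinery: how well do condition attributes
(saccade parameters, demographics, clinical scales) predict a decision
attribute (a binned UPDRS score, or the session)? The answer takes the form
of human-readable decision rules plus cross-validated accuracy and coverage.

## The model

An *information system* is a pair S = (U, A): a finite universe of
examination records and a set of attributes. A *decision table* S = (U, C, D)
distinguishes condition attributes C from one decision attribute D. For any
attribute subset B, the *indiscernibility relation* IND(B) relates objects
with equal values on every attribute of B; its classes are the B-elementary
granules. For a concept X ⊆ U, the *lower approximation* is the union of
granules wholly inside X, the *upper approximation* the union of granules
touching X, and their difference is the boundary region — X is rough iff the
boundary is nonempty. The *positive region* is the union of decision-pure
granules; its share of U is the dependency degree γ(B). A *reduct* is a
minimal B preserving γ of the full condition set.

Implementation notes:

* MISSING values equal only MISSING, so IND(B) stays an equivalence relation
  on incomplete tables.
* Reducts are minimal hitting sets of the decision-relative discernibility
  matrix, enumerated exhaustively by increasing size (capacity limit 20
  attributes; a greedy forward-selection/pruning variant covers larger
  tables). Every reduct returned passes a verification pass: its dependency
  equals the full dependency and dropping any member lowers it.

## Supervised discretization

Numeric attributes are replaced by interval labels. The decision-aware
("maximal discernibility") discretizer considers, per numeric attribute,
candidate cuts at midpoints between adjacent distinct values whose value
groups span more than one decision class, then greedily selects the cut
discerning the most not-yet-discerned object pairs with different decisions.
Ties break by schema attribute order, then by the smaller cut; selection
stops when no cut adds discernment. Attributes receiving no cuts are *starred*
(`"*"` for every object) and take no part in rules — the package's
star-elimination of non-significant attributes. Nominal condition attributes
(patient number, session) never enter the cut search and are always kept as
raw values; in the printed reference tables the starred attributes are
invariably numeric ones.

Numerical choices:

* Boundary convention: a value equal to a cut belongs to the upper interval
  (half-open bins). No observed value in the worked example equals a cut, so
  the convention is free; half-open is fixed for determinism.
* Two label dialects: `"rses"` (`"(-Inf, 55.0)"`, `"(55.0, Inf)"`) and
  `"bracket"` (`"[6, 25]"`, `"(25, 40]"`, outer endpoints from the data
  range). The internal representation is a bin index; renderers are
  byte-stable per dialect.
* A numeric decision is binned first (equal-frequency quantile cuts, four
  bins by default — the reference analyses all use four decision classes);
  condition cuts are then selected against those bins.
* Discretization is computed once on the full table before cross-validation,
  reproducing the reference workflow (its discretized tables are global).
  This leaks decision information from test folds into the cuts;
  `cuts_per_fold = TRUE` recomputes bins and cuts per training fold for a
  leakage-free estimate, at the cost of fold-specific label vocabularies.

## Rules, templates, decomposition trees

`induce_rules()` writes one rule per distinct row pattern (starred and
MISSING descriptors dropped), with support and confidence recounted over the
table — the worked-example rule

```
('Pat' = 38) & ('age' = "(55.0, Inf)") & ('Sess' = 4) & ('SccDur' = "(-Inf, 45.5)")
  & ('SccLat' = "(-Inf, 260.0)") & ('SccAmp' = "(-Inf, 10.5)")
  => ('UPDRS' = "(-Inf, 14.0)")
```

is the row-8 instance. Full-length antecedents describe, but they only ever
match literal row duplicates, so a trained classifier carries
`minimal_rules()` instead: for every object, all shortest antecedents whose
pattern is decision-pure over the training table (object-wise local reducts,
the classical "exhaustive" rule set); inconsistent rows contribute their full
antecedent with fractional confidence. Rule sets over explicit reducts
(`reduct_rules()`) and full antecedents remain available as options. This
choice was fixed by matching the *coverage* regime of the reference runs
(roughly half of test objects covered): full antecedents give coverage near
zero, reduct-restricted patterns well under a third.

Matching rules vote with weight support × confidence (an unweighted
`"simple"` scheme is available); ties break by the larger single-rule
support, then first-seen order. An uncovered object ABSTAINs — coverage is
the fraction of test objects covered and accuracy is correct/covered, the
two being reported separately throughout.

A *template* is a conjunction of attribute = value descriptors; its fitness
is the number of matching objects. `build_tree()` grows a binary
decomposition tree: each node splits its objects by the fittest template
that leaves both branches nonempty (ties prefer fewer descriptors, then
schema order), recursing until `min_leaf` objects (default 3; the reference
system's stopping parameters are unreported, so the default is fixed here
and exposed) or no splitting template. Leaves store the minimal consistent
rules of their objects, with consistency judged against the *full* training
table so decision-pure leaves stay selective. With `min_leaf >= n` the tree
is exactly the flat rule classifier — a tested equivalence.

## Evaluation

`make_folds()` shuffles (seeded) and deals round-robin; stratification on
the decision label is optional and off by default (the reference protocol
does not state it). `cross_validate()` accumulates integer counts over
covered objects only and divides by k at the end — the convention that makes
every reported matrix entry an integer multiple of 1/k. All metrics (global
accuracy and coverage, per-class TPR/ACC, the generalized Matthews
correlation, Cohen's kappa) are computed from the accumulated counts. The
per-class conventions follow the reference layout: TPR normalizes the
diagonal by predicted-class column sums, ACC by actual-class row sums; the
reference tables' printed per-class values do not always recompute from
their own printed averaged matrices, and this package recomputes strictly
rather than emulating the discrepancy. Pooled (not per-fold-averaged)
coverage is used. Because single runs are fold-seed dependent,
`cv_multi_seed()` reports means and SDs over ten seeds by default, and the
headline numbers quoted anywhere in this package are such means.

`smote_oversample()` implements the nearest-neighbor interpolation scheme
(3 neighbors, factor 3 by default, i.e. a tripled table) on standardized
numeric conditions, copying nominal slots from the seed record.

Baselines mirror the comparison set: categorical naive Bayes (default
probability 0, at most 20 nominal values per attribute), a gini decision
tree (rpart, minimum node size 2, no pruning), a majority decision table
over a greedy-reduct attribute subset, and a bagged ensemble of 100 rpart
trees with per-tree √p attribute sampling (one tree with full sampling and
no bootstrap reduces exactly to the single tree). Baselines always emit a
label, so their accuracy-on-all is compared against the rule classifiers'
accuracy-on-covered.

## The synthetic cohort generator

No public record-level dataset accompanies the reference analysis, so
`generate_cohort()` draws one: ten patients × four sessions, with the
per-session means and SDs of UPDRS total (66.6/30.0/58.1/22.3 ± 13.8–16.3),
UPDRS III and RS latency (291.2/199.6/232.9/183.2 ms) fixed as the study
conditions, cohort age 51.1 ± 10.2 and disease duration 11.3 ± 3.2 years. A
patient-level standard-normal effect enters every score with share ρ = 0.7
of the session SD and every latency with share γ = 0.85, so more affected
patients have longer latencies in all sessions; the pooled latency–UPDRS
rank correlation lands near 0.6, chosen once to match the qualitative
parallel session profiles of the two measures (no correlation value is
published). Saccade amplitude (≈10°), duration (≈38–49 ms) and velocity
(≈340–700 deg/s, tied to amplitude by a main-sequence slope) are
session-independent, as reported for the reference cohort. Hoehn–Yahr tracks
the DBS state, Schwab–England falls with UPDRS total, PDQ-39 is mostly a
patient trait centred near the published discretization cuts (65.5/78.5),
AIMS rises slightly on medication, Epworth is a patient trait. Scores are
clamped to their scale bounds and integer-rounded (latency keeps one
decimal).

`calibrated_cohort()` additionally pins the sample means (age; per-session
UPDRS, UPDRS III, latency) to the reference values to one decimal by an
affine moment match followed by grid-step nudging, and is shipped as
`inst/extdata/synthetic_cohort.csv` — a synthetic stand-in for the study's
full data table, suitable for exercising every pipeline stage.

What the generator does *not* emulate, hence what passing tests do not show
about real data:

* UPDRS subscale accounting (total = I + II + III + IV) is not enforced;
  total and III are drawn from their own printed moments, II and IV derived.
* Repeated examination blocks within one patient-session (the reference
  extract shows a duplicated session-2 row) are absent: exactly one record
  per patient × session.
* Patient-idiosyncratic treatment-response signatures beyond the shared
  random effect. Under the printed moments alone, the off-medication pairs
  of sessions (S1/S3) and on-medication pairs (S2/S4) overlap by ~0.6 SD, so
  a session classifier's accuracy over covered objects is capped well below
  the reference runs' reported values; the clinical-only session experiment
  and the zero-noise and low-noise limits do reproduce. The acceptance
  script reports all cross-validated accuracies as computed on the stand-in,
  without adjustment.

## Problem sizes

The test suite works on the eight-record worked example, random tables of
8–30 objects for property checks, 500-patient cohorts for parameter
recovery, and the 40-record calibrated cohort for end-to-end runs (six
folds, ten seeds). The acceptance script runs the five preset experiments at
ten seeds each and a 1000-cohort Monte-Carlo mean; these sizes are the
package's chosen defaults for a desk-scale reproduction.

## Worked example

```{r}
library(roughpd)
cohort <- load_table(system.file("extdata", "synthetic_cohort.csv",
                                 package = "roughpd"),
                     cohort_schema())
res <- run_experiment(cohort, "E1", folds = 6, seeds = 1:10)
res$metrics      # mean accuracy/coverage/MCC/kappa over seeds
res$cuts         # selected cuts and starred attributes
head(vapply(res$rules, format_rule, character(1)))
```

## Known limitations

* Exhaustive reduct search is exponential; beyond 20 condition attributes
  use `reduct_greedy()`.
* Global discretization before cross-validation is an intentional
  reproduction of the reference workflow and optimistically biases accuracy;
  prefer `cuts_per_fold = TRUE` for honest generalization estimates.
* The decomposition-tree template search is greedy and single-descriptor per
  step; it does not revisit earlier splits.
* Variable-precision and dominance-based rough-set extensions are out of
  scope.
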