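---
title: "Identifying and predicting difficult-to-treat rheumatoid arthritis in routine care data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and predicting difficult-to-treat rheumatoid arthritis in routine care data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A subgroup of rheumatoid arthritis (RA) patients stays symptomatic after
several biological or targeted synthetic disease-modifying drugs
(b/tsDMARDs). The EULAR definition calls these patients
difficult-to-treat (D2T): criterion 1 is failure of at least two
b/tsDMARDs with different mechanisms of action (MoA), criterion 2 is
signs of active or progressive disease, and criterion 3 — management
perceived as problematic — is subjective and is out of scope here, as is
criterion 2c (glucocorticoid tapering), because routine-care prescription
stop dates are too unreliable to evaluate it.

Finding these patients retrospectively in electronic health records is
hard: the components needed to score disease activity are missing for
most visits, and much of the signal sits in free-text letters. `d2tra`
implements a complete, testable pipeline for this phenotyping problem:

1. a rule engine applying criteria 1–2 to structured data,
2. a surrogate model approximating the DAS28-ESR where its components
   were never recorded,
3. a lexicon-driven letter miner with negation handling,
4. feature importance via FDR filtering and bootstrapped L1 logistic
   regression,
5. gradient-boosted identification and pre-biological prediction models,
6. a supervised 2-D embedding of longitudinal hematology,

all exercised against a synthetic routine-care generator with planted
ground truth, because the original hospital records cannot be shared.

## Disease activity and the rule engine

Disease activity is scored with the DAS28-ESR,

$$\mathrm{DAS28} = 0.56\sqrt{TJC28} + 0.28\sqrt{SJC28}
  + 0.70\ln(\mathrm{ESR}) + 0.014\,\mathrm{VAS},$$

with 3.2 the moderate-activity cut-off. The rule engine labels a patient
D2T when both hold:

* **Criterion 1** — prescriptions span ≥ 2 b/tsDMARD MoA classes
  (classes, not drugs: two TNF inhibitors count once). Repeat
  prescriptions collapse to the earliest start per class; same-day class
  starts are ordered by a fixed taxonomy enumeration and flagged as ties,
  a determinism choice the data cannot make for us.
* **Criterion 2** — either (a) the mean approximated DAS28-ESR in the
  closed window 3–12 months after starting the second-MoA drug is ≥ 3.2,
  or (b) a third MoA class was started, which by itself implies the
  second failed. A "month" is 30.44 days throughout.

Only start dates are used — stop dates are administratively unreliable in
routine care — so "failing" a drug is inferred from the sequence of
starts alone, and the reason for a switch (inefficacy vs intolerance) is
not modelled. Patients meeting criterion 1 whose window contains no
usable disease-activity record and who never started a third MoA are
classified non-D2T with `data_sufficiency = "insufficient"`: every
ambiguity resolves toward non-D2T, which is why data removal can lower
sensitivity but never creates false positives.

The window is anchored at the second-MoA start only (the literal reading
of the definition); anchoring at every MoA from the second onward would
be a small generalisation we did not adopt.

## The DAS28-ESR surrogate

Because joint counts and VAS are missing for most visits,
`train_das28_approximator()` regresses the measured DAS28-ESR on the
permitted feature classes only: same-day laboratory values, hospital
visit counts over the preceding year, age and sex, and the *pace of
cycling* through b/tsDMARD MoA classes, defined here (the concept is
named in the literature but no formula is given) as the number of
distinct classes started divided by the years since the first b/tsDMARD
start, evaluated at the record date. The model family is gradient-boosted
trees (missing inputs handled natively); a linear fallback is available
via `model = "linear"`.

Two deliberate conservatisms:

* The surrogate never scores a visit without a same-day ESR. It is
  trained exclusively on visits that have one (the target needs it), so
  its behaviour on ESR-less patterns is unsupported and regresses toward
  the training mean — dangerously close to the 3.2 threshold. Refusing to
  score such visits routes them into the insufficient-data path instead.
* Criterion 2 uses the surrogate's value at *every* window visit
  (`das28_source = "approximated"`), mirroring a mean *approximated*
  DAS28-ESR; `"mixed"` substitutes measured values where available.

On real data a model of this kind achieved a mean absolute error of
about 0.8 against a test-retest measurement error of about 0.6 for the
DAS28 itself; those are reference points, not reproducible targets, since
the source records are unavailable. On the synthetic cohorts the
surrogate's error is measured against known generative truth instead
(see below).

## Mining the clinical letters

Letters are segmented on line-anchored headings (a line ending in ":" or
an all-caps line; text before the first heading becomes a synthetic
`preamble`). Medications are extracted by exact, case-insensitive token
match — no fuzzy matching — and only under the "medication" and "DMARD
history" headings; criterion 1 is the union of MoA classes across all of
a patient's letters. Active disease (criterion 2) is a non-negated match
of an activity synonym ("flare", "active arthritis", "exacerbation")
under the conclusion/assessment/impression headings. A match is negated
when a negation cue (no, not, without, neither) occurs within the three
preceding tokens of the same sentence — a bounded NegEx-style window, so
"no flare" is excluded but "No signs of infection. Flare of RA." still
counts. Window size, cues, synonyms and headings are all plain data in
the lexicon and can be replaced wholesale; the shipped lists are
stand-ins assembled for this package, not a published vocabulary. No
temporal ordering between criterion-1 and criterion-2 evidence is
enforced. Patients without letters are non-D2T, insufficient.

## Feature engineering and importance

`assemble_features()` builds one row per labeled patient: demographics,
time since diagnosis, medication counts (distinct drugs, MoA classes,
cycling pace), visit counts, and per-series time aggregates — mean,
median, standard deviation, *mean difference* (mean of successive
differences in time order, a trend proxy; the mean absolute difference is
available via `abs_diff = TRUE`), mean minus median, plus min and max —
over every laboratory analyte, the clinical measurements and the DAS28
record series.

The importance procedure then follows the classical sequence: standard
scaling; imputation by iterative Bayesian ridge regression (each
incomplete feature regressed on the others, the penalty set by evidence
maximisation, cycled to convergence; the label is never a predictor);
univariate FDR filtering at alpha 0.05 (Welch t-test for continuous
features, Fisher's exact test for binary ones — no test is prescribed by
convention, these are the standard defaults) with Benjamini–Hochberg
adjustment; and finally L1-penalized logistic regression over random
train/test partitions of the labeled cohort (140/12 when 152 patients are
available), the penalty chosen per partition by internal
cross-validation at the one-standard-error lambda so that uninformative
coefficients are eliminated. We read "bootstrapped cross-validations"
as repeated partitions sampled without replacement; `replace = TRUE`
gives classical bootstrap resampling. Features are ranked by selection
frequency, then mean absolute coefficient; reported coefficients are
bootstrap means, not a single refit.

## Identification and prediction models

Both models are gradient-boosted tree ensembles (no imputation needed)
under stratified 10-fold cross-validation, reporting per-fold ROC AUCs,
their mean with a normal interval (mean ± 1.96 sd/√folds — the interval
construction is our choice), and the confusion matrix of the pooled
out-of-fold predictions at the decision threshold. Sensitivity and
specificity are reported as whole percents, the convention of validation
studies.

The prediction model sees only data from strictly before each patient's
first b/tsDMARD start; patients who never started one have no censoring
event and are excluded. Longitudinal series are regularized to a
one-month grid by forward fill — each cell carries the last value
observed at or before it, values never propagate backward, and nothing
on or after the censor date is ever read (a property the tests enforce by
perturbing post-censor records). The grid is then summarised with the
same aggregate set as above — the featureization is not prescribed
anywhere, so we reuse the package's standard one. Class labels use a
permissive threshold of 0.15, trading specificity for sensitivity, which
is the clinically sensible direction for a screening model.

## Supervised hematology embedding

To ask whether longitudinal hematology alone separates the two groups,
samples (one blood draw each) are standardized and embedded in two
dimensions. The embedding is a supervised metric MDS built in this
package: pairwise Euclidean distances are inflated between samples of
different classes by a penalty (default five times the median pairwise
distance) and the penalized distances are embedded by classical
multidimensional scaling, which is deterministic; a fixed sign convention
removes the reflection ambiguity. Supervision therefore separates the
training classes strictly, just as a supervised non-linear reducer does.
Cohorts beyond 1,200 samples are embedded via a seeded landmark subset.
Out-of-sample projection — needed to place the unlabeled majority of the
cohort — averages the coordinates of the `n_neighbors` nearest training
samples in feature space with inverse-distance weights and never uses
labels.

Each patient is summarised by the coordinate-wise median of their sample
embeddings, and a **Y-score** in [0, 1] combines the available binary
classifications (structured, letters, clinical label when present) as an
unweighted mean — the combination rule is not specified anywhere, so
equal weights are the default and `weights` exposes the choice. The
score is undefined (an error) when no component exists.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analyses
assume, with planted ground truth so every step can be scored:

* **Treatment histories.** Conventional DMARDs from diagnosis; planted
  D2T patients start 2–4 b/tsDMARD MoA classes, non-D2T patients 0–1, or
  2 with a responding trajectory. Prescriptions carry start dates only,
  plus refill rows that exercise class collapsing.
* **Disease activity.** Piecewise-constant episode means per treatment
  episode with Gaussian visit noise (`noise_sd`, default 0.3 score
  units). D2T episodes after the second MoA draw means in [3.6, 5.2] —
  at least 0.4 above the 3.2 threshold — and responders in [1.6, 2.6],
  at least 0.6 below, so rule-engine recovery is decidable by
  construction. Joint counts and VAS follow a monotone map of the noisy
  visit-level activity, while ESR is solved from the DAS28 formula at the
  episode-level activity and CRP is an affine function of it: the
  laboratory sees the underlying disease state, the physical examination
  carries the visit noise. With `noise_sd = 0` the two coincide and the
  surrogate's error tends to zero as data grow; with noise, the
  examination component is invisible to the labs and constitutes a
  computable irreducible error the tests check against.
* **Hematology.** A 21-parameter panel (CBC, differential, reticulocytes,
  platelet scatter proxies, small chemistry) with between- and
  within-patient variation; configured `effect_sizes` shift patient-level
  means between groups in units of the between-patient SD. Defaults
  (0.4–0.8 on a hematology subset plus blood pressure) reflect where
  routine-care data tends to separate these groups; effects are present
  from baseline, which is what gives the pre-biological prediction model
  its signal.
* **Letters.** Rendered from the same lexicon the miner uses — a shared
  template contract, which is why exact letter-level recovery is a fair
  test of the miner's negation logic but says nothing about free-form
  prose. With probability `negation_rate` an active phrase is rendered
  negated and the letter-level truth records inactivity.
* **Labels.** A `clinical_label_fraction` (default 0.3) of patients get a
  tri-state validation label; prevalence defaults to 0.2, within the
  5–20% range reported for D2T RA (the clinically classified validation
  cohort itself ran higher, 52/152).
* **Missingness** is row-wise, missing completely at random, per table.
  Informative missingness is deliberately out of scope: nothing is known
  about the source database's missingness mechanism, so modelling one
  would manufacture structure the analysis would then "discover".

What the generator does *not* emulate: correlated lab panels, informative
visit scheduling beyond activity-dependent intervals, Dutch clinical
prose, transfer-in patients with truncated histories. Passing tests on
synthetic cohorts therefore demonstrate internal correctness of the
pipeline's logic, not real-world operating characteristics; the
real-data figures (identification AUC 0.88, prediction AUC 0.73,
surrogate MAE 0.8) remain reference points only.

## Numerical choices and degenerate inputs

* Dates are ISO-8601 calendar dates; month arithmetic uses 30.44 days and
  the activity window is closed on both ends.
* `compute_das28_esr` validates ranges strictly (ESR > 0, counts 0–28,
  VAS 0–100) and is strictly increasing in each argument.
* Time aggregates of a singleton series leave sd and mean-difference
  missing rather than inventing zeros; empty series yield all-missing.
* The imputer errors on all-missing columns; assembly drops them first.
* cmdscale sign ambiguity is fixed by making the largest-magnitude
  coordinate positive in each dimension.
* Every stochastic step takes an explicit seed; `generate_cohort` is
  byte-identical under a fixed config and seed, and the pipeline derives
  per-stage seeds from one master seed by fixed increments.

## Problem sizes used by the test suite

The bundled analyses run at sizes a laptop handles comfortably: the
workflow cohort and rule-engine checks use 500 patients; surrogate
recovery uses a 60-patient noise-free cohort (~3,000 complete visits);
the importance bootstrap runs 200 repetitions (the full procedure is
conventionally quoted at 1,000); FDR calibration uses 200 null
replicates; the embedding check uses 40 patients × 5 samples × 30
parameters. These sizes were chosen so the planted effects are decidable
with comfortable margins while the whole suite stays quick to run.

## Known limitations

* The letter miner is exact only under its template contract; real
  letters need a richer lexicon and a language-appropriate negation
  grammar.
* The MoA taxonomy ships as an editable table covering the b/tsDMARDs
  standard in RA care; site formularies differ.
* The supervised embedding guarantees training-set separation by
  construction — Y-score structure in the projected cohort, not the
  training silhouette, is the informative readout.
* MCAR missingness and independent lab noise are idealisations; effect
  sizes realized on other data-generating mechanisms will differ.
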