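# d2tra

Identification and prediction of **difficult-to-treat rheumatoid
arthritis (D2T RA)** in routine-care electronic health record data.

A minority of RA patients remain symptomatic after multiple biological or
targeted synthetic DMARDs (b/tsDMARDs). The EULAR definition flags them
by (1) failure of ≥ 2 b/tsDMARDs with different mechanisms of action
(MoA) and (2) signs of active disease — in practice a mean DAS28-ESR
≥ 3.2 in months 3–12 after starting a second-MoA drug, or the start of a
third MoA. Finding these patients in routine-care extracts is a
phenotyping problem: disease-activity components are missing for most
visits and much of the record is free text.

The package implements the full pipeline for rheumatology researchers and
clinical data scientists working on this phenotype:

* **Rule engine** (`classify_structured`) — criteria 1–2 on prescription
  sequences and DAS28-ESR windows, with a conservative
  insufficient-data path (never errs toward D2T).
* **DAS28-ESR surrogate** (`train_das28_approximator`) — gradient-boosted
  regression of the score
  `0.56·√TJC28 + 0.28·√SJC28 + 0.70·ln(ESR) + 0.014·VAS`
  on laboratory values, visit counts, patient characteristics and the
  pace of b/tsDMARD cycling, for visits lacking the components.
* **Letter miner** (`classify_unstructured`) — heading-scoped medication
  extraction and negation-aware active-disease detection
  ("no flare" is excluded; negation never crosses a sentence).
* **Feature importance** (`fdr_filter`, `bootstrap_l1_importance`) —
  time-aggregated features, Bayesian-ridge imputation, FDR filter at
  alpha 0.05, bootstrapped L1-penalized logistic regression.
* **Models** (`train_identification_model`, `train_prediction_model`) —
  cross-validated gradient boosting; the prediction model uses only data
  from before the first b/tsDMARD, forward-filled onto a monthly grid,
  with a permissive 0.15 decision threshold.
* **Hematology embedding** (`embed_hematology`, `compute_y_score`) —
  supervised 2-D embedding of longitudinal hematology with out-of-sample
  projection, per-patient median coordinates, and a combined Y-score.
* **Synthetic generator** (`generate_cohort`) — routine-care cohorts with
  planted ground truth (treatment cycling, activity trajectories,
  group-shifted hematology, templated letters), so every step is
  testable end to end. Real source records are not publicly available.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
500-patient cohort (20% planted D2T prevalence) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_das28_surrogate.R
Rscript analysis/03_classify.R
Rscript analysis/04_feature_importance.R
Rscript analysis/05_models.R
Rscript analysis/06_embedding.R
```

Output from a run of stages 2, 3 and 5:

```
Held-out MAE 0.187 score units over 26656 complete visits (mean DAS28 3.22).

structured_vs_planted:   sens 100%  spec 100%  (TP 114 FP 0 FN 0 TN 386)
letters_vs_letter_truth: sens 100%  spec 100%  (TP 158 FP 0 FN 0 TN 342)
letters_vs_clinical:     sens 100%  spec 91%   (TP 34 FP 9 FN 0 TN 94)

Identification model (clinically labeled subset):
  Sensitivity 91%  Specificity 100%
  AUC 0.997 (0.99-1.003) over 10 folds

Prediction model (pre-biological, threshold 0.15):
  Confusion: TP 27 FP 25 FN 7 TN 27
  Sensitivity 79%  Specificity 52%
  AUC 0.715 (0.62-0.81) over 10 folds
```

Reading this: with visit-level DAS28 noise of 0.3 score units the
surrogate's held-out error (0.19) is far below the 0.6-unit margin the
generator plants around the 3.2 threshold, so the rule engine recovers
the planted truth exactly. The letter miner is exact against letter-level
truth by the shared template contract; its 9 false positives against the
*clinical* label are patients whose letters genuinely satisfy both
criteria while the clinical label disagrees — the same conservative gap
seen between data-driven and clinical classification on real records.
The pre-biological prediction task is much harder than identification, as
it should be: only baseline hematology shifts carry signal before the
first b/tsDMARD.

On real routine-care data the corresponding models reported an
identification AUC of 0.88, a prediction AUC of 0.73 and a surrogate MAE
of 0.8; those serve as reference points only, since the source records
cannot be redistributed.

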