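#!/usr/bin/env Rscript
# Stage 5: the identification model (gradient boosting on the full-history
# feature table, ten-fold stratified cross-validation) and the prediction
# model (data censored at the first b/tsDMARD start, monthly forward-filled
# features, decision threshold 0.15 favouring sensitivity).

suppressPackageStartupMessages(library(d2tra))
bundle <- read_bundle("results/cohort")

das <- measured_das28(bundle)
feats <- assemble_features(bundle, das28_records = das, labels = "clinical")
ident <- train_identification_model(feats, n_folds = 10, seed = 425)
cat("Identification model (clinically labeled subset):\n")
print(ident$report)

censored <- truncate_before_first_btsdmard(bundle)
mf <- d2tra:::monthly_feature_table(censored, labels = "clinical")
cat(sprintf("\n%d labeled patients with pre-biological data.\n", nrow(mf)))
pred <- train_prediction_model(mf, threshold = 0.15, n_folds = 10,
                               seed = 426)
cat("Prediction model (pre-biological, threshold 0.15):\n")
print(pred$report)

reports <- data.frame(
  model = c("identification", "prediction"),
  n = c(nrow(feats), nrow(mf)),
  auc = c(ident$report$auc, pred$report$auc),
  auc_lo = c(ident$report$auc_interval[1], pred$report$auc_interval[1]),
  auc_hi = c(ident$report$auc_interval[2], pred$report$auc_interval[2]),
  sensitivity = c(ident$report$sensitivity, pred$report$sensitivity),
  specificity = c(ident$report$specificity, pred$report$specificity),
  threshold = c(ident$report$threshold, pred$report$threshold))
write.csv(reports, "results/05_model_reports.csv", row.names = FALSE)
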