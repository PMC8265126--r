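#!/usr/bin/env Rscript
# Stage 6: supervised two-dimensional embedding of the longitudinal
# hematology, trained on the clinically labeled subset and projected onto
# the whole cohort; per-patient median coordinates plus the combined
# Y-score (structured + letter + clinical classifications).

suppressPackageStartupMessages(library(d2tra))
bundle <- read_bundle("results/cohort")
structured <- read.csv("results/03_classification_structured.csv",
                       stringsAsFactors = FALSE)
letters <- read.csv("results/03_classification_letters.csv",
                    stringsAsFactors = FALSE)

hm <- hematology_matrix(bundle)
pat <- bundle$patients
lab <- pat$clinical_label[match(hm$patient_id, pat$patient_id)]
lab[lab == "unlabeled"] <- NA
emb <- embed_hematology(hm$x, labels = lab, seed = 427)
med <- patient_median_embedding(emb$coords, hm$patient_id)

s_lab <- structured$label[match(med$patient_id, structured$patient_id)]
u_lab <- letters$label[match(med$patient_id, letters$patient_id)]
c_lab <- pat$clinical_label[match(med$patient_id, pat$patient_id)]
med$y_score <- vapply(seq_len(nrow(med)), function(i) {
  compute_y_score(s_lab[i] == "D2T", u_lab[i] == "D2T",
                  if (c_lab[i] == "unlabeled") NA else c_lab[i] == "D2T")
}, numeric(1))
write.csv(med, "results/06_embedding.csv", row.names = FALSE)

lab_med <- c_lab != "unlabeled"
sil <- silhouette_score(as.matrix(med[lab_med, c("median_d1", "median_d2")]),
                        c_lab[lab_med])
cat(sprintf(
  "Labeled patient-median silhouette: %.2f over %d patients.\n",
  sil, sum(lab_med)))
cat(sprintf(
  "Spearman correlation of Y-score with distance to D2T centroid: %.2f\n",
  {
    ctr <- colMeans(med[lab_med & c_lab == "D2T",
                        c("median_d1", "median_d2")])
    dd <- sqrt((med$median_d1 - ctr[1])^2 + (med$median_d2 - ctr[2])^2)
    cor(med$y_score, -dd, method = "spearman")
  }))
cat("\n")
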