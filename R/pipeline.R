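#' Run the full identification-and-prediction pipeline on a synthetic cohort
#'
#' End-to-end orchestration: generate (or accept) a cohort, train the
#' DAS28-ESR surrogate, classify every patient from structured data and
#' from clinical letters, assemble the feature table, run the FDR filter
#' and bootstrapped L1 importance, cross-validate the identification
#' model, censor at the first b/tsDMARD and cross-validate the prediction
#' model, embed the longitudinal hematology with supervision from the
#' clinical labels, and compute per-patient Y-scores. Artifacts are
#' written under `out_dir` (CSV tables plus a JSON summary and a run
#' manifest); stage seeds are derived from the master seed by a fixed
#' increment scheme so a rerun with the same config reproduces identical
#' outputs.
#'
#' @param config A [generator_config()], or an existing cohort bundle.
#' @param out_dir Output directory; `NULL` skips writing artifacts.
#' @param n_boot Bootstrap repetitions for the importance analysis.
#' @param prediction_threshold Decision threshold of the prediction model.
#' @return List with all stage results: `bundle`, `approximator`,
#'   `structured`, `unstructured`, `features`, `selected_features`,
#'   `importance`, `identification`, `prediction`, `embedding`,
#'   `patient_summary`, `summary` (named numerics), `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = NULL,
                         n_boot = 200, prediction_threshold = 0.15) {
  bundle <- if (inherits(config, "cohort_bundle")) config
    else generate_cohort(config)
  cfg <- bundle$config
  master <- cfg$seed %||% 1L
  seeds <- list(approx = master + 11L, importance = master + 13L,
                identify = master + 17L, predict = master + 19L,
                embed = master + 23L)

  approx <- train_das28_approximator(bundle, seed = seeds$approx)
  structured <- classify_structured(bundle, approximator = approx)
  unstructured <- classify_unstructured(
    bundle$letters, patient_ids = bundle$patients$patient_id)

  das <- measured_das28(bundle)
  feats <- assemble_features(bundle, das28_records = das,
                             labels = "clinical")
  feats_std <- standardize_features(feats)
  feats_imp <- impute_features(feats_std)
  selected <- fdr_filter(feats_imp)
  imp_table <- feats_imp[c("patient_id", "label", selected)]
  n_lab <- nrow(imp_table)
  importance <- if (length(selected) >= 1 && n_lab >= 30) {
    tr <- min(140L, n_lab - max(2L, round(n_lab / 12)))
    bootstrap_l1_importance(imp_table, n_boot = n_boot, train_size = tr,
                            test_size = n_lab - tr,
                            seed = seeds$importance)
  } else NULL

  identification <- train_identification_model(feats, seed = seeds$identify)

  censored <- truncate_before_first_btsdmard(bundle)
  prediction <- NULL
  if (nrow(censored$patients) > 0) {
    mfeat <- monthly_feature_table(censored, labels = "clinical")
    if (nrow(mfeat) >= 20 && length(unique(mfeat$label)) == 2)
      prediction <- train_prediction_model(
        mfeat, threshold = prediction_threshold, seed = seeds$predict)
  }

  hm <- hematology_matrix(bundle)
  lab_of <- bundle$patients$clinical_label[
    match(hm$patient_id, bundle$patients$patient_id)]
  lab_of[lab_of == "unlabeled"] <- NA
  emb <- embed_hematology(hm$x, labels = lab_of, seed = seeds$embed)
  med <- patient_median_embedding(emb$coords, hm$patient_id)

  pat <- bundle$patients
  s_lab <- structured$label[match(pat$patient_id, structured$patient_id)]
  u_lab <- unstructured$label[match(pat$patient_id,
                                    unstructured$patient_id)]
  y <- vapply(seq_len(nrow(pat)), function(i) {
    compute_y_score(
      structured = s_lab[i] == "D2T",
      unstructured = u_lab[i] == "D2T",
      clinical = if (pat$clinical_label[i] == "unlabeled") NA
        else pat$clinical_label[i] == "D2T")
  }, numeric(1))
  patient_summary <- merge(
    data.frame(patient_id = pat$patient_id, planted_truth = pat$planted_truth,
               clinical_label = pat$clinical_label, structured = s_lab,
               unstructured = u_lab, y_score = y, stringsAsFactors = FALSE),
    med, by = "patient_id", all.x = TRUE)

  ev_struct <- evaluate(s_lab, pat$planted_truth)
  ev_letter <- evaluate(u_lab, pat$letter_truth)
  summary <- c(
    structured_sensitivity = ev_struct$sensitivity,
    structured_specificity = ev_struct$specificity,
    letter_accuracy = ev_letter$accuracy,
    das28_approximator_mae = approx$mae,
    identification_auc = identification$report$auc,
    prediction_auc = if (!is.null(prediction)) prediction$report$auc
      else NA_real_,
    n_patients = nrow(pat))

  manifest <- list(config = unclass(cfg), seeds = seeds,
                   row_counts = list(
                     patients = nrow(pat), letters = length(bundle$letters),
                     labeled = n_lab,
                     censored_patients = nrow(censored$patients)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bundle(bundle, file.path(out_dir, "cohort"))
    utils::write.csv(structured,
                     file.path(out_dir, "classification_structured.csv"),
                     row.names = FALSE)
    utils::write.csv(unstructured,
                     file.path(out_dir, "classification_letters.csv"),
                     row.names = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(importance))
      utils::write.csv(importance$importance,
                       file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
    utils::write.csv(patient_summary,
                     file.path(out_dir, "patient_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = as.list(summary),
                              manifest = manifest),
                         file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(bundle = bundle, approximator = approx, structured = structured,
       unstructured = unstructured, features = feats,
       selected_features = selected, importance = importance,
       identification = identification, prediction = prediction,
       embedding = emb, patient_summary = patient_summary,
       summary = summary, manifest = manifest)
}
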