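#' Censor a cohort at the first b/tsDMARD start
#'
#' Keeps, per patient, only records dated strictly before that patient's
#' first b/tsDMARD prescription start. Patients who never started a
#' b/tsDMARD have no censoring event and are dropped — the prediction
#' model is only defined for patients observed before their first
#' biological.
#'
#' @param bundle A cohort bundle.
#' @param taxonomy ATC-to-MoA taxonomy.
#' @return The censored bundle; `censor_dates` (named Date vector) attached
#'   as an element.
#' @export
truncate_before_first_btsdmard <- function(bundle,
                                           taxonomy =
                                             default_moa_taxonomy()) {
  rx <- bundle$prescriptions
  if (nrow(rx) == 0) {
    bundle$patients <- bundle$patients[0, , drop = FALSE]
    for (nm in c("prescriptions", "labs", "clinical_measurements",
                 "visits"))
      bundle[[nm]] <- bundle[[nm]][0, , drop = FALSE]
    bundle$letters <- list()
    bundle$censor_dates <- as.Date(character(0))
    return(bundle)
  }
  rx$moa <- map_atc_to_moa(rx$atc_code, taxonomy)
  bts <- rx[rx$moa %in% bts_classes(), , drop = FALSE]
  censor <- tapply(bts$start_date, bts$patient_id, min)
  censor <- as.Date(censor, origin = "1970-01-01")
  keep_ids <- names(censor)
  bundle$patients <- bundle$patients[
    bundle$patients$patient_id %in% keep_ids, , drop = FALSE]
  cut_table <- function(df, date_col) {
    df <- df[df$patient_id %in% keep_ids, , drop = FALSE]
    df[df[[date_col]] < censor[df$patient_id], , drop = FALSE]
  }
  bundle$prescriptions <- cut_table(bundle$prescriptions, "start_date")
  bundle$labs <- cut_table(bundle$labs, "date")
  bundle$clinical_measurements <-
    cut_table(bundle$clinical_measurements, "date")
  bundle$visits <- cut_table(bundle$visits, "date")
  bundle$letters <- Filter(function(l)
    l$patient_id %in% keep_ids && l$date < censor[l$patient_id],
    bundle$letters)
  bundle$censor_dates <- censor
  bundle
}

#' Regularize an irregular series onto a monthly forward-filled grid
#'
#' Builds a regular grid at one-month (30.44-day) intervals from the first
#' observation (or `origin`) up to, but never on or after, `censor_date`.
#' Each cell carries the last value observed at or before the cell date
#' (forward fill-in); cells before the first observation are missing.
#' Values are never propagated backward and nothing after the censor date
#' is ever used.
#'
#' @param dates Observation dates.
#' @param values Observation values.
#' @param censor_date Grid end (exclusive); defaults to just after the
#'   last observation.
#' @param origin Optional grid start earlier than the first observation.
#' @return data.frame `month` (0-based index), `date`, `value`.
#' @export
regularize_timeline <- function(dates, values, censor_date = NULL,
                                origin = NULL) {
  stopifnot(length(dates) == length(values))
  if (length(dates) == 0) {
    if (is.null(censor_date) || is.null(origin))
      return(data.frame(month = integer(), date = as.Date(character()),
                        value = numeric()))
    dates <- as.Date(character(0))
  }
  if (is.unsorted(dates)) {
    warning("observations were not sorted by date; sorting")
  }
  ord <- order(dates)
  dates <- dates[ord]; values <- values[ord]
  start <- origin %||% dates[1]
  end <- censor_date %||% (dates[length(dates)] + 1)
  if (end <= start)
    return(data.frame(month = integer(), date = as.Date(character()),
                      value = numeric()))
  n_cells <- floor(as.numeric(end - 1 - start) / MONTH_DAYS + 1e-9) + 1
  month <- seq_len(n_cells) - 1L
  cell_dates <- start + month * MONTH_DAYS
  idx <- findInterval(as.numeric(cell_dates), as.numeric(dates))
  value <- ifelse(idx == 0, NA_real_, values[pmax(idx, 1)])
  data.frame(month = month, date = cell_dates, value = value)
}

# per-patient monthly-grid aggregates of every lab and clinical series in
# a censored bundle, plus demographics at censor
monthly_feature_table <- function(bundle, labels = "clinical") {
  pat <- bundle$patients
  censor <- bundle$censor_dates
  if (is.null(censor)) stop("bundle must be censored first")
  y <- switch(labels, clinical = pat$clinical_label,
              planted = pat$planted_truth, letter = pat$letter_truth)
  keep <- y %in% c("D2T", "nonD2T")
  pat <- pat[keep, , drop = FALSE]; y <- y[keep]
  ids <- pat$patient_id
  out <- data.frame(
    patient_id = ids, label = y,
    sex_female = as.numeric(pat$sex == "F"),
    age_at_censor = as.numeric(format(censor[ids], "%Y")) - pat$birth_year,
    years_to_first_bts =
      as.numeric(censor[ids] - pat$ra_diagnosis_date) / 365.25,
    stringsAsFactors = FALSE)

  grid_aggs <- function(df, code_col) {
    parts <- list()
    sp <- split(df, list(df$patient_id, df[[code_col]]), drop = TRUE)
    for (s in sp) {
      pid <- s$patient_id[1]
      if (!pid %in% ids) next
      g <- regularize_timeline(s$date, s$value, censor_date = censor[pid])
      a <- aggregate_timeseries(g$value)
      parts[[length(parts) + 1]] <- data.frame(
        patient_id = pid, code = s[[code_col]][1],
        t(a), stringsAsFactors = FALSE)
    }
    if (length(parts) == 0) return(NULL)
    do.call(rbind, parts)
  }
  labs <- bundle$labs[bundle$labs$patient_id %in% ids, , drop = FALSE]
  la <- grid_aggs(labs, "test_code")
  cm <- bundle$clinical_measurements[
    bundle$clinical_measurements$patient_id %in% ids, , drop = FALSE]
  cm_long <- NULL
  if (nrow(cm) > 0) {
    cm_long <- do.call(rbind, lapply(
      c("sjc28", "tjc28", "vas_gh", "systolic_bp", "weight"),
      function(col) data.frame(patient_id = cm$patient_id, date = cm$date,
                               test_code = col, value = cm[[col]],
                               stringsAsFactors = FALSE)))
    ca <- grid_aggs(cm_long, "test_code")
    la <- rbind(la, ca)
  }
  if (!is.null(la)) {
    la_dt <- data.table::as.data.table(la)
    wide <- data.table::dcast(
      data.table::melt(la_dt, id.vars = c("patient_id", "code"),
                       variable.name = "agg"),
      patient_id ~ code + agg, sep = "_")
    out <- merge(out, as.data.frame(wide), by = "patient_id", all.x = TRUE)
  }
  out <- out[match(ids, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  fc <- feature_cols(out)
  all_na <- fc[vapply(out[fc], function(v) all(is.na(v)), logical(1))]
  out[, setdiff(names(out), all_na), drop = FALSE]
}

#' Confusion matrix and operating characteristics
#'
#' Sensitivity and specificity are reported as whole percents
#' (`round(100 * TP / (TP + FN))` etc.), matching how validation studies
#' print them.
#'
#' @param predicted,truth Label vectors (values `"D2T"` / `"nonD2T"`), or
#'   logical with `TRUE` = positive.
#' @param positive The positive class label.
#' @return List of class `eval_report`: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity` (whole percents), `sensitivity_raw`,
#'   `specificity_raw`, `accuracy`.
#' @export
evaluate <- function(predicted, truth, positive = "D2T") {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  p <- if (is.logical(predicted)) predicted else predicted == positive
  t <- if (is.logical(truth)) truth else truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  sens_raw <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec_raw <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = round(sens_raw), specificity = round(spec_raw),
    sensitivity_raw = sens_raw, specificity_raw = spec_raw,
    accuracy = (tp + tn) / length(p)
  ), class = "eval_report")
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat("Confusion: TP ", x$tp, " FP ", x$fp, " FN ", x$fn, " TN ", x$tn,
      "\nSensitivity ", x$sensitivity, "%  Specificity ", x$specificity,
      "%\n", sep = "")
  if (!is.null(x$auc))
    cat("AUC ", round(x$auc, 3), " (", round(x$auc_interval[1], 3), "-",
        round(x$auc_interval[2], 3), ") over ", x$n_folds, " folds\n",
        sep = "")
  invisible(x)
}

# stratified fold assignment
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

# cross-validated gradient boosting: pooled out-of-fold probabilities and
# per-fold AUCs
cv_xgboost <- function(x, y, n_folds, seed, nrounds = 150, max_depth = 4,
                       eta = 0.1) {
  if (length(unique(y)) < 2) stop("need both classes present")
  with_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    oof <- numeric(length(y))
    aucs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- xgb_fit(x[tr, , drop = FALSE], y[tr],
                     objective = "binary:logistic", nrounds = nrounds,
                     max_depth = max_depth, eta = eta)
      oof[!tr] <- xgb_predict(fit, x[!tr, , drop = FALSE])
      aucs[f] <- if (length(unique(y[!tr])) < 2) NA_real_ else
        as.numeric(pROC::auc(pROC::roc(y[!tr], oof[!tr], quiet = TRUE,
                                       direction = "<")))
    }
    final <- xgb_fit(x, y, objective = "binary:logistic",
                     nrounds = nrounds, max_depth = max_depth, eta = eta)
    list(oof = oof, aucs = aucs, fold = fold, model = final)
  })
}

finish_model_report <- function(cvfit, y, threshold, n_folds, seed) {
  rep <- evaluate(cvfit$oof >= threshold, y == 1)
  aucs <- cvfit$aucs[!is.na(cvfit$aucs)]
  rep$auc <- mean(aucs)
  rep$auc_per_fold <- cvfit$aucs
  rep$auc_interval <- mean(aucs) +
    c(-1, 1) * 1.96 * stats::sd(aucs) / sqrt(length(aucs))
  rep$pooled_auc <- as.numeric(pROC::auc(pROC::roc(y, cvfit$oof,
                                                   quiet = TRUE,
                                                   direction = "<")))
  rep$n_folds <- n_folds
  rep$threshold <- threshold
  rep$seed <- seed
  rep
}

#' Train the D2T identification model
#'
#' Gradient-boosted decision-tree ensemble (handles missing feature values
#' natively, no imputation needed) over the full-history feature table,
#' evaluated by stratified cross-validation: per-fold ROC AUCs, their mean
#' and a normal interval `mean +/- 1.96 sd / sqrt(folds)`, plus the
#' confusion matrix of the pooled out-of-fold predictions at the decision
#' threshold.
#'
#' @param features A feature table (`patient_id`, `label`, numeric
#'   features); missing values are allowed.
#' @param n_folds Number of stratified folds.
#' @param threshold Decision threshold on the predicted probability.
#' @param seed Integer seed (fold assignment and fitting).
#' @param nrounds,max_depth,eta Boosting parameters.
#' @return List with `model` (the fit on all data) and `report`
#'   (`eval_report` with AUC fields).
#' @export
train_identification_model <- function(features, n_folds = 10,
                                       threshold = 0.5, seed = 1,
                                       nrounds = 150, max_depth = 4,
                                       eta = 0.1) {
  fc <- feature_cols(features)
  x <- as.matrix(features[fc])
  y <- as.numeric(features$label == "D2T")
  cvfit <- cv_xgboost(x, y, n_folds, seed, nrounds, max_depth, eta)
  list(model = cvfit$model,
       report = finish_model_report(cvfit, y, threshold, n_folds, seed))
}

#' Train the pre-biological D2T prediction model
#'
#' Same cross-validated gradient-boosting machinery as the identification
#' model, applied to monthly forward-filled features from data censored at
#' the first b/tsDMARD start, with class labels assigned at a permissive
#' decision threshold (default 0.15) that favours sensitivity.
#'
#' @param features Monthly-grid feature table (e.g. from a censored bundle
#'   via the pipeline).
#' @param threshold Decision threshold in (0, 1).
#' @param n_folds Number of stratified folds.
#' @param seed Integer seed.
#' @param nrounds,max_depth,eta Boosting parameters.
#' @return List with `model` and `report`.
#' @export
train_prediction_model <- function(features, threshold = 0.15,
                                   n_folds = 10, seed = 1, nrounds = 150,
                                   max_depth = 4, eta = 0.1) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  fc <- feature_cols(features)
  x <- as.matrix(features[fc])
  y <- as.numeric(features$label == "D2T")
  cvfit <- cv_xgboost(x, y, n_folds, seed, nrounds, max_depth, eta)
  list(model = cvfit$model,
       report = finish_model_report(cvfit, y, threshold, n_folds, seed))
}
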