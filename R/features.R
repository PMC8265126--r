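#' Time-aggregate a repeated-measures series
#'
#' The five aggregates applied to every longitudinal variable: mean,
#' median, standard deviation, mean difference (mean of successive
#' differences in time order, a trend proxy) and mean minus median. With a
#' single value the standard deviation and mean difference are undefined
#' and returned as `NA`; an empty series yields all `NA`.
#'
#' @param values Numeric vector.
#' @param dates Optional dates used to put `values` in time order; when
#'   omitted the given order is assumed chronological.
#' @param abs_diff If `TRUE`, use the mean absolute successive difference
#'   instead of the signed mean difference.
#' @return Named numeric vector `mean`, `median`, `sd`, `mean_diff`,
#'   `mean_minus_median`.
#' @export
aggregate_timeseries <- function(values, dates = NULL, abs_diff = FALSE) {
  if (!is.null(dates)) {
    stopifnot(length(dates) == length(values))
    values <- values[order(dates)]
  }
  values <- values[!is.na(values)]
  if (length(values) == 0)
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
             mean_diff = NA_real_, mean_minus_median = NA_real_))
  m <- mean(values); md <- stats::median(values)
  dd <- if (length(values) >= 2) {
    d <- diff(values)
    if (abs_diff) mean(abs(d)) else mean(d)
  } else NA_real_
  c(mean = m, median = md,
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
    mean_diff = dd, mean_minus_median = m - md)
}

agg_names <- function() c("mean", "median", "sd", "mean_diff",
                          "mean_minus_median", "max", "min")

#' Assemble the patient-level feature table
#'
#' One row per labelled patient; columns are demographics, medication
#' counts (number of distinct drugs prescribed, number of b/tsDMARD MoA
#' classes, cycling pace), hospital-visit counts, time since RA diagnosis,
#' and time aggregates (mean, median, sd, mean difference, mean minus
#' median, max, min) of every laboratory series, the numeric clinical
#' measurements, and the DAS28-ESR record series when supplied.
#'
#' @param bundle A cohort bundle.
#' @param das28_records Optional DAS28 records (measured and/or
#'   approximated) to aggregate per patient.
#' @param labels Which label to attach: `"clinical"` (drops unlabeled
#'   patients), `"planted"` or `"letter"`.
#' @param reference_date Reference date for ages and durations.
#' @param taxonomy ATC-to-MoA taxonomy.
#' @return data.frame with `patient_id`, `label` and numeric feature
#'   columns; all-missing columns are dropped.
#' @export
assemble_features <- function(bundle, das28_records = NULL,
                              labels = c("clinical", "planted", "letter"),
                              reference_date = DATA_END,
                              taxonomy = default_moa_taxonomy()) {
  labels <- match.arg(labels)
  pat <- bundle$patients
  y <- switch(labels,
              clinical = pat$clinical_label,
              planted = pat$planted_truth,
              letter = pat$letter_truth)
  keep <- y %in% c("D2T", "nonD2T")
  if (!any(keep)) stop("no labeled patients for label source '", labels, "'")
  pat <- pat[keep, , drop = FALSE]
  y <- y[keep]
  ids <- pat$patient_id

  ref_year <- as.numeric(format(reference_date, "%Y"))
  out <- data.frame(
    patient_id = ids, label = y,
    sex_female = as.numeric(pat$sex == "F"),
    age = ref_year - pat$birth_year,
    time_since_diagnosis =
      as.numeric(reference_date - pat$ra_diagnosis_date) / 365.25,
    stringsAsFactors = FALSE
  )

  rx <- bundle$prescriptions[bundle$prescriptions$patient_id %in% ids, ,
                             drop = FALSE]
  rx_dt <- data.table::as.data.table(rx)
  if (nrow(rx_dt) > 0) {
    rx_dt$moa <- map_atc_to_moa(rx_dt$atc_code, taxonomy)
    med <- rx_dt[, list(
      n_distinct_drugs = length(unique(drug_name)),
      n_prescriptions = .N,
      n_moa_classes = length(unique(moa[moa %in% bts_classes()])),
      first_bts = suppressWarnings(min(start_date[moa %in% bts_classes()]))
    ), by = "patient_id"]
    idx <- match(ids, med$patient_id)
    out$n_distinct_drugs <- ifelse(is.na(idx), 0, med$n_distinct_drugs[idx])
    out$n_prescriptions <- ifelse(is.na(idx), 0, med$n_prescriptions[idx])
    out$n_moa_classes <- ifelse(is.na(idx), 0, med$n_moa_classes[idx])
    yrs <- as.numeric(reference_date - med$first_bts[idx]) / 365.25
    out$cycling_pace <- ifelse(
      is.na(idx) | is.infinite(as.numeric(med$first_bts[idx])) | is.na(yrs),
      0, out$n_moa_classes / pmax(yrs, 0.25))
  } else {
    out$n_distinct_drugs <- 0; out$n_prescriptions <- 0
    out$n_moa_classes <- 0; out$cycling_pace <- 0
  }

  vis <- bundle$visits[bundle$visits$patient_id %in% ids, , drop = FALSE]
  out$n_outpatient_visits <-
    as.numeric(table(factor(vis$patient_id[vis$visit_type == "outpatient"],
                            levels = ids)))
  out$n_ward_visits <-
    as.numeric(table(factor(vis$patient_id[vis$visit_type == "ward"],
                            levels = ids)))

  agg_block <- function(dt, value_col, date_col, prefix_col) {
    # dt sorted by patient, date upstream
    a <- dt[, {
      v <- get(value_col)[order(get(date_col))]
      v <- v[!is.na(v)]
      s <- aggregate_timeseries(v)
      list(mean = s[["mean"]], median = s[["median"]], sd = s[["sd"]],
           mean_diff = s[["mean_diff"]],
           mean_minus_median = s[["mean_minus_median"]],
           max = if (length(v)) max(v) else NA_real_,
           min = if (length(v)) min(v) else NA_real_)
    }, by = c("patient_id", prefix_col)]
    a
  }

  labs <- data.table::as.data.table(
    bundle$labs[bundle$labs$patient_id %in% ids, , drop = FALSE])
  if (nrow(labs) > 0) {
    la <- agg_block(labs, "value", "date", "test_code")
    wide <- data.table::dcast(
      data.table::melt(la, id.vars = c("patient_id", "test_code"),
                       variable.name = "agg"),
      patient_id ~ test_code + agg, sep = "_")
    out <- merge(out, as.data.frame(wide), by = "patient_id", all.x = TRUE)
  }

  cm <- data.table::as.data.table(
    bundle$clinical_measurements[
      bundle$clinical_measurements$patient_id %in% ids, , drop = FALSE])
  if (nrow(cm) > 0) {
    for (col in c("sjc28", "tjc28", "vas_gh", "systolic_bp", "weight")) {
      cm2 <- cm[, c("patient_id", "date", col), with = FALSE]
      cm2$test_code <- col
      data.table::setnames(cm2, col, "value")
      la <- agg_block(cm2, "value", "date", "test_code")
      wide <- data.table::dcast(
        data.table::melt(la, id.vars = c("patient_id", "test_code"),
                         variable.name = "agg"),
        patient_id ~ test_code + agg, sep = "_")
      out <- merge(out, as.data.frame(wide), by = "patient_id", all.x = TRUE)
    }
    hm <- cm[, list(height_median = stats::median(height, na.rm = TRUE)),
             by = "patient_id"]
    out <- merge(out, as.data.frame(hm), by = "patient_id", all.x = TRUE)
  }

  if (!is.null(das28_records) && nrow(das28_records) > 0) {
    da <- data.table::as.data.table(
      das28_records[das28_records$patient_id %in% ids, , drop = FALSE])
    da$test_code <- "das28"
    la <- agg_block(da, "value", "date", "test_code")
    wide <- data.table::dcast(
      data.table::melt(la, id.vars = c("patient_id", "test_code"),
                       variable.name = "agg"),
      patient_id ~ test_code + agg, sep = "_")
    out <- merge(out, as.data.frame(wide), by = "patient_id", all.x = TRUE)
  }

  out <- out[match(ids, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  # no all-missing columns after assembly
  fc <- feature_cols(out)
  all_na <- fc[vapply(out[fc], function(v) all(is.na(v)), logical(1))]
  out[, setdiff(names(out), all_na), drop = FALSE]
}

feature_cols <- function(table) {
  setdiff(names(table), c("patient_id", "label"))
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Missing entries are ignored when computing the column statistics;
#' zero-variance columns are centred only.
#'
#' @param table A feature table from [assemble_features()].
#' @return The table with standardized feature columns.
#' @export
standardize_features <- function(table) {
  for (cc in feature_cols(table)) {
    v <- table[[cc]]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    table[[cc]] <- (v - m) / s
  }
  table
}

# Bayesian ridge regression with intercept (evidence approximation): the
# weight precision lambda and noise precision alpha are iterated to their
# evidence maximum, so the effective penalty adapts to the data — near-zero
# for exact (noiseless) structure, strong when predictors approach the
# sample size. Returns predictions at x_new.
ridge_predict <- function(x, y, x_new, max_iter = 50, tol = 1e-10) {
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  sv <- svd(xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  n <- nrow(xc)
  alpha <- 1 / max(stats::var(yc), 1e-12)   # noise precision
  lambda <- 1                                # weight precision
  for (it in seq_len(max_iter)) {
    r <- lambda / alpha
    coef_d <- sv$d / (d2 + r)
    beta <- sv$v %*% (coef_d * uty)
    gamma <- sum(d2 / (d2 + r))
    rss <- sum((yc - sv$u %*% (sv$d * coef_d * uty))^2)
    lambda_new <- (gamma + 1e-12) / (sum(beta^2) + 1e-12)
    alpha_new <- (n - gamma + 1e-12) / (rss + 1e-12)
    conv <- abs(log(lambda_new / lambda)) < tol &&
      abs(log(alpha_new / alpha)) < tol
    lambda <- lambda_new; alpha <- alpha_new
    if (conv) break
  }
  r <- lambda / alpha
  beta <- sv$v %*% ((sv$d / (d2 + r)) * uty)
  drop(sweep(x_new, 2, xm) %*% beta) + ym
}

#' Impute missing feature values by iterative Bayesian ridge regression
#'
#' Each incomplete feature is regressed on all other features with a
#' Bayesian ridge (the penalty set by evidence maximisation), cycling until
#' the imputed values stabilise — the iterative model-based scheme behind
#' chained-equation imputation. The label column is never used as a
#' predictor. Deterministic: initialisation is the column mean and the
#' column order is fixed.
#'
#' @param table A feature table.
#' @param max_iter Maximum sweeps over the incomplete columns.
#' @param tol Convergence tolerance on the largest change of an imputed
#'   value, in units of the column's standard deviation.
#' @return The table with all feature entries filled in.
#' @export
impute_features <- function(table, max_iter = 10, tol = 1e-8) {
  fc <- feature_cols(table)
  if (!all(vapply(table[fc], is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  x <- as.matrix(table[fc])
  miss <- is.na(x)
  if (!any(miss)) return(table)
  if (any(colSums(!miss) == 0)) stop("all-missing feature column")
  # initial fill: column means
  for (j in which(colSums(miss) > 0))
    x[miss[, j], j] <- mean(x[!miss[, j], j])
  incomplete <- which(colSums(miss) > 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in incomplete) {
      obs <- !miss[, j]
      if (sum(obs) < 2) next
      pred <- ridge_predict(x[obs, -j, drop = FALSE], x[obs, j],
                            x[!obs, -j, drop = FALSE])
      sj <- stats::sd(x[obs, j]); if (!is.finite(sj) || sj == 0) sj <- 1
      delta <- max(delta, max(abs(pred - x[!obs, j])) / sj)
      x[!obs, j] <- pred
    }
    if (delta < tol) break
  }
  table[fc] <- as.data.frame(x)
  table
}

#' Univariate FDR feature filter
#'
#' Per-feature two-sample test against the D2T / non-D2T label (Welch
#' t-test for continuous features, Fisher's exact test for binary ones),
#' Benjamini-Hochberg adjusted; features with adjusted p-value at or below
#' `alpha` survive.
#'
#' @param table A feature table with a two-class `label` column.
#' @param alpha False discovery rate level.
#' @return Character vector of surviving feature names (possibly empty).
#' @export
fdr_filter <- function(table, alpha = 0.05) {
  y <- table$label
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need at least two patients per class")
  fc <- feature_cols(table)
  g <- y == "D2T"
  p <- vapply(fc, function(cc) {
    v <- table[[cc]]
    ok <- !is.na(v)
    if (length(unique(v[ok])) <= 1) return(1)
    if (length(unique(v[ok])) <= 2) {
      tab <- table(factor(v[ok]), factor(g[ok], levels = c(FALSE, TRUE)))
      if (any(dim(tab) < 2)) return(1)
      stats::fisher.test(tab)$p.value
    } else {
      if (min(sum(ok & g), sum(ok & !g)) < 2) return(1)
      stats::t.test(v[ok & g], v[ok & !g])$p.value
    }
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  if (alpha <= 0) return(character(0))
  fc[padj <= alpha]
}

#' Bootstrapped L1-penalized logistic feature importance
#'
#' Repeats `n_boot` random 140/12-style train/test partitions; on each
#' training partition an L1-penalized logistic regression is fitted, the
#' penalty chosen by internal cross-validation (the one-standard-error
#' lambda, keeping the model sparse so uninformative coefficients are
#' eliminated). Reports the mean coefficient across repetitions and the
#' selection frequency (fraction of repetitions with a non-zero
#' coefficient) per feature, ranked by selection frequency then mean
#' absolute coefficient.
#'
#' @param table A standardized, imputed feature table with a two-class
#'   `label` column.
#' @param n_boot Number of repetitions.
#' @param train_size,test_size Partition sizes; `train_size + test_size`
#'   must not exceed the number of rows.
#' @param seed Integer seed.
#' @param replace If `TRUE`, draw the training set with replacement
#'   (bootstrap resampling) instead of sampling a partition.
#' @param lambda_choice `"1se"` (default) or `"min"`.
#' @return List of class `importance_report`: `importance` (data.frame
#'   `feature`, `mean_coef`, `selection_freq`, `rank`), `n_boot`,
#'   `train_size`, `test_size`, `seed`.
#' @export
bootstrap_l1_importance <- function(table, n_boot = 1000, train_size = 140,
                                    test_size = 12, seed = 1,
                                    replace = FALSE,
                                    lambda_choice = c("1se", "min")) {
  lambda_choice <- match.arg(lambda_choice)
  fc <- feature_cols(table)
  x <- as.matrix(table[fc])
  if (any(is.na(x))) stop("feature table must be imputed first")
  y <- as.numeric(table$label == "D2T")
  n <- nrow(x)
  if (n < train_size + test_size)
    stop("need at least train_size + test_size = ",
         train_size + test_size, " rows; got ", n)
  with_seed(seed, {
    coefs <- matrix(0, n_boot, length(fc),
                    dimnames = list(NULL, fc))
    if (min(table(y)) < 5)
      stop("need at least 5 patients in each class")
    for (b in seq_len(n_boot)) {
      tr <- sample(n, train_size, replace = replace)
      # guard: enough of both classes for the internal cross-validation
      while (min(table(factor(y[tr], levels = c(0, 1)))) < 4)
        tr <- sample(n, train_size, replace = replace)
      fid <- stratified_folds(y[tr], 4)
      # glmnet warns about small class counts on every fit; the stratified
      # folds already guard the degenerate case, so keep the log quiet
      cv <- withCallingHandlers(
        glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 1, foldid = fid,
                          standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8|dangerous ground", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      s <- if (lambda_choice == "1se") "lambda.1se" else "lambda.min"
      cf <- as.numeric(stats::coef(cv, s = s))[-1]
      coefs[b, ] <- cf
    }
    sel <- colMeans(coefs != 0)
    mc <- colMeans(coefs)
    imp <- data.frame(feature = fc, mean_coef = mc, selection_freq = sel,
                      stringsAsFactors = FALSE)
    imp <- imp[order(-imp$selection_freq, -abs(imp$mean_coef)), ,
               drop = FALSE]
    imp$rank <- NA_integer_
    imp$rank[imp$selection_freq > 0] <- seq_len(sum(imp$selection_freq > 0))
    rownames(imp) <- NULL
    structure(list(importance = imp, n_boot = n_boot,
                   train_size = train_size, test_size = test_size,
                   seed = seed),
              class = "importance_report")
  })
}

#' @method print importance_report
#' @export
print.importance_report <- function(x, ...) {
  cat("Bootstrapped L1 importance: ", x$n_boot, " repetitions, ",
      x$train_size, "/", x$test_size, " split\n", sep = "")
  print(utils::head(x$importance, 10))
  invisible(x)
}
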