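#' Compute the DAS28-ESR disease activity score
#'
#' The disease activity score over 28 joints with erythrocyte sedimentation
#' rate:
#' \deqn{0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.70\ln(ESR) + 0.014\,VAS}
#' A score of 3.2 or higher indicates at least moderate disease activity;
#' that cut-off is what the rule engine uses to decide treatment failure.
#'
#' @param tjc28 Tender joint count over 28 joints (0-28).
#' @param sjc28 Swollen joint count over 28 joints (0-28).
#' @param esr Erythrocyte sedimentation rate in mm/h; must be > 0.
#' @param vas_gh Patient global health on a 0-100 visual analog scale.
#' @return Numeric vector of DAS28-ESR scores.
#' @examples
#' compute_das28_esr(0, 0, 1, 0)    # 0
#' compute_das28_esr(4, 2, 30, 50)  # about 4.6
#' @export
compute_das28_esr <- function(tjc28, sjc28, esr, vas_gh) {
  if (any(!is.finite(tjc28)) || any(tjc28 < 0) || any(tjc28 > 28))
    stop("tjc28 must be a count in [0, 28]")
  if (any(!is.finite(sjc28)) || any(sjc28 < 0) || any(sjc28 > 28))
    stop("sjc28 must be a count in [0, 28]")
  if (any(!is.finite(esr)) || any(esr <= 0))
    stop("esr must be > 0 mm/h")
  if (any(!is.finite(vas_gh)) || any(vas_gh < 0) || any(vas_gh > 100))
    stop("vas_gh must lie in [0, 100]")
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.70 * log(esr) + 0.014 * vas_gh
}

#' DAS28-ESR activity threshold
#'
#' Scores at or above this value indicate at least moderate disease
#' activity; used to deem a b/tsDMARD of a second mechanism of action
#' failed.
#' @export
DAS28_ACTIVE_THRESHOLD <- 3.2

# days per month used in all window arithmetic
MONTH_DAYS <- 30.44

#' Measured DAS28-ESR records in a cohort
#'
#' Joins clinical measurement visits (SJC28, TJC28, VAS-GH) with a same-day
#' ESR laboratory result and computes the measured DAS28-ESR where all four
#' components are present.
#'
#' @param bundle A cohort bundle.
#' @return A data.frame of DAS28 records: `patient_id`, `date`, `value`,
#'   `source` (always `"measured"`).
#' @export
measured_das28 <- function(bundle) {
  cm <- bundle$clinical_measurements
  empty <- data.frame(patient_id = character(), date = as.Date(character()),
                      value = numeric(), source = character(),
                      stringsAsFactors = FALSE)
  if (is.null(cm) || nrow(cm) == 0) return(empty)
  labs <- bundle$labs
  esr <- labs[labs$test_code == "ESR", c("patient_id", "date", "value")]
  if (nrow(esr) == 0) return(empty)
  names(esr)[3] <- "esr"
  m <- merge(cm, esr, by = c("patient_id", "date"))
  m <- m[stats::complete.cases(m[, c("tjc28", "sjc28", "esr", "vas_gh")]) &
           m$esr > 0, , drop = FALSE]
  if (nrow(m) == 0) return(empty)
  out <- data.frame(
    patient_id = m$patient_id,
    date = m$date,
    value = compute_das28_esr(m$tjc28, m$sjc28, m$esr, m$vas_gh),
    source = "measured",
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id, out$date), , drop = FALSE]
}

# --- surrogate-model feature construction -------------------------------

# Laboratory codes fed to the DAS28 approximator. Only laboratory values,
# hospital-visit counts, patient characteristics and the pace of cycling
# through b/tsDMARD MoA classes are permitted as features.
approximator_lab_codes <- function() {
  c("ESR", "CRP", "HGB", "WBC", "PLT", "NEUT", "LYMPH", "RETIC_PCT",
    "NEUT_BAND", "IG_PCT", "CREAT", "K")
}

# Feature matrix for (patient, date) pairs: same-day lab values, hospital
# visit count over the preceding year, age, sex and MoA-cycling pace.
das28_visit_features <- function(bundle, patient_id, date,
                                 taxonomy = default_moa_taxonomy()) {
  stopifnot(length(patient_id) == length(date))
  n <- length(patient_id)
  codes <- approximator_lab_codes()
  labs <- data.table::as.data.table(bundle$labs)
  key <- data.table::data.table(patient_id = patient_id, date = date,
                                row = seq_len(n))
  lab_wide <- data.table::dcast(
    labs[labs$test_code %in% codes],
    patient_id + date ~ test_code, value.var = "value",
    fun.aggregate = function(v) mean(v)
  )
  out <- merge(key, lab_wide, by = c("patient_id", "date"),
               all.x = TRUE, sort = FALSE)
  data.table::setorder(out, row)
  out <- as.data.frame(out)
  for (cc in setdiff(codes, names(out))) out[[cc]] <- NA_real_

  # hospital visits in the preceding 365 days, vectorized per patient
  vis_by <- split(as.numeric(bundle$visits$date), bundle$visits$patient_id)
  vis_by <- lapply(vis_by, sort)
  row_by <- split(seq_len(n), patient_id)
  out$visits_past_year <- 0
  for (pid in names(row_by)) {
    v <- vis_by[[pid]]
    if (is.null(v)) next
    rows <- row_by[[pid]]
    dd <- as.numeric(date[rows])
    out$visits_past_year[rows] <- findInterval(dd, v) -
      findInterval(dd - 365, v)
  }

  pat <- bundle$patients
  pidx <- match(patient_id, pat$patient_id)
  out$age <- as.numeric(format(date, "%Y")) - pat$birth_year[pidx]
  out$sex_female <- as.numeric(pat$sex[pidx] == "F")

  # swiftness of cycling: distinct MoA classes started / years since first
  # b/tsDMARD start, as of the record date
  rx <- bundle$prescriptions
  rx$moa <- map_atc_to_moa(rx$atc_code, taxonomy)
  rx <- rx[rx$moa %in% bts_classes(), , drop = FALSE]
  rx_by <- split(rx, rx$patient_id)
  out$cycling_pace <- 0
  for (pid in intersect(names(row_by), names(rx_by))) {
    r <- rx_by[[pid]]
    # first start per MoA class, in time order
    firsts <- sort(as.numeric(tapply(as.numeric(r$start_date), r$moa, min)))
    rows <- row_by[[pid]]
    dd <- as.numeric(date[rows])
    k <- findInterval(dd, firsts)           # classes started by each date
    yrs <- pmax((dd - firsts[1]) / 365.25, 0.25)
    out$cycling_pace[rows] <- ifelse(k == 0, 0, k / yrs)
  }

  out[, c(codes, "visits_past_year", "age", "sex_female", "cycling_pace")]
}

#' Train a surrogate model approximating the DAS28-ESR
#'
#' Disease activity components (joint counts, VAS) are missing for many
#' routine-care visits, so a supervised regression is fitted that
#' approximates the measured DAS28-ESR from laboratory values, hospital
#' visit counts, patient characteristics and the pace of cycling through
#' b/tsDMARD MoA classes. Gradient-boosted trees are the default model
#' family (they tolerate missing inputs natively); a linear model is
#' available as a fallback.
#'
#' @param bundle A cohort bundle with at least 50 visits carrying all four
#'   DAS28 components.
#' @param taxonomy ATC-to-MoA taxonomy.
#' @param model `"xgboost"` (default) or `"linear"`.
#' @param holdout_fraction Fraction of complete visits held out to estimate
#'   the mean absolute error.
#' @param nrounds,max_depth,eta Boosting parameters.
#' @param max_train_visits Larger cohorts are subsampled to at most this
#'   many complete visits before fitting.
#' @param seed Integer seed controlling the train/test split and fitting.
#' @return An object of class `das28_approximator` with elements `model`,
#'   `features`, `mae` (held-out mean absolute error, score units), `n`,
#'   `seed`.
#' @export
train_das28_approximator <- function(bundle, taxonomy = default_moa_taxonomy(),
                                     model = c("xgboost", "linear"),
                                     holdout_fraction = 0.2,
                                     nrounds = 400, max_depth = 6, eta = 0.1,
                                     max_train_visits = 5000, seed = 1) {
  model <- match.arg(model)
  rec <- measured_das28(bundle)
  if (nrow(rec) < 50)
    stop("need at least 50 visits with all four DAS28 components; got ",
         nrow(rec))
  if (nrow(rec) > max_train_visits)
    rec <- rec[with_seed(seed, sort(sample(nrow(rec), max_train_visits))), ,
               drop = FALSE]
  feats <- das28_visit_features(bundle, rec$patient_id, rec$date, taxonomy)
  x <- as.matrix(feats)
  y <- rec$value
  with_seed(seed, {
    n_test <- max(1L, round(holdout_fraction * nrow(x)))
    test_idx <- sample(nrow(x), n_test)
    if (model == "xgboost") {
      fit <- xgb_fit(x[-test_idx, , drop = FALSE], y[-test_idx],
                     objective = "reg:squarederror", nrounds = nrounds,
                     max_depth = max_depth, eta = eta)
      pred <- xgb_predict(fit, x[test_idx, , drop = FALSE])
    } else {
      df <- as.data.frame(x)
      df$.y <- y
      fit <- stats::lm(.y ~ ., data = df[-test_idx, , drop = FALSE])
      pred <- stats::predict(fit, as.data.frame(x)[test_idx, , drop = FALSE])
    }
    structure(list(
      model = fit, kind = model, features = colnames(x),
      mae = mean(abs(pred - y[test_idx])),
      n = nrow(x), seed = seed, taxonomy = taxonomy
    ), class = "das28_approximator")
  })
}

#' @method print das28_approximator
#' @export
print.das28_approximator <- function(x, ...) {
  cat("DAS28-ESR surrogate model (", x$kind, ")\n",
      "  trained on ", x$n, " complete visits; held-out MAE ",
      round(x$mae, 3), " score units\n", sep = "")
  invisible(x)
}

# Predict the approximated DAS28-ESR at arbitrary (patient, date) pairs.
# Visits with no same-day ESR are returned as NA: the surrogate is trained
# only on visits that carry an ESR (the target needs one), so its behaviour
# on ESR-less feature patterns is unsupported and regresses toward the
# training mean — not a conservative basis for calling a treatment failed.
predict_das28 <- function(object, bundle, patient_id, date,
                          require_inflammation_marker = TRUE) {
  feats <- das28_visit_features(bundle, patient_id, date, object$taxonomy)
  x <- as.matrix(feats[, object$features, drop = FALSE])
  pred <- if (object$kind == "xgboost") {
    xgb_predict(object$model, x)
  } else {
    as.numeric(stats::predict(object$model, as.data.frame(x)))
  }
  if (require_inflammation_marker)
    pred[is.na(feats$ESR)] <- NA_real_
  pred
}

#' Approximate the DAS28-ESR at visits lacking a measured score
#'
#' Emits one approximated record per clinical visit date that has no
#' measured DAS28-ESR; measured values are never overwritten.
#'
#' @param object A fitted [train_das28_approximator()] model.
#' @param bundle A cohort bundle.
#' @param patient_id Optional patient filter (default: all patients).
#' @param date_range Optional `c(from, to)` date filter.
#' @return A data.frame of DAS28 records with `source = "approximated"`.
#' @export
approximate_das28 <- function(object, bundle, patient_id = NULL,
                              date_range = NULL) {
  stopifnot(inherits(object, "das28_approximator"))
  vis <- bundle$visits
  vis <- vis[vis$visit_type == "outpatient", , drop = FALSE]
  if (!is.null(patient_id)) {
    if (!all(patient_id %in% bundle$patients$patient_id))
      stop("unknown patient_id")
    vis <- vis[vis$patient_id %in% patient_id, , drop = FALSE]
  }
  if (!is.null(date_range))
    vis <- vis[vis$date >= date_range[1] & vis$date <= date_range[2], ,
               drop = FALSE]
  meas <- measured_das28(bundle)
  have <- paste(meas$patient_id, meas$date)
  vis <- vis[!(paste(vis$patient_id, vis$date) %in% have), , drop = FALSE]
  vis <- unique(vis[, c("patient_id", "date")])
  if (nrow(vis) == 0)
    return(data.frame(patient_id = character(), date = as.Date(character()),
                      value = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    patient_id = vis$patient_id, date = vis$date,
    value = predict_das28(object, bundle, vis$patient_id, vis$date),
    source = "approximated", stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$value), , drop = FALSE]
  out[order(out$patient_id, out$date), , drop = FALSE]
}

#' Mean DAS28-ESR in a window after an anchor date
#'
#' Averages all records dated within the closed interval
#' \[anchor + `start_months` months, anchor + `end_months` months\], with a
#' month taken as 30.44 days. Returns `NA` (with `n = 0`) when no record
#' falls in the window; callers treat that as insufficient data.
#'
#' @param records DAS28 record data.frame (`date`, `value`).
#' @param anchor_date Anchor date (e.g. start of the second-MoA b/tsDMARD).
#' @param start_months,end_months Window offsets in months.
#' @return A list with `mean` (NA if undefined) and `n` (records used).
#' @export
mean_das28_in_window <- function(records, anchor_date,
                                 start_months = 3, end_months = 12) {
  stopifnot(inherits(anchor_date, "Date"))
  lo <- anchor_date + start_months * MONTH_DAYS
  hi <- anchor_date + end_months * MONTH_DAYS
  inw <- records$date >= lo & records$date <= hi
  if (!any(inw)) return(list(mean = NA_real_, n = 0L))
  list(mean = mean(records$value[inw]), n = sum(inw))
}
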