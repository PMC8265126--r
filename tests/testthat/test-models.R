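test_that("censoring keeps only data before the first b/tsDMARD", {
  b <- fx_default()
  cen <- truncate_before_first_btsdmard(b)
  tax <- default_moa_taxonomy()
  # every kept patient has a censor date and no record on/after it
  expect_true(all(cen$patients$patient_id %in% names(cen$censor_dates)))
  for (pid in sample(cen$patients$patient_id, 10)) {
    cd <- cen$censor_dates[pid]
    expect_true(all(cen$labs$date[cen$labs$patient_id == pid] < cd))
    expect_true(all(cen$visits$date[cen$visits$patient_id == pid] < cd))
    expect_true(all(cen$prescriptions$start_date[
      cen$prescriptions$patient_id == pid] < cd))
  }
  # patients with no b/tsDMARD are dropped
  has_bts <- vapply(b$patients$patient_id, function(pid) {
    nrow(moa_start_sequence(
      b$prescriptions[b$prescriptions$patient_id == pid, , drop = FALSE],
      tax)) > 0
  }, logical(1))
  expect_setequal(cen$patients$patient_id,
                  b$patients$patient_id[has_bts])

  b0 <- b
  b0$prescriptions <- b0$prescriptions[0, , drop = FALSE]
  expect_equal(nrow(truncate_before_first_btsdmard(b0)$patients), 0)
})

test_that("forward fill regularizes onto the monthly grid", {
  d0 <- as.Date("2018-01-01")
  g <- regularize_timeline(c(d0, d0 + 3 * 30.44), c(5, 7))
  expect_equal(g$value, c(5, 5, 5, 7))
  expect_equal(g$month, 0:3)

  # single observation: constant grid up to the censor date
  g2 <- regularize_timeline(d0, 4, censor_date = d0 + 100)
  expect_true(all(g2$value == 4))
  expect_equal(nrow(g2), 4)   # months 0..3 within 100 days

  # no observations: all-missing grid over the stated span
  g3 <- regularize_timeline(as.Date(character(0)), numeric(0),
                            censor_date = d0 + 95, origin = d0)
  expect_true(all(is.na(g3$value)))
  expect_gt(nrow(g3), 0)

  # months before the first observation are missing, never back-filled
  g4 <- regularize_timeline(d0 + 70, 9, censor_date = d0 + 150,
                            origin = d0)
  expect_true(is.na(g4$value[1]))
  expect_equal(g4$value[4], 9)

  expect_warning(regularize_timeline(c(d0 + 50, d0), c(2, 1)), "sorted")
})

test_that("nothing after the censor date leaks into prediction features", {
  b <- fx_default()
  cen1 <- truncate_before_first_btsdmard(b)
  f1 <- d2tra:::monthly_feature_table(cen1, labels = "planted")

  # perturb every post-censor record wildly, re-censor, re-featurize
  b2 <- b
  cd <- cen1$censor_dates
  post <- b2$labs$patient_id %in% names(cd) &
    b2$labs$date >= cd[b2$labs$patient_id]
  b2$labs$value[post] <- b2$labs$value[post] * 100 + 1e4
  postv <- b2$clinical_measurements$patient_id %in% names(cd) &
    b2$clinical_measurements$date >= cd[b2$clinical_measurements$patient_id]
  b2$clinical_measurements$sjc28[postv] <- 28
  f2 <- d2tra:::monthly_feature_table(truncate_before_first_btsdmard(b2),
                                      labels = "planted")
  expect_identical(f1, f2)
})

test_that("evaluate matches hand-computed ratios on random tables", {
  withr::with_seed(77, {
    for (i in 1:200) {
      tp <- sample(0:40, 1); fp <- sample(0:40, 1)
      fn <- sample(0:40, 1); tn <- sample(0:40, 1)
      if (tp + fn == 0 || tn + fp == 0) next
      truth <- rep(c("D2T", "nonD2T"), c(tp + fn, fp + tn))
      pred <- c(rep("D2T", tp), rep("nonD2T", fn),
                rep("D2T", fp), rep("nonD2T", tn))
      r <- evaluate(pred, truth)
      expect_equal(c(r$tp, r$fp, r$fn, r$tn), c(tp, fp, fn, tn))
      expect_equal(r$sensitivity, round(100 * tp / (tp + fn)))
      expect_equal(r$specificity, round(100 * tn / (tn + fp)))
    }
  })
  expect_error(evaluate(c("D2T"), c("D2T", "nonD2T")), "equal length")
})

test_that("identification model separates a strongly labelled cohort and
           stays at chance under permutation", {
  tab <- planted_feature_table(n = 200, n_pos = 70, effect = 1.2, seed = 55)
  fit <- train_identification_model(tab, n_folds = 5, seed = 5)
  expect_gte(fit$report$auc, 0.85)
  expect_true(all(!is.na(fit$report$auc_per_fold)))
  expect_equal(fit$report$n_folds, 5)

  perm <- tab
  perm$label <- withr::with_seed(8, sample(perm$label))
  null_fit <- train_identification_model(perm, n_folds = 5, seed = 5)
  expect_gte(null_fit$report$pooled_auc, 0.4)
  expect_lte(null_fit$report$pooled_auc, 0.6)

  one <- tab[tab$label == "D2T", ]
  expect_error(train_identification_model(one, seed = 1), "class")
})

test_that("the prediction threshold drives the confusion matrix", {
  tab <- planted_feature_table(n = 120, n_pos = 40, effect = 1, seed = 66)
  fit <- train_prediction_model(tab, threshold = 0.15, n_folds = 5,
                                seed = 5)
  expect_equal(fit$report$threshold, 0.15)
  # a permissive threshold trades specificity for sensitivity
  strict <- train_prediction_model(tab, threshold = 0.9, n_folds = 5,
                                   seed = 5)
  expect_gte(fit$report$sensitivity, strict$report$sensitivity)
  expect_lte(fit$report$specificity, strict$report$specificity)

  # boundary: threshold 1 labels everything non-D2T
  all_neg <- train_prediction_model(tab, threshold = 1, n_folds = 5,
                                    seed = 5)
  expect_equal(all_neg$report$sensitivity, 0)
  expect_equal(all_neg$report$tp + all_neg$report$fp, 0)

  expect_error(train_prediction_model(tab, threshold = 0), "threshold")
  expect_error(train_prediction_model(tab, threshold = 1.2), "threshold")
})
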