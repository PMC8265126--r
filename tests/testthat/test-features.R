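test_that("time aggregation matches hand arithmetic", {
  a <- aggregate_timeseries(c(2, 2, 2))
  expect_equal(unname(a), c(2, 2, 0, 0, 0))

  b <- aggregate_timeseries(c(1, 2, 3))
  expect_equal(b[["mean"]], 2)
  expect_equal(b[["median"]], 2)
  expect_equal(b[["sd"]], 1)
  expect_equal(b[["mean_diff"]], 1)
  expect_equal(b[["mean_minus_median"]], 0)

  s <- aggregate_timeseries(5)
  expect_equal(s[["mean"]], 5)
  expect_true(is.na(s[["sd"]]))
  expect_true(is.na(s[["mean_diff"]]))
  expect_equal(s[["mean_minus_median"]], 0)

  expect_true(all(is.na(aggregate_timeseries(numeric(0)))))

  # dates control the ordering used by the trend aggregate
  d <- as.Date(c("2020-03-01", "2020-01-01", "2020-02-01"))
  expect_equal(aggregate_timeseries(c(3, 1, 2), dates = d)[["mean_diff"]],
               1)
})

test_that("aggregation matches a brute-force recomputation on random series", {
  withr::with_seed(21, {
    for (i in 1:50) {
      v <- rnorm(sample(2:30, 1))
      a <- aggregate_timeseries(v)
      expect_equal(a[["mean"]], sum(v) / length(v))
      expect_equal(a[["median"]], stats::median(v))
      expect_equal(a[["sd"]], sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
      expect_equal(a[["mean_diff"]],
                   mean(v[-1] - v[-length(v)]))
      expect_equal(a[["mean_minus_median"]], mean(v) - stats::median(v))
    }
  })
})

test_that("assembled features reflect the underlying record", {
  b <- fx_default()
  f <- assemble_features(b, measured_das28(b), labels = "planted")
  expect_equal(nrow(f), nrow(b$patients))
  expect_false(any(vapply(f[d2tra:::feature_cols(f)],
                          function(v) all(is.na(v)), logical(1))))

  pid <- f$patient_id[5]
  rx <- b$prescriptions[b$prescriptions$patient_id == pid, ]
  expect_equal(f$n_distinct_drugs[5], length(unique(rx$drug_name)))
  expect_equal(f$time_since_diagnosis[5],
               as.numeric(as.Date("2020-12-31") -
                            b$patients$ra_diagnosis_date[
                              b$patients$patient_id == pid]) / 365.25)
  esr <- b$labs[b$labs$patient_id == pid & b$labs$test_code == "ESR", ]
  expect_equal(f$ESR_max[5], max(esr$value))
})

test_that("standardization gives mean 0 and unit sd to complete columns", {
  b <- fx_default()
  f <- standardize_features(assemble_features(b, labels = "planted"))
  for (cc in sample(d2tra:::feature_cols(f), 20)) {
    v <- f[[cc]]
    if (any(is.na(v)) || stats::sd(v) == 0) next
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(v) - 1), 1e-9)
  }
})

test_that("imputation is a no-op on complete tables and recovers linear
           structure", {
  tab <- planted_feature_table(n = 100, n_pos = 30, seed = 3)
  expect_identical(impute_features(tab), tab)

  # one feature an exact linear function of another, 20% missing
  withr::with_seed(4, {
    tab$lin <- 2 * tab$inf1 + 3
    holes <- sample(nrow(tab), 20)
    truth <- tab$lin[holes]
    tab$lin[holes] <- NA
    imp <- impute_features(tab)
    expect_lt(max(abs(imp$lin[holes] - truth)), 1e-6)
  })

  # heavily missing noise column stays within the observed range
  withr::with_seed(5, {
    tab2 <- planted_feature_table(n = 100, n_pos = 30, seed = 6)
    holes <- sample(nrow(tab2), 50)
    tab2$noise1[holes] <- NA
    rng <- range(tab2$noise1, na.rm = TRUE)
    imp2 <- impute_features(tab2)
    expect_true(all(imp2$noise1[holes] >= rng[1] - 1 &
                      imp2$noise1[holes] <= rng[2] + 1))
  })

  tab3 <- planted_feature_table(n = 20, n_pos = 8, seed = 7)
  tab3$inf1 <- NA_real_
  expect_error(impute_features(tab3), "all-missing")
})

test_that("FDR filter keeps power on strong effects and respects alpha 0", {
  # a single standardized effect of 2.0 at n=152 is essentially always kept
  for (s in 1:20) {
    tab <- planted_feature_table(n = 152, n_pos = 52, effect = 2,
                                 p_inf = 1, p_noise = 20, seed = 200 + s)
    expect_true("inf1" %in% fdr_filter(tab))
  }
  tab <- planted_feature_table(seed = 9)
  expect_length(fdr_filter(tab, alpha = 0), 0)
  one_class <- tab[tab$label == "D2T", ]
  expect_error(fdr_filter(one_class), "two patients per class")
})

test_that("FDR false-selection fraction stays controlled under the null", {
  # 50 permuted-label replicates here; the acceptance suite runs 200
  withr::with_seed(31, {
    frac <- replicate(50, {
      tab <- planted_feature_table(n = 120, n_pos = 40, effect = 0,
                                   p_inf = 0, p_noise = 60,
                                   seed = sample.int(1e6, 1))
      length(fdr_filter(tab)) / 60
    })
    expect_lte(mean(frac), 1.5 * 0.05)
  })
})

test_that("bootstrap importance is reproducible and eliminates noise", {
  tab <- planted_feature_table(seed = 1)
  r1 <- bootstrap_l1_importance(tab, n_boot = 5, seed = 42)
  r2 <- bootstrap_l1_importance(tab, n_boot = 5, seed = 42)
  expect_identical(r1$importance, r2$importance)

  expect_error(bootstrap_l1_importance(tab[1:50, ], n_boot = 2, seed = 1),
               "at least")

  imp <- r1$importance
  expect_equal(sort(imp$rank[!is.na(imp$rank)]),
               seq_len(sum(!is.na(imp$rank))))
})
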