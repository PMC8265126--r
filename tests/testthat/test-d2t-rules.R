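test_that("ATC codes map to MoA classes, unknown codes to not_btsDMARD", {
  tax <- default_moa_taxonomy()
  expect_equal(map_atc_to_moa("L04AB04", tax), "TNFi")    # adalimumab
  expect_equal(map_atc_to_moa("L04AC07", tax), "IL6i")    # tocilizumab
  expect_equal(map_atc_to_moa("L01XC02", tax), "antiCD20")
  expect_equal(map_atc_to_moa("M01AE01", tax), "not_btsDMARD")
  expect_equal(map_atc_to_moa("ZZZZZZZ", tax), "not_btsDMARD")
})

test_that("MoA start sequences collapse repeats and order by first start", {
  rx <- data.frame(
    patient_id = "P1",
    atc_code = c("L04AB01", "L04AB04", "L04AC07"),   # TNFi, TNFi, IL6i
    drug_name = c("etanercept", "adalimumab", "tocilizumab"),
    start_date = as.Date(c("2010-05-01", "2012-02-01", "2013-07-01")))
  s <- moa_start_sequence(rx)
  expect_equal(s$moa_class, c("TNFi", "IL6i"))
  expect_equal(s$start_date[1], as.Date("2010-05-01"))
  expect_false(any(s$tie))

  # same-day starts: taxonomy enumeration order, tie flagged
  rx2 <- data.frame(patient_id = "P1",
                    atc_code = c("L04AC07", "L04AB01"),
                    drug_name = c("tocilizumab", "etanercept"),
                    start_date = as.Date(c("2011-01-01", "2011-01-01")))
  s2 <- moa_start_sequence(rx2)
  expect_equal(s2$moa_class, c("TNFi", "IL6i"))
  expect_true(all(s2$tie))

  expect_equal(nrow(moa_start_sequence(rx2[0, ])), 0)
})

test_that("criterion 1 counts classes, not drugs", {
  rx_two_tnfi <- data.frame(
    patient_id = "P1", atc_code = c("L04AB01", "L04AB04"),
    drug_name = c("etanercept", "adalimumab"),
    start_date = as.Date(c("2010-01-01", "2012-01-01")))
  expect_false(criterion1(moa_start_sequence(rx_two_tnfi)))

  rx_two_moa <- data.frame(
    patient_id = "P1", atc_code = c("L04AB01", "L04AC07"),
    drug_name = c("etanercept", "tocilizumab"),
    start_date = as.Date(c("2010-01-01", "2012-01-01")))
  expect_true(criterion1(moa_start_sequence(rx_two_moa)))
  expect_false(criterion1(moa_start_sequence(rx_two_moa[0, ])))
})

test_that("criterion 2 fires on window activity or a third MoA", {
  seq2 <- data.frame(moa_class = c("TNFi", "IL6i"),
                     start_date = as.Date(c("2010-01-01", "2012-01-01")),
                     tie = FALSE)
  anchor <- seq2$start_date[2]
  active <- data.frame(date = anchor + c(4, 8) * 30.44,
                       value = c(4.0, 4.2))
  r <- criterion2(seq2, active)
  expect_true(r$met)
  expect_match(r$evidence[[1]]$rule, "window_mean_das28")

  quiet <- data.frame(date = anchor + c(4, 8) * 30.44, value = c(2.0, 2.2))
  expect_false(criterion2(seq2, quiet)$met)

  # third MoA decides with no disease-activity data at all
  seq3 <- rbind(seq2, data.frame(moa_class = "JAKi",
                                 start_date = as.Date("2014-01-01"),
                                 tie = FALSE))
  r3 <- criterion2(seq3, active[0, ])
  expect_true(r3$met)
  expect_match(r3$evidence[[1]]$rule, "third_moa")

  # two MoA, no window data: insufficient, not met
  r0 <- criterion2(seq2, active[0, ])
  expect_false(r0$met)
  expect_false(r0$sufficient)
})

test_that("criterion functions agree with a brute-force oracle on random
           histories", {
  tax <- default_moa_taxonomy()
  bts_atc <- tax$atc_code[tax$moa_class != "not_btsDMARD"]
  withr::with_seed(314, {
    for (i in 1:1000) {
      n_rx <- sample(0:6, 1)
      rx <- data.frame(
        patient_id = rep("P1", n_rx),
        atc_code = sample(tax$atc_code, n_rx, replace = TRUE),
        drug_name = rep("x", n_rx),
        start_date = as.Date("2010-01-01") +
          sample(0:3000, n_rx, replace = TRUE))
      n_rec <- sample(0:8, 1)
      rec <- data.frame(date = as.Date("2010-01-01") +
                          sample(0:4000, n_rec, replace = TRUE),
                        value = runif(n_rec, 0.5, 7))

      s <- moa_start_sequence(rx, tax)
      got1 <- criterion1(s)
      got2 <- criterion2(s, rec)$met

      # oracle: direct enumeration over the raw tables
      moa <- tax$moa_class[match(rx$atc_code, tax$atc_code)]
      keep <- !is.na(moa) & moa != "not_btsDMARD"
      firsts <- c()
      for (m in unique(moa[keep]))
        firsts[m] <- min(rx$start_date[keep & moa == m])
      firsts <- sort(firsts)
      exp1 <- length(firsts) >= 2
      exp2 <- FALSE
      if (length(firsts) >= 3) exp2 <- TRUE
      if (length(firsts) == 2) {
        a <- as.Date(firsts[2], origin = "1970-01-01")
        inw <- rec$value[rec$date >= a + 3 * 30.44 &
                           rec$date <= a + 12 * 30.44]
        if (length(inw) > 0 && mean(inw) >= 3.2) exp2 <- TRUE
      }
      expect_identical(got1, exp1)
      expect_identical(got2, exp2)
    }
  })
})

test_that("structured classification recovers planted truth without noise", {
  b <- fx_noisefree()
  cl <- classify_structured(b, approximator = fx_approximator())
  expect_gte(mean(cl$label == b$patients$planted_truth), 0.95)
  expect_true(all((cl$label == "D2T") ==
                    (cl$criterion1_met & cl$criterion2_met)))
  expect_true(all(cl$label[cl$data_sufficiency == "insufficient"] ==
                    "nonD2T"))
})

test_that("the third-MoA branch is independent of clinical measurements", {
  b <- fx_noisefree()
  b$clinical_measurements <- b$clinical_measurements[0, , drop = FALSE]
  cl <- classify_structured(b, approximator = fx_approximator())
  tax <- default_moa_taxonomy()
  n_moa <- vapply(b$patients$patient_id, function(pid) {
    nrow(moa_start_sequence(
      b$prescriptions[b$prescriptions$patient_id == pid, , drop = FALSE],
      tax))
  }, numeric(1))
  expect_true(all(cl$label[n_moa >= 3] == "D2T"))
})

test_that("an empty cohort classifies to an empty result", {
  b <- fx_noisefree()
  b$patients <- b$patients[0, , drop = FALSE]
  cl <- classify_structured(b, approximator = fx_approximator())
  expect_equal(nrow(cl), 0)
})

test_that("classification is deterministic", {
  b <- fx_noisefree()
  ap <- fx_approximator()
  expect_identical(classify_structured(b, approximator = ap),
                   classify_structured(b, approximator = ap))
})
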