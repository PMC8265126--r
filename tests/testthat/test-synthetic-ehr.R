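test_that("generator config validates its fractions", {
  expect_error(generator_config(d2t_prevalence = 1.2), "fractions")
  expect_error(generator_config(negation_rate = -0.1), "fractions")
  expect_error(generator_config(missingness_rates = list(labs = 2)),
               "fractions")
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
})

test_that("degenerate prevalence plants no D2T patients", {
  b <- generate_cohort(generator_config(n_patients = 30,
                                        d2t_prevalence = 0, seed = 4))
  expect_true(all(b$patients$planted_truth == "nonD2T"))
})

test_that("planted D2T count falls in the central 99% binomial interval", {
  b <- fx_cohort("prev500", generator_config(n_patients = 500,
                                             d2t_prevalence = 0.2,
                                             seed = 17))
  k <- sum(b$patients$planted_truth == "D2T")
  expect_gte(k, qbinom(0.005, 500, 0.2))
  expect_lte(k, qbinom(0.995, 500, 0.2))
})

test_that("identical config and seed give identical cohorts", {
  cfg <- generator_config(n_patients = 25, seed = 99)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1[setdiff(names(b1), "config")],
                   b2[setdiff(names(b2), "config")])
})

test_that("planted D2T patients carry >= 2 distinct MoA classes", {
  b <- fx_default()
  tax <- default_moa_taxonomy()
  for (pid in b$patients$patient_id[b$patients$planted_truth == "D2T"]) {
    rx <- b$prescriptions[b$prescriptions$patient_id == pid, , drop = FALSE]
    expect_gte(nrow(moa_start_sequence(rx, tax)), 2)
  }
})

test_that("letters' DMARD history reflects the structured prescriptions", {
  b <- fx_default()
  tax <- default_moa_taxonomy()
  lex <- default_lexicon()
  for (pid in sample(b$patients$patient_id, 20)) {
    lt <- Filter(function(l) l$patient_id == pid, b$letters)
    if (length(lt) == 0) next
    last <- lt[[length(lt)]]
    mined <- extract_medications(last$sections, lex)
    rx <- b$prescriptions[b$prescriptions$patient_id == pid &
                            b$prescriptions$start_date <= last$date, ,
                          drop = FALSE]
    truth_bts <- unique(rx$drug_name[
      map_atc_to_moa(rx$atc_code, tax) %in% bts_classes()])
    mined_bts <- mined$drug_name[mined$moa_class %in% bts_classes()]
    expect_setequal(mined_bts, truth_bts)
  }
})

test_that("realized standardized group shifts track the configured effects", {
  eff <- c(NEUT_BAND = 0.8, WBC = 0.5, CREAT = 0.4, RETIC_PCT = 0)
  b <- fx_cohort("eff1000",
                 generator_config(n_patients = 1000, d2t_prevalence = 0.3,
                                  effect_sizes = eff, seed = 23))
  truth <- b$patients$planted_truth == "D2T"
  labs <- b$labs
  for (code in names(eff)) {
    v <- labs[labs$test_code == code, , drop = FALSE]
    pm <- tapply(v$value, v$patient_id, mean)
    pm <- pm[b$patients$patient_id]
    d <- (mean(pm[truth]) - mean(pm[!truth])) /
      sqrt((stats::var(pm[truth]) + stats::var(pm[!truth])) / 2)
    expect_lt(abs(d - eff[[code]]), 0.2)
  }
})

test_that("render_letters honours the negation rate at both extremes", {
  rec <- list(
    patient_id = "PX",
    bts = data.frame(drug_name = c("adalimumab", "tocilizumab"),
                     moa_class = c("TNFi", "IL6i"),
                     start_date = as.Date(c("2014-01-01", "2015-01-01"))),
    cs = data.frame(drug_name = "methotrexate",
                    start_date = as.Date("2012-01-01")),
    episodes = data.frame(start = as.Date(c("2011-12-31", "2015-01-01")),
                          mean = c(4.5, 4.8)),
    letter_dates = as.Date(c("2014-06-01", "2015-06-01", "2016-06-01"))
  )
  lt0 <- render_letters(rec, negation_rate = 0, seed = 5)
  det0 <- vapply(lt0, function(l)
    detect_active_disease(l$sections)$active, logical(1))
  expect_true(all(det0))
  expect_true(all(vapply(lt0, `[[`, logical(1), "active_truth")))

  lt1 <- render_letters(rec, negation_rate = 1, seed = 5)
  for (l in lt1) {
    d <- detect_active_disease(l$sections)
    expect_false(d$active)
    expect_true(all(d$matches$negated))
    expect_false(l$active_truth)
  }
  # both drugs listed under DMARD history once both have started
  meds <- extract_medications(lt0[[3]]$sections)
  expect_true(all(c("adalimumab", "tocilizumab") %in% meds$drug_name))
})

test_that("missingness injection deletes at the stated rate and nothing else", {
  b <- fx_default()
  b0 <- inject_missingness(b, list(labs = 0), seed = 1)
  expect_identical(b0$labs, b$labs)

  b1 <- inject_missingness(b, list(clinical_measurements = 1), seed = 1)
  expect_equal(nrow(b1$clinical_measurements), 0)
  expect_identical(b1$patients$planted_truth, b$patients$planted_truth)

  b3 <- inject_missingness(b, list(labs = 0.3), seed = 2)
  n <- nrow(b$labs)
  deleted <- n - nrow(b3$labs)
  expect_gte(deleted, qbinom(0.005, n, 0.3))
  expect_lte(deleted, qbinom(0.995, n, 0.3))

  expect_error(inject_missingness(b, list(labs = 1.5)), "rates")
})
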