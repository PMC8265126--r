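# Shared synthetic cohorts, built lazily once per test run.
.fx_cache <- new.env(parent = emptyenv())

fx_cohort <- function(key, config) {
  if (is.null(.fx_cache[[key]]))
    assign(key, generate_cohort(config), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# noise-free cohort: ~3300 visits with complete DAS28 components
fx_noisefree <- function() {
  fx_cohort("noisefree", generator_config(n_patients = 60, noise_sd = 0,
                                          seed = 101))
}

# default study conditions with heavy negation in the letters
fx_default <- function() {
  fx_cohort("default", generator_config(n_patients = 150, noise_sd = 0.3,
                                        negation_rate = 0.5, seed = 11,
                                        clinical_label_fraction = 0.4))
}

fx_approximator <- function() {
  if (is.null(.fx_cache$approx))
    assign("approx", train_das28_approximator(fx_noisefree(), seed = 3),
           envir = .fx_cache)
  get("approx", envir = .fx_cache)
}

# feature table with 10 informative (standardized shift `effect`) and 40
# pure-noise features, mimicking a 52/100 clinically classified cohort
planted_feature_table <- function(n = 152, n_pos = 52, effect = 1,
                                  p_inf = 10, p_noise = 40, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("D2T", "nonD2T"), c(n_pos, n - n_pos))
    tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)), label = y,
                      stringsAsFactors = FALSE)
    for (j in seq_len(p_inf))
      tab[[paste0("inf", j)]] <- stats::rnorm(n) + (y == "D2T") * effect
    for (j in seq_len(p_noise))
      tab[[paste0("noise", j)]] <- stats::rnorm(n)
    standardize_features(tab)
  })
}
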