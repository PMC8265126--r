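#' Hematology and chemistry panel generated for synthetic cohorts
#'
#' Complete blood count with differential, reticulocyte fraction, platelet
#' scatter proxies and a small chemistry set, each with a population
#' baseline, a between-patient standard deviation and a within-patient
#' (visit-to-visit) standard deviation. ESR and CRP are generated
#' separately because they track disease activity.
#'
#' @return data.frame with columns `test_code`, `name`, `unit`, `baseline`,
#'   `sd_between`, `sd_within`.
#' @export
hematology_panel <- function() {
  x <- rbind(
    c("HGB",       "hemoglobin",               "mmol/L",  "8.6",  "0.8",  "0.30"),
    c("HCT",       "hematocrit",               "L/L",     "0.42", "0.03", "0.010"),
    c("RBC",       "red blood cells",          "10^12/L", "4.8",  "0.40", "0.15"),
    c("WBC",       "white blood cells",        "10^9/L",  "7.5",  "1.8",  "0.80"),
    c("PLT",       "platelets",                "10^9/L",  "280",  "55",   "25"),
    c("MCV",       "mean corpuscular volume",  "fL",      "90",   "4.0",  "1.5"),
    c("MCH",       "mean corpuscular Hb",      "fmol",    "1.9",  "0.10", "0.04"),
    c("RDW",       "red cell distr. width",    "%",       "13.5", "1.0",  "0.40"),
    c("NEUT",      "neutrophils",              "10^9/L",  "4.5",  "1.3",  "0.60"),
    c("LYMPH",     "lymphocytes",              "10^9/L",  "2.0",  "0.50", "0.25"),
    c("MONO",      "monocytes",                "10^9/L",  "0.55", "0.15", "0.07"),
    c("EOS",       "eosinophils",              "10^9/L",  "0.20", "0.10", "0.05"),
    c("BASO",      "basophils",                "10^9/L",  "0.05", "0.02", "0.010"),
    c("NEUT_BAND", "banded neutrophils",       "10^9/L",  "0.08", "0.05", "0.020"),
    c("IG_PCT",    "immature granulocytes",    "%",       "0.40", "0.20", "0.10"),
    c("RETIC_PCT", "reticulocytes",            "%",       "1.2",  "0.30", "0.12"),
    c("NRBC",      "nucleated red cells",      "10^9/L",  "0.01", "0.01", "0.005"),
    c("PLT_IAS",   "platelet intermediate angle scatter", "a.u.", "48", "6.0", "2.5"),
    c("PLT_PSS",   "platelet polarized side scatter",     "a.u.", "32", "5.0", "2.0"),
    c("CREAT",     "creatinine",               "umol/L",  "78",   "12",   "4.0"),
    c("K",         "potassium",                "mmol/L",  "4.1",  "0.30", "0.12")
  )
  data.frame(test_code = x[, 1], name = x[, 2], unit = x[, 3],
             baseline = as.numeric(x[, 4]), sd_between = as.numeric(x[, 5]),
             sd_within = as.numeric(x[, 6]), stringsAsFactors = FALSE)
}

#' Default planted effect sizes
#'
#' Standardized mean shifts (difficult-to-treat minus non-difficult-to-treat,
#' in units of the between-patient standard deviation) planted on
#' patient-level means of selected signals. The defaults concentrate the
#' signal in hematology and blood pressure, mirroring where routine-care
#' data tends to separate the groups.
#'
#' @return Named numeric vector, names are lab test codes or `systolic_bp`.
#' @export
default_effect_sizes <- function() {
  c(NEUT_BAND = 0.8, IG_PCT = 0.8, RETIC_PCT = 0.6, PLT_IAS = 0.6,
    WBC = 0.5, NEUT = 0.5, CREAT = 0.4, systolic_bp = 0.4)
}

#' Configuration for the synthetic routine-care generator
#'
#' @param n_patients Number of patients (>= 1).
#' @param d2t_prevalence Fraction of patients with planted
#'   difficult-to-treat ground truth, in \[0, 1\].
#' @param missingness_rates Named list of per-table MCAR row-deletion
#'   fractions (`labs`, `clinical_measurements`, `prescriptions`, `visits`,
#'   `letters`), each in \[0, 1\].
#' @param negation_rate Fraction of active-disease phrases rendered in
#'   negated form in clinical letters, in \[0, 1\].
#' @param effect_sizes Named numeric vector of standardized mean shifts
#'   between the two groups; see [default_effect_sizes()].
#' @param noise_sd Visit-level measurement noise of the DAS28 trajectory in
#'   score units; laboratory within-patient noise scales proportionally, and
#'   `noise_sd = 0` switches all measurement noise off.
#' @param seed Integer seed; identical config + seed gives an identical
#'   cohort.
#' @param clinical_label_fraction Fraction of patients given a tri-state
#'   clinical validation label (the rest are `unlabeled`).
#' @return An object of class `d2t_generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             d2t_prevalence = 0.2,
                             missingness_rates = list(),
                             negation_rate = 0.2,
                             effect_sizes = default_effect_sizes(),
                             noise_sd = 0.3,
                             seed = 1,
                             clinical_label_fraction = 0.3) {
  rates <- utils::modifyList(
    list(labs = 0, clinical_measurements = 0, prescriptions = 0,
         visits = 0, letters = 0),
    as.list(missingness_rates)
  )
  fr <- c(d2t_prevalence = d2t_prevalence, negation_rate = negation_rate,
          clinical_label_fraction = clinical_label_fraction,
          unlist(rates))
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0")
  structure(list(
    n_patients = as.integer(n_patients), d2t_prevalence = d2t_prevalence,
    missingness_rates = rates, negation_rate = negation_rate,
    effect_sizes = effect_sizes, noise_sd = noise_sd,
    seed = as.integer(seed),
    clinical_label_fraction = clinical_label_fraction
  ), class = "d2t_generator_config")
}

# piecewise-constant episode mean applying at each date
activity_at <- function(dates, episodes) {
  episodes$mean[findInterval(as.numeric(dates), as.numeric(episodes$start))]
}

# DAS28 components: joint counts and VAS follow a monotone activity
# fraction of the (noisy) visit-level activity d_visit, while ESR is solved
# from the DAS28-ESR formula at the episode-level activity d_esr — ESR is a
# laboratory signal of the underlying disease state, whereas joint counts
# and VAS carry the visit-level examination noise. With noise_sd = 0 the
# two coincide and the recorded components reproduce d exactly (up to rare
# ESR clamping).
das28_joint_vas <- function(d) {
  frac <- clamp((d - 0.5) / 6, 0, 1)
  data.frame(tjc28 = round(20 * frac), sjc28 = round(14 * frac),
             vas_gh = round(5 + 80 * frac))
}

das28_components <- function(d_visit, d_esr = d_visit) {
  out <- das28_joint_vas(d_visit)
  jv <- das28_joint_vas(d_esr)
  esr <- exp((d_esr - 0.56 * sqrt(jv$tjc28) - 0.28 * sqrt(jv$sjc28) -
                0.014 * jv$vas_gh) / 0.70)
  out$esr <- clamp(esr, 1, 140)
  out
}

DATA_END <- as.Date("2020-12-31")

#' Generate a synthetic routine-care cohort with planted ground truth
#'
#' Emulates the statistical structure the downstream analyses assume:
#' treatment-cycling b/tsDMARD histories, piecewise-constant DAS28
#' trajectories with Gaussian visit noise, group-shifted hematology, and
#' templated clinical letters rendered consistently with the structured
#' record. Planted difficult-to-treat patients start at least two b/tsDMARD
#' mechanism-of-action classes and keep a window-mean DAS28-ESR of at least
#' 3.2 in months 3-12 after the second-MoA start; planted non-D2T patients
#' either start at most one class or respond (window mean below 3.2).
#'
#' @param config A [generator_config()].
#' @return A `cohort_bundle`: list of tables `patients`, `prescriptions`,
#'   `labs`, `clinical_measurements`, `visits`, a list `letters`, and the
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "d2t_generator_config"))
    stop("config must be a d2t_generator_config")
  bundle <- with_seed(config$seed, generate_cohort_impl(config))
  if (any(unlist(config$missingness_rates) > 0))
    bundle <- inject_missingness(bundle, config$missingness_rates,
                                 seed = config$seed + 1L)
  bundle
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  panel <- hematology_panel()
  eff <- config$effect_sizes
  nf <- config$noise_sd / 0.3   # lab-noise multiplier, 0 = noise-free
  tax <- default_moa_taxonomy()
  lex <- default_lexicon()
  cs_pool <- tax[tax$moa_class == "not_btsDMARD", , drop = FALSE]

  ids <- sprintf("P%05d", seq_len(n))
  truth <- stats::runif(n) < config$d2t_prevalence
  sex <- ifelse(stats::runif(n) < 0.7, "F", "M")
  birth_year <- sample(1940:1985, n, replace = TRUE)
  diag_date <- as.Date("2005-01-01") +
    floor(stats::runif(n, 0, 3650))

  labeled <- stats::runif(n) < config$clinical_label_fraction
  clinical_label <- ifelse(!labeled, "unlabeled",
                           ifelse(truth, "D2T", "nonD2T"))

  pat_l <- vector("list", n); rx_l <- vector("list", n)
  lab_l <- vector("list", n); cm_l <- vector("list", n)
  vis_l <- vector("list", n); letters <- list()
  letter_truth <- character(n)

  for (i in seq_len(n)) {
    d0 <- diag_date[i]
    # --- conventional synthetic DMARDs, all started before any b/tsDMARD
    cs <- cs_pool[cs_pool$drug_name == "methotrexate", , drop = FALSE]
    cs_start <- d0
    extra <- cs_pool[cs_pool$drug_name %in%
                       c("sulfasalazine", "hydroxychloroquine",
                         "prednisolone", "naproxen"), , drop = FALSE]
    take <- stats::runif(4) < c(0.25, 0.30, 0.30, 0.35)
    if (any(take)) {
      cs <- rbind(cs, extra[take, , drop = FALSE])
      cs_start <- c(cs_start, d0 + floor(stats::runif(sum(take), 30, 330)))
    }

    # --- b/tsDMARD MoA class sequence
    if (truth[i]) {
      n_moa <- sample(2:4, 1, prob = c(0.5, 0.3, 0.2))
    } else {
      n_moa <- sample(0:2, 1, prob = c(0.45, 0.40, 0.15))
    }
    classes <- character(0); bts_starts <- as.Date(character(0))
    bts_drugs <- character(0); bts_atc <- character(0)
    if (n_moa > 0) {
      avail <- setdiff(bts_classes(), "other_btsDMARD")
      first <- if (stats::runif(1) < 0.8) "TNFi" else sample(avail, 1)
      classes <- c(first, sample(setdiff(avail, first), n_moa - 1))
      caps <- as.Date(c("2017-06-30", "2019-09-01", "2020-03-01",
                        "2020-06-01"))
      s <- min(d0 + floor(stats::runif(1, 365, 1000)), caps[1])
      bts_starts <- s
      for (k in seq_len(n_moa - 1)) {
        s <- min(s + floor(stats::runif(1, 200, 540)), caps[k + 1])
        if (s <= bts_starts[k]) s <- bts_starts[k] + 60
        bts_starts <- c(bts_starts, s)
      }
      for (k in seq_len(n_moa)) {
        pool <- tax[tax$moa_class == classes[k], , drop = FALSE]
        j <- sample(nrow(pool), 1)
        bts_drugs <- c(bts_drugs, pool$drug_name[j])
        bts_atc <- c(bts_atc, pool$atc_code[j])
      }
    }

    # --- prescriptions (start dates only; refills repeat the same drug)
    rx <- data.frame(
      patient_id = ids[i],
      atc_code = c(cs$atc_code, bts_atc),
      drug_name = c(cs$drug_name, bts_drugs),
      start_date = c(cs_start, bts_starts),
      stringsAsFactors = FALSE
    )
    if (length(bts_atc) > 0) {
      n_refill <- sample(0:2, length(bts_atc), replace = TRUE)
      for (k in seq_along(bts_atc)) {
        if (n_refill[k] > 0) {
          rx <- rbind(rx, data.frame(
            patient_id = ids[i], atc_code = bts_atc[k],
            drug_name = bts_drugs[k],
            start_date = bts_starts[k] + 90 * seq_len(n_refill[k]),
            stringsAsFactors = FALSE))
        }
      }
    }

    # --- disease-activity episodes (piecewise-constant DAS28 means)
    ev <- data.frame(start = c(cs_start, bts_starts),
                     kind = c(rep("cs", length(cs_start)),
                              rep("bts", length(bts_starts))),
                     stringsAsFactors = FALSE)
    ev <- ev[order(ev$start), , drop = FALSE]
    cur <- stats::runif(1, 3.8, 5.8)
    ep_start <- d0 - 1; ep_mean <- cur
    k_bts <- 0
    for (e in seq_len(nrow(ev))) {
      if (ev$kind[e] == "cs") {
        cur <- max(1.2, cur - stats::runif(1, 0.3, 1.2))
      } else {
        k_bts <- k_bts + 1
        cur <- if (!truth[i]) {
          stats::runif(1, 1.6, 2.6)          # responder
        } else if (k_bts == 1) {
          stats::runif(1, 3.0, 4.5)          # partial / no response
        } else {
          stats::runif(1, 3.6, 5.2)          # sustained activity
        }
      }
      ep_start <- c(ep_start, ev$start[e]); ep_mean <- c(ep_mean, cur)
    }
    episodes <- data.frame(start = ep_start, mean = ep_mean)

    # --- outpatient visit schedule (shorter intervals while active)
    vdates <- as.Date(character(0))
    t <- d0 + floor(stats::runif(1, 10, 40))
    while (t <= DATA_END) {
      vdates <- c(vdates, t)
      gap <- if (activity_at(t, episodes) >= DAS28_ACTIVE_THRESHOLD)
        stats::runif(1, 45, 80) else stats::runif(1, 70, 110)
      t <- t + floor(gap)
    }
    nv <- length(vdates)
    d_mean <- activity_at(vdates, episodes)
    d_visit <- clamp(d_mean + stats::rnorm(nv, 0, config$noise_sd), 0.4, 9)
    comp <- das28_components(d_visit, d_esr = d_mean)

    n_ward <- stats::rpois(1, if (truth[i]) 1.5 else 0.3)
    ward <- if (n_ward > 0)
      d0 + floor(stats::runif(n_ward, 30, as.numeric(DATA_END - d0)))
    else as.Date(character(0))

    vis_l[[i]] <- data.frame(
      patient_id = ids[i], date = c(vdates, ward),
      visit_type = c(rep("outpatient", nv), rep("ward", n_ward)),
      stringsAsFactors = FALSE
    )

    # --- clinical measurements
    height <- if (sex[i] == "F") stats::rnorm(1, 167, 6) else
      stats::rnorm(1, 180, 7)
    weight0 <- stats::rnorm(1, 75, 12)
    e_bp <- unname(eff["systolic_bp"]); if (is.na(e_bp)) e_bp <- 0
    bp0 <- 128 + 12 * (stats::rnorm(1) + e_bp * truth[i])
    cm_l[[i]] <- data.frame(
      patient_id = ids[i], date = vdates,
      sjc28 = comp$sjc28, tjc28 = comp$tjc28, vas_gh = comp$vas_gh,
      systolic_bp = round(bp0 + stats::rnorm(nv, 0, 6 * nf), 0),
      height = round(height, 1),
      weight = round(weight0 + stats::rnorm(nv, 0, 1.5 * nf), 1),
      stringsAsFactors = FALSE
    )

    # --- laboratory values: activity-linked ESR/CRP plus shifted panel
    crp <- pmax(0.2, 1 + 9 * pmax(d_mean - 1, 0) +
                  stats::rnorm(nv, 0, 2 * nf))
    lab_i <- list(
      data.frame(patient_id = ids[i], test_code = "ESR", value = comp$esr,
                 unit = "mm/h", date = vdates, stringsAsFactors = FALSE),
      data.frame(patient_id = ids[i], test_code = "CRP", value = crp,
                 unit = "mg/L", date = vdates, stringsAsFactors = FALSE)
    )
    e_code <- eff[panel$test_code]; e_code[is.na(e_code)] <- 0
    pat_mean <- panel$baseline +
      panel$sd_between * (stats::rnorm(nrow(panel)) + e_code * truth[i])
    for (j in seq_len(nrow(panel))) {
      v <- pat_mean[j] + stats::rnorm(nv, 0, panel$sd_within[j] * nf)
      lab_i[[2 + j]] <- data.frame(
        patient_id = ids[i], test_code = panel$test_code[j],
        value = pmax(v, 0), unit = panel$unit[j], date = vdates,
        stringsAsFactors = FALSE)
    }
    lab_l[[i]] <- data.table::rbindlist(lab_i)

    # --- clinical letters at b/tsDMARD starts and every fourth visit
    ldates <- sort(unique(c(bts_starts, vdates[seq_along(vdates) %% 4 == 2])))
    record <- list(
      patient_id = ids[i],
      prescriptions = rx,
      bts = data.frame(drug_name = bts_drugs, moa_class = classes,
                       start_date = bts_starts, stringsAsFactors = FALSE),
      cs = data.frame(drug_name = cs$drug_name, start_date = cs_start,
                      stringsAsFactors = FALSE),
      episodes = episodes,
      letter_dates = ldates
    )
    lt <- render_letters(record, config$negation_rate, lex)
    letters <- c(letters, lt)
    any_active <- any(vapply(lt, function(x) isTRUE(x$active_truth),
                             logical(1)))
    letter_truth[i] <- if (length(classes) >= 2 && any_active) "D2T" else
      "nonD2T"

    rx_l[[i]] <- rx
    pat_l[[i]] <- data.frame(
      patient_id = ids[i], sex = sex[i], birth_year = birth_year[i],
      ra_diagnosis_date = d0, clinical_label = clinical_label[i],
      planted_truth = if (truth[i]) "D2T" else "nonD2T",
      letter_truth = letter_truth[i], stringsAsFactors = FALSE
    )
  }

  bundle <- structure(list(
    patients = as.data.frame(data.table::rbindlist(pat_l)),
    prescriptions = as.data.frame(data.table::rbindlist(rx_l)),
    labs = as.data.frame(data.table::rbindlist(lab_l)),
    clinical_measurements = as.data.frame(data.table::rbindlist(cm_l)),
    visits = as.data.frame(data.table::rbindlist(vis_l)),
    letters = letters,
    config = config
  ), class = "cohort_bundle")
  sort_bundle(bundle)
}

#' @method print cohort_bundle
#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic routine-care cohort: ", nrow(x$patients), " patients, ",
      nrow(x$prescriptions), " prescriptions, ", nrow(x$labs), " lab rows, ",
      length(x$letters), " letters\n", sep = "")
  invisible(x)
}

# deterministic row order for diffable output
sort_bundle <- function(bundle) {
  ord <- function(df, cols) df[do.call(order, df[cols]), , drop = FALSE]
  bundle$patients <- ord(bundle$patients, "patient_id")
  bundle$prescriptions <- ord(bundle$prescriptions,
                              c("patient_id", "start_date", "atc_code"))
  bundle$labs <- ord(bundle$labs, c("patient_id", "date", "test_code"))
  bundle$clinical_measurements <-
    ord(bundle$clinical_measurements, c("patient_id", "date"))
  bundle$visits <- ord(bundle$visits,
                       c("patient_id", "date", "visit_type"))
  for (nm in names(bundle))
    if (is.data.frame(bundle[[nm]])) rownames(bundle[[nm]]) <- NULL
  key <- vapply(bundle$letters,
                function(l) paste(l$patient_id, l$date), character(1))
  bundle$letters <- bundle$letters[order(key)]
  bundle
}

#' Render templated clinical letters for one patient
#'
#' Letters carry a "Medication" section (drugs current at the letter date),
#' a "DMARD history" section (all b/tsDMARDs started up to the letter date)
#' and a "Conclusion". When the disease-activity trajectory is active at
#' the letter date, the conclusion contains an active-disease phrase from
#' the lexicon; with probability `negation_rate` the phrase is rendered in
#' negated form ("No flare ...") and the letter-level truth records the
#' disease as inactive.
#'
#' @param record Per-patient structured record: a list with `patient_id`,
#'   `bts` (data.frame `drug_name`, `moa_class`, `start_date`), `cs`
#'   (data.frame `drug_name`, `start_date`), `episodes` (data.frame `start`,
#'   `mean`) and `letter_dates` (Date vector).
#' @param negation_rate Probability that an active phrase is negated.
#' @param lexicon Lexicon shared with the letter miner.
#' @param seed Optional seed for standalone use.
#' @return List of clinical letters: each a list with `patient_id`, `date`,
#'   `sections` (named list) and `active_truth` (logical).
#' @export
render_letters <- function(record, negation_rate,
                           lexicon = default_lexicon(), seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, render_letters(record, negation_rate, lexicon)))
  lapply(record$letter_dates, function(dt) {
    cur_cs <- record$cs[record$cs$start_date <= dt, , drop = FALSE]
    hist_bts <- record$bts[record$bts$start_date <= dt, , drop = FALSE]
    cur_bts <- if (nrow(hist_bts) > 0)
      hist_bts[nrow(hist_bts), , drop = FALSE] else hist_bts
    med_lines <- c(
      if (nrow(cur_cs) > 0) paste0("- ", cur_cs$drug_name),
      if (nrow(cur_bts) > 0) paste0("- ", cur_bts$drug_name)
    )
    med <- if (length(med_lines) > 0) paste(med_lines, collapse = "\n")
      else "None."
    hist <- if (nrow(hist_bts) > 0)
      paste(sprintf("%s (since %s)", hist_bts$drug_name,
                    format(hist_bts$start_date, "%Y")), collapse = "\n")
      else "None."

    active <- activity_at(dt, record$episodes) >= DAS28_ACTIVE_THRESHOLD
    phrase <- sample(lexicon$activity_terms, 1)
    cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
    if (active && stats::runif(1) >= negation_rate) {
      body <- if (stats::runif(1) < 0.5)
        paste0(cap(phrase), " of rheumatoid arthritis.")
      else
        paste0("Patient presents with a ", phrase, ".")
      if (stats::runif(1) < 0.3)
        body <- paste("No signs of infection.", body)
      truth <- TRUE
    } else if (active) {
      body <- paste0("No ", phrase, " at present.")
      truth <- FALSE
    } else {
      body <- if (stats::runif(1) < 0.5)
        "Disease is stable under current therapy."
      else paste0("No ", phrase, ".")
      truth <- FALSE
    }
    list(patient_id = record$patient_id, date = dt,
         sections = list("Medication" = med, "DMARD history" = hist,
                         "Conclusion" = body),
         active_truth = truth)
  })
}

#' Delete rows completely at random from a cohort bundle
#'
#' Emulates the missingness of routine-care extracts: rows of the selected
#' tables are deleted independently at the stated rate (missing completely
#' at random). The patients table and the planted ground truth are never
#' touched.
#'
#' @param bundle A cohort bundle.
#' @param rates Named list of per-table deletion fractions in \[0, 1\]
#'   (`labs`, `clinical_measurements`, `prescriptions`, `visits`,
#'   `letters`).
#' @param seed Integer seed.
#' @return The thinned bundle.
#' @export
inject_missingness <- function(bundle, rates, seed = 1) {
  rates <- as.list(rates)
  bad <- unlist(rates)[unlist(rates) < 0 | unlist(rates) > 1]
  if (length(bad) > 0) stop("missingness rates must lie in [0, 1]")
  with_seed(seed, {
    for (nm in intersect(names(rates),
                         c("labs", "clinical_measurements",
                           "prescriptions", "visits"))) {
      r <- rates[[nm]]
      if (r > 0) {
        keep <- stats::runif(nrow(bundle[[nm]])) >= r
        bundle[[nm]] <- bundle[[nm]][keep, , drop = FALSE]
        rownames(bundle[[nm]]) <- NULL
      }
    }
    if (!is.null(rates$letters) && rates$letters > 0) {
      keep <- stats::runif(length(bundle$letters)) >= rates$letters
      bundle$letters <- bundle$letters[keep]
    }
    bundle
  })
}
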