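#' Ordered sequence of first starts per b/tsDMARD MoA class
#'
#' Collapses repeat prescriptions within one mechanism-of-action class to
#' the earliest start date and orders the distinct classes by that date.
#' Classes starting on the same day are ordered by the fixed taxonomy
#' enumeration ([bts_classes()]) and flagged as ties.
#'
#' @param prescriptions Prescription table for one patient (`atc_code`,
#'   `start_date`).
#' @param taxonomy ATC-to-MoA taxonomy.
#' @return data.frame `moa_class`, `start_date`, `tie` (logical), ordered
#'   by first start date.
#' @export
moa_start_sequence <- function(prescriptions,
                               taxonomy = default_moa_taxonomy()) {
  if (nrow(prescriptions) == 0)
    return(data.frame(moa_class = character(),
                      start_date = as.Date(character()), tie = logical(),
                      stringsAsFactors = FALSE))
  moa <- map_atc_to_moa(prescriptions$atc_code, taxonomy)
  keep <- moa %in% bts_classes()
  if (!any(keep))
    return(data.frame(moa_class = character(),
                      start_date = as.Date(character()), tie = logical(),
                      stringsAsFactors = FALSE))
  d <- data.frame(moa_class = moa[keep],
                  start_date = prescriptions$start_date[keep],
                  stringsAsFactors = FALSE)
  first <- stats::aggregate(start_date ~ moa_class, data = d, FUN = min)
  first$rank <- match(first$moa_class, bts_classes())
  first <- first[order(first$start_date, first$rank), , drop = FALSE]
  first$tie <- duplicated(first$start_date) |
    duplicated(first$start_date, fromLast = TRUE)
  rownames(first) <- NULL
  first[, c("moa_class", "start_date", "tie")]
}

#' D2T criterion 1: at least two b/tsDMARD MoA classes started
#'
#' Counts distinct mechanism-of-action classes, not distinct drugs: two
#' TNF inhibitors count once.
#'
#' @param sequence Output of [moa_start_sequence()].
#' @return Logical.
#' @export
criterion1 <- function(sequence) nrow(sequence) >= 2

#' D2T criterion 2: failure of the second-MoA b/tsDMARD
#'
#' Met when either (a) the mean DAS28-ESR in months 3-12 after starting the
#' b/tsDMARD of a second MoA is defined and at least 3.2, or (b) a third
#' distinct MoA class was started (which itself implies failure of the
#' second, with no disease-activity data needed). Returns which branch
#' fired in the evidence.
#'
#' @param sequence Output of [moa_start_sequence()].
#' @param das28_records DAS28 record data.frame (`date`, `value`) for the
#'   patient, typically approximated scores at visit dates.
#' @return List: `met` (logical), `sufficient` (logical — FALSE when
#'   criterion 1 holds but no window data and no third MoA), `evidence`
#'   (list of rule firings).
#' @export
criterion2 <- function(sequence, das28_records) {
  if (!criterion1(sequence))
    return(list(met = FALSE, sufficient = TRUE, evidence = list()))
  ev <- list()
  if (nrow(sequence) >= 3) {
    ev[[1]] <- list(rule = "third_moa_started",
                    date = as.character(sequence$start_date[3]),
                    detail = sequence$moa_class[3])
    return(list(met = TRUE, sufficient = TRUE, evidence = ev))
  }
  anchor <- sequence$start_date[2]
  w <- mean_das28_in_window(das28_records, anchor)
  if (w$n == 0)
    return(list(met = FALSE, sufficient = FALSE, evidence = list(
      list(rule = "window_undefined", date = as.character(anchor),
           detail = "no DAS28 records 3-12 months after second MoA"))))
  met <- w$mean >= DAS28_ACTIVE_THRESHOLD
  ev[[1]] <- list(rule = "window_mean_das28", date = as.character(anchor),
                  detail = sprintf("mean=%.2f over n=%d", w$mean, w$n))
  list(met = met, sufficient = TRUE, evidence = ev)
}

#' Classify a cohort as D2T / non-D2T from structured data
#'
#' Applies the first two criteria of the EULAR difficult-to-treat
#' definition to prescription sequences and (approximated) DAS28-ESR
#' trajectories. The classification is conservative: patients meeting
#' criterion 1 whose months-3-to-12 window after the second-MoA start
#' contains no disease-activity data, and who never started a third MoA,
#' are labelled non-D2T with `data_sufficiency = "insufficient"`.
#'
#' By default the window mean uses the surrogate model's approximation at
#' every outpatient visit date in the window (`das28_source =
#' "approximated"`); `"mixed"` substitutes the measured DAS28-ESR where the
#' components were recorded.
#'
#' @param bundle A cohort bundle.
#' @param taxonomy ATC-to-MoA taxonomy.
#' @param approximator A fitted [train_das28_approximator()]; may be `NULL`
#'   with `das28_source = "measured_only"`.
#' @param das28_source `"approximated"`, `"mixed"`, or `"measured_only"`.
#' @return data.frame with one row per patient: `patient_id`,
#'   `criterion1_met`, `criterion2_met`, `label`, `data_sufficiency`,
#'   `evidence` (JSON string).
#' @export
classify_structured <- function(bundle, taxonomy = default_moa_taxonomy(),
                                approximator = NULL,
                                das28_source = c("approximated", "mixed",
                                                 "measured_only")) {
  das28_source <- match.arg(das28_source)
  ids <- bundle$patients$patient_id
  if (length(ids) == 0)
    return(data.frame(patient_id = character(), criterion1_met = logical(),
                      criterion2_met = logical(), label = character(),
                      data_sufficiency = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  rx_by <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  seqs <- lapply(ids, function(pid) {
    rx <- rx_by[[pid]]
    if (is.null(rx)) rx <- bundle$prescriptions[0, , drop = FALSE]
    moa_start_sequence(rx, taxonomy)
  })
  names(seqs) <- ids

  # disease-activity records only matter for two-MoA patients' windows
  need <- ids[vapply(seqs, function(s) nrow(s) == 2, logical(1))]
  recs <- list()
  if (length(need) > 0) {
    vis <- bundle$visits
    vis <- vis[vis$visit_type == "outpatient" & vis$patient_id %in% need, ,
               drop = FALSE]
    win <- do.call(rbind, lapply(need, function(pid) {
      anchor <- seqs[[pid]]$start_date[2]
      v <- vis[vis$patient_id == pid, , drop = FALSE]
      v <- v[v$date >= anchor + 3 * MONTH_DAYS &
               v$date <= anchor + 12 * MONTH_DAYS, , drop = FALSE]
      v
    }))
    if (!is.null(win) && nrow(win) > 0) {
      win <- unique(win[, c("patient_id", "date")])
      vals <- switch(das28_source,
        approximated = {
          if (is.null(approximator))
            stop("das28_source = 'approximated' needs an approximator")
          predict_das28(approximator, bundle, win$patient_id, win$date)
        },
        mixed = {
          meas <- measured_das28(bundle)
          key <- paste(win$patient_id, win$date)
          mkey <- paste(meas$patient_id, meas$date)
          v <- meas$value[match(key, mkey)]
          if (any(is.na(v))) {
            if (is.null(approximator))
              stop("das28_source = 'mixed' needs an approximator")
            v[is.na(v)] <- predict_das28(approximator, bundle,
                                         win$patient_id[is.na(v)],
                                         win$date[is.na(v)])
          }
          v
        },
        measured_only = {
          meas <- measured_das28(bundle)
          key <- paste(win$patient_id, win$date)
          mkey <- paste(meas$patient_id, meas$date)
          meas$value[match(key, mkey)]
        })
      win$value <- vals
      win <- win[!is.na(win$value), , drop = FALSE]
      recs <- split(win, win$patient_id)
    }
  }

  empty_rec <- data.frame(date = as.Date(character()), value = numeric())
  out <- lapply(ids, function(pid) {
    s <- seqs[[pid]]
    c1 <- criterion1(s)
    r <- recs[[pid]] %||% empty_rec
    c2 <- criterion2(s, r)
    suff <- if (c1 && !c2$sufficient) "insufficient" else "sufficient"
    ev <- c2$evidence
    if (c1)
      ev <- c(list(list(rule = "two_moa_classes",
                        date = as.character(s$start_date[2]),
                        detail = paste(s$moa_class[1:2], collapse = ";"))),
              ev)
    data.frame(
      patient_id = pid, criterion1_met = c1, criterion2_met = c2$met,
      label = if (c1 && c2$met) "D2T" else "nonD2T",
      data_sufficiency = suff,
      evidence = as.character(jsonlite::toJSON(ev, auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
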