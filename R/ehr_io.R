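bundle_tables <- function() {
  c("patients", "prescriptions", "labs", "clinical_measurements", "visits")
}

bundle_schemas <- function() {
  list(
    patients = c("patient_id", "sex", "birth_year", "ra_diagnosis_date",
                 "clinical_label", "planted_truth", "letter_truth"),
    prescriptions = c("patient_id", "atc_code", "drug_name", "start_date"),
    labs = c("patient_id", "test_code", "value", "unit", "date"),
    clinical_measurements = c("patient_id", "date", "sjc28", "tjc28",
                              "vas_gh", "systolic_bp", "height", "weight"),
    visits = c("patient_id", "date", "visit_type")
  )
}

#' Write a cohort bundle to a directory
#'
#' One UTF-8 CSV per table with ISO-8601 dates, letters as JSON Lines (one
#' object per letter) and a `manifest.json` recording the generator config,
#' seed and per-table row counts. Rows are written in a deterministic sort
#' order so repeated writes are byte-identical and diffable.
#'
#' @param bundle A cohort bundle.
#' @param path Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  bundle <- sort_bundle(bundle)
  for (nm in bundle_tables()) {
    utils::write.csv(bundle[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  con <- file(file.path(path, "letters.jsonl"), open = "w",
              encoding = "UTF-8")
  for (l in bundle$letters) {
    writeLines(jsonlite::toJSON(list(
      patient_id = l$patient_id, date = as.character(l$date),
      sections = l$sections, active_truth = l$active_truth
    ), auto_unbox = TRUE), con)
  }
  close(con)
  manifest <- list(
    config = if (!is.null(bundle$config)) unclass(bundle$config),
    row_counts = c(lapply(bundle[bundle_tables()], nrow),
                   list(letters = length(bundle$letters)))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort bundle from a directory
#'
#' Parses the CSVs written by [write_bundle()] back into typed tables with
#' `Date` columns, and the letters JSONL back into a letter list. Errors if
#' an expected file is absent; unparseable dates raise a row-indexed error.
#'
#' @param path Directory containing the bundle files.
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(path) {
  date_cols <- list(patients = "ra_diagnosis_date",
                    prescriptions = "start_date", labs = "date",
                    clinical_measurements = "date", visits = "date")
  out <- list()
  for (nm in bundle_tables()) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing bundle file: ", basename(f))
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
    for (dc in date_cols[[nm]]) {
      parsed <- as.Date(df[[dc]], format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & !is.na(df[[dc]]) & nzchar(df[[dc]]))
      if (length(bad) > 0)
        stop("unparseable date in ", nm, ".csv column ", dc, ", row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
      df[[dc]] <- parsed
    }
    out[[nm]] <- df
  }
  lf <- file.path(path, "letters.jsonl")
  if (!file.exists(lf)) stop("missing bundle file: letters.jsonl")
  lines <- readLines(lf, encoding = "UTF-8")
  out$letters <- lapply(lines, function(ln) {
    l <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    l$date <- as.Date(l$date)
    l$active_truth <- isTRUE(l$active_truth)
    l
  })
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    if (!is.null(man$config)) {
      cfg <- man$config
      cfg$effect_sizes <- unlist(cfg$effect_sizes)
      out$config <- structure(cfg, class = "d2t_generator_config")
    }
  }
  structure(out, class = "cohort_bundle")
}

#' Validate a cohort bundle against its schema
#'
#' Reports (never repairs) schema violations: missing columns, child rows
#' whose `patient_id` is absent from the patients table, negative or
#' out-of-range clinical measurements (joint counts 0-28, VAS-GH 0-100),
#' and non-positive lab values for strictly positive analytes.
#'
#' @param bundle A cohort bundle.
#' @param strict If `TRUE`, any violation raises an error instead of being
#'   reported.
#' @return A `schema_report`: list with `missing_columns`, `bad_rows`
#'   (named counts), `warnings` (character).
#' @export
validate_schema <- function(bundle, strict = FALSE) {
  schemas <- bundle_schemas()
  missing_columns <- list(); bad_rows <- integer(0); warn <- character(0)
  ids <- bundle$patients$patient_id
  for (nm in bundle_tables()) {
    df <- bundle[[nm]]
    mc <- setdiff(schemas[[nm]], names(df))
    if (length(mc) > 0) missing_columns[[nm]] <- mc
    n_bad <- 0L
    if (nm != "patients" && "patient_id" %in% names(df)) {
      orphans <- sum(!df$patient_id %in% ids)
      if (orphans > 0) {
        n_bad <- n_bad + orphans
        warn <- c(warn, sprintf("%s: %d row(s) with unknown patient_id",
                                nm, orphans))
      }
    }
    if (nm == "clinical_measurements" && nrow(df) > 0) {
      bad <- (!is.na(df$sjc28) & (df$sjc28 < 0 | df$sjc28 > 28)) |
        (!is.na(df$tjc28) & (df$tjc28 < 0 | df$tjc28 > 28)) |
        (!is.na(df$vas_gh) & (df$vas_gh < 0 | df$vas_gh > 100))
      if (any(bad)) {
        n_bad <- n_bad + sum(bad)
        warn <- c(warn, sprintf(
          "clinical_measurements: %d row(s) out of range", sum(bad)))
      }
    }
    if (nm == "labs" && nrow(df) > 0) {
      bad <- !is.na(df$value) & df$test_code %in% c("ESR") & df$value <= 0
      if (any(bad)) {
        n_bad <- n_bad + sum(bad)
        warn <- c(warn, sprintf("labs: %d non-positive ESR value(s)",
                                sum(bad)))
      }
    }
    bad_rows[nm] <- n_bad
  }
  report <- structure(list(missing_columns = missing_columns,
                           bad_rows = bad_rows, warnings = warn),
                      class = "schema_report")
  if (strict && (length(missing_columns) > 0 || sum(bad_rows) > 0))
    stop("schema validation failed: ", paste(warn, collapse = "; "))
  report
}

#' @method print schema_report
#' @export
print.schema_report <- function(x, ...) {
  cat("Schema report: ", sum(x$bad_rows), " bad row(s)\n", sep = "")
  if (length(x$missing_columns) > 0)
    for (nm in names(x$missing_columns))
      cat("  ", nm, ": missing columns ",
          paste(x$missing_columns[[nm]], collapse = ", "), "\n", sep = "")
  for (w in x$warnings) cat("  ", w, "\n", sep = "")
  invisible(x)
}
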