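#' Default lexicon for mining clinical letters
#'
#' Medication surface forms mapped to drug name and MoA class, synonyms of
#' active disease, negation cues, and the headings screened for each. The
#' activity synonyms and negation cues are stand-ins assembled for this
#' package (no published list exists); they are plain data and can be
#' replaced wholesale.
#'
#' @return A list with `medication_terms` (data.frame `surface`,
#'   `drug_name`, `moa_class`), `activity_terms`, `negation_cues`,
#'   `target_headings`, `activity_headings`, `negation_window`.
#' @export
default_lexicon <- function() {
  tax <- default_moa_taxonomy()
  list(
    medication_terms = data.frame(
      surface = tax$drug_name, drug_name = tax$drug_name,
      moa_class = tax$moa_class, stringsAsFactors = FALSE
    ),
    activity_terms = c("flare", "active arthritis", "exacerbation"),
    negation_cues = c("no", "not", "without", "neither"),
    target_headings = c("medication", "dmard history"),
    activity_headings = c("conclusion", "assessment", "impression"),
    negation_window = 3L
  )
}

norm_heading <- function(h) tolower(trimws(gsub("\\s+", " ", h)))

#' Segment a clinical letter into sections
#'
#' Headings are detected line-anchored: a line ending in a colon, or a line
#' consisting entirely of capitals. Text before the first heading is stored
#' under a synthetic `preamble` heading. Heading comparison downstream is
#' case-insensitive after whitespace normalization.
#'
#' @param raw_text Letter text.
#' @return Named list mapping heading to body text, in document order.
#' @export
segment_sections <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1, nzchar(raw_text))
  lines <- strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  is_heading <- grepl("^\\s*[A-Za-z][A-Za-z0-9 /-]*:\\s*$", lines) |
    (grepl("^[A-Z][A-Z0-9 /-]+$", lines) & nchar(trimws(lines)) >= 3)
  headings <- character(0); bodies <- character(0)
  cur_head <- "preamble"; cur_body <- character(0)
  flush <- function() {
    if (length(cur_body) > 0 || cur_head != "preamble") {
      headings <<- c(headings, cur_head)
      bodies <<- c(bodies, paste(cur_body, collapse = "\n"))
    }
  }
  for (k in seq_along(lines)) {
    if (is_heading[k]) {
      flush()
      cur_head <- sub(":\\s*$", "", trimws(lines[k]))
      cur_body <- character(0)
    } else {
      cur_body <- c(cur_body, lines[k])
    }
  }
  flush()
  if (length(headings) == 0) return(stats::setNames(list(raw_text),
                                                    "preamble"))
  stats::setNames(as.list(bodies), headings)
}

# render a sections map back to raw text (used when letters are stored
# structured rather than as flat text)
sections_to_text <- function(sections) {
  paste(vapply(seq_along(sections), function(k) {
    paste0(names(sections)[k], ":\n", sections[[k]])
  }, character(1)), collapse = "\n")
}

# tokenize into sentences of lowercase punctuation-stripped tokens
tokenize_sentences <- function(text) {
  sentences <- strsplit(text, "[.!?]+")[[1]]
  lapply(sentences, function(s) {
    s <- gsub("[^A-Za-z0-9 ]", " ", tolower(s))
    tok <- strsplit(trimws(gsub("\\s+", " ", s)), " ", fixed = TRUE)[[1]]
    tok[nzchar(tok)]
  })
}

#' Extract medications from the target headings of a letter
#'
#' Lexicon surface forms are matched (case-insensitively, exact token
#' match, no fuzzy matching) only within the target headings — by default
#' "medication" and "DMARD history". Duplicates are collapsed per letter.
#'
#' @param sections Named list as from [segment_sections()].
#' @param lexicon Lexicon; see [default_lexicon()].
#' @return data.frame with columns `drug_name`, `moa_class`.
#' @export
extract_medications <- function(sections, lexicon = default_lexicon()) {
  target <- norm_heading(names(sections)) %in% lexicon$target_headings
  body <- tolower(paste(unlist(sections[target]), collapse = "\n"))
  tokens <- unlist(tokenize_sentences(body))
  hit <- lexicon$medication_terms$surface %in% tokens |
    tolower(lexicon$medication_terms$surface) %in% tokens
  out <- unique(lexicon$medication_terms[hit, c("drug_name", "moa_class")])
  rownames(out) <- NULL
  out
}

#' Detect non-negated mentions of active disease
#'
#' Screens the activity headings (by default conclusion / assessment /
#' impression) for synonyms of active disease such as "flare". A match is
#' considered negated when a negation cue ("no", "not", "without", ...)
#' occurs within the preceding `negation_window` tokens of the same
#' sentence, so "no flare" is excluded while "No signs of infection.
#' Flare of RA." still counts: negation never crosses a sentence boundary.
#'
#' @param sections Named list as from [segment_sections()].
#' @param lexicon Lexicon; see [default_lexicon()].
#' @return A list: `active` (logical) and `matches` (data.frame `phrase`,
#'   `heading`, `negated`).
#' @export
detect_active_disease <- function(sections, lexicon = default_lexicon()) {
  k <- lexicon$negation_window %||% 3L
  act <- norm_heading(names(sections)) %in% lexicon$activity_headings
  matches <- list()
  for (h in which(act)) {
    for (sent in tokenize_sentences(sections[[h]])) {
      for (phrase in lexicon$activity_terms) {
        ptok <- strsplit(tolower(phrase), " ", fixed = TRUE)[[1]]
        np <- length(ptok)
        if (length(sent) < np) next
        for (pos in seq_len(length(sent) - np + 1)) {
          if (all(sent[pos:(pos + np - 1)] == ptok)) {
            pre <- sent[max(1, pos - k):max(1, pos - 1)]
            negated <- pos > 1 && any(pre %in% lexicon$negation_cues)
            matches[[length(matches) + 1]] <- data.frame(
              phrase = phrase, heading = names(sections)[h],
              negated = negated, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  matches <- if (length(matches) > 0)
    do.call(rbind, matches)
  else data.frame(phrase = character(), heading = character(),
                  negated = logical(), stringsAsFactors = FALSE)
  list(active = any(!matches$negated), matches = matches)
}

#' Classify patients as D2T / non-D2T from their clinical letters
#'
#' Criterion 1: the union of medications extracted from all of a patient's
#' letters spans at least two b/tsDMARD mechanism-of-action classes.
#' Criterion 2: at least one letter carries a non-negated active-disease
#' phrase. Patients with no letters are classified non-D2T with
#' insufficient data — the conservative default.
#'
#' @param letters List of clinical letters (each with `patient_id`, `date`,
#'   `sections`), e.g. `bundle$letters`.
#' @param lexicon Lexicon; see [default_lexicon()].
#' @param patient_ids Optional vector of patients to report on (patients
#'   without letters are then included as insufficient/non-D2T).
#' @return data.frame with `patient_id`, `criterion1_met`, `criterion2_met`,
#'   `label`, `data_sufficiency`, `evidence` (JSON string).
#' @export
classify_unstructured <- function(letters, lexicon = default_lexicon(),
                                  patient_ids = NULL) {
  by_pat <- split(letters, vapply(letters, `[[`, character(1), "patient_id"))
  ids <- patient_ids %||% names(by_pat)
  res <- lapply(ids, function(pid) {
    lt <- by_pat[[pid]]
    if (is.null(lt) || length(lt) == 0) {
      return(data.frame(
        patient_id = pid, criterion1_met = FALSE, criterion2_met = FALSE,
        label = "nonD2T", data_sufficiency = "insufficient",
        evidence = "[]", stringsAsFactors = FALSE))
    }
    meds <- unique(do.call(rbind, lapply(lt, function(l)
      extract_medications(l$sections, lexicon))))
    moa <- unique(meds$moa_class[meds$moa_class %in% bts_classes()])
    c1 <- length(moa) >= 2
    ev <- list()
    c2 <- FALSE
    for (l in lt) {
      det <- detect_active_disease(l$sections, lexicon)
      if (det$active) {
        c2 <- TRUE
        ev[[length(ev) + 1]] <- list(
          rule = "active_disease_phrase", date = as.character(l$date),
          detail = paste(det$matches$phrase[!det$matches$negated],
                         collapse = ";"))
      }
    }
    if (c1)
      ev <- c(list(list(rule = "moa_classes_in_letters", date = NA,
                        detail = paste(sort(moa), collapse = ";"))), ev)
    data.frame(
      patient_id = pid, criterion1_met = c1, criterion2_met = c2,
      label = if (c1 && c2) "D2T" else "nonD2T",
      data_sufficiency = "sufficient",
      evidence = as.character(jsonlite::toJSON(ev, auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$patient_id), , drop = FALSE]
}
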