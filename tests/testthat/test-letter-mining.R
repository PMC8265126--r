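test_that("letters segment on line-anchored headings", {
  s <- segment_sections("Medication:\nadalimumab 40mg\nConclusion:\nflare")
  expect_equal(names(s), c("Medication", "Conclusion"))
  expect_match(s$Medication, "adalimumab")
  expect_match(s$Conclusion, "flare")

  s2 <- segment_sections("just some narrative text with no headings")
  expect_equal(names(s2), "preamble")

  # conservation: headings + bodies reconstruct the text modulo whitespace
  txt <- "Intro line\nMedication:\n- methotrexate\nConclusion:\nstable"
  s3 <- segment_sections(txt)
  squash <- function(x) gsub("[\\s:]+", "", x, perl = TRUE)
  expect_equal(squash(paste(c(rbind(names(s3), unlist(s3))),
                            collapse = "")),
               squash(paste("preamble", txt)))
})

test_that("medications are extracted from target headings only", {
  lex <- default_lexicon()
  s <- list("DMARD history" = "etanercept, tocilizumab",
            "Conclusion" = "consider rituximab")
  m <- extract_medications(s, lex)
  expect_setequal(m$drug_name, c("etanercept", "tocilizumab"))
  expect_setequal(m$moa_class, c("TNFi", "IL6i"))
  expect_false("rituximab" %in% m$drug_name)   # wrong section

  # no fuzzy matching: a misspelling is not matched
  s2 <- list("Medication" = "etanrecept 50mg")
  expect_equal(nrow(extract_medications(s2, lex)), 0)

  # duplicates collapse, matching is case-insensitive
  s3 <- list("Medication" = "Adalimumab and adalimumab")
  expect_equal(nrow(extract_medications(s3, lex)), 1)
})

test_that("negation is detected within its window and sentence", {
  lex <- default_lexicon()
  r1 <- detect_active_disease(list(Conclusion = "flare of arthritis"), lex)
  expect_true(r1$active)
  expect_false(any(r1$matches$negated))

  r2 <- detect_active_disease(list(Conclusion = "no flare"), lex)
  expect_false(r2$active)
  expect_true(all(r2$matches$negated))

  # negation does not cross a sentence boundary
  r3 <- detect_active_disease(
    list(Conclusion = "No signs of infection. Flare of RA."), lex)
  expect_true(r3$active)

  # cue outside the 3-token window does not negate
  r4 <- detect_active_disease(
    list(Conclusion = "no evidence was found of ongoing flare"), lex)
  expect_true(r4$active)

  # multi-token phrase, negated
  r5 <- detect_active_disease(
    list(Conclusion = "No active arthritis at present."), lex)
  expect_false(r5$active)

  # activity headings only
  r6 <- detect_active_disease(list(Medication = "flare"), lex)
  expect_false(r6$active)
  expect_equal(nrow(r6$matches), 0)
})

test_that("patients classify from their letters per the two criteria", {
  mk <- function(pid, date, sections)
    list(patient_id = pid, date = as.Date(date), sections = sections)
  lex <- default_lexicon()

  letters <- list(
    mk("A", "2015-01-01",
       list("DMARD history" = "etanercept (since 2013)",
            "Conclusion" = "stable")),
    mk("A", "2016-01-01",
       list("DMARD history" = "etanercept (since 2013)\ntocilizumab (since 2015)",
            "Conclusion" = "flare of arthritis")),
    mk("B", "2016-01-01",
       list("DMARD history" = "etanercept (since 2013)\ntocilizumab (since 2015)",
            "Conclusion" = "no flare")),
    mk("C", "2016-01-01",
       list("Medication" = "- methotrexate", "Conclusion" = "flare"))
  )
  cl <- classify_unstructured(letters, lex,
                              patient_ids = c("A", "B", "C", "D"))
  expect_equal(cl$label[cl$patient_id == "A"], "D2T")
  # both criteria met across different letters
  expect_true(cl$criterion1_met[cl$patient_id == "A"])
  # all activity mentions negated: non-D2T despite two MoA classes
  expect_equal(cl$label[cl$patient_id == "B"], "nonD2T")
  # activity but only one csDMARD: criterion 1 fails
  expect_equal(cl$label[cl$patient_id == "C"], "nonD2T")
  # no letters at all: conservative non-D2T, insufficient
  expect_equal(cl$label[cl$patient_id == "D"], "nonD2T")
  expect_equal(cl$data_sufficiency[cl$patient_id == "D"], "insufficient")
})

test_that("the miner reproduces letter-level planted truth exactly", {
  b <- fx_default()   # negation_rate 0.5
  det <- vapply(b$letters, function(l)
    detect_active_disease(l$sections)$active, logical(1))
  tru <- vapply(b$letters, function(l) isTRUE(l$active_truth), logical(1))
  expect_equal(mean(det == tru), 1)

  cl <- classify_unstructured(b$letters,
                              patient_ids = b$patients$patient_id)
  expect_equal(mean(cl$label == b$patients$letter_truth), 1)
})

test_that("evidence is cumulative: adding letters never revokes D2T", {
  b <- fx_default()
  pats <- sample(b$patients$patient_id, 25)
  for (pid in pats) {
    lt <- Filter(function(l) l$patient_id == pid, b$letters)
    if (length(lt) < 2) next
    k <- length(lt) %/% 2
    partial <- classify_unstructured(lt[seq_len(k)],
                                     patient_ids = pid)$label
    full <- classify_unstructured(lt, patient_ids = pid)$label
    if (partial == "D2T") expect_equal(full, "D2T")
  }
})
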