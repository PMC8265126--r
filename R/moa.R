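#' Mechanism-of-action classes for b/tsDMARDs
#'
#' The EULAR difficult-to-treat definition counts biological/targeted
#' synthetic DMARDs by their mechanism of action (MoA), not by individual
#' drug. These are the MoA classes the rule engine recognises, in the fixed
#' enumeration order used to break same-day start ties.
#'
#' @return Character vector of the seven b/tsDMARD MoA classes.
#' @export
bts_classes <- function() {
  c("TNFi", "IL6i", "CTLA4Ig", "antiCD20", "JAKi", "IL1i", "other_btsDMARD")
}

moa_levels <- function() c(bts_classes(), "not_btsDMARD")

#' Default ATC-to-MoA taxonomy
#'
#' Maps WHO ATC codes of the b/tsDMARDs standard in rheumatoid arthritis
#' care to their mechanism-of-action class, plus the conventional synthetic
#' DMARDs, glucocorticoids and NSAIDs commonly found in RA prescription
#' records (all mapped to `not_btsDMARD`). The table is an ordinary data
#' frame and can be edited or replaced by the user.
#'
#' @return A data.frame with columns `atc_code`, `drug_name`, `moa_class`.
#' @examples
#' tax <- default_moa_taxonomy()
#' map_atc_to_moa("L04AB04", tax)  # adalimumab -> TNFi
#' @export
default_moa_taxonomy <- function() {
  x <- rbind(
    c("L04AB01", "etanercept",         "TNFi"),
    c("L04AB02", "infliximab",         "TNFi"),
    c("L04AB04", "adalimumab",         "TNFi"),
    c("L04AB05", "certolizumab",       "TNFi"),
    c("L04AB06", "golimumab",          "TNFi"),
    c("L04AC07", "tocilizumab",        "IL6i"),
    c("L04AC14", "sarilumab",          "IL6i"),
    c("L04AA24", "abatacept",          "CTLA4Ig"),
    c("L01XC02", "rituximab",          "antiCD20"),
    c("L04AA29", "tofacitinib",        "JAKi"),
    c("L04AA37", "baricitinib",        "JAKi"),
    c("L04AA44", "upadacitinib",       "JAKi"),
    c("L04AA45", "filgotinib",         "JAKi"),
    c("L04AC03", "anakinra",           "IL1i"),
    c("L04AX03", "methotrexate",       "not_btsDMARD"),
    c("A07EC01", "sulfasalazine",      "not_btsDMARD"),
    c("P01BA02", "hydroxychloroquine", "not_btsDMARD"),
    c("L04AA13", "leflunomide",        "not_btsDMARD"),
    c("H02AB06", "prednisolone",       "not_btsDMARD"),
    c("H02AB07", "prednisone",         "not_btsDMARD"),
    c("M01AE01", "ibuprofen",          "not_btsDMARD"),
    c("M01AE02", "naproxen",           "not_btsDMARD"),
    c("N02BE01", "paracetamol",        "not_btsDMARD")
  )
  data.frame(atc_code = x[, 1], drug_name = x[, 2], moa_class = x[, 3],
             stringsAsFactors = FALSE)
}

#' Map ATC codes to mechanism-of-action classes
#'
#' Total function: codes absent from the taxonomy are returned as
#' `not_btsDMARD` rather than an error, so arbitrary prescription tables can
#' be classified without pre-filtering.
#'
#' @param atc_code Character vector of ATC codes.
#' @param taxonomy A taxonomy data.frame as from [default_moa_taxonomy()].
#' @return Character vector of MoA classes, same length as `atc_code`.
#' @export
map_atc_to_moa <- function(atc_code, taxonomy = default_moa_taxonomy()) {
  stopifnot(is.character(atc_code))
  idx <- match(atc_code, taxonomy$atc_code)
  out <- taxonomy$moa_class[idx]
  out[is.na(out)] <- "not_btsDMARD"
  out
}
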