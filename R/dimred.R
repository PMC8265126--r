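#' Extract the sample-by-parameter hematology matrix of a cohort
#'
#' One row per laboratory draw (patient, date), one column per hematology
#' panel parameter.
#'
#' @param bundle A cohort bundle.
#' @return List: `x` (numeric matrix), `patient_id`, `date` (row
#'   annotation).
#' @export
hematology_matrix <- function(bundle) {
  codes <- hematology_panel()$test_code
  labs <- data.table::as.data.table(
    bundle$labs[bundle$labs$test_code %in% codes, , drop = FALSE])
  wide <- data.table::dcast(labs, patient_id + date ~ test_code,
                            value.var = "value",
                            fun.aggregate = function(v) mean(v))
  wide <- as.data.frame(wide)
  x <- as.matrix(wide[, setdiff(names(wide), c("patient_id", "date")),
                      drop = FALSE])
  list(x = x, patient_id = wide$patient_id, date = wide$date)
}

#' Supervised two-dimensional embedding of hematology samples
#'
#' Non-linear dimension reduction of the sample-by-parameter matrix to two
#' coordinates. Samples are standardized (missing entries imputed with the
#' column mean); pairwise Euclidean distances are computed, and — when
#' class labels are supplied — inflated between samples of different
#' classes by a supervision penalty, so the training classes separate
#' strictly. The penalized distances are embedded by classical
#' multidimensional scaling. Cohorts larger than `max_landmark` samples
#' are embedded via a landmark subset plus out-of-sample projection. New
#' samples (or the non-landmark remainder) are projected by
#' inverse-distance-weighted averaging of their `n_neighbors` nearest
#' training samples in feature space, which never uses labels — so the
#' projection of an unlabeled cohort is meaningful.
#'
#' @param x Numeric sample-by-parameter matrix (>= 10 rows).
#' @param labels Optional class labels (length `nrow(x)`, `NA` allowed;
#'   only non-NA labels supervise).
#' @param n_neighbors Neighbors used for out-of-sample projection; must
#'   not exceed the number of training samples.
#' @param supervision_weight Distance penalty between classes; default 5
#'   times the median pairwise distance.
#' @param max_landmark Maximum number of samples embedded directly.
#' @param seed Integer seed (landmark subsampling only; the embedding
#'   itself is deterministic).
#' @return Object of class `hema_embedding` with `coords` (n x 2),
#'   plus the training information needed by [project_embedding()].
#' @export
embed_hematology <- function(x, labels = NULL, n_neighbors = 15,
                             supervision_weight = NULL,
                             max_landmark = 1200, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 samples")
  if (nrow(x) < n_neighbors)
    stop("fewer samples than n_neighbors")
  center <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  for (j in seq_len(ncol(xs))) xs[is.na(xs[, j]), j] <- 0

  land <- seq_len(nrow(xs))
  if (nrow(xs) > max_landmark)
    land <- sort(with_seed(seed, sample(nrow(xs), max_landmark)))
  xl <- xs[land, , drop = FALSE]
  d <- as.matrix(stats::dist(xl))
  supervised <- !is.null(labels)
  if (supervised) {
    ll <- as.character(labels)[land]
    w <- supervision_weight %||% (5 * stats::median(d[upper.tri(d)]))
    diff <- outer(ll, ll, FUN = function(a, b)
      !is.na(a) & !is.na(b) & a != b)
    d <- sqrt(d^2 + (w^2) * diff)
  }
  mds <- stats::cmdscale(d, k = 2)
  # deterministic sign convention: largest-magnitude coordinate positive
  for (k in 1:2) {
    j <- which.max(abs(mds[, k]))
    if (mds[j, k] < 0) mds[, k] <- -mds[, k]
  }
  colnames(mds) <- c("d1", "d2")
  emb <- structure(list(
    train_coords = mds, train_x = xl, center = center, scale = scl,
    n_neighbors = n_neighbors, seed = seed, supervised = supervised
  ), class = "hema_embedding")
  coords <- matrix(NA_real_, nrow(xs), 2,
                   dimnames = list(NULL, c("d1", "d2")))
  coords[land, ] <- mds
  if (length(land) < nrow(xs))
    coords[-land, ] <- project_embedding(emb, x[-land, , drop = FALSE])
  emb$coords <- coords
  emb
}

#' Project new samples into a fitted hematology embedding
#'
#' @param embedding A fitted [embed_hematology()] object.
#' @param x New sample-by-parameter matrix (same columns as training).
#' @return Matrix of projected coordinates (n x 2).
#' @export
project_embedding <- function(embedding, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, embedding$center), 2, embedding$scale, "/")
  for (j in seq_len(ncol(xs))) xs[is.na(xs[, j]), j] <- 0
  k <- min(embedding$n_neighbors, nrow(embedding$train_x))
  out <- matrix(NA_real_, nrow(xs), 2,
                dimnames = list(NULL, c("d1", "d2")))
  tx <- embedding$train_x
  for (i in seq_len(nrow(xs))) {
    dd <- sqrt(colSums((t(tx) - xs[i, ])^2))
    nn <- order(dd)[seq_len(k)]
    wts <- 1 / (dd[nn] + 1e-8)
    out[i, ] <- colSums(embedding$train_coords[nn, , drop = FALSE] * wts) /
      sum(wts)
  }
  out
}

#' Per-patient median embedding coordinates
#'
#' The coordinate-wise median of each patient's sample embeddings — the
#' per-patient summary plotted when looking for D2T / non-D2T clusters in
#' longitudinal hematology.
#'
#' @param coords Sample coordinates (n x 2).
#' @param patient_id Patient of each sample.
#' @return data.frame `patient_id`, `median_d1`, `median_d2`.
#' @export
patient_median_embedding <- function(coords, patient_id) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(patient_id))
  if (any(is.na(patient_id))) stop("every sample must map to a patient")
  d1 <- tapply(coords[, 1], patient_id, stats::median)
  d2 <- tapply(coords[, 2], patient_id, stats::median)
  data.frame(patient_id = names(d1), median_d1 = as.numeric(d1),
             median_d2 = as.numeric(d2), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Combined Y-score from the three classification sources
#'
#' Equal-weight mean of the available binary classifications (D2T = 1,
#' non-D2T = 0) from structured data, unstructured data, and the clinical
#' validation label when present. With all three available the score takes
#' values in \{0, 1/3, 2/3, 1\}; it is an error to call with no component.
#'
#' @param structured,unstructured,clinical Logical (TRUE = D2T), or `NA` /
#'   `NULL` when the source is absent.
#' @param weights Optional numeric weights for the three sources (defaults
#'   to equal weighting of the available components).
#' @return Numeric score in \[0, 1\].
#' @export
compute_y_score <- function(structured = NA, unstructured = NA,
                            clinical = NA, weights = c(1, 1, 1)) {
  comp <- c(structured %||% NA, unstructured %||% NA, clinical %||% NA)
  have <- !is.na(comp)
  if (!any(have)) stop("Y-score undefined: no component available")
  sum(weights[have] * as.numeric(comp[have])) / sum(weights[have])
}
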