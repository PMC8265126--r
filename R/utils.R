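# required for data.table [] semantics when data.table is used via ::
.datatable.aware <- TRUE

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# thin wrappers over the stable low-level xgboost interface
xgb_fit <- function(x, y, objective, nrounds, max_depth, eta) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = objective, max_depth = max_depth, eta = eta,
                  nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_predict <- function(fit, x) {
  as.numeric(stats::predict(
    fit, xgboost::xgb.DMatrix(data = x, nthread = 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coordinate-wise silhouette score of a labelled point set (Euclidean)
#' Mean silhouette width of a labelled point set
#'
#' Standard silhouette: for each point, `(b - a) / max(a, b)` where `a` is
#' the mean distance to points sharing its label and `b` the smallest mean
#' distance to any other label. Used to quantify class separation of
#' embedding coordinates.
#'
#' @param coords Numeric matrix (points x dimensions).
#' @param labels Vector of class labels, one per row.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels), length(unique(labels)) >= 2)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]
    same[i] <- FALSE
    if (!any(same)) return(0)
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
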