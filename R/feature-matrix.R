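#' Feature matrix container
#'
#' A `feature_matrix` holds one omic layer as a samples-by-features numeric
#' matrix (inbred lines in rows, features in columns), a layer tag, and
#' optional per-feature metadata (gene id, position, SIFT score). Missing
#' values are `NA` in the matrix itself; no sentinel codes are used.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids). `NA` marks missing.
#' @param layer Character layer tag, one of the recognised omic layers
#'   (`"SNP"`, `"SV"`, `"dSV"`, `"tSV"`, `"ePAV_s"`, `"ePAV_l"`, `"ePAV_ls"`,
#'   `"GE_s"`, `"GE_l"`, `"TE_s"`, `"TE_l"`, `"M"`) or any other label.
#' @param feature_meta Optional data frame of per-feature metadata with one
#'   row per feature, in column order. Recognised columns include `feature_id`,
#'   `gene_id`, `position`, `sift_score`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, layer = "unknown", feature_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids")
  if (!is.null(feature_meta)) {
    feature_meta <- tibble::as_tibble(feature_meta)
    if (nrow(feature_meta) != ncol(values))
      stop("feature_meta must have one row per feature")
  }
  structure(
    list(values = values, layer = layer, feature_meta = feature_meta),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> layer=%s: %d samples x %d features (%.1f%% missing)\n",
    x$layer, nrow(x$values), ncol(x$values),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Sample ids of a feature matrix or kernel
#' @param x A `feature_matrix` or `omic_kernel`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.feature_matrix <- function(x) rownames(x$values)

#' @export
sample_ids.omic_kernel <- function(x) rownames(x$matrix)

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id")
}

#' Quality-control filter for a feature matrix
#'
#' Removes monomorphic features (zero variance among non-missing entries,
#' including features with fewer than two observed values) and features with
#' missing rate strictly above `max_missing`. Mirrors the usual marker QC for
#' relationship-matrix construction.
#'
#' @param fm A [feature_matrix()].
#' @param max_missing Maximum tolerated per-feature missing fraction
#'   (features with missing rate strictly greater are dropped). Default 0.2.
#' @return The filtered `feature_matrix`, with a `qc_report` attribute: a
#'   tibble counting features removed per reason.
#' @export
qc_filter <- function(fm, max_missing = 0.2) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  miss_frac <- colMeans(is.na(v))
  too_missing <- miss_frac > max_missing
  vars <- apply(v, 2, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) < 2L) 0 else stats::var(obs)
  })
  monomorphic <- !too_missing & vars == 0
  keep <- !too_missing & !monomorphic
  if (!any(keep))
    stop("qc_filter removed all features in layer ", fm$layer)
  out <- feature_matrix(
    v[, keep, drop = FALSE], layer = fm$layer,
    feature_meta = if (!is.null(fm$feature_meta)) fm$feature_meta[keep, , drop = FALSE]
  )
  attr(out, "qc_report") <- tibble::tibble(
    reason = c("retained", "missing_rate", "monomorphic"),
    n = c(sum(keep), sum(too_missing), sum(monomorphic))
  )
  out
}

#' Mean-impute missing entries of a feature matrix
#'
#' Replaces each missing entry by the mean of the observed entries of its
#' feature. Intended to run after [qc_filter()], which guarantees every
#' retained feature has at least 80\% observed values.
#'
#' @param fm A [feature_matrix()].
#' @return A complete `feature_matrix` (no missing values).
#' @export
impute_mean <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (anyNA(v)) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2L]]
  }
  feature_matrix(v, layer = fm$layer, feature_meta = fm$feature_meta)
}
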