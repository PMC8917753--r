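#' Additive relationship kernel from a feature matrix
#'
#' Builds the standardized additive relationship matrix
#' \deqn{G = W^* {W^*}^T / m}
#' where the columns of \eqn{W^*} are the features centered and scaled to unit
#' variance. The population variance convention (divisor \eqn{n}) is used so
#' that \eqn{\mathrm{trace}(G) = n} exactly and the average diagonal element
#' is 1, the usual GBLUP normalisation. The kernel is invariant to affine
#' recoding of any feature (0/1 vs 0/2 genotype coding gives the same G).
#'
#' @param fm A complete [feature_matrix()] (run [qc_filter()] and
#'   [impute_mean()] first); zero-variance columns are an error.
#' @return An `omic_kernel`: list with `matrix` (n x n symmetric PSD),
#'   `m` (number of features used) and `layer`.
#' @export
build_kernel <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (anyNA(v)) stop("feature matrix has missing values; run impute_mean() first")
  if (ncol(v) < 1L) stop("no features")
  n <- nrow(v)
  mu <- colMeans(v)
  # population sd (divisor n) so each standardized column has sum of squares n
  sd_pop <- sqrt(colMeans(sweep(v, 2L, mu)^2))
  if (any(sd_pop == 0))
    stop("zero-variance feature present; run qc_filter() first")
  w <- sweep(sweep(v, 2L, mu), 2L, sd_pop, "/")
  g <- tcrossprod(w) / ncol(w)
  g <- (g + t(g)) / 2
  new_kernel(g, m = ncol(w), layer = fm$layer)
}

new_kernel <- function(g, m, layer) {
  structure(list(matrix = g, m = m, layer = layer), class = "omic_kernel")
}

#' @export
print.omic_kernel <- function(x, ...) {
  cat(sprintf("<omic_kernel> layer=%s: %d samples, m=%d features, trace=%.3f\n",
              x$layer, nrow(x$matrix), x$m, sum(diag(x$matrix))))
  invisible(x)
}

#' Subset a kernel to a set of samples
#' @param x An `omic_kernel`.
#' @param ids Sample ids to keep (order respected).
#' @return The restricted `omic_kernel`.
#' @export
kernel_subset <- function(x, ids) {
  stopifnot(inherits(x, "omic_kernel"))
  missing_ids <- setdiff(ids, rownames(x$matrix))
  if (length(missing_ids))
    stop("samples not in kernel: ", paste(missing_ids, collapse = ", "))
  new_kernel(x$matrix[ids, ids, drop = FALSE], m = x$m, layer = x$layer)
}

#' Partition sequence variants by SIFT score
#'
#' Splits an SV feature matrix into deleterious (SIFT score <= 0.05) and
#' tolerant (score > 0.05) subsets. Variants without a score enter neither
#' subset and are counted in the `n_unscored` attribute of the result.
#'
#' @param fm A [feature_matrix()] whose `feature_meta` has a `sift_score`
#'   column.
#' @return Named list with elements `dSV` and `tSV` (feature matrices) and
#'   attribute `n_unscored`.
#' @export
classify_sift <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  meta <- fm$feature_meta
  if (is.null(meta) || is.null(meta$sift_score))
    stop("feature_meta$sift_score required")
  s <- meta$sift_score
  del <- !is.na(s) & s <= 0.05
  tol <- !is.na(s) & s > 0.05
  out <- list(
    dSV = feature_matrix(fm$values[, del, drop = FALSE], layer = "dSV",
                         feature_meta = meta[del, , drop = FALSE]),
    tSV = feature_matrix(fm$values[, tol, drop = FALSE], layer = "tSV",
                         feature_meta = meta[tol, , drop = FALSE])
  )
  attr(out, "n_unscored") <- sum(is.na(s))
  out
}

#' Call expression presence/absence variation (ePAV)
#'
#' Per gene (column) with per-gene maximum expression `Mx` across inbreds:
#' a value of exactly 0 is an absence call (0); a value strictly between 0 and
#' `0.1 * Mx` is ambiguous and coded `NA`; a value at or above `0.1 * Mx` is a
#' presence call (1). Genes whose maximum is 0 are all-absent. Both
#' inequalities of the ambiguity zone are strict, so a value equal to
#' `0.1 * Mx` is called present.
#'
#' @param ge Non-negative gene-expression [feature_matrix()] for one tissue.
#' @param layer Layer tag for the result (e.g. `"ePAV_s"`).
#' @param na_fraction Ambiguity zone as a fraction of the per-gene maximum;
#'   default 0.1.
#' @return A `feature_matrix` of calls coded present = 1, absent = 0,
#'   ambiguous = `NA`.
#' @export
call_epav <- function(ge, layer = "ePAV", na_fraction = 0.1) {
  stopifnot(inherits(ge, "feature_matrix"))
  v <- ge$values
  if (any(v < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  mx <- apply(v, 2L, max, na.rm = TRUE)
  cut <- na_fraction * mx
  calls <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    cj <- ifelse(x == 0, 0, ifelse(x < cut[j], NA_real_, 1))
    calls[, j] <- cj
  }
  feature_matrix(calls, layer = layer, feature_meta = ge$feature_meta)
}

#' Combine tissue-specific ePAV calls into an across-tissue call
#'
#' For each (inbred, gene) over the union of gene sets: present (1) if the
#' gene is called present in at least one tissue; absent (0) if it has at
#' least one non-missing call and all non-missing calls are absences; `NA`
#' when every available call is ambiguous. Genes measured in only one tissue
#' use that tissue's call alone.
#'
#' @param epav_s,epav_l Tissue-specific ePAV call matrices from [call_epav()].
#' @return A `feature_matrix` with layer `"ePAV_ls"`.
#' @export
combine_epav <- function(epav_s, epav_l) {
  stopifnot(inherits(epav_s, "feature_matrix"), inherits(epav_l, "feature_matrix"))
  samp <- rownames(epav_s$values)
  if (!identical(sort(samp), sort(rownames(epav_l$values))))
    stop("sample sets differ between tissues")
  genes <- union(colnames(epav_s$values), colnames(epav_l$values))
  expand <- function(m) {
    out <- matrix(NA_real_, length(samp), length(genes),
                  dimnames = list(samp, genes))
    out[samp, colnames(m)] <- m[samp, , drop = FALSE]
    out
  }
  a <- expand(epav_s$values)
  b <- expand(epav_l$values)
  comb <- matrix(NA_real_, length(samp), length(genes),
                 dimnames = list(samp, genes))
  present <- (a == 1 & !is.na(a)) | (b == 1 & !is.na(b))
  absent <- !present &
    ((a == 0 & !is.na(a)) | (b == 0 & !is.na(b)))
  comb[present] <- 1
  comb[absent] <- 0
  feature_matrix(comb, layer = "ePAV_ls")
}

#' Convert ePAV calls to a numeric feature matrix for kernel construction
#'
#' Presence/absence calls already live on a 0/1 scale; this pass-through
#' re-tags the matrix so that downstream [qc_filter()], [impute_mean()] and
#' [build_kernel()] treat the calls like any other layer (ambiguous calls are
#' ordinary missing values and get mean-imputed).
#'
#' @param epav An ePAV call `feature_matrix`.
#' @return A numeric `feature_matrix` (same layer tag).
#' @export
epav_to_numeric <- function(epav) {
  stopifnot(inherits(epav, "feature_matrix"))
  feature_matrix(epav$values, layer = epav$layer, feature_meta = epav$feature_meta)
}

#' Standard layer preparation: QC, imputation, kernel
#'
#' Convenience wrapper applying [qc_filter()] then [impute_mean()] then
#' [build_kernel()], the preparation every omic layer undergoes before
#' prediction.
#'
#' @inheritParams build_kernel
#' @param max_missing Passed to [qc_filter()].
#' @return An `omic_kernel`.
#' @export
layer_kernel <- function(fm, max_missing = 0.2) {
  build_kernel(impute_mean(qc_filter(fm, max_missing = max_missing)))
}
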