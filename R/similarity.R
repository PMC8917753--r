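#' PCA scores of one omic layer
#'
#' Principal component scores of the column-standardized feature matrix,
#' with a deterministic sign convention: each component is flipped so that
#' its largest-magnitude loading is positive.
#'
#' @param fm A complete [feature_matrix()].
#' @param k Number of components to keep (`k <= n - 1`).
#' @return A `pca_config`: `coordinates` (n x k score matrix), `layer`,
#'   `percent_var`.
#' @export
pca_scores <- function(fm, k) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (anyNA(v)) stop("feature matrix has missing values; impute first")
  n <- nrow(v)
  if (k > n - 1) stop("k must be at most n - 1")
  keep <- apply(v, 2, stats::sd) > 0
  pc <- stats::prcomp(v[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k_eff <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  if (k_eff < k) # pad so configurations entering GPA share dimensions
    scores <- cbind(scores, matrix(0, n, k - k_eff))
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(coordinates = scores, layer = fm$layer,
         percent_var = 100 * pc$sdev^2 / sum(pc$sdev^2)),
    class = "pca_config"
  )
}

#' Generalized Procrustes alignment of omic-layer configurations
#'
#' Iteratively superimposes several n-point configurations (e.g. per-layer
#' PCA scores over the same inbreds) by translation, rotation/reflection, and
#' isotropic scaling onto their consensus (the mean configuration), until the
#' residual sum of squares changes by less than `tol` or `max_iter`
#' iterations. The total sum of squares over configurations is held constant
#' during scaling so the solution does not collapse. Configurations with
#' fewer columns than the widest one are padded with zero columns.
#'
#' @param configs List of `pca_config` objects or plain score matrices over
#'   the same samples in the same order.
#' @param tol Convergence tolerance on the residual change (default 1e-10).
#' @param max_iter Maximum iterations (default 100).
#' @return A `gpa_result`: `aligned` (list of aligned matrices),
#'   `consensus`, `rss`, `iterations`, `labels`.
#' @export
gpa_align <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2) stop("need at least 2 configurations")
  labels <- names(configs)
  if (is.null(labels))
    labels <- vapply(seq_along(configs), function(i) {
      if (inherits(configs[[i]], "pca_config")) configs[[i]]$layer
      else paste0("config", i)
    }, "")
  mats <- lapply(configs, function(cc)
    if (inherits(cc, "pca_config")) cc$coordinates else as.matrix(cc))
  n <- nrow(mats[[1]])
  for (m in mats) if (nrow(m) != n) stop("configurations must share samples")
  kmax <- max(vapply(mats, ncol, 0L))
  mats <- lapply(mats, function(m)
    cbind(m, matrix(0, n, kmax - ncol(m))))
  # center and scale each to unit sum of squares
  mats <- lapply(mats, function(m) {
    m <- sweep(m, 2, colMeans(m))
    ss <- sum(m^2)
    if (ss == 0) stop("degenerate (all-zero) configuration")
    m / sqrt(ss)
  })
  n_conf <- length(mats)
  total_ss <- n_conf # after unit scaling
  rotate_to <- function(x, target) {
    s <- svd(crossprod(x, target))
    x %*% (s$u %*% t(s$v))
  }
  rss_old <- Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    consensus <- Reduce(`+`, mats) / n_conf
    mats <- lapply(mats, rotate_to, target = consensus)
    consensus <- Reduce(`+`, mats) / n_conf
    # isotropic scaling preserving total sum of squares
    num <- vapply(mats, function(m) sum(m * consensus), 0)
    den <- vapply(mats, function(m) sum(m^2), 0)
    rho <- num / den
    scale_norm <- sqrt(total_ss / sum(rho^2 * den))
    mats <- Map(function(m, r) m * (r * scale_norm), mats, rho)
    consensus <- Reduce(`+`, mats) / n_conf
    rss <- sum(vapply(mats, function(m) sum((m - consensus)^2), 0))
    if (abs(rss_old - rss) < tol || iter >= max_iter) break
    rss_old <- rss
  }
  names(mats) <- labels
  structure(
    list(aligned = mats, consensus = consensus, rss = rss,
         iterations = iter, labels = labels),
    class = "gpa_result"
  )
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("<gpa_result> %d configurations, rss=%.4g after %d iterations\n",
              length(x$aligned), x$rss, x$iterations))
  invisible(x)
}

# symmetric Procrustes statistic m^2 between two centered configurations
procrustes_m2 <- function(x, y) {
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) return(NA_real_)
  # clamp: floating-point rounding can push identical configurations a hair
  # below 0
  min(max(1 - (sum(svd(crossprod(x, y))$d)^2) / denom^2, 0), 1)
}

#' Pairwise Procrustes dissimilarity between aligned configurations
#'
#' For every pair of configurations the Procrustes similarity index is the
#' Procrustes correlation \eqn{1 - m^2}, where \eqn{m^2} is the symmetric
#' scaled residual statistic of the optimal superimposition (Gower);
#' dissimilarity is 1 minus the similarity, i.e. \eqn{m^2} itself, in
#' \[0, 1\].
#'
#' @param gpa A [gpa_align()] result (or a named list of score matrices).
#' @return A `dissimilarity_matrix`: symmetric `matrix` with zero diagonal
#'   and `source = "gpa"`.
#' @export
procrustes_dissimilarity <- function(gpa) {
  mats <- if (inherits(gpa, "gpa_result")) gpa$aligned else gpa
  k <- length(mats)
  d <- matrix(0, k, k, dimnames = list(names(mats), names(mats)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m2 <- procrustes_m2(mats[[i]], mats[[j]])
      d[i, j] <- d[j, i] <- m2
    }
  }
  structure(list(matrix = d, source = "gpa"), class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d items, source=%s\n",
              nrow(x$matrix), x$source))
  invisible(x)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2} and eigendecomposes it. Negative
#' eigenvalues (non-Euclidean dissimilarities) are dropped with a warning;
#' percent variance per axis is computed over the positive eigenvalues only.
#' Axes use the same deterministic sign convention as [pca_scores()].
#'
#' @param d A `dissimilarity_matrix` or a symmetric numeric matrix / `dist`.
#' @param n_axes Number of axes requested; truncated with a warning when it
#'   exceeds the number of positive eigenvalues.
#' @return A `pcoa_result`: `coordinates`, `percent_var`, `eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- if (inherits(d, "dissimilarity_matrix")) d$matrix else as.matrix(d)
  n <- nrow(m)
  b <- -0.5 * m^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  ev <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- ev$values > 1e-10 * max(abs(ev$values), 1e-300)
  if (any(ev$values < -1e-8 * max(abs(ev$values))))
    warning("negative eigenvalues dropped (non-Euclidean dissimilarity)")
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); truncating axes")
    n_axes <- n_pos
  }
  lambda <- ev$values[pos]
  coords <- ev$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda), n_pos)
  for (j in seq_len(n_pos))
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  coords <- coords[, seq_len(n_axes), drop = FALSE]
  dimnames(coords) <- list(rownames(m), paste0("PCo", seq_len(n_axes)))
  structure(
    list(coordinates = coords,
         percent_var = 100 * lambda / sum(lambda),
         eigenvalues = ev$values),
    class = "pcoa_result"
  )
}

#' Correlation-based distance between per-layer predicted values
#'
#' For each cross-validation replicate, the hold-out predictions of every
#' layer (concatenated over folds into one vector per replicate) are
#' correlated pairwise; the distance is 1 minus the Pearson correlation. The
#' reported matrix is the element-wise median across replicates. A constant
#' predicted vector has no defined correlation; its correlation is treated
#' as 0, giving distance 1.
#'
#' @param cv_results Named list of `cv_result` objects run with
#'   `keep_predictions = TRUE` on shared fold partitions.
#' @return A `dissimilarity_matrix` with
#'   `source = "predicted_value_correlation"`.
#' @export
predicted_value_distance <- function(cv_results) {
  stopifnot(length(cv_results) >= 2)
  labels <- names(cv_results)
  if (is.null(labels)) labels <- vapply(cv_results, `[[`, "", "layer")
  preds <- lapply(cv_results, function(cv) {
    if (is.null(cv$predictions))
      stop("run cross_validate() with keep_predictions = TRUE")
    cv$predictions
  })
  n_rep <- nrow(preds[[1]])
  k <- length(preds)
  d <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      per_rep <- vapply(seq_len(n_rep), function(r) {
        x <- preds[[i]][r, ]; y <- preds[[j]][r, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)
        1 - stats::cor(x, y)
      }, 0)
      d[i, j] <- d[j, i] <- stats::median(per_rep)
    }
  }
  structure(list(matrix = d, source = "predicted_value_correlation"),
            class = "dissimilarity_matrix")
}
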