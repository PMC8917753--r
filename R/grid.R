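#' Enumerate the simplex lattice of kernel weights
#'
#' All vectors of `n_kernels` non-negative weights on the lattice
#' `{0, step, 2*step, ..., 1}` summing to exactly 1, each exactly once, in
#' deterministic lexicographic order. With four kernels and step 0.1 this
#' yields 286 combinations (compositions of 10 into 4 parts).
#'
#' @param n_kernels Number of kernels.
#' @param step Lattice step; `1/step` must be an integer.
#' @return Tibble with one weight column per kernel (`w1` ... or named after
#'   `names`), one row per combination.
#' @param names Optional kernel names used as column names.
#' @export
enumerate_weight_grid <- function(n_kernels, step = 0.1, names = NULL) {
  if (n_kernels < 1) stop("need at least one kernel")
  s <- round(1 / step)
  if (abs(1 / step - s) > 1e-9) stop("`step` must divide 1 exactly")
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- lapply(0:total, function(first)
      cbind(first, compositions(total - first, parts - 1)))
    do.call(rbind, out)
  }
  m <- compositions(s, n_kernels) / s
  colnames(m) <- if (!is.null(names)) names else paste0("w", seq_len(n_kernels))
  tibble::as_tibble(m)
}

#' Joined weighted relationship matrix
#'
#' Convex combination \eqn{G_{joint} = \sum_k w_k G_k} of per-layer kernels
#' over the same samples in the same order. Each input kernel has trace n, so
#' the joined kernel does too; a convex combination of PSD matrices is PSD.
#'
#' @param kernels List of `omic_kernel` objects with identical sample sets
#'   and ordering.
#' @param w Numeric weight vector (same length, sums to 1 within 1e-9).
#' @return An `omic_kernel` with layer tag `"joint"`.
#' @export
combine_kernels <- function(kernels, w) {
  stopifnot(length(kernels) == length(w))
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(w < 0)) stop("weights must be non-negative")
  ids <- rownames(kernels[[1]]$matrix)
  for (k in kernels)
    if (!identical(rownames(k$matrix), ids))
      stop("kernels must share sample set and ordering")
  g <- Reduce(`+`, Map(function(k, wk) wk * k$matrix, kernels, w))
  new_kernel(g, m = sum(vapply(kernels, `[[`, 0, "m") * (w > 0)),
             layer = "joint")
}

#' Grid search over the joined weighted relationship matrix
#'
#' Evaluates every weight vector of the simplex lattice by replicated k-fold
#' cross-validation of the joined kernel, with the same fold partitions
#' reused across all weight vectors (paired comparison). The optimum is the
#' weight vector with the highest median-of-medians ability; ties are broken
#' by fewest nonzero weights, then by the lexicographically smallest vector.
#' Vertex weight vectors (all weight on one kernel) reproduce the
#' single-kernel cross-validation exactly under the same partitions.
#'
#' @param kernels Named list of `omic_kernel` objects (same samples/order).
#' @param y Named vector of adjusted entry means.
#' @param step Grid step (default 0.1).
#' @param n_folds,n_replicates,base_seed CV settings (see [cross_validate()]).
#' @param folds Optional precomputed partitions.
#' @return A `grid_search_result`: tibble `grid` (one row per weight vector
#'   with its median-of-medians ability), `best` (the optimal row), and the
#'   CV settings.
#' @export
grid_search <- function(kernels, y, step = 0.1, n_folds = 5,
                        n_replicates = 200, base_seed = 1, folds = NULL) {
  if (is.null(names(kernels)))
    names(kernels) <- vapply(kernels, `[[`, "", "layer")
  grid <- enumerate_weight_grid(length(kernels), step, names = names(kernels))
  if (is.null(folds))
    folds <- make_cv_folds(names(y), n_folds, n_replicates, base_seed)
  ability <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- as.numeric(grid[i, ])
    joint <- combine_kernels(kernels, w)
    cv <- cross_validate(joint, y, folds = folds)
    ability[i] <- cv$median_of_medians
  }
  grid$ability <- ability
  grid$n_active <- rowSums(grid[, names(kernels), drop = FALSE] > 0)
  best_pool <- grid[grid$ability == max(grid$ability), , drop = FALSE]
  best_pool <- best_pool[best_pool$n_active == min(best_pool$n_active), ,
                         drop = FALSE]
  ord <- do.call(order, as.list(best_pool[, names(kernels), drop = FALSE]))
  best <- best_pool[ord[1], , drop = FALSE]
  structure(
    list(grid = grid, best = best, kernel_names = names(kernels),
         step = step, n_folds = n_folds, n_replicates = length(folds),
         base_seed = base_seed),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  w <- paste(sprintf("%s=%.1f", x$kernel_names,
                     as.numeric(x$best[, x$kernel_names])), collapse = ", ")
  cat(sprintf(
    "<grid_search_result> %d weight vectors (step %.2f); best ability %.3f at %s\n",
    nrow(x$grid), x$step, x$best$ability, w))
  invisible(x)
}
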