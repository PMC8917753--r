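#' Random cross-validation fold partitions
#'
#' Generates `n_replicates` independent partitions of the samples into
#' `n_folds` folds with sizes differing by at most one. Replicate `r` is
#' seeded with `base_seed + r`, so partitions can be regenerated (and shared
#' across predictors for paired comparisons).
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_folds Number of folds (default 5).
#' @param n_replicates Number of replicate partitions (default 200).
#' @param base_seed Integer base seed.
#' @return List of length `n_replicates`; each element is a list of `n_folds`
#'   id vectors. Attributes record the seeds used.
#' @export
make_cv_folds <- function(sample_ids, n_folds = 5, n_replicates = 200,
                          base_seed = 1) {
  n <- length(sample_ids)
  if (n < n_folds) stop("fewer samples than folds")
  seeds <- base_seed + seq_len(n_replicates)
  folds <- lapply(seeds, function(s) {
    set.seed(s)
    shuffled <- sample(sample_ids)
    assign <- rep(seq_len(n_folds), length.out = n)
    lapply(seq_len(n_folds), function(f) shuffled[assign == f])
  })
  attr(folds, "seeds") <- seeds
  folds
}

#' Replicated k-fold cross-validation of GBLUP prediction
#'
#' For each replicate partition, fits GBLUP on four folds (re-estimating the
#' variance ratio within each training set, so no information leaks from the
#' held-out fold) and predicts the fifth; the prediction ability is the
#' Pearson correlation between observed and predicted entry means in the
#' held-out fold. Reported summaries follow the median-of-medians protocol:
#' the median ability across folds within each replicate, then the median of
#' those medians across replicates.
#'
#' @param kernel An `omic_kernel` covering all phenotyped samples.
#' @param y Named numeric vector of adjusted entry means.
#' @param n_folds,n_replicates,base_seed Passed to [make_cv_folds()] when
#'   `folds` is not supplied.
#' @param folds Optional precomputed partitions from [make_cv_folds()]
#'   (shared partitions give paired comparisons across predictors).
#' @param keep_predictions Keep the hold-out predictions per replicate
#'   (needed for predicted-value distances); default `FALSE`.
#' @return A `cv_result`: tibble `abilities` (`replicate`, `fold`,
#'   `ability`), `median_per_replicate`, `median_of_medians`, `layer`, and
#'   (optionally) `predictions`, a replicates-by-samples matrix of hold-out
#'   predictions.
#' @export
cross_validate <- function(kernel, y, n_folds = 5, n_replicates = 200,
                           base_seed = 1, folds = NULL,
                           keep_predictions = FALSE) {
  stopifnot(inherits(kernel, "omic_kernel"))
  ids <- names(y)
  if (is.null(ids)) stop("`y` must be named by sample id")
  if (is.null(folds))
    folds <- make_cv_folds(ids, n_folds, n_replicates, base_seed)
  n_rep <- length(folds)
  rows <- vector("list", n_rep)
  preds <- if (keep_predictions)
    matrix(NA_real_, n_rep, length(ids), dimnames = list(NULL, ids))
  for (r in seq_len(n_rep)) {
    part <- folds[[r]]
    ab <- numeric(length(part))
    for (f in seq_along(part)) {
      test_ids <- part[[f]]
      train_ids <- setdiff(ids, test_ids)
      fit <- fit_gblup(kernel_subset(kernel, train_ids), y[train_ids])
      pred <- predict_holdout(fit, kernel, y[train_ids], test_ids)
      ab[f] <- as.numeric(prediction_ability(y[test_ids], pred))
      if (keep_predictions) preds[r, test_ids] <- pred
    }
    rows[[r]] <- tibble::tibble(replicate = r, fold = seq_along(part),
                                ability = ab)
  }
  abilities <- dplyr::bind_rows(rows)
  med_rep <- abilities |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(median_ability = stats::median(.data$ability),
                     .groups = "drop")
  structure(
    list(abilities = abilities,
         median_per_replicate = med_rep,
         median_of_medians = stats::median(med_rep$median_ability),
         layer = kernel$layer,
         n_folds = if (length(folds)) length(folds[[1]]) else n_folds,
         seeds = attr(folds, "seeds"),
         predictions = preds),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> layer=%s: %d-fold CV x %d replicates, median of medians = %.3f\n",
    x$layer, x$n_folds, nrow(x$median_per_replicate), x$median_of_medians))
  invisible(x)
}
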