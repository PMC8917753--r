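#' Fit a GBLUP model by spectral REML
#'
#' Fits the mixed model
#' \deqn{y = 1\mu + Z u + \varepsilon,\quad u \sim N(0, G\sigma^2_u),\quad
#'       \varepsilon \sim N(0, I\sigma^2_e)}
#' on the adjusted entry means of the training samples, where `G` is a
#' standardized relationship kernel. The residual-to-genetic variance ratio
#' \eqn{\lambda = \sigma^2_e / \sigma^2_u} is profiled out of the restricted
#' likelihood using a single eigendecomposition of the training kernel, and
#' optimized on the log scale. Because centered kernels at small n are
#' rank-deficient, \eqn{\lambda} is floored at `1e-6`; all downstream solves
#' use \eqn{(G + \lambda I)^{-1}} with this floored value, so holdout
#' predictions coincide exactly with ridge regression on the standardized
#' feature matrix with penalty \eqn{m\lambda}.
#'
#' @param kernel An `omic_kernel` restricted to (or covering) the training
#'   samples.
#' @param y Named numeric vector of adjusted entry means for the training
#'   samples (names = sample ids present in the kernel).
#' @return A `gblup_fit`: `mu_hat`, `lambda_hat`, `u_hat` (BLUPs for the
#'   training samples), `train_ids`, `sigma2_u`.
#' @export
fit_gblup <- function(kernel, y) {
  stopifnot(inherits(kernel, "omic_kernel"))
  if (is.null(names(y))) stop("`y` must be named by sample id")
  n <- length(y)
  if (n < 3) stop("need at least 3 training samples")
  G <- kernel_subset(kernel, names(y))$matrix
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-6)
    stop("kernel is not positive semi-definite (min eigenvalue ",
         format(min(ev$values)), ")")
  if (stats::var(y) == 0) {
    fit <- list(mu_hat = unname(y[1]), lambda_hat = Inf,
                u_hat = stats::setNames(rep(0, n), names(y)),
                train_ids = names(y), sigma2_u = 0)
    return(structure(fit, class = "gblup_fit"))
  }
  d <- pmax(ev$values, 0)
  yt <- drop(crossprod(ev$vectors, y))
  xt <- drop(crossprod(ev$vectors, rep(1, n)))
  # -2 * restricted log-likelihood, profiled over mu and sigma2_u
  neg2reml <- function(log_lambda) {
    v <- d + exp(log_lambda)
    mu <- sum(xt * yt / v) / sum(xt^2 / v)
    rt <- yt - xt * mu
    s2 <- sum(rt^2 / v) / (n - 1)
    (n - 1) * log(s2) + sum(log(v)) + log(sum(xt^2 / v))
  }
  opt <- stats::optimize(neg2reml, lower = log(1e-6), upper = log(1e8),
                         tol = 1e-10)
  lambda <- max(exp(opt$minimum), 1e-6)
  v <- d + lambda
  mu <- sum(xt * yt / v) / sum(xt^2 / v)
  rt <- yt - xt * mu
  sigma2_u <- sum(rt^2 / v) / (n - 1)
  # u = G (G + lambda I)^-1 (y - 1 mu)
  u <- drop(ev$vectors %*% (d * (rt / v)))
  structure(
    list(mu_hat = mu, lambda_hat = lambda,
         u_hat = stats::setNames(u, names(y)),
         train_ids = names(y), sigma2_u = sigma2_u),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> %d training samples, mu=%.4g, lambda=%.4g\n",
              length(x$train_ids), x$mu_hat, x$lambda_hat))
  invisible(x)
}

#' Predict held-out samples from a GBLUP fit
#'
#' Standard BLUP conditional expectation:
#' \deqn{\hat u_{test} = G_{test,train} (G_{train,train} + \hat\lambda I)^{-1}
#'       (y_{train} - \hat\mu 1)}
#' and prediction \eqn{\hat\mu + \hat u_{test}}. A test sample with zero
#' kernel covariance to every training sample is predicted at \eqn{\hat\mu}.
#'
#' @param fit A [fit_gblup()] result.
#' @param kernel An `omic_kernel` covering training and test samples.
#' @param y Named training phenotype vector used for the fit.
#' @param test_ids Sample ids to predict.
#' @return Named numeric vector of predictions.
#' @export
predict_holdout <- function(fit, kernel, y, test_ids) {
  stopifnot(inherits(fit, "gblup_fit"), inherits(kernel, "omic_kernel"))
  missing_ids <- setdiff(test_ids, rownames(kernel$matrix))
  if (length(missing_ids))
    stop("test sample(s) missing from kernel: ",
         paste(missing_ids, collapse = ", "))
  if (!identical(names(y), fit$train_ids)) y <- y[fit$train_ids]
  if (is.infinite(fit$lambda_hat))
    return(stats::setNames(rep(fit$mu_hat, length(test_ids)), test_ids))
  Gtt <- kernel$matrix[fit$train_ids, fit$train_ids, drop = FALSE]
  Gxt <- kernel$matrix[test_ids, fit$train_ids, drop = FALSE]
  alpha <- solve(Gtt + fit$lambda_hat * diag(nrow(Gtt)), y - fit$mu_hat)
  stats::setNames(fit$mu_hat + drop(Gxt %*% alpha), test_ids)
}

#' Prediction ability
#'
#' Pearson correlation between observed and predicted adjusted entry means in
#' a validation set. A constant prediction vector has no defined correlation;
#' by convention the ability is then 0, flagged via the `constant_prediction`
#' attribute.
#'
#' @param observed,predicted Numeric vectors (at least 3 pairs).
#' @return Correlation in \[-1, 1\].
#' @export
prediction_ability <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(structure(0, constant_prediction = TRUE))
  stats::cor(observed, predicted)
}
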