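test_that("holdout GBLUP equals explicit ridge regression on random instances", {
  set.seed(101)
  worst <- 0
  for (rep in 1:12) {
    n <- sample(12:22, 1); m <- sample(30:100, 1)
    W <- matrix(rnorm(n * m), n, m,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:m)))
    kern <- build_kernel(fm_of(W))
    b <- rnorm(m, 0, 0.2)
    y <- setNames(drop(scale(W) %*% b) + rnorm(n, 0, 0.5), rownames(W))
    test <- sample(rownames(W), 4)
    train <- setdiff(rownames(W), test)
    fit <- fit_gblup(kernel_subset(kern, train), y[train])
    pred <- predict_holdout(fit, kern, y[train], test)
    # independent oracle: ridge on the population-standardized features
    mu <- colMeans(W); sdp <- sqrt(colMeans(sweep(W, 2, mu)^2))
    Ws <- sweep(sweep(W, 2, mu), 2, sdp, "/")
    beta <- solve(crossprod(Ws[train, ]) + fit$lambda_hat * m * diag(m),
                  crossprod(Ws[train, ], y[train] - fit$mu_hat))
    oracle <- fit$mu_hat + drop(Ws[test, ] %*% beta)
    worst <- max(worst, max(abs(pred - oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("masked-phenotype joint covariance solve gives identical predictions", {
  set.seed(102)
  n <- 15
  W <- matrix(rnorm(n * 60), n, 60,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:60)))
  kern <- build_kernel(fm_of(W))
  y <- setNames(drop(scale(W) %*% rnorm(60, 0, 0.3)) + rnorm(n, 0, 0.4),
                rownames(W))
  test <- rownames(W)[1:4]; train <- setdiff(rownames(W), test)
  fit <- fit_gblup(kernel_subset(kern, train), y[train])
  pred <- predict_holdout(fit, kern, y[train], test)
  # alternative formulation: conditional expectation under the joint
  # covariance of (u_test, y_train), no eigen machinery
  G <- kern$matrix
  V <- G[train, train] + fit$lambda_hat * diag(length(train))
  alt <- fit$mu_hat + G[test, train] %*% solve(V) %*% (y[train] - fit$mu_hat)
  expect_equal(unname(pred), unname(drop(alt)), tolerance = 1e-8)
})

test_that("shrinkage and interpolation limits behave as expected", {
  set.seed(103)
  n <- 18
  W <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:50)))
  kern <- build_kernel(fm_of(W))
  train <- rownames(W)[1:14]
  y <- setNames(rnorm(n), rownames(W))
  fit <- fit_gblup(kernel_subset(kern, train), y[train])
  # sigma2_u -> 0 limit: with the variance ratio pushed to infinity the
  # holdout predictions collapse onto the general mean
  shrunk <- fit
  shrunk$lambda_hat <- 1e10
  pred <- predict_holdout(shrunk, kern, y[train], rownames(W)[15:18])
  expect_lt(max(abs(pred - fit$mu_hat)), 1e-6)
  # lambda -> 0 limit: a noiseless phenotype in the kernel's column space
  # is interpolated in sample
  y_gen <- setNames(drop(scale(W) %*% rnorm(50)), rownames(W))
  fit2 <- fit_gblup(kern, y_gen)
  interp <- fit2
  interp$lambda_hat <- 1e-6
  pred2 <- predict_holdout(interp, kern, y_gen, rownames(W))
  expect_gt(cor(pred2, y_gen), 0.999)

  # zero phenotypic variance: lambda = Inf convention, u = 0
  y_flat <- setNames(rep(2.5, n), rownames(W))
  fit3 <- fit_gblup(kern, y_flat)
  expect_identical(fit3$lambda_hat, Inf)
  expect_true(all(fit3$u_hat == 0))
  expect_equal(unname(predict_holdout(fit3, kern, y_flat, "s01")),
               2.5)
})

test_that("holdout prediction edge cases: zero covariance and near duplicates", {
  set.seed(104)
  ids <- sprintf("s%02d", 1:9)
  # block kernel: sample s09 unrelated to the rest
  G <- diag(9) * 0.5 + 0.5
  G[9, 1:8] <- 0; G[1:8, 9] <- 0
  dimnames(G) <- list(ids, ids)
  kern <- omicblup:::new_kernel(G, m = 10, layer = "toy")
  y <- setNames(rnorm(8, 10), ids[1:8])
  fit <- fit_gblup(kernel_subset(kern, ids[1:8]), y)
  expect_equal(unname(predict_holdout(fit, kern, y, "s09")), fit$mu_hat)
  expect_error(predict_holdout(fit, kern, y, "nope"), "missing from kernel")

  # a test sample whose kernel row duplicates a training sample's: with a
  # near-interpolating fit its prediction approaches that sample's phenotype
  W <- matrix(rnorm(10 * 40), 10, 40)
  W[10, ] <- W[1, ]
  rownames(W) <- sprintf("s%02d", 1:10); colnames(W) <- sprintf("f%d", 1:40)
  kern2 <- build_kernel(fm_of(W))
  y2 <- setNames(drop(scale(W[1:9, ]) %*% rnorm(40)), rownames(W)[1:9])
  fit2 <- fit_gblup(kernel_subset(kern2, names(y2)), y2)
  if (fit2$lambda_hat < 1e-3) {
    pred2 <- predict_holdout(fit2, kern2, y2, "s10")
    expect_equal(unname(pred2), unname(y2["s01"]), tolerance = 0.1)
  }
})

test_that("prediction ability conventions", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(as.numeric(prediction_ability(y, y)), 1)
  expect_equal(as.numeric(prediction_ability(y, -y)), -1)
  flat <- prediction_ability(y, rep(1, 5))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "constant_prediction"))
  expect_error(prediction_ability(1:2, 1:2), "3 pairs")
})

test_that("fold partitions are balanced, exhaustive, and seed-reproducible", {
  ids <- sprintf("g%02d", 1:22)
  folds <- make_cv_folds(ids, 5, 10, base_seed = 3)
  for (part in folds) {
    sizes <- sort(lengths(part), decreasing = TRUE)
    expect_equal(sizes, c(5, 5, 4, 4, 4))
    expect_setequal(unlist(part), ids)
  }
  folds2 <- make_cv_folds(ids, 5, 10, base_seed = 3)
  expect_identical(folds, folds2)
  expect_false(identical(folds[[1]], folds[[2]]))
})

test_that("cross-validation recovers a noiseless kernel trait and summarises by medians", {
  cfg <- panel_config(seed = 31, trait_h2 = c(T = 1))
  g <- simulate_genotypes(cfg)
  p <- simulate_phenotypes(g, cfg)
  y <- fit_entry_means(p$observations, "T")$means
  kern <- layer_kernel(g$genotypes)
  cv <- cross_validate(kern, y, n_replicates = 10, base_seed = 5)
  expect_gt(cv$median_of_medians, 0.5)
  # median-of-medians summarises the ability table correctly
  med <- cv$abilities |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(m = median(ability))
  expect_equal(cv$median_of_medians, median(med$m))
  expect_true(all(cv$abilities$ability >= -1 & cv$abilities$ability <= 1))
})
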