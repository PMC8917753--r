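make_obs <- function(n_geno = 6, n_env = 3, reps = 2, seed = 1,
                     s2G = 1, s2E = 0.5, s2GxE = 0.4, s2e = 0.8) {
  set.seed(seed)
  g <- rnorm(n_geno, 0, sqrt(s2G))
  e <- rnorm(n_env, 0, sqrt(s2E))
  gxe <- matrix(rnorm(n_geno * n_env, 0, sqrt(s2GxE)), n_geno, n_env)
  d <- expand.grid(genotype = sprintf("g%d", 1:n_geno),
                   environment = sprintf("e%d", 1:n_env),
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  gi <- as.integer(sub("g", "", d$genotype))
  ej <- as.integer(sub("e", "", d$environment))
  d$trait <- "T"
  d$value <- 5 + g[gi] + e[ej] + gxe[cbind(gi, ej)] +
    rnorm(nrow(d), 0, sqrt(s2e))
  tibble::as_tibble(d)
}

test_that("balanced designs give adjusted means equal to raw genotype means", {
  obs <- make_obs(seed = 2)
  em <- fit_entry_means(obs, "T")
  raw <- tapply(obs$value, obs$genotype, mean)
  expect_equal(em$means[names(raw)], c(raw), tolerance = 1e-8)
  expect_identical(em$model_used, "multi_env")

  # single-environment: genotype A with replicates 2 and 4 has mean 3
  single <- tibble::tibble(genotype = c("A", "A", "B", "B"),
                           environment = "e1", replicate = c(1, 2, 1, 2),
                           trait = "M1", value = c(2, 4, 1, 5))
  em1 <- fit_entry_means(single)
  expect_equal(unname(em1$means["A"]), 3)
  expect_identical(em1$model_used, "single_env")
})

test_that("unbalanced adjusted means match an explicit GLS oracle", {
  obs <- make_obs(n_geno = 8, n_env = 4, reps = 3, seed = 3)
  obs <- obs[-sample(nrow(obs), 20), ]  # knock out cells -> unbalanced
  em <- fit_entry_means(obs, "T")
  vc <- estimate_genetic_variance(obs, "T")

  # oracle: GLS with V assembled directly from the design and the REML
  # components of the genotype-fixed fit (recovered here via lme4 on the
  # same model, then explicit matrix algebra -- an independent solve path)
  fit <- lme4::lmer(value ~ 0 + genotype + (1 | environment) +
                      (1 | genotype:environment), data = obs, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(fit))
  s2E <- vcs$vcov[vcs$grp == "environment"]
  s2GxE <- vcs$vcov[vcs$grp == "genotype:environment"]
  s2e <- vcs$vcov[vcs$grp == "Residual"]
  X <- model.matrix(~ 0 + genotype, obs)
  Ze <- model.matrix(~ 0 + environment, obs)
  Zge <- model.matrix(~ 0 + genotype:environment, obs)
  V <- s2E * tcrossprod(Ze) + s2GxE * tcrossprod(Zge) +
    s2e * diag(nrow(obs))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% obs$value)
  C <- solve(t(X) %*% Vi %*% X)
  gnames <- sub("^genotype", "", rownames(beta))
  expect_equal(unname(em$means[gnames]), unname(drop(beta)),
               tolerance = 1e-6)
  expect_equal(unname(diag(em$vcov)[gnames]), unname(diag(C)),
               tolerance = 1e-6)
})

test_that("balanced single-environment REML equals the EMS-ANOVA closed form", {
  set.seed(4)
  n_geno <- 10; reps <- 4
  d <- tibble::tibble(
    genotype = rep(sprintf("g%d", 1:n_geno), each = reps),
    environment = "e1",
    replicate = rep(1:reps, n_geno),
    trait = "T",
    value = rep(rnorm(n_geno, 0, 1.5), each = reps) + rnorm(n_geno * reps)
  )
  vc <- estimate_genetic_variance(d, "T")
  a <- anova(aov(value ~ genotype, data = d))
  ms_g <- a["genotype", "Mean Sq"]; ms_e <- a["Residuals", "Mean Sq"]
  expect_equal(vc$sigma2_G, max((ms_g - ms_e) / reps, 0), tolerance = 1e-6)
  expect_equal(vc$sigma2_e, ms_e, tolerance = 1e-6)
})

test_that("variance components are recovered in the noiseless limit", {
  cfg <- sim_config(n_inbreds = 15, n_variants = 60, n_genes = 15,
                    n_environments = 3, reps_per_env = 2,
                    trait_h2 = c(T1 = 1), seed = 5)
  g <- simulate_genotypes(cfg)
  p <- simulate_phenotypes(g, cfg)
  vc <- estimate_genetic_variance(p$observations)
  expect_lt(vc$sigma2_e, 1e-8)
  true_var <- var(p$truth$genetic_values[, 1])
  expect_equal(vc$sigma2_G, true_var, tolerance = 0.02)

  # all-identical observations are degenerate, all components zero
  d <- tibble::tibble(genotype = rep(c("a", "b"), each = 2),
                      environment = "e1", replicate = c(1, 2, 1, 2),
                      trait = "T", value = 1)
  vc0 <- estimate_genetic_variance(d)
  expect_true(vc0$degenerate)
  expect_equal(vc0$sigma2_G, 0)
})

test_that("entry-mean heritability formula and bounds", {
  expect_equal(heritability_entry_mean(3, 2), 0.75)
  expect_equal(as.numeric(heritability_entry_mean(0, 2)), 0)
  h00 <- heritability_entry_mean(0, 0)
  expect_equal(as.numeric(h00), 0)
  expect_true(attr(h00, "degenerate"))
  # balanced single environment with r replicates: nu_bar = 2 sigma2_e / r,
  # so sigma2_G = 1, sigma2_e = 1, r = 2 gives H2 = 2/3
  expect_equal(heritability_entry_mean(1, 2 * 1 / 2), 2 / 3)
  # monotone in sigma2_G for fixed nu_bar
  h <- vapply(seq(0, 5, by = 0.5), heritability_entry_mean, 0, nu_bar = 1)
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 0 & h <= 1))
})

test_that("nu_bar matches the balanced closed form", {
  # balanced single env: var(mean_i - mean_j) = 2 sigma2_e / r for all pairs
  set.seed(6)
  d <- tibble::tibble(
    genotype = rep(sprintf("g%d", 1:5), each = 3), environment = "e1",
    replicate = rep(1:3, 5), trait = "T",
    value = rep(rnorm(5), each = 3) + rnorm(15, 0, 2)
  )
  em <- fit_entry_means(d)
  s2e <- estimate_genetic_variance(d)$sigma2_e
  # lm residual variance (genotype fixed) equals the single-env REML residual
  s2e_lm <- summary(lm(value ~ 0 + genotype, d))$sigma^2
  expect_equal(em$nu_bar, 2 * s2e_lm / 3, tolerance = 1e-8)
})

test_that("correlations carry exact r and the star coding of the t-test", {
  set.seed(7)
  x <- rnorm(23)
  expect_equal(correlate(cbind(a = x, b = x))$r["a", "b"], 1)
  y <- rnorm(23)
  y_orth <- residuals(lm(y ~ x))
  co <- correlate(cbind(a = x, b = y_orth))
  expect_equal(co$r["a", "b"], 0, tolerance = 1e-12)
  expect_identical(co$stars["a", "b"], "")

  # r = 0.685 at n = 23 is significant beyond the 0.001 threshold
  xs <- scale(x)[, 1]
  z <- scale(residuals(lm(y ~ x)))[, 1]
  yc <- 0.685 * xs + sqrt(1 - 0.685^2) * z
  co2 <- correlate(cbind(a = xs, b = yc))
  expect_equal(co2$r["a", "b"], 0.685, tolerance = 1e-10)
  expect_lt(co2$p["a", "b"], 0.001)
  expect_identical(co2$stars["a", "b"], "***")

  # zero-variance column: correlation undefined, reported missing
  co3 <- correlate(cbind(a = x, b = rep(1, 23)))
  expect_true(is.na(co3$r["a", "b"]))
})

test_that("metabolite filtering keeps max-H2 duplicates and nests the groups", {
  tab <- tibble::tibble(
    metabolite = c("m1", "m2", "m3", "m4", "m5"),
    H2 = c(0.3, 0.7, 0.05, 0.15, 0.65),
    identity = c("glu", "glu", NA, NA, NA)
  )
  out <- filter_metabolites(tab)
  expect_false("m1" %in% out$retained$metabolite)  # 0.3 < 0.7 duplicate
  expect_true("m2" %in% out$retained$metabolite)
  # thresholds: {0.05, 0.15, 0.65, 0.7} -> M_0.1 has 3, M_0.6 has 2
  expect_length(out$datasets$M_0.1, 3)
  expect_length(out$datasets$M_0.6, 2)
  expect_length(out$datasets$M, 4)
  # strict nesting M_0.8 subset of ... subset of M
  sets <- out$datasets
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})
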