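test_that("simulation is bit-identical under the same configuration", {
  cfg <- sim_config(n_inbreds = 10, n_variants = 50, n_genes = 15,
                    n_metabolites = 4, seed = 7)
  a <- simulate_multiomic(cfg)
  b <- simulate_multiomic(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$expression$GE_s$values, b$expression$GE_s$values)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$phenotypes, b$phenotypes)
  # a different seed actually changes the data
  cfg2 <- sim_config(n_inbreds = 10, n_variants = 50, n_genes = 15,
                     n_metabolites = 4, seed = 8)
  expect_false(identical(simulate_genotypes(cfg2)$genotypes$values,
                         a$genotypes$values))
})

test_that("genotypes respect the deleterious fraction and its boundary", {
  cfg0 <- sim_config(n_inbreds = 8, n_variants = 200, n_genes = 20,
                     fraction_deleterious = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0)
  expect_true(all(g0$genotypes$feature_meta$sift_score > 0.05))

  cfg <- sim_config(n_inbreds = 8, n_variants = 10000, n_genes = 100,
                    fraction_deleterious = 0.12, seed = 3)
  g <- simulate_genotypes(cfg)
  n_del <- sum(g$genotypes$feature_meta$sift_score <= 0.05)
  # the generator rounds the expected count; a binomial 99% interval around
  # np = 1200 must contain it
  interval <- qbinom(c(0.005, 0.995), 10000, 0.12)
  expect_gte(n_del, interval[1])
  expect_lte(n_del, interval[2])
})

test_that("genotype structure: biallelic inbred coding, genes covered, errors", {
  s <- small_sim(seed = 4)
  g <- s$geno
  vals <- g$genotypes$values
  expect_true(all(vals %in% c(0, 1) | is.na(vals)))
  # every gene carries at least one variant inside its span
  meta <- g$genotypes$feature_meta
  expect_setequal(unique(meta$gene_id), g$gene_models$gene_id)
  idx <- match(meta$gene_id, g$gene_models$gene_id)
  expect_true(all(meta$pos >= g$gene_models$start[idx] &
                    meta$pos <= g$gene_models$end[idx]))
  # deleterious variants have larger effects by construction
  expect_gt(mean(abs(g$truth$variant_effects[g$truth$deleterious])),
            mean(abs(g$truth$variant_effects[!g$truth$deleterious])))
  expect_error(sim_config(n_variants = 5, n_genes = 10), "n_variants")
})

test_that("transcript expression sums exactly to gene expression", {
  s <- small_sim(seed = 5)
  e <- simulate_expression(s$geno, s$config)
  for (te in list(e$TE_s, e$TE_l)) {
    ge <- if (identical(te$layer, "TE_s")) e$GE_s else e$GE_l
    by_gene <- split(seq_len(ncol(te$values)), te$feature_meta$gene_id)
    for (gid in names(by_gene)) {
      sums <- rowSums(te$values[, by_gene[[gid]], drop = FALSE])
      expect_equal(sums, ge$values[, gid], tolerance = 1e-12)
    }
  }
  expect_true(all(e$GE_s$values >= 0))
})

test_that("tissue divergence controls cross-tissue agreement", {
  cfg <- sim_config(n_inbreds = 15, n_variants = 100, n_genes = 30,
                    tissue_divergence = 0, expr_noise_sd = 0.05,
                    epav_fraction = 0, seed = 6)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  cors <- vapply(seq_len(30), function(j)
    cor(e$GE_s$values[, j], e$GE_l$values[, j]), 0)
  expect_gt(median(cors, na.rm = TRUE), 0.9)
})

test_that("degenerate expression: zero effects and zero noise are constant", {
  cfg <- sim_config(n_inbreds = 10, n_variants = 40, n_genes = 10,
                    expr_noise_sd = 0, epav_fraction = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  g$truth$variant_effects[] <- 0
  e <- simulate_expression(g, cfg)
  expect_true(all(apply(e$GE_s$values, 2, function(x) diff(range(x))) < 1e-12))
})

test_that("metabolite targets: h2 = 1 errors, h2 = 0 carries no genetic signal", {
  s <- small_sim(seed = 10)
  e <- simulate_expression(s$geno, s$config)
  expect_error(simulate_metabolites(e, s$config, h2_targets = 1),
               "unreachable")
  m0 <- simulate_metabolites(e, s$config, h2_targets = rep(0, 3))
  expect_true(all(m0$truth$genetic_values == 0))
})

test_that("metabolite heritability targets are recovered on average", {
  # 60 metabolites at target 0.8, 4 replicates each; mean estimated
  # entry-mean H2 must sit within +/-0.05 of the target
  cfg <- sim_config(n_inbreds = 22, n_variants = 80, n_genes = 20,
                    seed = 11)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  m <- simulate_metabolites(e, cfg, h2_targets = rep(0.8, 60))
  est <- estimate_heritability(m$observations)
  expect_lt(abs(mean(est$H2) - 0.8), 0.05)

  # zero targets: the H2 estimate under a true null at 22 genotypes and 4
  # replicates follows roughly 1 - 1/F with F ~ F(21, 66), so the
  # distribution hugs zero but keeps a long right tail
  m0 <- simulate_metabolites(e, cfg, h2_targets = rep(0, 40))
  est0 <- estimate_heritability(m0$observations)
  expect_lt(median(est0$H2), 0.2)
  expect_gte(mean(est0$H2 < 0.5), 0.85)
})

test_that("phenotypes follow the balanced mixed-model structure", {
  cfg <- sim_config(n_inbreds = 8, n_variants = 40, n_genes = 10,
                    n_environments = 3, reps_per_env = 2,
                    trait_h2 = c(T1 = 1), seed = 12)
  g <- simulate_genotypes(cfg)
  p <- simulate_phenotypes(g, cfg)
  obs <- p$observations
  # balanced: every genotype x environment x replicate cell exactly once
  expect_equal(nrow(obs), 8 * 3 * 2)
  expect_equal(max(table(obs$genotype, obs$environment)), 2)
  # noiseless limit: y = mu + G_i + E_j exactly, so within-cell range is 0
  cell_range <- tapply(obs$value, paste(obs$genotype, obs$environment),
                       function(x) diff(range(x)))
  expect_true(all(cell_range < 1e-12))
  # and the genotype means differ by exactly the true genetic values
  gm <- tapply(obs$value, obs$genotype, mean)[rownames(p$truth$genetic_values)]
  expect_equal(as.numeric(gm - mean(gm)), unname(p$truth$genetic_values[, 1]),
               tolerance = 1e-10)
})

test_that("traits sharing causal variants have correlated entry means", {
  cfg <- panel_config(trait_h2 = c(A = 0.9, B = 0.9), seed = 13)
  g <- simulate_genotypes(cfg)
  set.seed(99)
  shared <- sample(colnames(g$truth$geno_complete), 240)
  own_a <- sample(setdiff(colnames(g$truth$geno_complete), shared), 50)
  own_b <- sample(setdiff(colnames(g$truth$geno_complete), c(shared, own_a)), 50)
  p <- simulate_phenotypes(g, cfg, causal_sets = list(A = c(shared, own_a),
                                                      B = c(shared, own_b)))
  em_a <- fit_entry_means(p$observations, "A")$means
  em_b <- fit_entry_means(p$observations, "B")$means
  expect_gt(cor(em_a, em_b[names(em_a)]), 0)
})
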