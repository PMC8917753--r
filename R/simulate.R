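#' Configuration for the multi-omic simulator
#'
#' Bundles every parameter of the synthetic multi-omic dataset: a small panel
#' of fully homozygous inbred lines genotyped at biallelic variants arranged
#' in per-gene linkage blocks, two-tissue gene- and transcript-level
#' expression driven by the genotypes, metabolites downstream of expression
#' with per-metabolite target heritabilities, and multi-environment replicated
#' phenotypes with genotype-by-environment interaction. Defaults emulate a
#' spring barley diversity panel: 23 inbreds, seven environments, and
#' metabolite heritabilities spanning 0 to 0.98 with greenhouse
#' quadruplicates.
#'
#' @param n_inbreds Number of inbred lines (default 23).
#' @param n_variants Number of biallelic variants; must be at least `n_genes`
#'   so every gene carries a variant.
#' @param n_genes Number of gene models.
#' @param transcripts_per_gene Maximum transcripts per gene; each gene draws
#'   its transcript count uniformly from `1:transcripts_per_gene`.
#' @param fraction_deleterious Fraction of variants flagged deleterious
#'   (SIFT-like score <= 0.05) and given larger effects.
#' @param fraction_missing Fraction of genotype entries masked as missing.
#' @param n_metabolites Number of metabolites.
#' @param metabolite_h2_range Interval in \[0, 1) from which per-metabolite
#'   target entry-mean heritabilities are drawn.
#' @param metabolite_reps Replicates per genotype in the single-environment
#'   metabolite experiment (default 4, a greenhouse quadruplicate).
#' @param n_environments Number of phenotyping environments.
#' @param reps_per_env Replicates per genotype within each environment.
#' @param trait_h2 Named vector of target entry-mean heritabilities, one per
#'   phenotypic trait; each in \[0, 1\] (1 = exact noiseless limit).
#' @param tissue_divergence Proportion of genes with tissue-specific
#'   expression shifts between seedling and leaf.
#' @param expr_noise_sd Standard deviation of the expression noise on the
#'   latent (pre-softplus) scale.
#' @param epav_fraction Baseline probability that an (inbred, gene, tissue)
#'   expression value is zeroed; the realised probability decreases with the
#'   genetic value so presence/absence carries signal.
#' @param block_r Within-gene linkage: probability that a variant copies its
#'   gene's block haplotype rather than segregating independently.
#' @param seed Integer seed; one seed fans out to fixed per-stage child seeds
#'   so each stage is individually reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_inbreds = 23, n_variants = 1500, n_genes = 150,
                       transcripts_per_gene = 4,
                       fraction_deleterious = 0.12,
                       fraction_missing = 0.02,
                       n_metabolites = 60,
                       metabolite_h2_range = c(0, 0.98),
                       metabolite_reps = 4,
                       n_environments = 7, reps_per_env = 2,
                       trait_h2 = c(LA = 0.91, PH = 0.83, HT = 0.90),
                       tissue_divergence = 0.3,
                       expr_noise_sd = 0.3,
                       epav_fraction = 0.15,
                       block_r = 0.85,
                       seed = 1L) {
  cfg <- list(
    n_inbreds = n_inbreds, n_variants = n_variants, n_genes = n_genes,
    transcripts_per_gene = transcripts_per_gene,
    fraction_deleterious = fraction_deleterious,
    fraction_missing = fraction_missing,
    n_metabolites = n_metabolites,
    metabolite_h2_range = metabolite_h2_range,
    metabolite_reps = metabolite_reps,
    n_environments = n_environments, reps_per_env = reps_per_env,
    trait_h2 = trait_h2,
    tissue_divergence = tissue_divergence,
    expr_noise_sd = expr_noise_sd,
    epav_fraction = epav_fraction,
    block_r = block_r,
    seed = as.integer(seed)
  )
  counts <- c("n_inbreds", "n_variants", "n_genes", "transcripts_per_gene",
              "n_metabolites", "metabolite_reps", "n_environments",
              "reps_per_env")
  for (f in counts)
    if (cfg[[f]] < 1) stop("`", f, "` must be >= 1")
  props <- c("fraction_deleterious", "fraction_missing", "tissue_divergence",
             "epav_fraction", "block_r")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("`", f, "` must be in [0, 1]")
  if (any(metabolite_h2_range < 0) || any(metabolite_h2_range > 1) ||
      diff(metabolite_h2_range) < 0)
    stop("`metabolite_h2_range` must be an interval within [0, 1]")
  if (any(trait_h2 < 0) || any(trait_h2 > 1))
    stop("`trait_h2` must lie in [0, 1]")
  if (n_variants < n_genes)
    stop("`n_variants` must be >= `n_genes` (each gene needs a variant)")
  if (is.null(names(cfg$trait_h2)))
    names(cfg$trait_h2) <- paste0("trait", seq_along(cfg$trait_h2))
  class(cfg) <- "sim_config"
  cfg
}

# per-stage child seeds: one master seed, fixed offsets
stage_seed <- function(config, stage) {
  offsets <- c(genotypes = 101L, expression = 202L, metabolites = 303L,
               phenotypes = 404L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Simulate inbred genotypes, gene models, and variant effects
#'
#' Generates fully homozygous biallelic genotypes coded 0/1 for a panel of
#' inbred lines. Variants are placed inside gene models laid out along seven
#' chromosomes; variants within a gene share a linkage block (each variant
#' copies the gene's block haplotype with probability `block_r`). A stated
#' fraction of variants is flagged deleterious with SIFT-like scores at or
#' below 0.05 and effect sizes drawn with a larger spread than tolerant
#' variants; a small fraction of genotype entries is masked missing.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [feature_matrix()] of layer `"SV"` whose
#'   `feature_meta` carries `gene_id`, `chrom`, `pos`, `sift_score`),
#'   `gene_models` (tibble: `gene_id`, `chrom`, `strand`, `start`, `end`), and
#'   `truth` (complete genotype matrix before masking, per-variant effects,
#'   deleterious flags).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genotypes"))
  n <- config$n_inbreds
  p <- config$n_variants
  ng <- config$n_genes

  inbreds <- sprintf("inbred_%02d", seq_len(n))
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  chrom <- sprintf("chr%dH", 1 + (seq_len(ng) - 1L) %% 7L)
  len <- sample(800:6000, ng, replace = TRUE)
  # sequential layout per chromosome with intergenic gaps
  start <- integer(ng)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    gaps <- sample(500:5000, length(idx), replace = TRUE)
    start[idx] <- cumsum(gaps + c(0L, len[idx][-length(idx)]))
  }
  gene_models <- tibble::tibble(
    gene_id = gene_ids, chrom = chrom,
    strand = sample(c("+", "-"), ng, replace = TRUE),
    start = start, end = start + len - 1L
  )

  # every gene gets one variant, remaining variants spread at random
  gene_of <- c(seq_len(ng), sample.int(ng, p - ng, replace = TRUE))
  gene_of <- sort(gene_of)
  pos <- integer(p)
  for (g in seq_len(ng)) {
    idx <- which(gene_of == g)
    pos[idx] <- sort(sample(seq(gene_models$start[g], gene_models$end[g]),
                            length(idx)))
  }

  # linkage blocks: one block haplotype per (inbred, gene)
  block <- matrix(stats::rbinom(n * ng, 1L, 0.5), n, ng)
  geno <- matrix(0L, n, p, dimnames = list(inbreds, sprintf("var_%05d", seq_len(p))))
  copies <- matrix(stats::rbinom(n * p, 1L, config$block_r), n, p) == 1L
  indep <- matrix(stats::rbinom(n * p, 1L, 0.5), n, p)
  for (k in seq_len(p)) {
    bk <- block[, gene_of[k]]
    geno[, k] <- ifelse(copies[, k], bk, indep[, k])
  }

  n_del <- round(config$fraction_deleterious * p)
  del <- rep(FALSE, p)
  if (n_del > 0) del[sample.int(p, n_del)] <- TRUE
  sift <- numeric(p)
  sift[del] <- stats::runif(sum(del), 0, 0.05)
  sift[!del] <- 0.05 + stats::runif(sum(!del)) * 0.95

  effects <- stats::rnorm(p)
  effects[del] <- effects[del] * 2.5

  masked <- geno * 1.0
  n_miss <- round(config$fraction_missing * length(masked))
  if (n_miss > 0) masked[sample.int(length(masked), n_miss)] <- NA_real_

  meta <- tibble::tibble(
    feature_id = colnames(geno),
    gene_id = gene_ids[gene_of],
    chrom = gene_models$chrom[gene_of],
    pos = pos,
    sift_score = sift
  )
  list(
    genotypes = feature_matrix(masked, layer = "SV", feature_meta = meta),
    gene_models = gene_models,
    truth = list(
      geno_complete = geno,
      variant_effects = stats::setNames(effects, colnames(geno)),
      deleterious = stats::setNames(del, colnames(geno)),
      variant_gene = stats::setNames(gene_ids[gene_of], colnames(geno))
    )
  )
}

#' Simulate two-tissue gene- and transcript-level expression
#'
#' Each gene's expression per inbred is `softplus(` baseline + standardized
#' cis genetic value + tissue shift + Gaussian noise `)`, a non-negative
#' FPKM-like value. A `tissue_divergence` fraction of genes receives a
#' tissue-specific shift for leaf relative to seedling. Presence/absence
#' structure is injected by zeroing each (inbred, gene, tissue) value with a
#' probability that decreases with the genetic value, so absence calls carry
#' genetic signal. Transcript values are a random isoform split of the gene
#' value; by construction gene expression equals the sum of its transcript
#' expressions exactly.
#'
#' @param sim Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return List of four [feature_matrix()] objects: `GE_s`, `GE_l`
#'   (genes), `TE_s`, `TE_l` (transcripts, with `gene_id` metadata), plus
#'   `truth` holding the noise-free per-gene genetic values.
#' @export
simulate_expression <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "expression"))
  geno <- sim$truth$geno_complete
  gene_ids <- sim$gene_models$gene_id
  n <- nrow(geno)
  ng <- length(gene_ids)
  gene_of <- sim$truth$variant_gene
  effects <- sim$truth$variant_effects

  z <- matrix(0, n, ng, dimnames = list(rownames(geno), gene_ids))
  for (g in seq_len(ng)) {
    k <- which(gene_of == gene_ids[g])
    zg <- geno[, k, drop = FALSE] %*% effects[k]
    s <- stats::sd(zg)
    z[, g] <- if (s > 0) (zg - mean(zg)) / s else 0
  }

  baseline <- stats::rnorm(ng, mean = 2, sd = 1)
  diverged <- stats::runif(ng) < config$tissue_divergence
  shift_l <- ifelse(diverged, stats::rnorm(ng, 0, 2), 0)

  mk_tissue <- function(shift, tag) {
    eta <- sweep(z, 2L, baseline + shift, "+") +
      matrix(stats::rnorm(n * ng, 0, config$expr_noise_sd), n, ng)
    ge <- softplus(eta)
    # drop-out probability decreasing in genetic value
    p_zero <- config$epav_fraction * 2 * stats::plogis(-1.5 * z)
    ge[matrix(stats::runif(n * ng), n, ng) < p_zero] <- 0
    dimnames(ge) <- list(rownames(geno), gene_ids)
    feature_matrix(ge, layer = tag,
                   feature_meta = tibble::tibble(feature_id = gene_ids,
                                                 gene_id = gene_ids))
  }
  ge_s <- mk_tissue(0, "GE_s")
  ge_l <- mk_tissue(shift_l, "GE_l")

  n_tx <- sample.int(config$transcripts_per_gene, ng, replace = TRUE)
  split_tx <- function(ge, tag) {
    cols <- vector("list", ng)
    ids <- vector("list", ng)
    genes <- vector("list", ng)
    for (g in seq_len(ng)) {
      t <- n_tx[g]
      props <- matrix(stats::rgamma(n * t, shape = 2), n, t)
      props <- props / rowSums(props)
      vals <- ge$values[, g] * props
      if (t > 1) # force exact conservation against fp rounding
        vals[, t] <- ge$values[, g] - rowSums(vals[, -t, drop = FALSE])
      cols[[g]] <- vals
      ids[[g]] <- sprintf("%s.t%d", gene_ids[g], seq_len(t))
      genes[[g]] <- rep(gene_ids[g], t)
    }
    te <- do.call(cbind, cols)
    dimnames(te) <- list(rownames(geno), unlist(ids))
    feature_matrix(te, layer = tag,
                   feature_meta = tibble::tibble(feature_id = unlist(ids),
                                                 gene_id = unlist(genes)))
  }
  list(GE_s = ge_s, GE_l = ge_l,
       TE_s = split_tx(ge_s, "TE_s"), TE_l = split_tx(ge_l, "TE_l"),
       truth = list(gene_genetic_value = z, n_transcripts = n_tx))
}

#' Simulate replicated metabolite observations downstream of expression
#'
#' Each metabolite's genotype-level value is a sparse linear combination of
#' gene-expression columns, standardized to unit variance; replicate-level
#' Gaussian noise is scaled so the entry-mean heritability of the metabolite
#' in a single-environment design with `metabolite_reps` replicates matches
#' its target: for target \eqn{h^2} and \eqn{K} replicates the residual
#' variance is \eqn{K (1 - h^2) / h^2}. A target of 0 zeroes the genetic
#' component; a target of 1 is unreachable with finite replication and is an
#' error.
#'
#' @param expression Output of [simulate_expression()]; the seedling
#'   gene-expression matrix feeds the metabolites.
#' @param config The [sim_config()].
#' @param h2_targets Optional vector of target heritabilities overriding the
#'   draw from `config$metabolite_h2_range` (length = number of metabolites).
#' @return List with `observations` (tibble: `genotype`, `environment`,
#'   `replicate`, `trait`, `value`; one implicit environment) and `truth`
#'   (`target_h2`, genotype-level genetic values).
#' @export
simulate_metabolites <- function(expression, config, h2_targets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "metabolites"))
  ge <- expression$GE_s$values
  n <- nrow(ge)
  nm <- if (is.null(h2_targets)) config$n_metabolites else length(h2_targets)
  K <- config$metabolite_reps
  if (is.null(h2_targets))
    h2_targets <- stats::runif(nm, config$metabolite_h2_range[1],
                               config$metabolite_h2_range[2])
  if (any(h2_targets >= 1))
    stop("target heritability of 1 is unreachable with finite replicates")
  met_ids <- sprintf("met_%03d", seq_len(nm))
  gvals <- matrix(0, n, nm, dimnames = list(rownames(ge), met_ids))
  obs <- vector("list", nm)
  for (j in seq_len(nm)) {
    h2 <- h2_targets[j]
    if (h2 > 0) {
      genes <- sample.int(ncol(ge), min(3L, ncol(ge)))
      gv <- ge[, genes, drop = FALSE] %*% stats::rnorm(length(genes))
      s <- stats::sd(gv)
      gv <- if (s > 0) (gv - mean(gv)) / s else gv * 0
      sigma_e <- sqrt(K * (1 - h2) / h2)
    } else {
      gv <- rep(0, n)
      sigma_e <- 1
    }
    gvals[, j] <- gv
    vals <- rep(gv, each = K) + stats::rnorm(n * K, 0, sigma_e)
    obs[[j]] <- tibble::tibble(
      genotype = rep(rownames(ge), each = K),
      environment = "greenhouse",
      replicate = rep(seq_len(K), times = n),
      trait = met_ids[j],
      value = vals
    )
  }
  list(
    observations = dplyr::bind_rows(obs),
    truth = list(target_h2 = stats::setNames(h2_targets, met_ids),
                 genetic_values = gvals)
  )
}

#' Simulate multi-environment replicated phenotypes
#'
#' Observations follow
#' \deqn{y_{ijk} = \mu + G_i + E_j + (G \times E)_{ij} + \varepsilon_{ijk}}
#' in a balanced design (every genotype in every environment with equal
#' replication). Per-trait true genetic values are built from a random causal
#' subset of the simulated variants and standardized to unit variance; the
#' interaction and residual variances are then chosen so the entry-mean
#' heritability \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \bar\nu / 2)} with
#' \eqn{\bar\nu / 2 = \sigma^2_{G\times E}/J + \sigma^2_e/(JK)} matches the
#' target (J environments, K replicates per environment). The non-genetic
#' part is split 40/60 between interaction and residual.
#'
#' @param sim Output of [simulate_genotypes()].
#' @param config The [sim_config()]; `trait_h2` supplies one target per trait.
#' @param causal_sets Optional named list of variant-id vectors fixing each
#'   trait's causal variants (e.g. to give two traits overlapping
#'   architecture); default: each trait draws 30\% of variants at random.
#' @param genetic_values Optional matrix (genotypes x traits) of true genetic
#'   values overriding the draw from variant effects, for controlled
#'   experiments where traits must share identical architecture (e.g. two
#'   traits differing only in heritability). Columns are standardized to
#'   unit variance.
#' @return List with `observations` (tibble: `genotype`, `environment`,
#'   `replicate`, `trait`, `value`) and `truth` (per-trait true genetic value
#'   per genotype and the variance components used).
#' @export
simulate_phenotypes <- function(sim, config, causal_sets = NULL,
                                genetic_values = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "phenotypes"))
  geno <- sim$truth$geno_complete
  effects <- sim$truth$variant_effects
  n <- nrow(geno)
  J <- config$n_environments
  K <- config$reps_per_env
  traits <- names(config$trait_h2)
  envs <- sprintf("env_%d", seq_len(J))
  gvals <- matrix(0, n, length(traits),
                  dimnames = list(rownames(geno), traits))
  vc_used <- list()
  obs <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    h2 <- config$trait_h2[[t]]
    if (h2 > 0) {
      if (!is.null(genetic_values)) {
        gv <- genetic_values[, min(t, ncol(genetic_values))]
      } else {
        causal <- if (!is.null(causal_sets)) causal_sets[[traits[t]]] else
          sample(colnames(geno), round(0.3 * ncol(geno)))
        a <- effects[causal] * stats::rnorm(length(causal), 1, 0.3)
        gv <- drop(geno[, causal, drop = FALSE] %*% a)
      }
      s <- stats::sd(gv)
      gv <- if (s > 0) (gv - mean(gv)) / s else gv * 0
      # sigma2_G standardized to 1; h2 = 1 is the exact noiseless limit
      nongen <- (1 - h2) / h2
    } else {
      gv <- rep(0, n)
      nongen <- 1
    }
    s2_gxe <- 0.4 * nongen * J
    s2_e <- 0.6 * nongen * J * K
    gvals[, t] <- gv
    vc_used[[traits[t]]] <- c(sigma2_G = if (h2 > 0) 1 else 0,
                              sigma2_E = 1, sigma2_GxE = s2_gxe,
                              sigma2_e = s2_e)
    e_j <- stats::rnorm(J, 0, 1)
    gxe <- matrix(stats::rnorm(n * J, 0, sqrt(s2_gxe)), n, J)
    vals <- numeric(n * J * K)
    idx <- 1L
    df <- expand.grid(replicate = seq_len(K), environment = seq_len(J),
                      genotype = seq_len(n))
    vals <- 10 + gvals[df$genotype, t] + e_j[df$environment] +
      gxe[cbind(df$genotype, df$environment)] +
      stats::rnorm(nrow(df), 0, sqrt(s2_e))
    obs[[t]] <- tibble::tibble(
      genotype = rownames(geno)[df$genotype],
      environment = envs[df$environment],
      replicate = df$replicate,
      trait = traits[t],
      value = vals
    )
  }
  list(observations = dplyr::bind_rows(obs),
       truth = list(genetic_values = gvals, variance_components = vc_used))
}

#' Simulate a complete multi-omic dataset
#'
#' Runs the full generator: genotypes and gene models, two-tissue expression,
#' metabolites, and phenotypes, all from one [sim_config()]. Identical
#' configurations (including the seed) reproduce the output bit for bit.
#'
#' @param config A [sim_config()].
#' @return List with components `genotypes`, `gene_models`, `expression`
#'   (GE/TE for both tissues), `metabolites`, `phenotypes`, and `truth`.
#' @export
simulate_multiomic <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  e <- simulate_expression(g, config)
  m <- simulate_metabolites(e, config)
  p <- simulate_phenotypes(g, config)
  list(
    genotypes = g$genotypes,
    gene_models = g$gene_models,
    expression = e[c("GE_s", "GE_l", "TE_s", "TE_l")],
    metabolites = m$observations,
    phenotypes = p$observations,
    truth = c(g$truth, e$truth, m$truth["target_h2"],
              list(phenotype_genetic_values = p$truth$genetic_values,
                   phenotype_variance_components = p$truth$variance_components))
  )
}
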