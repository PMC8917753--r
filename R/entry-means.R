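#' Adjusted entry means for one trait
#'
#' Fits the multi-environment model
#' \deqn{y_{ijk} = \mu + E_j + G_i + (G \times E)_{ij} + \varepsilon_{ijk}}
#' with genotype effects fixed and environment and interaction effects random
#' (REML), and returns the adjusted entry means (the genotype BLUEs) together
#' with their variance-covariance matrix. With a single environment the model
#' reduces to genotype plus residual. With one replicate per cell the
#' interaction is confounded with the residual and is dropped.
#'
#' @param observations Long tibble with columns `genotype`, `environment`,
#'   `replicate`, `trait`, `value` (see [read_long_phenotypes()]).
#' @param trait Trait name to fit; may be omitted when only one trait is
#'   present.
#' @return An `entry_means` object: `trait`, `means` (named vector),
#'   `vcov` (variance-covariance of the means), `model_used`
#'   (`"multi_env"`/`"single_env"`), `nu_bar` (mean variance of a difference
#'   between two adjusted entry means), and `low_replication` flags for
#'   genotypes observed in a single cell of a multi-environment design.
#' @export
fit_entry_means <- function(observations, trait = NULL) {
  d <- one_trait(observations, trait)
  n_env <- dplyr::n_distinct(d$environment)
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  if (n_env >= 2) {
    max_cell <- max(table(d$genotype, d$environment))
    form <- if (max_cell > 1)
      value ~ 0 + genotype + (1 | environment) + (1 | genotype:environment)
    else
      value ~ 0 + genotype + (1 | environment)
    fit <- fit_lmer(form, d)
    means <- lme4::fixef(fit)
    C <- as.matrix(stats::vcov(fit))
    model_used <- "multi_env"
  } else {
    fit <- stats::lm(value ~ 0 + genotype, data = d)
    means <- stats::coef(fit)
    C <- stats::vcov(fit)
    model_used <- "single_env"
  }
  gnames <- sub("^genotype", "", names(means))
  names(means) <- gnames
  dimnames(C) <- list(gnames, gnames)
  cells <- dplyr::count(d, .data$genotype, .data$environment)
  n_cells <- table(cells$genotype)
  low_rep <- names(n_cells)[n_cells < 2] # one cell only
  structure(
    list(trait = unique(d$trait), means = means, vcov = C,
         model_used = model_used, nu_bar = nu_bar_from_vcov(C),
         low_replication = if (model_used == "multi_env") low_rep else character()),
    class = "entry_means"
  )
}

quiet_lmer <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore")
}

# muffle the optimizer roundoff warning emitted on numerically perfect fits
fit_lmer <- function(formula, data) {
  withCallingHandlers(
    lme4::lmer(formula, data = data, REML = TRUE, control = quiet_lmer()),
    warning = function(w) {
      if (grepl("ROUNDOFF", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

one_trait <- function(observations, trait) {
  stopifnot(all(c("genotype", "replicate", "trait", "value") %in%
                  names(observations)))
  if (!"environment" %in% names(observations))
    observations$environment <- "env_1"
  if (is.null(trait)) {
    tr <- unique(observations$trait)
    if (length(tr) > 1) stop("several traits present; supply `trait`")
    trait <- tr
  }
  d <- observations[observations$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait ", trait)
  d
}

#' @export
print.entry_means <- function(x, ...) {
  cat(sprintf("<entry_means> %s (%s): %d genotypes, nu_bar=%.4g\n",
              x$trait, x$model_used, length(x$means), x$nu_bar))
  invisible(x)
}

# mean over unordered genotype pairs of var(mean_i - mean_j)
nu_bar_from_vcov <- function(C) {
  n <- nrow(C)
  if (n < 2) return(0)
  dC <- diag(C)
  # sum over ordered pairs of C_ii + C_jj - 2 C_ij, halved twice for unordered mean
  total <- n * sum(dC) + n * sum(dC) - 2 * sum(C) # includes i == j (zero terms)
  total / (n * (n - 1))
}

#' REML variance components for one trait
#'
#' Refits the entry-mean model with genotype as a random effect and returns
#' the REML variance components. Negative estimates cannot occur (lme4
#' constrains components to be non-negative); boundary estimates come back
#' as exact zeros.
#'
#' @inheritParams fit_entry_means
#' @return A `variance_components` object: `sigma2_G`, `sigma2_E`,
#'   `sigma2_GxE` (NA for single-environment data), `sigma2_e`, `model_used`,
#'   and a `degenerate` flag when all observations are identical.
#' @export
estimate_genetic_variance <- function(observations, trait = NULL) {
  d <- one_trait(observations, trait)
  n_env <- dplyr::n_distinct(d$environment)
  out <- list(trait = unique(d$trait), sigma2_G = 0, sigma2_E = NA_real_,
              sigma2_GxE = NA_real_, sigma2_e = 0, degenerate = FALSE)
  if (stats::var(d$value) == 0) {
    out$degenerate <- TRUE
    out$model_used <- if (n_env >= 2) "multi_env" else "single_env"
    if (n_env >= 2) { out$sigma2_E <- 0; out$sigma2_GxE <- 0 }
    return(structure(out, class = "variance_components"))
  }
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  balanced <- length(unique(table(d$genotype, d$environment))) == 1L
  if (n_env >= 2) {
    max_cell <- max(table(d$genotype, d$environment))
    form <- if (max_cell > 1)
      value ~ 1 + (1 | genotype) + (1 | environment) + (1 | genotype:environment)
    else
      value ~ 1 + (1 | genotype) + (1 | environment)
    fit <- fit_lmer(form, d)
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(term) {
      v <- vc$vcov[vc$grp == term]
      if (length(v)) v else NA_real_
    }
    out$sigma2_G <- get("genotype")
    out$sigma2_E <- get("environment")
    out$sigma2_GxE <- get("genotype:environment")
    out$sigma2_e <- get("Residual")
    out$model_used <- "multi_env"
    # the profiled likelihood degenerates when the residual variance
    # vanishes (noiseless data); balanced designs then admit the exact
    # expected-mean-squares solution
    if (balanced && max_cell > 1 && out$sigma2_e < 1e-8) {
      ems <- ems_two_way(d)
      out[names(ems)] <- ems
    }
  } else {
    fit <- fit_lmer(value ~ 1 + (1 | genotype), d)
    vc <- as.data.frame(lme4::VarCorr(fit))
    out$sigma2_G <- vc$vcov[vc$grp == "genotype"]
    out$sigma2_e <- vc$vcov[vc$grp == "Residual"]
    out$model_used <- "single_env"
    if (balanced && out$sigma2_e < 1e-8) {
      r <- nrow(d) / nlevels(d$genotype)
      a <- suppressWarnings(
        stats::anova(stats::aov(value ~ genotype, data = d)))
      ms_g <- a["genotype", "Mean Sq"]
      ms_e <- a["Residuals", "Mean Sq"]
      out$sigma2_e <- ms_e
      out$sigma2_G <- max((ms_g - ms_e) / r, 0)
    }
  }
  structure(out, class = "variance_components")
}

# expected-mean-squares estimates for a balanced genotype x environment
# design with replication (random-effects two-way ANOVA)
ems_two_way <- function(d) {
  n <- nlevels(d$genotype)
  j <- nlevels(d$environment)
  k <- nrow(d) / (n * j)
  a <- suppressWarnings(
    stats::anova(stats::aov(value ~ genotype * environment, data = d)))
  ms_g <- a["genotype", "Mean Sq"]
  ms_env <- a["environment", "Mean Sq"]
  ms_gxe <- a["genotype:environment", "Mean Sq"]
  ms_e <- a["Residuals", "Mean Sq"]
  list(
    sigma2_e = ms_e,
    sigma2_GxE = max((ms_gxe - ms_e) / k, 0),
    sigma2_E = max((ms_env - ms_gxe) / (n * k), 0),
    sigma2_G = max((ms_g - ms_gxe) / (j * k), 0)
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> %s (%s): sigma2_G=%.4g, sigma2_e=%.4g%s\n",
    x$trait, x$model_used, x$sigma2_G, x$sigma2_e,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Entry-mean heritability
#'
#' \deqn{H^2 = \sigma^2_G / (\sigma^2_G + \bar\nu / 2)}
#' where \eqn{\bar\nu} is the mean variance of a difference between two
#' adjusted entry means (averaged over all unordered genotype pairs from the
#' variance-covariance matrix of the means). When both \eqn{\sigma^2_G} and
#' \eqn{\bar\nu} are zero the heritability is defined as 0 and flagged.
#'
#' @param sigma2_G Genetic variance (>= 0), e.g. from
#'   [estimate_genetic_variance()].
#' @param nu_bar Mean variance of a difference between two adjusted entry
#'   means (>= 0), e.g. from [fit_entry_means()].
#' @return Heritability in \[0, 1\] (attribute `degenerate` = TRUE in the
#'   0/0 case).
#' @export
heritability_entry_mean <- function(sigma2_G, nu_bar) {
  stopifnot(sigma2_G >= 0, nu_bar >= 0)
  if (sigma2_G == 0 && nu_bar == 0)
    return(structure(0, degenerate = TRUE))
  if (sigma2_G == 0) return(0)
  sigma2_G / (sigma2_G + nu_bar / 2)
}

#' Estimate entry-mean heritability for each trait in a dataset
#'
#' Convenience wrapper: for each trait, fits the genotype-fixed model for the
#' adjusted means and \eqn{\bar\nu}, the genotype-random model for
#' \eqn{\sigma^2_G}, and combines them with [heritability_entry_mean()].
#'
#' @param observations Long observation tibble.
#' @param traits Traits to process (default: all present).
#' @return Tibble with `trait`, `sigma2_G`, `nu_bar`, `H2`, `model_used`.
#' @export
estimate_heritability <- function(observations, traits = NULL) {
  if (is.null(traits)) traits <- unique(observations$trait)
  purrr::map_dfr(traits, function(tr) {
    em <- fit_entry_means(observations, tr)
    vc <- estimate_genetic_variance(observations, tr)
    tibble::tibble(
      trait = tr, sigma2_G = vc$sigma2_G, nu_bar = em$nu_bar,
      H2 = as.numeric(heritability_entry_mean(vc$sigma2_G, em$nu_bar)),
      model_used = em$model_used
    )
  })
}

#' Pairwise Pearson correlations with significance stars
#'
#' Correlates every pair of columns (traits and metabolite entry means) over
#' genotypes, with two-sided t-test p-values and the conventional star coding
#' (`*`, `**`, `***` at P < 0.05, 0.01, 0.001; no multiplicity correction).
#' Zero-variance columns yield undefined correlations, reported as `NA`.
#'
#' @param means Data frame whose first column is the genotype id and whose
#'   remaining numeric columns are per-genotype trait/metabolite means, or a
#'   plain numeric matrix with genotypes in rows.
#' @return An `omic_correlation` object with matrices `r`, `p`, `stars`.
#' @export
correlate <- function(means) {
  m <- if (is.matrix(means)) means else {
    stopifnot(is.data.frame(means))
    as.matrix(means[, -1, drop = FALSE])
  }
  if (nrow(m) < 3) stop("need at least 3 genotypes")
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(m[, i], m[, j])
      x <- m[ok, i]; y <- m[ok, j]
      if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = nrow(m)),
            class = "omic_correlation")
}

#' @export
print.omic_correlation <- function(x, ...) {
  cat(sprintf("<omic_correlation> %d variables over %d genotypes\n",
              ncol(x$r), x$n))
  invisible(x)
}

#' Collapse duplicate metabolites and build heritability-threshold groups
#'
#' When several measured compounds are annotated as the same metabolite, only
#' the one with the greatest entry-mean heritability is retained. The
#' retained set is then stratified into nested groups: all metabolites (`M`)
#' plus `M_0.1` ... `M_0.8`, where `M_t` keeps metabolites with heritability
#' strictly greater than `t`.
#'
#' @param metabolite_h2 Tibble with columns `metabolite`, `H2`, and
#'   optionally `identity` (annotation group; `NA` = unique compound).
#' @param thresholds Heritability thresholds (default 0.1 to 0.8 by 0.1).
#' @return List with `retained` (tibble after duplicate collapse) and
#'   `datasets` (named list of metabolite-id vectors, `M` first, strictly
#'   nested).
#' @export
filter_metabolites <- function(metabolite_h2,
                               thresholds = seq(0.1, 0.8, by = 0.1)) {
  stopifnot(all(c("metabolite", "H2") %in% names(metabolite_h2)))
  d <- tibble::as_tibble(metabolite_h2)
  if (!"identity" %in% names(d)) d$identity <- NA_character_
  dup_groups <- d[!is.na(d$identity), , drop = FALSE]
  singles <- d[is.na(d$identity), , drop = FALSE]
  kept_dups <- dup_groups |>
    dplyr::group_by(.data$identity) |>
    dplyr::slice_max(.data$H2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  retained <- dplyr::bind_rows(singles, kept_dups) |>
    dplyr::arrange(.data$metabolite)
  datasets <- c(
    list(M = retained$metabolite),
    stats::setNames(
      lapply(thresholds, function(t) retained$metabolite[retained$H2 > t]),
      sprintf("M_%.1f", thresholds)
    )
  )
  list(retained = retained, datasets = datasets)
}
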