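#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy an entry-means fit
#' @param x An `entry_means` object.
#' @param ... Unused.
#' @return Tibble with `genotype`, `estimate`, `std.error`.
#' @export
tidy.entry_means <- function(x, ...) {
  tibble::tibble(genotype = names(x$means),
                 estimate = unname(x$means),
                 std.error = sqrt(diag(x$vcov)))
}

#' @rdname tidy.entry_means
#' @export
glance.entry_means <- function(x, ...) {
  tibble::tibble(trait = x$trait, model_used = x$model_used,
                 n_genotypes = length(x$means), nu_bar = x$nu_bar)
}

#' Tidy a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Per-replicate-per-fold abilities (tidy) or a one-row summary
#'   (glance).
#' @export
tidy.cv_result <- function(x, ...) x$abilities

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(layer = x$layer,
                 n_replicates = nrow(x$median_per_replicate),
                 n_folds = x$n_folds,
                 median_of_medians = x$median_of_medians)
}

#' Tidy a grid-search result
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @return One row per weight vector with its ability (tidy); the optimal
#'   row (glance).
#' @export
tidy.grid_search_result <- function(x, ...) x$grid

#' @rdname tidy.grid_search_result
#' @export
glance.grid_search_result <- function(x, ...) tibble::as_tibble(x$best)

#' Tidy a correlation matrix with stars
#' @param x An `omic_correlation`.
#' @param ... Unused.
#' @return Long tibble: `var1`, `var2`, `r`, `p.value`, `stars`
#'   (upper-triangle pairs).
#' @export
tidy.omic_correlation <- function(x, ...) {
  k <- ncol(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = rownames(x$r)[idx[, 1]],
    var2 = colnames(x$r)[idx[, 2]],
    r = x$r[idx],
    p.value = x$p[idx],
    stars = x$stars[idx]
  )
}

#' Tidy a PCoA embedding
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return Tibble of item coordinates (tidy) or per-axis percent variance
#'   (glance).
#' @export
tidy.pcoa_result <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "item")
}

#' @rdname tidy.pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$percent_var),
                 percent_var = x$percent_var)
}

#' Tidy a dissimilarity matrix
#' @param x A `dissimilarity_matrix`.
#' @param ... Unused.
#' @return Long tibble of upper-triangle pairs.
#' @export
tidy.dissimilarity_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    item1 = rownames(x$matrix)[idx[, 1]],
    item2 = colnames(x$matrix)[idx[, 2]],
    dissimilarity = x$matrix[idx],
    source = x$source
  )
}

#' Tidy a 3'end comparison
#' @param x A `three_prime_result`.
#' @param ... Unused.
#' @return The per-(N, layer) comparison table.
#' @export
tidy.three_prime_result <- function(x, ...) x$table
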