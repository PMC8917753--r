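#' 3'end window of each gene
#'
#' Genomic interval covering the last `N` bases of each gene, strand-aware:
#' on the plus strand the window is `[max(start, end - N + 1), end]`, on the
#' minus strand `[start, min(end, start + N - 1)]`. Genes shorter than `N`
#' return their whole span. Coordinates are 1-based inclusive. `N = Inf` is
#' the full-length sentinel.
#'
#' @param gene_models Tibble of gene models (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`), e.g. from [read_gff3_genes()] or the simulator.
#' @param N Window size in bp (>= 1, or `Inf`).
#' @return The gene-model tibble with `win_start`, `win_end`, `win_length`
#'   columns appended.
#' @export
three_prime_window <- function(gene_models, N) {
  if (N < 1) stop("N must be >= 1")
  gm <- tibble::as_tibble(gene_models)
  plus <- gm$strand == "+"
  gm$win_start <- ifelse(plus, pmax(gm$start, gm$end - N + 1), gm$start)
  gm$win_end <- ifelse(plus, gm$end, pmin(gm$end, gm$start + N - 1))
  gm$win_start <- as.integer(gm$win_start)
  gm$win_end <- as.integer(gm$win_end)
  gm$win_length <- gm$win_end - gm$win_start + 1L
  gm
}

#' Subset variants to the 3'end windows
#'
#' Keeps variants whose genomic position lies inside their gene's 3'end
#' window (inclusive bounds). Variants without a gene annotation are
#' excluded and counted in the `n_unannotated` attribute.
#'
#' @param sv A variant [feature_matrix()] whose metadata has `gene_id` and
#'   `pos`.
#' @param windows Output of [three_prime_window()].
#' @return The windowed variant `feature_matrix` (attribute `n_retained`).
#' @export
subset_variants <- function(sv, windows) {
  stopifnot(inherits(sv, "feature_matrix"))
  meta <- sv$feature_meta
  if (is.null(meta) || is.null(meta$gene_id) || is.null(meta$pos))
    stop("variant metadata needs `gene_id` and `pos`")
  idx <- match(meta$gene_id, windows$gene_id)
  unannot <- is.na(idx)
  keep <- !unannot &
    meta$pos >= windows$win_start[idx] &
    meta$pos <= windows$win_end[idx]
  keep[is.na(keep)] <- FALSE
  out <- feature_matrix(sv$values[, keep, drop = FALSE], layer = sv$layer,
                        feature_meta = meta[keep, , drop = FALSE])
  attr(out, "n_unannotated") <- sum(unannot)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Re-quantify expression from a 3'end window by read thinning
#'
#' Models 3'end library quantification as Poisson read thinning: for each
#' (inbred, gene) a full-length read count is drawn as
#' `Poisson(depth * GE * L / 1000)`, each read start is uniform on the gene,
#' and the 3'end count is the number of reads falling in the window. The
#' count is re-normalized to an FPKM-like value on the window length
#' (`count / (depth * win_length / 1000)`), which makes the re-quantified
#' value unbiased for the original expression; before normalization the
#' expected window count is `depth * GE * L / 1000 * min(N, L) / L`. The
#' random draws depend only on the seed and the input ordering, never on
#' `N`, so windows of different sizes thin the same reads and `N >= L`
#' reproduces a full-length re-quantification exactly.
#'
#' @param ge Non-negative expression [feature_matrix()].
#' @param gene_models Gene models covering all columns of `ge`.
#' @param N Window size in bp (`Inf` = full length).
#' @param depth Sequencing depth scale (expected reads per FPKM unit per kb);
#'   default 20.
#' @param seed Integer seed.
#' @return A `feature_matrix` of re-quantified values (same layer tag).
#' @export
requantify_expression <- function(ge, gene_models, N, depth = 20, seed = 1) {
  stopifnot(inherits(ge, "feature_matrix"))
  v <- ge$values
  if (any(v < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  gm <- three_prime_window(gene_models, N)
  idx <- match(colnames(v), gm$gene_id)
  if (anyNA(idx)) stop("gene model missing for some expression columns")
  set.seed(seed)
  out <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    g <- idx[j]
    L <- gm$end[g] - gm$start[g] + 1L
    # window relative to the gene span, 1-based
    rel_lo <- gm$win_start[g] - gm$start[g] + 1L
    rel_hi <- gm$win_end[g] - gm$start[g] + 1L
    for (i in seq_len(nrow(v))) {
      lam <- depth * v[i, j] * L / 1000
      count <- stats::rpois(1L, lam)
      if (count > 0) {
        pos <- sample.int(L, count, replace = TRUE)
        hits <- sum(pos >= rel_lo & pos <= rel_hi)
      } else hits <- 0L
      out[i, j] <- hits / (depth * gm$win_length[g] / 1000)
    }
  }
  feature_matrix(out, layer = ge$layer, feature_meta = ge$feature_meta)
}

#' Compare 3'end prediction against the full-length baseline
#'
#' For each window size `N`, derives the 3'end variant subset, re-quantified
#' seedling expression, and the ePAV calls from the re-quantified expression;
#' builds the three kernels; and cross-validates each against the trait's
#' adjusted entry means with fold partitions shared across all window sizes
#' and the baseline. The baseline is the full-length sentinel `N = Inf`
#' processed through the identical machinery (same thinning seed), so a
#' finite `N` at least as long as every gene reproduces the baseline exactly.
#'
#' @param sv Full variant [feature_matrix()].
#' @param ge_s Full seedling expression [feature_matrix()].
#' @param gene_models Gene-model tibble.
#' @param y Named vector of adjusted entry means for one trait.
#' @param N_list Window sizes in bp (default the seven standard lengths
#'   200-500).
#' @param n_folds,n_replicates,base_seed CV settings.
#' @param depth,thin_seed Read-thinning parameters for
#'   [requantify_expression()].
#' @return A `three_prime_result`: tibble `table` with one row per
#'   (N, layer): `N` (`Inf` = baseline), `layer`, `median_ability`,
#'   `n_features`, `baseline_ability`, `delta`.
#' @export
three_prime_study <- function(sv, ge_s, gene_models, y,
                              N_list = c(200, 250, 300, 350, 400, 450, 500),
                              n_folds = 5, n_replicates = 20, base_seed = 1,
                              depth = 20, thin_seed = 1) {
  folds <- make_cv_folds(names(y), n_folds, n_replicates, base_seed)
  eval_at <- function(N) {
    windows <- three_prime_window(gene_models, N)
    sv_n <- subset_variants(sv, windows)
    ge_n <- requantify_expression(ge_s, gene_models, N, depth = depth,
                                  seed = thin_seed)
    epav_n <- epav_to_numeric(call_epav(ge_n, layer = "ePAV_s"))
    layers <- list(SV = sv_n, GE_s = ge_n, ePAV_s = epav_n)
    purrr::map_dfr(names(layers), function(nm) {
      fm <- layers[[nm]]
      kern <- layer_kernel(fm)
      cv <- cross_validate(kern, y, folds = folds)
      tibble::tibble(N = N, layer = nm, median_ability = cv$median_of_medians,
                     n_features = kern$m)
    })
  }
  baseline <- eval_at(Inf)
  per_n <- purrr::map_dfr(N_list, eval_at)
  tab <- dplyr::bind_rows(baseline, per_n) |>
    dplyr::left_join(
      dplyr::select(baseline, "layer", baseline_ability = "median_ability"),
      by = "layer"
    ) |>
    dplyr::mutate(delta = .data$median_ability - .data$baseline_ability)
  structure(list(table = tab, N_list = N_list, base_seed = base_seed),
            class = "three_prime_result")
}

#' @export
print.three_prime_result <- function(x, ...) {
  cat(sprintf("<three_prime_result> %d window sizes x %d layers (+ baseline)\n",
              length(x$N_list), dplyr::n_distinct(x$table$layer)))
  invisible(x)
}
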