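#' Read a feature matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids, and one
#' numeric cell per (feature, sample). Empty cells and the token `NA` are
#' missing. Features are rows on disk (the common wide layout for
#' marker/expression tables); the returned matrix is samples x features.
#'
#' @param path TSV file path.
#' @param layer Layer tag for the resulting [feature_matrix()].
#' @return A [feature_matrix()].
#' @export
read_feature_matrix_tsv <- function(path, layer = "unknown") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("TSV needs a header and at least one feature row")
  split_row <- function(l) { # keep trailing empty cells
    f <- strsplit(paste0(l, "\tx"), "\t", fixed = TRUE)[[1]]
    f[-length(f)]
  }
  header <- split_row(lines[1])
  samples <- header[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in header")
  n_col <- length(header)
  body <- lapply(seq_along(lines[-1]), function(i) {
    f <- split_row(lines[i + 1L])
    if (length(f) != n_col)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L, n_col, length(f)))
    f
  })
  feature_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  vals <- matrix(NA_real_, length(samples), length(feature_ids),
                 dimnames = list(samples, feature_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    missing <- cells == "" | cells == "NA"
    num <- suppressWarnings(as.numeric(cells))
    if (any(is.na(num) & !missing))
      stop(sprintf("line %d: non-numeric cell", i + 1L))
    vals[, i] <- num
  }
  feature_matrix(vals, layer = layer)
}

#' Write a feature matrix to TSV
#'
#' Inverse of [read_feature_matrix_tsv()]: features as rows, samples as
#' columns, missing entries written as `NA`.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix_tsv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- t(fm$values)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read biallelic inbred genotypes from a VCF
#'
#' Maps homozygous calls 0/0 to 0 and 1/1 to 1; `./.` is missing.
#' Heterozygous calls in inbred material are treated according to
#' `het_policy`: `"missing"` (default) recodes them missing and reports a
#' warning with the count; `"error"` aborts. Multi-allelic records are an
#' error unless `allow_multiallelic_drop = TRUE`, in which case they are
#' dropped with a warning. A per-variant SIFT score is read from the INFO
#' field named by `sift_key` when present.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sift_key INFO key holding the SIFT score (default `"SIFT"`).
#' @param het_policy `"missing"` or `"error"`.
#' @param allow_multiallelic_drop Drop multi-allelic records instead of
#'   erroring.
#' @return A [feature_matrix()] of layer `"SV"` with `gene_id` (when a
#'   `GENE` INFO key is present), `chrom`, `pos`, and `sift_score` metadata.
#' @export
read_vcf_genotypes <- function(path, sift_key = "SIFT",
                               het_policy = c("missing", "error"),
                               allow_multiallelic_drop = FALSE) {
  het_policy <- match.arg(het_policy)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # 1-row safety
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (!allow_multiallelic_drop)
      stop(sum(multi), " multi-allelic record(s); set allow_multiallelic_drop = TRUE to drop them")
    warning("dropping ", sum(multi), " multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(vcf)
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  core <- gsub("\\|", "/", gt)
  num <- matrix(NA_real_, nrow(core), ncol(core), dimnames = dimnames(core))
  num[core == "0/0"] <- 0
  num[core == "1/1"] <- 1
  het <- core %in% c("0/1", "1/0")
  if (any(het)) {
    if (het_policy == "error") stop(sum(het), " heterozygous call(s) in inbred material")
    warning(sum(het), " heterozygous call(s) set to missing")
  }
  ids <- unname(fix[, "ID"])
  bad_id <- is.na(ids) | ids == "." | ids == ""
  ids[bad_id] <- paste0(fix[bad_id, "CHROM"], "_", fix[bad_id, "POS"])
  info_field <- function(key) {
    val <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", fix[, "INFO"])
    val[!grepl(paste0("(^|;)", key, "="), fix[, "INFO"])] <- NA
    val
  }
  sift <- suppressWarnings(as.numeric(info_field(sift_key)))
  gene <- info_field("GENE")
  meta <- tibble::tibble(
    feature_id = ids,
    gene_id = gene,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    sift_score = sift
  )
  vals <- t(num)
  colnames(vals) <- ids
  fm <- feature_matrix(vals, layer = "SV", feature_meta = meta)
  attr(fm, "n_het_recoded") <- sum(het)
  fm
}

#' Write simulated genotypes as a minimal VCF 4.2 file
#'
#' One biallelic SNP record per variant, homozygous genotypes (0 -> `0/0`,
#' 1 -> `1/1`, missing -> `./.`), with the SIFT score and gene id in INFO.
#'
#' @param fm A genotype [feature_matrix()] with `chrom`, `pos`, `sift_score`,
#'   `gene_id` metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  meta <- fm$feature_meta
  samples <- rownames(fm$values)
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT-like deleteriousness score">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_code <- function(x) ifelse(is.na(x), "./.", ifelse(x == 0, "0/0", "1/1"))
  rows <- vapply(seq_len(ncol(fm$values)), function(k) {
    paste(c(meta$chrom[k], meta$pos[k], meta$feature_id[k], "A", "T", ".",
            "PASS",
            sprintf("SIFT=%.6g;GENE=%s", meta$sift_score[k], meta$gene_id[k]),
            "GT", gt_code(fm$values[, k])), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Returns gene features only, with 1-based inclusive coordinates per the
#' GFF3 standard. The strand is required (the 3'end windowing is
#' strand-dependent) and `end >= start` is enforced.
#'
#' @param path GFF3 file path.
#' @return Tibble of gene models: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `length`.
#' @export
read_gff3_genes <- function(path) {
  gff <- ape::read.gff(path)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  if (any(is.na(genes$strand) | !genes$strand %in% c("+", "-")))
    stop("gene without strand; 3'end windowing is strand-dependent")
  if (any(genes$end < genes$start)) stop("gene with end < start")
  ids <- sub('.*ID=([^;]+).*', "\\1", genes$attributes)
  tibble::tibble(
    gene_id = ids,
    chrom = as.character(genes$seqid),
    strand = as.character(genes$strand),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    length = as.integer(genes$end - genes$start + 1L)
  )
}

#' Write gene models as GFF3
#'
#' @param gene_models Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(gene_models, path) {
  rows <- sprintf("%s\tomicblup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  gene_models$chrom, gene_models$start, gene_models$end,
                  gene_models$strand, gene_models$gene_id)
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read replicated observations in long format
#'
#' Expects a TSV with columns `genotype`, `environment`, `replicate`,
#' `trait`, `value`. The `environment` column may be absent (a
#' single-environment experiment, e.g. greenhouse metabolites); an implicit
#' environment is then added. Duplicate (genotype, environment, replicate,
#' trait) rows and non-numeric values are errors.
#'
#' @param path TSV path.
#' @return Tibble of validated observations plus a `completeness` attribute:
#'   per-trait count of genotype-environment cells with data.
#' @export
read_long_phenotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  needed <- c("genotype", "replicate", "trait", "value")
  if (!all(needed %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  if (!"environment" %in% names(df)) df$environment <- "env_1"
  if (!is.numeric(df$value)) stop("`value` must be numeric")
  key <- paste(df$genotype, df$environment, df$replicate, df$trait)
  if (anyDuplicated(key))
    stop("duplicate (genotype, environment, replicate, trait) row(s)")
  out <- tibble::as_tibble(df[, c("genotype", "environment", "replicate",
                                  "trait", "value")])
  attr(out, "completeness") <- dplyr::count(out, .data$trait,
                                            name = "n_observations")
  out
}
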