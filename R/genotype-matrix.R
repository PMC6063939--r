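#' Construct a genotype matrix object
#'
#' A `genotype_matrix` bundles a samples-by-variants dosage matrix (counts of
#' the coded allele `allele1`, values 0/1/2 or `NA` for missing calls) with
#' variant and sample metadata tables. It is the container every stage of the
#' pipeline (QC, association, scoring) operates on.
#'
#' @param dosages integer or numeric matrix, samples in rows, variants in
#'   columns; values must be 0, 1, 2 or `NA`.
#' @param variants a data frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele1` (coded/effect allele) and `allele2`, one row per column of
#'   `dosages`. If `NULL`, placeholder metadata on a single pseudo-chromosome
#'   with positions `1..m` and alleles `A`/`B` is generated.
#' @param samples a data frame with column `sample_id`, one row per row of
#'   `dosages`. If `NULL`, ids `S000001...` are generated.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (tibble), `samples` (tibble).
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3))
#' gm
#' n_variants(gm)
#' @export
genotype_matrix <- function(dosages, variants = NULL, samples = NULL) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) abort("`dosages` must contain only 0, 1, 2 or NA.")
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(variants)) {
    variants <- tibble(
      variant_id = sprintf("V%06d", seq_len(m)),
      chrom = 1L, pos = seq_len(m), allele1 = "A", allele2 = "B"
    )
  }
  variants <- as_tibble(variants)
  req <- c("variant_id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    abort(paste0("`variants` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(variants) != m) abort("`variants` must have one row per dosage column.")
  if (anyDuplicated(variants$variant_id)) abort("duplicate variant ids.")
  if (is.null(samples)) {
    samples <- tibble(sample_id = sprintf("S%06d", seq_len(n)))
  }
  samples <- as_tibble(samples)
  if (!"sample_id" %in% names(samples)) abort("`samples` needs a `sample_id` column.")
  if (nrow(samples) != n) abort("`samples` must have one row per dosage row.")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids.")
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord) && any(ord != seq_len(m))) {
    # keep positions strictly increasing within chromosome
    pd <- diff(variants$pos)
    cd <- diff(as.integer(factor(variants$chrom)))
    if (any(pd <= 0 & cd == 0)) {
      abort("variant positions must be strictly increasing within chromosome.")
    }
  }
  dimnames(dosages) <- list(samples$sample_id, variants$variant_id)
  structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages), 100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return An integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param gm a [genotype_matrix()].
#' @param samples,variants integer or logical index vectors (`NULL` keeps all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(n_samples(gm)) else samples
  vi <- if (is.null(variants)) seq_len(n_variants(gm)) else variants
  # contents are already validated; skip the constructor checks
  structure(
    list(
      dosages = gm$dosages[si, vi, drop = FALSE],
      variants = gm$variants[vi, , drop = FALSE],
      samples = gm$samples[si, , drop = FALSE]
    ),
    class = "genotype_matrix"
  )
}

#' Coded (allele1) allele frequency per variant
#'
#' Frequency of the coded allele computed over non-missing genotypes,
#' `sum(dosage) / (2 * n_nonmissing)`. Variants with no calls return `NA`.
#'
#' @param gm a [genotype_matrix()] or a dosage matrix.
#' @return Numeric vector, one frequency per variant.
#' @export
allele_freq <- function(gm) {
  d <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
  if (is.matrix(d) && is.integer(d)) {
    cc <- geno_counts_cpp(d)
    nn <- nrow(d) - cc[, 4]
    f <- (cc[, 2] + 2 * cc[, 3]) / (2 * nn)
    f[nn == 0] <- NA_real_
    names(f) <- colnames(d)
    return(f)
  }
  nn <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * nn)
  f[nn == 0] <- NA_real_
  f
}

# Standardized dosage matrix for PCA / LD work: missing values mean-imputed,
# then each column centred at 2f and scaled by sqrt(2f(1-f)). Monomorphic
# columns become all-zero rather than NaN.
standardize_dosages <- function(gm) {
  d <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
  storage.mode(d) <- "double"
  f <- allele_freq(d)
  mu <- 2 * f
  s <- sqrt(2 * f * (1 - f))
  s[!is.finite(s) | s == 0] <- Inf # monomorphic -> zero column
  for (j in seq_len(ncol(d))) {
    col <- d[, j]
    col[is.na(col)] <- mu[j]
    d[, j] <- (col - mu[j]) / s[j]
  }
  d
}

# Mean-imputed raw-scale dosage matrix (double), used by association/scoring.
impute_dosages <- function(gm) {
  d <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
  if (is.integer(d)) {
    out <- impute_dosages_cpp(d)
    dimnames(out) <- dimnames(d)
    return(out)
  }
  storage.mode(d) <- "double"
  if (!anyNA(d)) return(d)
  mu <- 2 * allele_freq(d)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}
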