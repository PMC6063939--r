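#' Principal components of a genotype panel
#'
#' Computes the top-`k` principal components of the standardized dosage
#' matrix (missing calls mean-imputed, each variant centred at `2f` and
#' scaled by `sqrt(2f(1-f))`, then exactly column-centred). Small panels use
#' an exact SVD; large ones a randomized (Halko-type) SVD with a fixed
#' internal projection seed, so results are deterministic. Component signs
#' are fixed by making the largest-magnitude variant loading positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (`0` yields an empty score matrix, i.e.
#'   unadjusted association downstream).
#' @return A `pca_result` list: `scores` (samples x k, zero column means),
#'   `loadings` (variants x k), `explained` (proportion of total variance per
#'   component) and `k`.
#' @export
pca_genotypes <- function(gm, k = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_samples(gm)
  m <- n_variants(gm)
  check_count(k, "k", min = 0)
  if (k > min(n, m)) abort("`k` must not exceed min(n_samples, n_variants).")
  if (k == 0) {
    return(structure(
      list(
        scores = matrix(0, n, 0), loadings = matrix(0, m, 0),
        explained = numeric(0), k = 0L
      ),
      class = "pca_result"
    ))
  }
  Z <- standardize_dosages(gm)
  Z <- sweep(Z, 2, colMeans(Z))
  tot_ss <- sum(Z^2)
  if (tot_ss == 0) abort("genotype matrix has no variance; PCA undefined.")
  if (min(n, m) <= 600) {
    sv <- svd(Z, nu = k, nv = k)
    U <- sv$u
    d <- sv$d[seq_len(k)]
    V <- sv$v
  } else {
    q <- min(k + 8L, min(n, m))
    Omega <- withr::with_seed(1907L, matrix(rnorm(m * q), m, q))
    Q <- qr.Q(qr(Z %*% Omega))
    for (it in 1:2) {
      Q <- qr.Q(qr(crossprod(Z, Q)))
      Q <- qr.Q(qr(Z %*% Q))
    }
    B <- crossprod(Q, Z)
    sb <- svd(B, nu = k, nv = k)
    U <- Q %*% sb$u
    d <- sb$d[seq_len(k)]
    V <- sb$v
  }
  for (j in seq_len(k)) {
    i_star <- which.max(abs(V[, j]))
    if (V[i_star, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(d, nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = scores, loadings = V, explained = d^2 / tot_ss,
      k = as.integer(k)
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d components; explained: %s\n", x$k,
    paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")
  ))
  invisible(x)
}

#' Per-variant logistic case/control association
#'
#' Fits, for every variant, a logistic regression of the 0/1 label on the
#' coded-allele dosage plus covariates (intercept always included), by
#' iteratively reweighted least squares warm-started at the covariate-only
#' fit. Reports the per-allele log odds ratio, its standard error and Wald
#' p-value. Non-convergence within the iteration budget — including complete
#' separation, detected by a coefficient exceeding `beta_cap` in magnitude —
#' is flagged, and flagged variants carry no usable estimate. Missing dosages
#' are mean-imputed per variant.
#'
#' @param gm a [genotype_matrix()].
#' @param labels 0/1 vector, one per sample; both classes must be present.
#' @param covariates optional numeric matrix of extra covariates (e.g. PC
#'   scores), samples in rows.
#' @param max_iter,tol IRLS budget: iteration cap and absolute log-likelihood
#'   change tolerance.
#' @param beta_cap coefficient magnitude treated as divergence/separation.
#' @param imputed,eaf optional precomputed mean-imputed dosage matrix and
#'   effect-allele frequencies for `gm` (a cache used by the
#'   cross-validation driver; results are identical either way).
#' @return An `assoc_result` tibble with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf` (effect-allele frequency in the
#'   fitted samples), `log_or`, `se`, `p`, `converged`; the genomic inflation
#'   factor of the converged Wald statistics is attached as attribute
#'   `lambda_gc`.
#' @export
logistic_assoc <- function(gm, labels, covariates = NULL,
                           max_iter = 25L, tol = 1e-8, beta_cap = 25,
                           imputed = NULL, eaf = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  labels <- as.numeric(labels)
  if (length(labels) != n_samples(gm)) abort("`labels` length must equal sample count.")
  if (anyNA(labels) || !all(labels %in% c(0, 1))) abort("`labels` must be 0/1 with no NA.")
  if (length(unique(labels)) < 2) abort("`labels` must contain both classes.")
  C <- matrix(1, n_samples(gm), 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_samples(gm)) abort("`covariates` rows must match samples.")
    if (ncol(covariates) > 0) C <- cbind(C, covariates)
  }
  D <- if (is.null(imputed)) impute_dosages(gm) else imputed
  fit <- logistic_scan_cpp(C, D, labels,
    max_iter = as.integer(max_iter),
    tol = tol, beta_cap = beta_cap
  )
  out <- tibble(
    variant_id = gm$variants$variant_id,
    effect_allele = gm$variants$allele1,
    other_allele = gm$variants$allele2,
    eaf = if (is.null(eaf)) unname(allele_freq(gm)) else eaf,
    log_or = as.vector(fit$log_or),
    se = as.vector(fit$se),
    p = as.vector(fit$p),
    converged = as.vector(fit$converged) == 1L
  )
  chisq <- with(out[out$converged, ], (log_or / se)^2)
  attr(out, "lambda_gc") <- if (length(chisq)) lambda_gc(chisq) else NA_real_
  class(out) <- c("assoc_result", class(out))
  out
}

#' Genomic inflation factor
#'
#' The median of the observed 1-df association chi-square statistics divided
#' by the median of the chi-square(1) distribution (0.4549364...). Values
#' near 1 indicate no systematic inflation; structured cohorts analysed
#' without adjustment inflate above 1.
#'
#' @param chisq vector of 1-df chi-square statistics (non-finite values
#'   dropped).
#' @return A positive scalar.
#' @export
lambda_gc <- function(chisq) {
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) == 0) abort("no finite chi-square statistics supplied.")
  median(chisq) / qchisq(0.5, df = 1)
}

#' Quantile-quantile points for association p-values
#'
#' Pairs the i-th smallest observed p-value with the expected uniform
#' quantile `(i - 0.5) / n`, both on the `-log10` scale, ready for a Q-Q
#' plot.
#'
#' @param p p-values in `(0, 1]`.
#' @return A tibble with columns `expected` and `observed`.
#' @export
qq_points <- function(p) {
  p <- p[is.finite(p)]
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  n <- length(p)
  tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
}

#' Write / read an association result table
#'
#' Tab-separated with columns `variant_id effect_allele other_allele eaf
#' log_or se p converged`. The same dialect doubles as an internal weights
#' file: [read_weights()] accepts it directly.
#'
#' @param assoc an `assoc_result` tibble.
#' @param path file path.
#' @return `path` (write) or a tibble (read), invisibly for the writer.
#' @export
write_assoc <- function(assoc, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- as.data.frame(assoc)
  # full double precision so weights round-trip bit-for-bit
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc
#' @export
read_assoc <- function(path) {
  out <- as_tibble(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  out$converged <- as.logical(out$converged)
  class(out) <- c("assoc_result", class(out))
  out
}
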