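#' Minor allele frequency of dosage vectors
#'
#' `compute_maf()` folds the coded-allele frequency to the minor side:
#' `min(f, 1 - f)` with `f = sum(dosages) / (2 * n_nonmissing)`. Missing
#' genotypes are excluded from the denominator; all-missing variants return
#' `NA` (they fail call-rate filtering regardless).
#'
#' @param dosages a 0/1/2/NA vector, matrix (samples x variants) or
#'   [genotype_matrix()].
#' @return Numeric MAF vector, one per variant.
#' @examples
#' compute_maf(c(0, 1, 2, 2)) # 0.375
#' @export
compute_maf <- function(dosages) {
  if (is.null(dim(dosages)) && !inherits(dosages, "genotype_matrix")) {
    dosages <- matrix(dosages, ncol = 1)
  }
  f <- allele_freq(dosages)
  pmin(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' The exact conditional test: given the observed allele counts, the p-value
#' is the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (the plain exact
#' test, not mid-p). Monomorphic variants return 1 by convention. All
#' arguments are vectorized.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (hom coded, het, hom
#'   other).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' hwe_test(25, 50, 25) # exactly 1
#' hwe_test(50, 0, 50) # vanishingly small
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  len <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), len)
  n_Aa <- rep_len(as.integer(n_Aa), len)
  n_aa <- rep_len(as.integer(n_aa), len)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE)) {
    abort("genotype counts must be nonnegative.")
  }
  # one shared log-factorial table instead of millions of lgamma calls
  n_tot <- n_AA + n_Aa + n_aa
  lfact <- lgamma(seq_len(max(2L * n_tot, 1L, na.rm = TRUE) + 1L))
  vapply(seq_len(len), function(i) {
    hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i], lfact)
  }, numeric(1))
}

hwe_exact_one <- function(nAA, nAa, naa, lfact = NULL) {
  if (anyNA(c(nAA, nAa, naa))) return(NA_real_)
  n <- nAA + nAa + naa
  if (n == 0) abort("total genotype count must be positive.")
  nA <- 2L * nAA + nAa
  na <- 2L * n - nA
  if (nA == 0L || na == 0L) return(1)
  if (is.null(lfact)) lfact <- lgamma(seq_len(2L * n + 1L))
  lf <- function(k) lfact[k + 1L]
  # all heterozygote counts sharing the parity of the allele count
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  lp <- lf(n) - lf((nA - hets) %/% 2L) - lf(hets) - lf((na - hets) %/% 2L) +
    hets * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Applies the standard marker filters sequentially: non-autosomal variants
#' are dropped first, then call rate (retain `>= callrate_min`), then minor
#' allele frequency (retain strictly `> maf_min`), then the exact
#' Hardy-Weinberg test (retain `p >= hwe_alpha`). Each removal is counted
#' against the first stage that catches it.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.01; retained variants are strictly
#'   above it).
#' @param callrate_min minimum genotyping rate (default 0.90, inclusive).
#' @param hwe_alpha HWE p-value threshold (default `1e-6`).
#' @param autosomes chromosome codes treated as autosomal.
#' @param sample_callrate_min optional per-sample genotyping-rate threshold;
#'   `NULL` (the default) disables sample-level QC, which is not part of the
#'   core marker pipeline. When set, low-call-rate samples are dropped before
#'   any variant filter and counted in the report.
#' @return A list: `genotypes` (filtered [genotype_matrix()]) and `report`, a
#'   one-row tibble of per-stage removal counts and the thresholds used.
#' @export
filter_variants <- function(gm, maf_min = 0.01, callrate_min = 0.90,
                            hwe_alpha = 1e-6, autosomes = 1:22,
                            sample_callrate_min = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_removed_samples <- 0L
  if (!is.null(sample_callrate_min)) {
    cr <- rowMeans(!is.na(gm$dosages))
    keep_s <- cr >= sample_callrate_min
    n_removed_samples <- sum(!keep_s)
    if (!any(keep_s)) abort("all samples removed by sample-level QC.")
    gm <- subset_genotypes(gm, samples = which(keep_s))
  }
  m0 <- n_variants(gm)
  auto <- gm$variants$chrom %in% autosomes
  n_nonauto <- sum(!auto)
  gm <- subset_genotypes(gm, variants = which(auto))

  cc <- geno_counts_cpp(gm$dosages)
  n <- n_samples(gm)
  callrate <- (n - cc[, 4]) / n
  pass_cr <- callrate >= callrate_min
  n_cr <- sum(!pass_cr)
  gm <- subset_genotypes(gm, variants = which(pass_cr))
  cc <- cc[pass_cr, , drop = FALSE]

  nn <- n - cc[, 4]
  f <- (cc[, 2] + 2 * cc[, 3]) / (2 * nn)
  maf <- pmin(f, 1 - f)
  pass_maf <- !is.na(maf) & maf > maf_min
  n_maf <- sum(!pass_maf)
  gm <- subset_genotypes(gm, variants = which(pass_maf))
  cc <- cc[pass_maf, , drop = FALSE]

  # counts are (n_hom_other, n_het, n_hom_coded): coded allele is allele1
  hwe_p <- hwe_test(cc[, 3], cc[, 2], cc[, 1])
  pass_hwe <- hwe_p >= hwe_alpha
  n_hwe <- sum(!pass_hwe)
  gm <- subset_genotypes(gm, variants = which(pass_hwe))

  if (n_variants(gm) == 0) abort("all variants removed by QC; empty panel.")
  report <- tibble(
    n_input = m0, n_removed_nonautosomal = n_nonauto,
    n_removed_callrate = n_cr, n_removed_maf = n_maf, n_removed_hwe = n_hwe,
    n_removed_prune = NA_integer_, n_retained = n_variants(gm),
    n_removed_samples = n_removed_samples,
    maf_min = maf_min, callrate_min = callrate_min, hwe_alpha = hwe_alpha
  )
  list(genotypes = gm, report = report)
}

#' Sliding-window VIF linkage-disequilibrium pruning
#'
#' Slides a window of `window` variants along the panel, advancing by `step`
#' variants, and within each window iteratively removes the variant with the
#' largest variance inflation factor (`VIF_j = 1 / (1 - R2_j)` from regressing
#' variant *j* on the other surviving window variants) until every remaining
#' VIF is below `vif_max`. Removals are global — a removed variant never
#' re-enters — and the whole sweep is repeated `passes` times. Missing
#' dosages are mean-imputed for the correlation computations only. Ties on
#' the maximal VIF are broken by removing the lower-MAF variant, then the
#' lower-index one, making output deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param window,step,vif_max pruning parameters (defaults 50 / 5 / 10).
#' @param passes number of full sweeps (default 3).
#' @return A list: `genotypes` (pruned panel), `kept` and `removed` variant
#'   id vectors.
#' @export
ld_prune_vif <- function(gm, window = 50, step = 5, vif_max = 10, passes = 3) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window < 2) abort("`window` must be at least 2.")
  if (step < 1) abort("`step` must be at least 1.")
  maf <- compute_maf(gm)
  maf[is.na(maf)] <- 0
  keep <- ld_prune_cpp(
    impute_dosages(gm), maf,
    window = as.integer(window), step = as.integer(step),
    vif_max = vif_max, passes = as.integer(passes)
  )
  kept_ids <- gm$variants$variant_id[keep]
  removed_ids <- gm$variants$variant_id[!keep]
  list(
    genotypes = subset_genotypes(gm, variants = which(keep)),
    kept = kept_ids, removed = removed_ids
  )
}

#' Run full marker QC: filters plus LD pruning
#'
#' Convenience wrapper chaining [filter_variants()] and [ld_prune_vif()],
#' filling the pruning count in the QC report.
#'
#' @inheritParams filter_variants
#' @inheritParams ld_prune_vif
#' @return A list: `genotypes`, `report` (with `n_removed_prune` filled) and
#'   `pruned_ids`.
#' @export
qc_pipeline <- function(gm, maf_min = 0.01, callrate_min = 0.90,
                        hwe_alpha = 1e-6, window = 50, step = 5,
                        vif_max = 10, passes = 3) {
  fl <- filter_variants(gm, maf_min = maf_min, callrate_min = callrate_min,
                        hwe_alpha = hwe_alpha)
  pr <- ld_prune_vif(fl$genotypes, window = window, step = step,
                     vif_max = vif_max, passes = passes)
  rep <- fl$report
  rep$n_removed_prune <- length(pr$removed)
  rep$n_retained <- n_variants(pr$genotypes)
  list(genotypes = pr$genotypes, report = rep, pruned_ids = pr$removed)
}
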