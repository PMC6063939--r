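# Shared fixtures and independent oracles used across test files. Oracles are
# deliberately naive (enumeration, pair counting, direct optimization) and
# never call the package's own fast paths.

# small deterministic genotype matrix with optional missingness
toy_genotypes <- function(n = 40, m = 12, maf = NULL, missing_rate = 0,
                          seed = 42) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
    d <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA_integer_
    genotype_matrix(d)
  })
}

small_cohort <- function(n = 400, m = 150, n_causal = 20, h2 = 0.5,
                         prevalence = 0.15, seed = 1, ...) {
  simulate_cohort(sim_config(
    n_samples = n, n_variants = m, n_causal = n_causal,
    h2_liability = h2, prevalence = prevalence, seed = seed, ...
  ))
}

# exact HWE test by direct enumeration over heterozygote counts, using
# plain binomial-coefficient arithmetic (log scale) - independent of the
# package's implementation
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  # multinomial table count times 2^h; the allele-count normalizer is
  # constant across tables and cancels when probabilities are renormalized
  logp <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    lchoose(n, a) + lchoose(n - a, h) + h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# AUC by brute-force case/control pair counting with half-credit ties
auc_oracle <- function(scores, labels) {
  ca <- scores[labels == 1]
  co <- scores[labels == 0]
  tot <- 0
  for (x in ca) tot <- tot + sum(x > co) + 0.5 * sum(x == co)
  tot / (length(ca) * length(co))
}

# logistic log OR by direct numerical maximization of the log-likelihood
logistic_mle_oracle <- function(d, y, covariates = NULL) {
  X <- cbind(1, covariates, d)
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par[ncol(X)]
}

# VIF of each variant against the others in a set, via lm on standardized
# dosages (mean-imputed)
vif_oracle <- function(gm, ids) {
  Z <- impute_dosages(subset_genotypes(
    gm, variants = match(ids, gm$variants$variant_id)
  ))
  Z <- scale(Z)
  vapply(seq_along(ids), function(j) {
    others <- Z[, -j, drop = FALSE]
    fit <- lm.fit(cbind(1, others), Z[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum(Z[, j]^2)
    1 / (1 - r2)
  }, numeric(1))
}

# independent PLINK bed decoder built on rawToBits, never touching the
# package's reader
decode_bed_oracle <- function(path, n, m) {
  raw <- readBin(path, "raw", n = 3 + ceiling(n / 4) * m)
  stopifnot(identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
  body <- raw[-(1:3)]
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 8, 2), , drop = FALSE] + 2 * bits[seq(2, 8, 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4 * ceiling(n / 4))
  map <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  out <- matrix(map[as.character(codes[seq_len(n), , drop = FALSE])], n, m)
  out
}
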