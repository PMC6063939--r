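test_that("exact HWE test matches enumeration oracle on frozen cases", {
  # the modal-configuration case sums to exactly 1
  expect_equal(hwe_test(25, 50, 25), 1.0)
  # gross heterozygote deficit at 100 samples
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  expect_equal(hwe_test(50, 0, 50), hwe_oracle(50, 0, 50), tolerance = 1e-10)
  # monomorphic convention
  expect_equal(hwe_test(0, 0, 100), 1.0)
  expect_equal(hwe_test(100, 0, 0), 1.0)
  expect_error(hwe_test(-1, 2, 3), "nonnegative")
})

test_that("exact HWE test equals brute-force enumeration across random triples", {
  withr::with_seed(11, {
    for (i in 1:300) {
      n <- sample(1:200, 1)
      nAA <- sample(0:n, 1)
      nAa <- sample(0:(n - nAA), 1)
      naa <- n - nAA - nAa
      expect_equal(hwe_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
        tolerance = 1e-9,
        info = sprintf("triple (%d,%d,%d)", nAA, nAa, naa)
      )
    }
  })
})

test_that("variant filters apply sequentially with per-stage counts", {
  withr::with_seed(21, {
    n <- 200
    good <- matrix(rbinom(n * 3, 2L, 0.3), n, 3)
    low_cr <- c(rbinom(n, 2L, 0.3))
    low_cr[1:30] <- NA_integer_ # 85% call rate
    rare <- rbinom(n, 2L, 0.005) # MAF ~ 0.005
    hwe_bad <- rep(c(0L, 2L), each = n / 2) # no hets at MAF 0.5
    d <- cbind(good[, 1], low_cr, rare, good[, 2], hwe_bad, good[, 3])
    gm <- genotype_matrix(d)
    res <- filter_variants(gm, maf_min = 0.01, callrate_min = 0.90, hwe_alpha = 1e-6)
    expect_equal(res$report$n_removed_callrate, 1L)
    expect_equal(res$report$n_removed_maf, 1L)
    expect_equal(res$report$n_removed_hwe, 1L)
    expect_equal(res$report$n_retained, 3L)
    expect_setequal(
      res$genotypes$variants$variant_id,
      gm$variants$variant_id[c(1, 4, 6)]
    )
  })
})

test_that("MAF boundary is strict and non-autosomal variants are dropped first", {
  withr::with_seed(31, {
    n <- 1000
    d <- cbind(
      rbinom(n, 2L, 0.009), # MAF below 1%
      rbinom(n, 2L, 0.011), # just above
      rbinom(n, 2L, 0.3)
    )
    # force the empirical frequencies to the intended side of the boundary
    v <- tibble::tibble(
      variant_id = c("v_low", "v_high", "v_x"), chrom = c(1L, 1L, 23L),
      pos = 1:3, allele1 = "A", allele2 = "B"
    )
    freqs <- colSums(d) / (2 * n)
    res <- filter_variants(genotype_matrix(d, variants = v))
    expect_false("v_x" %in% res$genotypes$variants$variant_id) # not autosomal
    expect_equal(res$report$n_removed_nonautosomal, 1L)
    if (freqs[1] <= 0.01) expect_false("v_low" %in% res$genotypes$variants$variant_id)
    if (freqs[2] > 0.01) expect_true("v_high" %in% res$genotypes$variants$variant_id)
  })
})

test_that("optional sample-level QC drops low-call-rate individuals", {
  gm <- toy_genotypes(n = 50, m = 30, missing_rate = 0, seed = 9)
  d <- gm$dosages
  d[1:2, 1:20] <- NA_integer_ # two samples with 2/3 of calls missing
  gm2 <- genotype_matrix(d)
  res <- filter_variants(gm2, sample_callrate_min = 0.9)
  expect_equal(res$report$n_removed_samples, 2L)
  expect_equal(n_samples(res$genotypes), 48L)
  # default leaves samples untouched
  res0 <- filter_variants(gm2)
  expect_equal(res0$report$n_removed_samples, 0L)
  expect_equal(n_samples(res0$genotypes), 50L)
})

test_that("QC is idempotent and signals an empty panel", {
  gm <- toy_genotypes(n = 300, m = 40, missing_rate = 0.02, seed = 5)
  r1 <- qc_pipeline(gm)
  r2 <- qc_pipeline(r1$genotypes)
  expect_equal(
    r2$report$n_removed_callrate + r2$report$n_removed_maf +
      r2$report$n_removed_hwe + r2$report$n_removed_prune, 0L
  )
  mono <- genotype_matrix(matrix(0L, 50, 3))
  expect_error(filter_variants(mono), "empty panel")
})

test_that("VIF pruning removes planted collinear blocks and spares the rest", {
  withr::with_seed(41, {
    n <- 300
    base <- matrix(rbinom(n * 7, 2L, 0.4), n, 7)
    # a 3-variant correlated block: near-copies of column 1
    flip <- function(x, rate) {
      i <- runif(n) < rate
      out <- x
      out[i] <- rbinom(sum(i), 2L, 0.4)
      out
    }
    block <- cbind(base[, 1], flip(base[, 1], 0.02), flip(base[, 1], 0.02))
    d <- cbind(block, base[, 2:7])
    gm <- genotype_matrix(d)
    pruned <- ld_prune_vif(gm, window = 10, step = 5, vif_max = 10)
    expect_gt(length(pruned$removed), 0)
    # independent recomputation: every survivor has VIF < 10
    v <- vif_oracle(gm, pruned$kept)
    expect_true(all(v < 10))
  })
})

test_that("duplicated variants lose exactly one copy; independent ones survive", {
  withr::with_seed(51, {
    n <- 200
    d <- matrix(rbinom(n * 6, 2L, 0.4), n, 6)
    d[, 4] <- d[, 2] # exact duplicate
    gm <- genotype_matrix(d)
    pruned <- ld_prune_vif(gm, window = 6, step = 3, vif_max = 10)
    expect_equal(length(pruned$removed), 1)
    expect_true(pruned$removed %in% gm$variants$variant_id[c(2, 4)])

    indep <- toy_genotypes(n = 200, m = 12, seed = 52)
    p2 <- ld_prune_vif(indep, window = 6, step = 3, vif_max = 10)
    expect_equal(length(p2$removed), 0)
  })
})

test_that("pruning is insensitive to sample order and validates its window", {
  gm <- toy_genotypes(n = 150, m = 20, seed = 6)
  perm <- sample(seq_len(150))
  p1 <- ld_prune_vif(gm)
  p2 <- ld_prune_vif(subset_genotypes(gm, samples = perm))
  expect_identical(p1$kept, p2$kept)
  expect_error(ld_prune_vif(gm, window = 1), "window")
})

test_that("null-simulation HWE removals stay near the nominal rate", {
  cfg <- sim_config(
    n_samples = 800, n_variants = 5000, n_causal = 5,
    missing_rate = 0, seed = 77
  )
  gm <- simulate_genotypes(cfg)
  res <- filter_variants(gm, hwe_alpha = 1e-3)
  # alpha = 1e-3 over 5000 HWE-true variants: rejection fraction in [0, 0.005]
  expect_lte(res$report$n_removed_hwe / 5000, 0.005)
})
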