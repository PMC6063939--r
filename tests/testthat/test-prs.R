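test_that("threshold grid spans its endpoints and validates", {
  g <- threshold_grid()
  expect_length(g, 12)
  expect_equal(g[1], 5e-5)
  expect_equal(g[12], 0.1)
  expect_true(all(diff(g) > 0))
  expect_error(threshold_grid(p_min = 0.2, p_max = 0.1), "p_min")
})

test_that("fold plans partition, stratify, and reproduce", {
  withr::with_seed(2, {
    labels <- cbind(rep(c(1, 0), c(50, 950)))
    plan <- make_folds(labels, k = 5, seed = 7)
    expect_equal(sort(unique(plan$fold)), 1:5)
    expect_equal(tabulate(plan$fold, 5), rep(200L, 5))
    # stratification: 10 +/- 1 cases per fold (50 cases over 5 folds)
    per_fold_cases <- tapply(labels[, 1], plan$fold, sum)
    expect_true(all(abs(per_fold_cases - 10) <= 1))
    expect_identical(make_folds(labels, k = 5, seed = 7)$fold, plan$fold)
    expect_false(identical(make_folds(labels, k = 5, seed = 8)$fold, plan$fold))
    expect_error(make_folds(cbind(rep(c(1, 0), c(3, 997))), k = 5), "fewer")
  })
})

test_that("threshold selection keeps converged sub-threshold variants, nested sets", {
  assoc <- tibble::tibble(
    variant_id = paste0("v", 1:4), effect_allele = "A", other_allele = "B",
    eaf = 0.3, log_or = c(0.2, -0.1, 0.4, 0.9),
    se = 0.1, p = c(0.01, 0.2, 0.04, 0.5), converged = c(TRUE, TRUE, TRUE, FALSE)
  )
  sel <- select_by_threshold(assoc, 0.05)
  expect_equal(sel$variant_id, c("v1", "v3"))
  expect_equal(sel$weight, c(0.2, 0.4))
  all_sel <- select_by_threshold(assoc, 1)
  expect_equal(all_sel$variant_id, c("v1", "v2", "v3")) # v4 never converged
  expect_true(all(sel$variant_id %in% all_sel$variant_id))
  empty <- select_by_threshold(dplyr::mutate(assoc, p = 1), 0.1)
  expect_equal(nrow(empty), 0)
})

test_that("scores follow the mean-over-variants dot product convention", {
  d <- matrix(c(2L, 0L, 1L, 0L, 0L, 2L), nrow = 2) # rows (2,1,0) and (0,0,2)
  gm <- genotype_matrix(d)
  w <- tibble::tibble(
    variant_id = gm$variants$variant_id, effect_allele = "A",
    other_allele = "B", weight = c(0.1, -0.2, 0.4), p = 0.01, eaf = 0.5,
    provenance = "internal"
  )
  class(w) <- c("weight_set", class(w))
  sc <- score_prs(gm, w)
  expect_equal(sc$prs, c((0.2 - 0.2 + 0) / 3, (0 + 0 + 0.8) / 3))

  # single ln(2) weight gives 0, 0.693, 1.386 before the 1/m normalization
  gm1 <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1))
  w1 <- w[1, ]
  w1$variant_id <- gm1$variants$variant_id[1]
  w1$weight <- log(2)
  expect_equal(score_prs(gm1, w1)$prs * 1, c(0, log(2), 2 * log(2)))
})

test_that("allele flips shift scores by a constant and missingness uses trained freq", {
  gm <- toy_genotypes(n = 30, m = 4, seed = 3)
  w <- tibble::tibble(
    variant_id = gm$variants$variant_id, effect_allele = "A",
    other_allele = "B", weight = c(0.3, -0.1, 0.2, 0.5), p = 0.01,
    eaf = NA_real_, provenance = "internal"
  )
  base <- score_prs(gm, w)
  # recode variant 2 in the weights file (alleles swapped, weight negated):
  # every score shifts by the constant -2w/m
  wf <- w
  wf$effect_allele[2] <- "B"
  wf$other_allele[2] <- "A"
  wf$weight[2] <- -w$weight[2]
  flipped <- score_prs(gm, wf)
  shift <- flipped$prs - base$prs
  expect_equal(shift, rep(-2 * w$weight[2] / 4, nrow(base)), tolerance = 1e-12)
  expect_equal(
    roc_auc(flipped$prs, rep(c(0, 1), 15)),
    roc_auc(base$prs, rep(c(0, 1), 15))
  )

  # recoding the panel itself (complement dosages, swap allele metadata)
  # leaves scores exactly invariant
  d2 <- gm$dosages
  d2[, 2] <- 2L - d2[, 2]
  v2 <- gm$variants
  v2$allele1[2] <- "B"
  v2$allele2[2] <- "A"
  gm_rec <- genotype_matrix(d2, variants = v2, samples = gm$samples)
  expect_equal(score_prs(gm_rec, w)$prs, base$prs, tolerance = 1e-14)

  # missing dosages imputed at 2 x supplied effect-allele frequency
  dm <- gm$dosages
  dm[1, 1] <- NA_integer_
  gm_m <- genotype_matrix(dm)
  w_eaf <- w
  w_eaf$eaf <- c(0.25, 0.5, 0.5, 0.5)
  sc_m <- score_prs(gm_m, w_eaf)
  manual <- (2 * 0.25 * 0.3 + sum(impute_dosages(gm)[1, 2:4] * w$weight[2:4])) / 4
  expect_equal(sc_m$prs[1], manual)
})

test_that("unknown variants are dropped with diagnostics; zero overlap fails", {
  gm <- toy_genotypes(n = 20, m = 10, seed = 4)
  w <- tibble::tibble(
    variant_id = c(gm$variants$variant_id[1:9], "rs_unknown"),
    effect_allele = "A", other_allele = "B", weight = 0.1, p = 0.01,
    eaf = 0.4, provenance = "external"
  )
  sc <- score_prs(gm, w)
  expect_equal(attr(sc, "n_variants_used"), 9L)
  expect_equal(attr(sc, "n_missing_panel"), 1L)
  w_bad <- w
  w_bad$variant_id <- paste0("rs", 1:10)
  expect_error(score_prs(gm, w_bad), "no overlap")
  # mismatched alleles are dropped and counted
  w_mm <- w[1:9, ]
  w_mm$effect_allele[1] <- "C"
  sc_mm <- score_prs(gm, w_mm)
  expect_equal(attr(sc_mm, "n_mismatch"), 1L)
  expect_equal(attr(sc_mm, "n_variants_used"), 8L)
})

test_that("weights files round-trip, reject malformed rows, accept OR columns", {
  path <- file.path(withr::local_tempdir(), "w.tsv")
  df <- data.frame(
    variant_id = c("v1", "v2", "v3"), effect_allele = c("A", "A", ""),
    other_allele = "B", or = c(1.5, exp(-0.2), 1.1), p = c(0.01, 0.5, 0.2)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  w <- read_weights(path)
  expect_equal(nrow(w), 2)
  expect_equal(attr(w, "n_rejected"), 1L)
  expect_equal(w$weight, c(log(1.5), -0.2))
  expect_error(read_weights(df[0, ]), "missing column|no usable")
})

test_that("external scoring equals the internal path when weights are re-read", {
  co <- small_cohort(n = 250, m = 60, n_causal = 15, seed = 6, missing_rate = 0.03)
  gm <- co$genotypes
  a <- logistic_assoc(gm, co$pheno$algorithm)
  path <- file.path(withr::local_tempdir(), "assoc.tsv")
  write_assoc(a, path)
  internal <- score_prs(gm, select_by_threshold(a, 0.1))
  external <- score_with_external(gm, path, cutoff = 0.1)
  expect_identical(internal$prs, external$prs)
  # swapping effect/other alleles leaves AUC untouched
  w <- read_weights(path)
  w_sw <- w
  w_sw$effect_allele <- w$other_allele
  w_sw$other_allele <- w$effect_allele
  w_sw$weight <- -w$weight
  w_sw$eaf <- 1 - w$eaf
  sw <- score_prs(gm, w_sw[is.finite(w_sw$p) & w_sw$p <= 0.1, ])
  expect_equal(
    roc_auc(sw$prs, co$pheno$algorithm),
    roc_auc(internal$prs, co$pheno$algorithm),
    tolerance = 1e-12
  )
})

test_that("cross-validated weights never see their own test fold", {
  co <- small_cohort(n = 300, m = 80, n_causal = 15, seed = 8)
  gm <- co$genotypes
  plan <- make_folds(co$pheno[, channel_names(co)], k = 4, seed = 5)
  cv <- cross_validated_scores(gm, co$pheno$billing,
    grid = threshold_grid(n = 4), plan = plan
  )
  f <- 2
  tr <- which(plan$fold != f)
  redo <- logistic_assoc(
    subset_genotypes(gm, samples = tr),
    co$pheno$billing[tr]
  )
  expect_equal(cv$fold_assoc[[f]]$log_or, redo$log_or, tolerance = 1e-12)
  expect_equal(cv$fold_assoc[[f]]$p, redo$p, tolerance = 1e-12)
  # determinism end to end
  cv2 <- cross_validated_scores(gm, co$pheno$billing,
    grid = threshold_grid(n = 4), plan = plan
  )
  expect_identical(cv$cells, cv2$cells)
  expect_identical(cv$scores$prs, cv2$scores$prs)
})

test_that("cv scores are invariant to variant order and glance summarises cells", {
  co <- small_cohort(n = 240, m = 50, n_causal = 10, seed = 9, missing_rate = 0)
  gm <- co$genotypes
  plan <- make_folds(co$pheno[, channel_names(co)], k = 3, seed = 2)
  cv1 <- cross_validated_scores(gm, co$pheno$billing,
    grid = c(0.05, 0.5), plan = plan
  )
  perm <- withr::with_seed(4, sample(50))
  gm_p <- subset_genotypes(gm, variants = perm)
  cv2 <- cross_validated_scores(gm_p, co$pheno$billing,
    grid = c(0.05, 0.5), plan = plan
  )
  s1 <- dplyr::arrange(cv1$scores, .data$fold, .data$threshold, .data$sample_id)
  s2 <- dplyr::arrange(cv2$scores, .data$fold, .data$threshold, .data$sample_id)
  expect_equal(s1$prs, s2$prs, tolerance = 1e-12)
  g <- glance(cv1)
  expect_equal(g$n_folds, 3)
  expect_true(g$best_threshold %in% c(0.05, 0.5))
  expect_equal(g$selection, "selected-on-test")
  td <- tidy(cv1)
  expect_true(all(c("fold", "threshold", "auc", "usable") %in% names(td)))
})
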