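test_that("roc_auc matches brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(2, 3, 1, 4), c(1, 1, 0, 0)), 0.5)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  withr::with_seed(10, {
    for (i in 1:100) {
      n <- sample(10:200, 1)
      sc <- sample(1:20, n, replace = TRUE) # heavy ties
      lb <- rbinom(n, 1, 0.4)
      if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
      expect_equal(roc_auc(sc, lb), auc_oracle(sc, lb), tolerance = 1e-12)
    }
  })
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  withr::with_seed(12, {
    sc <- rnorm(150)
    lb <- rbinom(150, 1, 0.3)
    lb[1:2] <- c(0, 1)
    a <- roc_auc(sc, lb)
    expect_equal(roc_auc(exp(sc), lb), a)
    expect_equal(roc_auc(rank(sc), lb), a)
  })
})

test_that("mean difference and OR-per-SD behave on frozen cases", {
  expect_equal(mean_difference(c(0.1, 0.3, 0.0, 0.1), c(1, 1, 0, 0)), 0.15)
  expect_equal(mean_difference(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(mean_difference(rep(2, 4), c(1, 1, 0, 0)), 0)
  expect_error(or_per_sd(rep(1, 6), rep(c(0, 1), 3)), "zero variance")
  # perfectly separating scores are flagged non-estimable, not huge
  expect_warning(
    out <- or_per_sd(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0)),
    "separation"
  )
  expect_true(is.na(out))
})

test_that("OR-per-SD recovers the generative effect and matches a direct fit", {
  withr::with_seed(14, {
    n <- 20000
    lb <- rep(c(0, 1), each = n / 2)
    sc <- rnorm(n, mean = 0.5 * lb, sd = 1)
    est <- or_per_sd(sc, lb)
    z <- (sc - mean(sc)) / sd(sc)
    direct <- exp(logistic_mle_oracle(z, lb))
    expect_equal(est, direct, tolerance = 0.05 * direct)
    # independence gives OR near 1
    est0 <- or_per_sd(rnorm(n), lb)
    expect_lt(abs(log(est0)), 3 * 2 / sqrt(n))
  })
})

test_that("fold summaries use the sample SD convention", {
  fs <- tibble::tibble(mean_diff = c(0.1, 0.1), auc = c(0.6, 0.7), or_per_sd = c(1.2, 1.2))
  sm <- summarize_folds(fs)
  expect_equal(sm$auc, 0.65)
  expect_equal(sm$auc_sd, sd(c(0.6, 0.7)))
  expect_equal(round(sm$auc_sd, 4), 0.0707)
  expect_equal(sm$mean_diff_sd, 0)
  expect_error(summarize_folds(fs[1, ]), "two folds")
  withr::with_seed(16, {
    f5 <- tibble::tibble(
      mean_diff = rnorm(5), auc = runif(5), or_per_sd = exp(rnorm(5))
    )
    s5 <- summarize_folds(f5)
    expect_equal(s5$or_per_sd, mean(f5$or_per_sd))
    expect_equal(s5$or_per_sd_sd, sd(f5$or_per_sd))
  })
})

test_that("overlap report gives exact region counts and consistent totals", {
  lab <- data.frame(
    A = c(1, 1, 1, 0, 0), B = c(0, 1, 1, 0, 0), C = c(0, 0, 1, 0, 1)
  )
  ov <- overlap_report(lab)
  three <- ov$regions$n[ov$regions$region == "A+B+C"]
  expect_equal(three, 1L)
  a_only <- ov$regions$n[ov$regions$region == "A"]
  expect_equal(a_only, 1L)
  pcA <- ov$per_channel[ov$per_channel$channel == "A", ]
  expect_equal(sum(pcA$n), pcA$n_positive[1]) # inclusion-exclusion consistency
  expect_equal(pcA$pct[pcA$order == 3], 100 / 3, tolerance = 1e-10)

  ident <- data.frame(x = c(1, 1, 0), y = c(1, 1, 0), z = c(1, 1, 0))
  ovi <- overlap_report(ident)
  expect_true(all(ovi$per_channel$pct[ovi$per_channel$order == 3] == 100))
  disj <- data.frame(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  ovd <- overlap_report(disj)
  expect_true(all(ovd$per_channel$pct[ovd$per_channel$order > 1] == 0))
  expect_error(overlap_report(lab[, 1, drop = FALSE]), "two channels")
})

test_that("channel evaluation shares folds and ranks by AUC with tie handling", {
  co <- small_cohort(n = 400, m = 120, n_causal = 20, seed = 21)
  q <- qc_pipeline(co$genotypes, window = 20, step = 5)
  ev <- evaluate_channels(q$genotypes, co$pheno,
    grid = threshold_grid(n = 4), k = 4, seed = 3
  )
  expect_setequal(ev$summary$channel, c("billing", "problem_list", "algorithm"))
  expect_true(all(ev$summary$auc >= 0 & ev$summary$auc <= 1))
  expect_true(all(ev$summary$auc_sd >= 0, na.rm = TRUE))
  expect_true("auc_vs_truth" %in% names(ev$summary))
  rk <- compare_channels(ev)
  expect_equal(rk$ranking$auc, sort(ev$summary$auc, decreasing = TRUE))
  # a duplicated channel produces an explicit tie
  ph2 <- co$pheno
  ph2$algo2 <- ph2$algorithm
  ev2 <- evaluate_channels(q$genotypes, ph2,
    channels = c("algorithm", "algo2"),
    grid = threshold_grid(n = 4), k = 4, seed = 3
  )
  rk2 <- compare_channels(ev2)
  expect_length(rk2$ties, 1)
  expect_equal(rk2$ranking$rank, c(1L, 1L))
  # statistics agree in sign across evaluated channels
  fs <- ev$fold_stats[ev$fold_stats$against == "channel", ]
  agg <- stats::aggregate(cbind(mean_diff, auc, or_per_sd) ~ channel, fs, mean)
  expect_true(all(sign(agg$mean_diff) == sign(agg$auc - 0.5) |
    agg$mean_diff == 0))
})

test_that("billing-count sweep redefines cases and reports overlap", {
  co <- small_cohort(n = 500, m = 100, n_causal = 15, seed = 31, prevalence = 0.2)
  plan <- make_folds(co$pheno[, channel_names(co)], k = 4, seed = 2)
  sw <- billing_count_sweep(co$genotypes, co$pheno,
    thresholds = c(1, 2, 50),
    grid = threshold_grid(n = 3), plan = plan
  )
  expect_equal(nrow(sw), 3)
  expect_equal(sw$n_cases[1], sum(co$pheno$billing_count >= 1))
  expect_equal(sw$n_cases[1], sum(co$pheno$billing)) # t = 1 is the plain channel
  expect_equal(sw$n_cases[2], sum(co$pheno$billing_count >= 2))
  expect_false(sw$estimable[3]) # nobody billed 50 times
  expect_true(all(sw$estimable[1:2]))
  # overlap percentage relative to each subset's own positives
  in_all <- rowSums(co$pheno[, c("problem_list", "algorithm")]) == 2
  t2 <- co$pheno$billing_count >= 2
  expect_equal(sw$pct_full_overlap[2], 100 * sum(t2 & in_all) / sum(t2))
})

test_that("counts [1,2,3,4] at threshold 3 keep two cases", {
  ph <- tibble::tibble(
    sample_id = paste0("s", 1:4), true_status = c(0L, 1L, 1L, 1L),
    billing = c(1L, 1L, 1L, 1L), billing_count = c(1L, 2L, 3L, 4L)
  )
  expect_equal(sum(ph$billing_count >= 3), 2)
})
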