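#' Specify a phenotype labeling channel
#'
#' A labeling channel is an imperfect binary observation of true disease
#' status, characterised by its sensitivity (probability a true case is
#' labeled positive) and specificity (probability a true non-case is labeled
#' negative). The three EHR extraction methods the package benchmarks map
#' onto three such channels.
#'
#' @param name channel name (unique within a config).
#' @param sensitivity,specificity probabilities in `[0, 1]`.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, sensitivity, specificity) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  structure(
    list(name = name, sensitivity = sensitivity, specificity = specificity),
    class = "channel_spec"
  )
}

#' Default EHR labeling channels
#'
#' Three channels mirroring the qualitative character of common EHR phenotype
#' sources: administrative billing codes (high sensitivity, low specificity),
#' the clinician-curated problem list (low sensitivity, high specificity) and
#' a curated phenotyping algorithm (balanced, high accuracy). The numeric
#' values are package defaults chosen to reproduce that qualitative pattern;
#' override them per analysis with [channel_spec()].
#'
#' @return A named list of three [channel_spec()] objects.
#' @export
default_channels <- function() {
  list(
    billing = channel_spec("billing", sensitivity = 0.95, specificity = 0.90),
    problem_list = channel_spec("problem_list", sensitivity = 0.60, specificity = 0.995),
    algorithm = channel_spec("algorithm", sensitivity = 0.80, specificity = 0.995)
  )
}

#' Configuration for a synthetic cohort
#'
#' Defines one simulated study: a biallelic autosomal genotype panel in
#' Hardy-Weinberg equilibrium (optionally with two-subpopulation structure via
#' the Balding-Nichols model), a liability-threshold polygenic disease, a set
#' of imperfect labeling channels and a billing occurrence-count model.
#' Identical configs with identical seeds yield byte-identical cohorts.
#'
#' @param n_samples,n_variants cohort and panel size.
#' @param maf_low,maf_high range of per-variant coded-allele frequencies,
#'   drawn uniformly; each in `(0, 0.5]`.
#' @param n_causal number of causal variants (`<= n_variants`).
#' @param h2_liability narrow-sense heritability of liability, in `[0, 1]`.
#' @param prevalence population disease prevalence, in `(0, 1)`.
#' @param n_subpops number of subpopulations (1 = unstructured).
#' @param fst Balding-Nichols differentiation parameter, in `[0, 1)`.
#' @param channels named list of [channel_spec()]s.
#' @param billing_count_params length-2 numeric: mean extra billing
#'   occurrences beyond the first for labeled true cases and for labeled
#'   false positives. The default (2.0, 0.3) makes repeat billing informative:
#'   positive predictive value rises with the count threshold.
#' @param missing_rate per-entry missing-genotype rate (exercises call-rate QC).
#' @param seed integer seed controlling every random draw.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_samples = 200, n_variants = 100, n_causal = 10, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$pheno)
#' @export
sim_config <- function(n_samples = 4000, n_variants = 5000,
                       maf_low = 0.05, maf_high = 0.5,
                       n_causal = 50, h2_liability = 0.5, prevalence = 0.05,
                       n_subpops = 1, fst = 0,
                       channels = default_channels(),
                       billing_count_params = c(case_extra = 2.0, fp_extra = 0.3),
                       missing_rate = 0.02,
                       seed = 1L) {
  check_count(n_samples, "n_samples")
  check_count(n_variants, "n_variants")
  check_count(n_causal, "n_causal", min = 0)
  if (n_causal > n_variants) abort("`n_causal` must be <= `n_variants`.")
  check_prob(h2_liability, "h2_liability")
  check_range(prevalence, "prevalence", 0, 1, open = TRUE)
  check_range(maf_low, "maf_low", 0, 0.5, open_lo = TRUE)
  check_range(maf_high, "maf_high", 0, 0.5, open_lo = TRUE)
  if (maf_low > maf_high) abort("`maf_low` must be <= `maf_high`.")
  check_count(n_subpops, "n_subpops")
  check_range(fst, "fst", 0, 1, open_hi = TRUE)
  if (n_subpops > 1 && fst <= 0) abort("`fst` must be > 0 when `n_subpops` > 1.")
  check_range(missing_rate, "missing_rate", 0, 1, open_hi = TRUE)
  if (length(billing_count_params) != 2 || any(!is.finite(billing_count_params)) ||
    any(billing_count_params < 0)) {
    abort("`billing_count_params` must be two nonnegative finite means.")
  }
  if (!length(channels)) abort("`channels` must contain at least one channel_spec.")
  channels <- purrr::map(channels, function(ch) {
    if (!inherits(ch, "channel_spec")) abort("`channels` entries must be channel_spec objects.")
    ch
  })
  nm <- purrr::map_chr(channels, "name")
  if (anyDuplicated(nm)) abort("channel names must be unique within `channels`.")
  names(channels) <- nm
  check_count(seed, "seed", min = 0)
  structure(
    list(
      n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
      maf_low = maf_low, maf_high = maf_high, n_causal = as.integer(n_causal),
      h2_liability = h2_liability, prevalence = prevalence,
      n_subpops = as.integer(n_subpops), fst = fst, channels = channels,
      billing_count_params = unname(billing_count_params),
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

check_prob <- function(x, nm) check_range(x, nm, 0, 1)

check_range <- function(x, nm, lo, hi, open = FALSE,
                        open_lo = open, open_hi = open) {
  ok <- length(x) == 1 && is.numeric(x) && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a finite number in %s%g, %g%s.", nm,
      if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, nm, min = 1) {
  ok <- length(x) == 1 && is.numeric(x) && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be an integer >= %d.", nm, min))
  invisible(x)
}

#' Simulate a genotype panel
#'
#' Draws a per-variant coded-allele frequency from
#' `Uniform(maf_low, maf_high)` and genotypes as `Binomial(2, freq)` per
#' sample, i.e. Hardy-Weinberg equilibrium. With `n_subpops > 1`,
#' subpopulation-specific frequencies are drawn around the ancestral frequency
#' by the Balding-Nichols construction
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)` and samples are assigned
#' to subpopulations in equal contiguous blocks. Missing calls are injected
#' uniformly at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` if supplied.
#' @return A [genotype_matrix()]; when structured, the samples table carries a
#'   `subpop` column.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m <- config$n_variants
  withr::with_seed(seed, {
    p_anc <- runif(m, config$maf_low, config$maf_high)
    subpop <- rep(seq_len(config$n_subpops), length.out = n)
    subpop <- sort(subpop)
    if (config$n_subpops > 1) {
      a <- (1 - config$fst) / config$fst
      pk <- matrix(0, config$n_subpops, m)
      for (k in seq_len(config$n_subpops)) {
        pk[k, ] <- rbeta(m, p_anc * a, (1 - p_anc) * a)
      }
      # guard degenerate beta draws so variants stay polymorphic in expectation
      pk <- pmin(pmax(pk, 1e-6), 1 - 1e-6)
      d <- matrix(0L, n, m)
      for (k in seq_len(config$n_subpops)) {
        rows <- which(subpop == k)
        d[rows, ] <- matrix(
          rbinom(length(rows) * m, 2L, rep(pk[k, ], each = length(rows))),
          nrow = length(rows)
        )
      }
    } else {
      d <- matrix(rbinom(n * m, 2L, rep(p_anc, each = n)), nrow = n)
    }
    if (config$missing_rate > 0) {
      d[runif(n * m) < config$missing_rate] <- NA_integer_
    }
    samples <- tibble(sample_id = sprintf("S%06d", seq_len(n)), subpop = subpop)
    genotype_matrix(d, samples = samples)
  })
}

#' Simulate a liability-threshold polygenic disease
#'
#' Samples `n_causal` causal variants without replacement, draws i.i.d. normal
#' per-allele effects, and rescales the resulting genetic score to variance
#' `h2_liability`. Liability is that score plus an independent
#' `Normal(0, 1 - h2_liability)` residual; disease status is 1 when liability
#' exceeds the `1 - prevalence` standard-normal quantile.
#'
#' @param gm a [genotype_matrix()] (missing dosages are mean-imputed for the
#'   genetic score).
#' @param config a [sim_config()].
#' @param seed overrides `config$seed + 1` if supplied.
#' @return A `true_cohort` list: `genotypes`, a `pheno` tibble
#'   (`sample_id`, `liability`, `true_status`, plus `subpop` when present) and
#'   a `causal` tibble of variant effects.
#' @export
simulate_disease <- function(gm, config, seed = config$seed + 1L) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  if (config$n_causal > n_variants(gm)) abort("`n_causal` exceeds panel size.")
  withr::with_seed(seed, {
    causal_idx <- sort(sample.int(n_variants(gm), config$n_causal))
    beta <- rnorm(config$n_causal)
    g0 <- impute_dosages(subset_genotypes(gm, variants = causal_idx)) %*% beta
    sg <- sd(g0)
    if (config$h2_liability > 0 && (!is.finite(sg) || sg == 0)) {
      abort("causal genetic score has zero variance; cannot impose h2_liability > 0.")
    }
    g <- if (config$h2_liability > 0) {
      as.vector(scale(g0)) * sqrt(config$h2_liability)
    } else {
      rep(0, n_samples(gm))
    }
    resid <- rnorm(n_samples(gm), 0, sqrt(1 - config$h2_liability))
    liability <- g + resid
    thr <- qnorm(1 - config$prevalence)
    pheno <- gm$samples
    pheno$liability <- liability
    pheno$genetic_liability <- g
    pheno$true_status <- as.integer(liability > thr)
    structure(
      list(
        genotypes = gm, pheno = pheno,
        causal = tibble(
          variant_id = gm$variants$variant_id[causal_idx],
          beta = beta
        )
      ),
      class = "true_cohort"
    )
  })
}

#' @export
print.true_cohort <- function(x, ...) {
  chan <- setdiff(
    names(x$pheno),
    c("sample_id", "subpop", "liability", "genetic_liability", "true_status", "billing_count")
  )
  cat(sprintf(
    "<true_cohort> %d samples x %d variants; %d cases (%.1f%%); channels: %s\n",
    n_samples(x$genotypes), n_variants(x$genotypes),
    sum(x$pheno$true_status), 100 * mean(x$pheno$true_status),
    if (length(chan)) paste(chan, collapse = ", ") else "<none>"
  ))
  invisible(x)
}

#' Observe true status through an imperfect labeling channel
#'
#' Each true case is labeled positive with probability `sensitivity`; each
#' true non-case is labeled positive with probability `1 - specificity`,
#' independently across samples.
#'
#' @param true_status 0/1 vector.
#' @param spec a [channel_spec()].
#' @param seed integer seed.
#' @return 0/1 integer vector of observed labels.
#' @export
apply_label_channel <- function(true_status, spec, seed) {
  stopifnot(inherits(spec, "channel_spec"))
  if (!all(true_status %in% 0:1)) abort("`true_status` must be 0/1.")
  withr::with_seed(seed, {
    p <- ifelse(true_status == 1, spec$sensitivity, 1 - spec$specificity)
    as.integer(rbinom(length(true_status), 1L, p))
  })
}

#' Simulate billing occurrence counts
#'
#' Samples labeled positive by the billing channel receive at least one
#' billing occurrence; labeled true cases add `Poisson(mean_case_extra)`
#' repeat occurrences and labeled false positives add
#' `Poisson(mean_fp_extra)`. With the default means (2.0 vs 0.3) repeat
#' billing is informative, so restricting cases to higher counts raises
#' positive predictive value. Unbilled samples get count 0.
#'
#' @param true_status,billing_labels 0/1 vectors.
#' @param params length-2 nonnegative means `(mean_case_extra, mean_fp_extra)`.
#' @param seed integer seed.
#' @return Nonnegative integer count vector.
#' @export
simulate_billing_counts <- function(true_status, billing_labels,
                                    params = c(2.0, 0.3), seed = 1L) {
  if (length(params) != 2 || any(!is.finite(params)) || any(params < 0)) {
    abort("`params` must be two nonnegative finite means.")
  }
  if (length(true_status) != length(billing_labels)) {
    abort("`true_status` and `billing_labels` differ in length.")
  }
  withr::with_seed(seed, {
    counts <- integer(length(true_status))
    pos <- billing_labels == 1
    mu <- ifelse(true_status[pos] == 1, params[1], params[2])
    counts[pos] <- 1L + rpois(sum(pos), mu)
    counts
  })
}

#' Simulate a complete labeled cohort
#'
#' Runs the full generative model: genotypes, liability-threshold disease,
#' every configured labeling channel, and billing occurrence counts (when a
#' channel named `billing` exists). Per-stage seeds are derived from
#' `config$seed` by a fixed offset scheme (genotypes `+0`, disease `+1`,
#' channel *i* `+10+i`, billing counts `+100`), so stages can be reproduced in
#' isolation.
#'
#' @param config a [sim_config()].
#' @return A `true_cohort` whose `pheno` tibble carries one 0/1 column per
#'   channel and a `billing_count` column.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gm <- simulate_genotypes(config)
  cohort <- simulate_disease(gm, config)
  for (i in seq_along(config$channels)) {
    ch <- config$channels[[i]]
    cohort$pheno[[ch$name]] <- apply_label_channel(
      cohort$pheno$true_status, ch,
      seed = config$seed + 10L + i
    )
  }
  if ("billing" %in% names(config$channels)) {
    cohort$pheno$billing_count <- simulate_billing_counts(
      cohort$pheno$true_status, cohort$pheno$billing,
      params = config$billing_count_params, seed = config$seed + 100L
    )
  }
  cohort$config <- config
  cohort
}

#' Channel names carried by a cohort's phenotype table
#' @param pheno a cohort phenotype tibble (or `true_cohort`).
#' @return Character vector of channel column names.
#' @export
channel_names <- function(pheno) {
  if (inherits(pheno, "true_cohort")) pheno <- pheno$pheno
  setdiff(
    names(pheno),
    c("sample_id", "subpop", "liability", "genetic_liability", "true_status", "billing_count")
  )
}

#' Write a cohort to disk
#'
#' Emits the PLINK bed/bim/fam triplet for the genotypes and a tab-separated
#' phenotype table (`sample_id`, `true_status`, one column per channel,
#' `billing_count`); the pair round-trips losslessly through [read_plink()]
#' and [read_pheno()].
#'
#' @param cohort a `true_cohort`.
#' @param prefix output path prefix; writes `<prefix>.bed/.bim/.fam` and
#'   `<prefix>.pheno.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "true_cohort"))
  write_plink(cohort$genotypes, prefix)
  cols <- c(
    "sample_id", "true_status", channel_names(cohort),
    intersect("billing_count", names(cohort$pheno))
  )
  write_pheno(cohort$pheno[, cols], paste0(prefix, ".pheno.tsv"))
  invisible(prefix)
}
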