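#' P-value threshold grid for score construction
#'
#' The default grid is 12 cutoffs log-spaced from 5e-5 to 0.1 inclusive, the
#' range over which candidate variant subsets are tuned.
#'
#' @param p_min,p_max grid endpoints in `(0, 1]`.
#' @param n number of cutoffs.
#' @return Strictly increasing numeric vector of cutoffs.
#' @export
threshold_grid <- function(p_min = 5e-5, p_max = 0.1, n = 12) {
  check_range(p_min, "p_min", 0, 1, open_lo = TRUE)
  check_range(p_max, "p_max", 0, 1, open_lo = TRUE)
  if (p_min >= p_max) abort("`p_min` must be < `p_max`.")
  check_count(n, "n", min = 2)
  exp(seq(log(p_min), log(p_max), length.out = n))
}

#' Build a shared stratified cross-validation fold plan
#'
#' Partitions the cohort into `k` folds, stratified on the union-of-channels
#' case indicator (a sample is a stratum-1 member if any channel labels it
#' positive), so that a single plan serves every labeling channel and their
#' scores remain comparable: all channels see the same training and testing
#' subgroups. Within each stratum, shuffled samples are dealt round-robin, so
#' each fold's case count is within one of the others.
#'
#' @param labels_by_channel 0/1 vector, matrix or data frame (one column per
#'   channel).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_plan`: list with `fold` (integer assignments), `k`,
#'   `seed`.
#' @export
make_folds <- function(labels_by_channel, k = 5, seed = 1L) {
  check_count(k, "k", min = 2)
  lab <- as.matrix(labels_by_channel)
  if (anyNA(lab) || !all(lab %in% c(0, 1))) abort("labels must be 0/1 with no NA.")
  pos <- rowSums(lab) > 0
  n <- length(pos)
  if (sum(pos) < k) abort("fewer union-positive samples than folds.")
  if (sum(!pos) < k) abort("fewer union-negative samples than folds.")
  fold <- integer(n)
  withr::with_seed(seed, {
    for (stratum in c(TRUE, FALSE)) {
      idx <- which(pos == stratum)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed)),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf(
    "<fold_plan> k = %d over %d samples (seed %d); fold sizes: %s\n",
    x$k, length(x$fold), x$seed, paste(tabulate(x$fold, x$k), collapse = ", ")
  ))
  invisible(x)
}

#' Select a weight set by p-value threshold
#'
#' Keeps every converged variant with Wald p at or below `cutoff`; weights
#' are the log odds ratios oriented to the effect allele. An empty selection
#' returns a zero-row weight set (callers treat that cell as unusable).
#'
#' @param assoc an `assoc_result` (from [logistic_assoc()] or
#'   [read_assoc()]).
#' @param cutoff p-value cutoff in `(0, 1]`.
#' @return A `weight_set` tibble: `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, `p`, `eaf`, `provenance`.
#' @export
select_by_threshold <- function(assoc, cutoff) {
  if (nrow(assoc) == 0) abort("`assoc` is empty.")
  check_range(cutoff, "cutoff", 0, 1, open_lo = TRUE)
  sel <- assoc |>
    filter(.data$converged, is.finite(.data$p), .data$p <= cutoff) |>
    mutate(weight = .data$log_or, provenance = "internal") |>
    select("variant_id", "effect_allele", "other_allele", "weight", "p", "eaf",
           "provenance")
  class(sel) <- c("weight_set", setdiff(class(sel), "assoc_result"))
  sel
}

#' Read a GWAS summary-statistic / weights table
#'
#' Tab-separated with columns `variant_id`, `effect_allele`, `other_allele`,
#' an effect column (`log_or`, `weight`, or an odds ratio `or`/`OR` which is
#' log-transformed), and optionally `p` and `eaf`. Rows with missing alleles
#' or non-finite effects are rejected; the rejected count is attached as
#' attribute `n_rejected`.
#'
#' @param path file path (or a data frame already in this dialect).
#' @return A `weight_set` tibble with `provenance = "external"`.
#' @export
read_weights <- function(path) {
  w <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    as_tibble(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  }
  names(w)[names(w) %in% c("OR", "odds_ratio")] <- "or"
  req <- c("variant_id", "effect_allele", "other_allele")
  miss <- setdiff(req, names(w))
  if (length(miss)) abort(paste0("weights file missing column(s): ", paste(miss, collapse = ", ")))
  if (!"weight" %in% names(w)) {
    if ("log_or" %in% names(w)) {
      w$weight <- as.numeric(w$log_or)
    } else if ("or" %in% names(w)) {
      w$weight <- log(as.numeric(w$or))
    } else {
      abort("weights file needs a `log_or`, `weight` or `or` column.")
    }
  }
  if (!"p" %in% names(w)) w$p <- NA_real_
  if (!"eaf" %in% names(w)) w$eaf <- NA_real_
  ok <- !is.na(w$variant_id) & nzchar(w$effect_allele) & nzchar(w$other_allele) &
    is.finite(w$weight) & !is.na(w$effect_allele) & !is.na(w$other_allele)
  n_rejected <- sum(!ok)
  w <- w[ok, c("variant_id", "effect_allele", "other_allele", "weight", "p", "eaf")]
  if (nrow(w) == 0) abort("no usable rows in weights file.")
  if (anyDuplicated(w$variant_id)) abort("duplicate variant ids in weights file.")
  w$provenance <- "external"
  attr(w, "n_rejected") <- n_rejected
  class(w) <- c("weight_set", class(w))
  w
}

# Orient a weight set to the panel's coded allele (allele1). Weights whose
# effect allele is the panel's allele2 count complementary dosage: their
# contribution is w * (2 - d), implemented as a negated weight plus the
# constant 2w (so scores are exactly invariant to how the panel codes its
# alleles). Weights matching neither allele are dropped and counted. Returns
# the weight subset aligned to panel columns with a `col` index, the constant
# `offset`, and an imputation frequency for the coded allele.
harmonize_weights <- function(gm, weights) {
  idx <- match(weights$variant_id, gm$variants$variant_id)
  in_panel <- !is.na(idx)
  n_missing_panel <- sum(!in_panel)
  w <- weights[in_panel, ]
  col <- idx[in_panel]
  a1 <- gm$variants$allele1[col]
  a2 <- gm$variants$allele2[col]
  same <- w$effect_allele == a1 & w$other_allele == a2
  flipped <- w$effect_allele == a2 & w$other_allele == a1
  keep <- same | flipped
  n_mismatch <- sum(!keep)
  w <- w[keep, ]
  col <- col[keep]
  flipped <- flipped[keep]
  weight <- ifelse(flipped, -w$weight, w$weight)
  # imputation frequency refers to the panel's coded allele; fall back to the
  # panel frequency only where the weight set carries none
  eaf1 <- ifelse(flipped, 1 - w$eaf, w$eaf)
  need_f <- !is.finite(eaf1)
  if (any(need_f)) {
    panel_f <- allele_freq(subset_genotypes(gm, variants = col[need_f]))
    eaf1[need_f] <- panel_f
  }
  list(
    col = col, weight = weight, eaf = eaf1,
    offset = 2 * sum(w$weight[flipped]),
    n_missing_panel = n_missing_panel, n_mismatch = n_mismatch
  )
}

#' Score a cohort with a weight set
#'
#' The polygenic score of a sample is the mean over scored variants of
#' (coded-allele dosage x log-OR weight), the PLINK `--score` convention.
#' Missing dosages are imputed as twice the weight set's effect-allele
#' frequency (training-set frequency for internally derived weights, panel
#' frequency otherwise); weight variants absent from the panel are skipped
#' and counted, as are variants whose alleles match neither panel allele.
#' Weights whose effect allele is the panel's `allele2` contribute
#' `weight * (2 - dosage)`, so scores do not depend on which allele the
#' panel happens to code.
#'
#' @param gm a [genotype_matrix()].
#' @param weights a `weight_set` (from [select_by_threshold()] or
#'   [read_weights()]).
#' @return A `score_set` tibble (`sample_id`, `prs`) with attributes
#'   `n_variants_used`, `n_missing_panel`, `n_mismatch`.
#' @export
score_prs <- function(gm, weights) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(weights) == 0) abort("empty weight set; nothing to score.")
  h <- harmonize_weights(gm, weights)
  if (length(h$col) == 0) {
    abort(sprintf(
      "no overlap between weights and panel (%d absent, %d allele-mismatched).",
      h$n_missing_panel, h$n_mismatch
    ))
  }
  D <- gm$dosages[, h$col, drop = FALSE]
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- 2 * h$eaf[na_idx[, 2]]
  }
  prs <- (as.vector(D %*% h$weight) + h$offset) / length(h$col)
  out <- tibble(sample_id = gm$samples$sample_id, prs = prs)
  attr(out, "n_variants_used") <- length(h$col)
  attr(out, "n_missing_panel") <- h$n_missing_panel
  attr(out, "n_mismatch") <- h$n_mismatch
  class(out) <- c("score_set", class(out))
  out
}

#' Cross-validated p-value-thresholded polygenic scores
#'
#' For each fold of the plan, per-variant logistic association is fit on the
#' training samples only; test samples are then scored at every grid cutoff.
#' The selected cutoff maximizes the fold-mean test AUC (the conventional
#' procedure, flagged `selected-on-test` because it is optimistically
#' biased); `selection = "nested"` instead picks each fold's cutoff by an
#' inner cross-validation within its training set.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param labels 0/1 vector for the channel under evaluation.
#' @param covariates optional covariate matrix (e.g. PC scores).
#' @param grid cutoff grid from [threshold_grid()].
#' @param plan a [make_folds()] plan.
#' @param selection `"test-auc"` (default) or `"nested"`.
#' @param inner_k inner fold count for nested selection.
#' @param fold_data optional precomputed per-fold genotype subsets from
#'   `make_fold_data()`, shared across channels to avoid repeated copies.
#' @return A `cv_prs` object: `scores` (sample x fold x threshold tibble),
#'   `cells` (per fold x threshold AUC and variant counts), `best_threshold`,
#'   `fold_assoc` (per-fold association tables), plus the plan/grid/labels.
#' @export
cross_validated_scores <- function(gm, labels, covariates = NULL,
                                   grid = threshold_grid(), plan,
                                   selection = c("test-auc", "nested"),
                                   inner_k = 4L, fold_data = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(plan, "fold_plan"))
  selection <- match.arg(selection)
  if (length(plan$fold) != n_samples(gm)) abort("fold plan does not match cohort size.")
  labels <- as.integer(labels)
  grid <- sort(unique(grid))
  folds <- seq_len(plan$k)
  if (is.null(fold_data)) fold_data <- make_fold_data(gm, plan)
  fold_assoc <- vector("list", plan$k)
  score_rows <- list()
  cell_rows <- list()
  for (f in folds) {
    tr <- fold_data[[f]]$tr
    te <- fold_data[[f]]$te
    if (length(unique(labels[tr])) < 2) {
      abort(sprintf("fold %d has single-class training labels.", f))
    }
    gm_tr <- fold_data[[f]]$gm_tr
    gm_te <- fold_data[[f]]$gm_te
    cov_tr <- if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE]
    assoc <- logistic_assoc(gm_tr, labels[tr],
      covariates = cov_tr,
      imputed = fold_data[[f]]$D_tr, eaf = fold_data[[f]]$eaf_tr
    )
    fold_assoc[[f]] <- assoc
    for (t in grid) {
      ws <- select_by_threshold(assoc, t)
      if (nrow(ws) == 0) {
        cell_rows[[length(cell_rows) + 1]] <- tibble(
          fold = f, threshold = t, n_variants = 0L, auc = NA_real_, usable = FALSE
        )
        next
      }
      sc <- score_prs(gm_te, ws)
      auc <- if (length(unique(labels[te])) < 2) NA_real_ else roc_auc(sc$prs, labels[te])
      score_rows[[length(score_rows) + 1]] <- tibble(
        sample_id = sc$sample_id, fold = f, threshold = t, prs = sc$prs,
        n_variants_used = attr(sc, "n_variants_used")
      )
      cell_rows[[length(cell_rows) + 1]] <- tibble(
        fold = f, threshold = t, n_variants = attr(sc, "n_variants_used"),
        auc = auc, usable = TRUE
      )
    }
  }
  cells <- bind_rows(cell_rows)
  scores <- bind_rows(score_rows)
  if (nrow(scores) == 0) abort("no usable (fold, threshold) cell produced any scores.")
  best <- pick_best_threshold(cells)
  if (selection == "nested") {
    per_fold_best <- vapply(folds, function(f) {
      tr <- which(plan$fold != f)
      inner_plan <- make_folds(labels[tr], k = inner_k, seed = plan$seed + 1000L + f)
      inner <- cross_validated_scores(
        subset_genotypes(gm, samples = tr), labels[tr],
        covariates = if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE],
        grid = grid, plan = inner_plan, selection = "test-auc"
      )
      inner$best_threshold
    }, numeric(1))
  } else {
    per_fold_best <- rep(best, plan$k)
  }
  structure(
    list(
      scores = scores, cells = cells, best_threshold = best,
      per_fold_threshold = per_fold_best, selection = selection,
      selection_flag = if (selection == "test-auc") "selected-on-test" else "nested",
      fold_assoc = fold_assoc, plan = plan, grid = grid, labels = labels,
      sample_ids = gm$samples$sample_id
    ),
    class = "cv_prs"
  )
}

# Per-fold training/test genotype subsets, built once and shared across the
# channels evaluated on one plan.
make_fold_data <- function(gm, plan) {
  lapply(seq_len(plan$k), function(f) {
    tr <- which(plan$fold != f)
    te <- which(plan$fold == f)
    gm_tr <- subset_genotypes(gm, samples = tr)
    list(
      tr = tr, te = te,
      gm_tr = gm_tr,
      gm_te = subset_genotypes(gm, samples = te),
      D_tr = impute_dosages(gm_tr),
      eaf_tr = unname(allele_freq(gm_tr))
    )
  })
}

# Fold-mean AUC per threshold, preferring thresholds usable in every fold.
pick_best_threshold <- function(cells) {
  agg <- cells |>
    group_by(.data$threshold) |>
    summarise(
      n_usable = sum(.data$usable & is.finite(.data$auc)),
      mean_auc = mean(.data$auc[.data$usable]),
      .groups = "drop"
    ) |>
    filter(.data$n_usable > 0)
  if (nrow(agg) == 0) abort("no threshold produced a usable AUC in any fold.")
  agg <- agg |> filter(.data$n_usable == max(.data$n_usable))
  agg$threshold[which.max(agg$mean_auc)]
}

#' @export
print.cv_prs <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_prs> k = %d folds x %d thresholds; best cutoff %.3g (fold-mean AUC %.4f, %s)\n",
    x$plan$k, length(x$grid), x$best_threshold, g$mean_auc, x$selection_flag
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.cv_prs <- function(x, ...) x$cells

#' @rdname tidiers
#' @export
glance.cv_prs <- function(x, ...) {
  at_best <- x$cells |> filter(.data$threshold == x$best_threshold, .data$usable)
  tibble(
    best_threshold = x$best_threshold,
    mean_auc = mean(at_best$auc, na.rm = TRUE),
    sd_auc = sd(at_best$auc[is.finite(at_best$auc)]),
    n_folds = x$plan$k,
    mean_n_variants = mean(at_best$n_variants),
    selection = x$selection_flag
  )
}

#' Score a cohort with external (published) weights
#'
#' Applies a published summary-statistic table to the panel: weights are the
#' log odds ratios, harmonized to the panel's coded alleles (see
#' [score_prs()] for the allele rules), optionally restricted to variants
#' whose published p-value passes `cutoff`.
#'
#' @param gm a [genotype_matrix()].
#' @param weights a `weight_set` from [read_weights()], or a path to one.
#' @param cutoff optional p-value cutoff applied to the file's `p` column
#'   (`NULL` scores all usable variants).
#' @return A `score_set` tibble, as [score_prs()].
#' @export
score_with_external <- function(gm, weights, cutoff = NULL) {
  if (!inherits(weights, "weight_set")) weights <- read_weights(weights)
  if (!is.null(cutoff)) {
    check_range(cutoff, "cutoff", 0, 1, open_lo = TRUE)
    if (all(is.na(weights$p))) abort("cutoff requested but weights file has no p column.")
    weights <- weights[is.finite(weights$p) & weights$p <= cutoff, ]
    if (nrow(weights) == 0) abort("no weights pass the requested cutoff.")
  }
  score_prs(gm, weights)
}

#' Cross-validated evaluation of external weights
#'
#' External weights need no training, but to stay comparable with internally
#' trained scores they are evaluated on the same test folds: per grid cutoff
#' the whole cohort is scored once and AUC is measured fold by fold; the
#' reported cutoff maximizes fold-mean test AUC. Pass `grid = NULL` to use
#' all variants without thresholding.
#'
#' @inheritParams cross_validated_scores
#' @param weights a `weight_set` from [read_weights()].
#' @return A `cv_prs` object (with empty `fold_assoc`).
#' @export
cv_external_scores <- function(gm, weights, labels, grid = threshold_grid(), plan) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(plan, "fold_plan"))
  if (!inherits(weights, "weight_set")) weights <- read_weights(weights)
  labels <- as.integer(labels)
  if (is.null(grid) || all(is.na(weights$p))) grid <- 1
  grid <- sort(unique(grid))
  score_rows <- list()
  cell_rows <- list()
  for (t in grid) {
    ws <- if (all(is.na(weights$p))) {
      weights
    } else {
      weights[is.finite(weights$p) & weights$p <= t, ]
    }
    if (nrow(ws) == 0) {
      cell_rows[[length(cell_rows) + 1]] <- tibble(
        fold = seq_len(plan$k), threshold = t, n_variants = 0L,
        auc = NA_real_, usable = FALSE
      )
      next
    }
    sc <- score_prs(gm, ws)
    for (f in seq_len(plan$k)) {
      te <- which(plan$fold == f)
      auc <- if (length(unique(labels[te])) < 2) NA_real_ else roc_auc(sc$prs[te], labels[te])
      score_rows[[length(score_rows) + 1]] <- tibble(
        sample_id = sc$sample_id[te], fold = f, threshold = t, prs = sc$prs[te],
        n_variants_used = attr(sc, "n_variants_used")
      )
      cell_rows[[length(cell_rows) + 1]] <- tibble(
        fold = f, threshold = t, n_variants = attr(sc, "n_variants_used"),
        auc = auc, usable = TRUE
      )
    }
  }
  cells <- bind_rows(cell_rows)
  scores <- bind_rows(score_rows)
  if (nrow(scores) == 0) abort("external weights produced no usable scores at any cutoff.")
  best <- pick_best_threshold(cells)
  structure(
    list(
      scores = scores, cells = cells, best_threshold = best,
      per_fold_threshold = rep(best, plan$k), selection = "test-auc",
      selection_flag = "selected-on-test", fold_assoc = list(),
      plan = plan, grid = grid, labels = labels,
      sample_ids = gm$samples$sample_id
    ),
    class = "cv_prs"
  )
}
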