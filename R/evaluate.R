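#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) formulation: the probability that a randomly
#' chosen case outscores a randomly chosen control, with ties counted one
#' half.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(2, 3, 1, 4), c(1, 1, 0, 0)) # 0.5
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels, scores)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PRS mean difference between cases and controls
#'
#' `mean(case scores) - mean(control scores)`, the first of the three
#' channel-comparison statistics.
#'
#' @inheritParams roc_auc
#' @return A real number.
#' @export
mean_difference <- function(scores, labels) {
  check_two_classes(labels, scores)
  mean(scores[labels == 1]) - mean(scores[labels == 0])
}

#' Odds ratio per standard deviation of score
#'
#' Exponentiated slope from a logistic regression of the label on the
#' z-scored PRS (mean and SD taken over the full evaluated set). Complete
#' separation or non-convergence is flagged: the statistic is returned as
#' `NA` with a warning, never as a spuriously huge number.
#'
#' @inheritParams roc_auc
#' @return A positive scalar, or `NA` when non-estimable.
#' @export
or_per_sd <- function(scores, labels) {
  check_two_classes(labels, scores)
  s <- sd(scores)
  if (!is.finite(s) || s == 0) abort("scores have zero variance; OR per SD undefined.")
  z <- (scores - mean(scores)) / s
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(labels ~ z, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  b <- coef(fit)[["z"]]
  if (sep || !fit$converged || abs(b) > 25) {
    warn("separation or non-convergence in OR-per-SD fit; reported as NA.")
    return(NA_real_)
  }
  exp(b)
}

check_two_classes <- function(labels, scores) {
  if (length(labels) != length(scores)) abort("`scores` and `labels` differ in length.")
  if (anyNA(labels) || !all(labels %in% c(0, 1))) abort("`labels` must be 0/1 with no NA.")
  if (length(unique(labels)) < 2) abort("both classes must be present.")
  invisible(TRUE)
}

#' Aggregate per-fold statistics into a summary row
#'
#' Mean and sample (n-1) standard deviation across folds, the "(S.D.)"
#' convention of the channel comparison tables.
#'
#' @param fold_stats data frame with one row per fold and numeric statistic
#'   columns.
#' @param stats columns to summarise.
#' @return One-row tibble with `<stat>` and `<stat>_sd` columns.
#' @export
summarize_folds <- function(fold_stats,
                            stats = c("mean_diff", "auc", "or_per_sd")) {
  if (nrow(fold_stats) < 2) abort("need at least two folds to summarise.")
  out <- purrr::map(stats, function(s) {
    v <- fold_stats[[s]]
    tibble(!!s := mean(v, na.rm = TRUE), !!paste0(s, "_sd") := sd(v[is.finite(v)]))
  })
  bind_cols(out)
}

#' Per-fold test-set statistics for a cross-validated score set
#'
#' Extracts, for each fold, the test-fold scores at that fold's selected
#' cutoff and computes the three comparison statistics against the supplied
#' labels (by default the labels the scores were trained on; pass
#' `true_status` to evaluate against simulated truth).
#'
#' @param cv a `cv_prs` object.
#' @param labels optional 0/1 vector in cohort order (defaults to the
#'   training labels stored in `cv`).
#' @return Tibble with one row per fold: `fold`, `threshold`, `n_test`,
#'   `n_cases`, `mean_diff`, `auc`, `or_per_sd`.
#' @export
fold_statistics <- function(cv, labels = NULL) {
  stopifnot(inherits(cv, "cv_prs"))
  labels <- if (is.null(labels)) cv$labels else as.integer(labels)
  lab_of <- setNames(labels, cv$sample_ids)
  purrr::map(seq_len(cv$plan$k), function(f) {
    thr <- cv$per_fold_threshold[f]
    rows <- cv$scores |> filter(.data$fold == f, .data$threshold == thr)
    if (nrow(rows) == 0) {
      return(tibble(
        fold = f, threshold = thr, n_test = 0L, n_cases = 0L,
        mean_diff = NA_real_, auc = NA_real_, or_per_sd = NA_real_
      ))
    }
    lab <- unname(lab_of[rows$sample_id])
    two <- length(unique(lab)) == 2
    tibble(
      fold = f, threshold = thr, n_test = nrow(rows), n_cases = sum(lab == 1),
      mean_diff = if (two) mean_difference(rows$prs, lab) else NA_real_,
      auc = if (two) roc_auc(rows$prs, lab) else NA_real_,
      or_per_sd = if (two && sd(rows$prs) > 0) {
        suppressWarnings(or_per_sd(rows$prs, lab))
      } else {
        NA_real_
      }
    )
  }) |> bind_rows()
}

#' Evaluate every labeling channel on a shared fold plan
#'
#' The core comparison: for each channel, cross-validated thresholded scores
#' are trained on that channel's labels (cases = labeled positive, controls =
#' everyone else) and the three statistics are aggregated across test folds.
#' All channels share one fold plan so their figures are directly
#' comparable. When the phenotype table carries `true_status`, each channel
#' is additionally evaluated against truth.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param pheno phenotype tibble (`sample_id`, channel columns, optionally
#'   `true_status`), rows aligned with `gm` samples.
#' @param channels channel column names to evaluate.
#' @param grid p-value cutoff grid.
#' @param plan optional [make_folds()] plan (built from the union of the
#'   evaluated channels when omitted).
#' @param k,seed fold plan parameters when `plan` is omitted.
#' @param covariates optional covariate matrix (PC scores).
#' @param selection threshold selection rule, see [cross_validated_scores()].
#' @return A `channel_eval` object: `summary` (one row per channel),
#'   `fold_stats`, `cv` (per-channel `cv_prs`), `plan`.
#' @export
evaluate_channels <- function(gm, pheno, channels = channel_names(pheno),
                              grid = threshold_grid(), plan = NULL,
                              k = 5, seed = 1L, covariates = NULL,
                              selection = "test-auc") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(pheno$sample_id == gm$samples$sample_id)) {
    abort("`pheno` rows must align with the genotype samples.")
  }
  if (length(channels) == 0) abort("no channels to evaluate.")
  if (is.null(plan)) {
    plan <- make_folds(pheno[, channels, drop = FALSE], k = k, seed = seed)
  }
  has_truth <- "true_status" %in% names(pheno) && !anyNA(pheno$true_status)
  fold_data <- make_fold_data(gm, plan)
  cvs <- list()
  fold_stats <- list()
  for (ch in channels) {
    cv <- cross_validated_scores(gm, pheno[[ch]],
      covariates = covariates,
      grid = grid, plan = plan, selection = selection, fold_data = fold_data
    )
    cvs[[ch]] <- cv
    fs <- fold_statistics(cv) |> mutate(channel = ch, against = "channel")
    if (has_truth) {
      fs_true <- fold_statistics(cv, labels = pheno$true_status) |>
        mutate(channel = ch, against = "truth")
      fs <- bind_rows(fs, fs_true)
    }
    fold_stats[[ch]] <- fs
  }
  fold_stats <- bind_rows(fold_stats)
  summary <- fold_stats |>
    filter(.data$against == "channel") |>
    group_by(.data$channel) |>
    dplyr::group_modify(~ summarize_folds(.x)) |>
    ungroup()
  counts <- purrr::imap(
    cvs,
    ~ tibble(
      channel = .y, best_threshold = .x$best_threshold,
      n_cases = sum(.x$labels == 1), n_controls = sum(.x$labels == 0)
    )
  ) |> bind_rows()
  summary <- left_join(counts, summary, by = "channel")
  if (has_truth) {
    truth <- fold_stats |>
      filter(.data$against == "truth") |>
      group_by(.data$channel) |>
      summarise(auc_vs_truth = mean(.data$auc, na.rm = TRUE), .groups = "drop")
    summary <- left_join(summary, truth, by = "channel")
  }
  structure(
    list(summary = summary, fold_stats = fold_stats, cv = cvs, plan = plan),
    class = "channel_eval"
  )
}

#' @export
print.channel_eval <- function(x, ...) {
  cat("<channel_eval>\n")
  print(compare_channels(x)$ranking)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.channel_eval <- function(x, ...) x$fold_stats

#' @rdname tidiers
#' @export
glance.channel_eval <- function(x, ...) x$summary

#' Rank labeling channels by discriminative power
#'
#' Orders channels by fold-mean AUC (computed on their own labels). Channels
#' whose fold-mean AUCs differ by less than `tie_tol` are reported as tied
#' rather than silently ordered. Requires that every channel was evaluated on
#' the same fold plan; a single channel yields a degenerate ranking with a
#' warning.
#'
#' @param eval a `channel_eval` object.
#' @param tie_tol AUC difference treated as a tie.
#' @return A list: `ranking` (summary tibble ordered by AUC with a `rank`
#'   column, ties sharing a rank) and `ties` (character vector of tied
#'   groups, if any).
#' @export
compare_channels <- function(eval, tie_tol = 1e-10) {
  stopifnot(inherits(eval, "channel_eval"))
  s <- eval$summary |> arrange(desc(.data$auc))
  if (nrow(s) == 1) warn("single channel: ranking is degenerate.")
  rank <- integer(nrow(s))
  rank[1] <- 1L
  if (nrow(s) > 1) {
    for (i in 2:nrow(s)) {
      rank[i] <- if (abs(s$auc[i] - s$auc[i - 1]) <= tie_tol) rank[i - 1] else i
    }
  }
  s$rank <- rank
  ties <- s |>
    group_by(.data$rank) |>
    filter(n() > 1) |>
    summarise(group = paste(.data$channel, collapse = " = "), .groups = "drop")
  list(ranking = s |> select("rank", dplyr::everything()), ties = ties$group)
}

#' Label-set overlap report across channels
#'
#' Partitions the union of positively labeled samples into exact set regions
#' (labeled by exactly one channel, each pair, all three, ...) and reports,
#' per channel, what fraction of its positives fall in regions of each
#' overlap order. Channel totals equal the sum of their regions by
#' construction.
#'
#' @param labels_by_channel data frame or matrix of 0/1 columns, one per
#'   channel (at least two).
#' @return An `overlap_report` list: `regions` (tibble `region`, `n`) and
#'   `per_channel` (tibble `channel`, `n_positive`, `order`, `n`, `pct`).
#' @export
overlap_report <- function(labels_by_channel) {
  lab <- as.matrix(labels_by_channel)
  if (ncol(lab) < 2) abort("need at least two channels for an overlap report.")
  if (is.null(colnames(lab))) colnames(lab) <- paste0("channel", seq_len(ncol(lab)))
  if (anyNA(lab) || !all(lab %in% c(0, 1))) abort("labels must be 0/1 with no NA.")
  ord <- rowSums(lab)
  pos <- ord > 0
  region_key <- apply(lab[pos, , drop = FALSE], 1, function(r) {
    paste(colnames(lab)[r == 1], collapse = "+")
  })
  regions <- tibble(region = region_key) |>
    dplyr::count(.data$region, name = "n") |>
    arrange(desc(.data$n))
  per_channel <- purrr::map(colnames(lab), function(ch) {
    np <- sum(lab[, ch])
    tibble(
      channel = ch, n_positive = np, order = seq_len(ncol(lab)),
      n = vapply(
        seq_len(ncol(lab)),
        function(o) sum(lab[, ch] == 1 & ord == o), integer(1)
      )
    ) |> mutate(pct = if (np > 0) 100 * .data$n / np else 0)
  }) |> bind_rows()
  structure(list(regions = regions, per_channel = per_channel),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  print(x$per_channel)
  invisible(x)
}

#' Billing-count sub-phenotype sweep
#'
#' Re-defines the billing channel at increasing occurrence-count thresholds
#' (cases = billed at least `t` times, controls = everyone else), reruns the
#' cross-validated scoring pipeline at the same fixed cutoff grid, and
#' reports the three statistics per threshold together with the fraction of
#' each sub-phenotype's cases that every other channel also labels positive
#' (the full-overlap percentage). Thresholds leaving fewer cases than folds
#' are reported as non-estimable rows.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param pheno phenotype tibble with `billing_count` and channel columns.
#' @param thresholds count thresholds (default 1, 2, 3).
#' @param grid,plan,covariates,selection as in [evaluate_channels()].
#' @param other_channels channels used for the overlap column (defaults to
#'   all channels except `billing`).
#' @return A tibble, one row per threshold: the summary statistics columns of
#'   [evaluate_channels()] plus `count_threshold`, `pct_full_overlap` and
#'   `estimable`.
#' @export
billing_count_sweep <- function(gm, pheno, thresholds = c(1, 2, 3),
                                grid = threshold_grid(), plan = NULL,
                                covariates = NULL, selection = "test-auc",
                                other_channels = NULL) {
  if (!"billing_count" %in% names(pheno)) abort("`pheno` has no `billing_count` column.")
  if (is.null(other_channels)) {
    other_channels <- setdiff(channel_names(pheno), "billing")
  }
  if (is.null(plan)) {
    plan <- make_folds(pheno[, channel_names(pheno), drop = FALSE], k = 5, seed = 1L)
  }
  fold_data <- make_fold_data(gm, plan)
  purrr::map(thresholds, function(t) {
    labels_t <- as.integer(pheno$billing_count >= t)
    base <- tibble(count_threshold = t, n_cases = sum(labels_t), n_controls = sum(labels_t == 0))
    if (sum(labels_t) < plan$k || sum(labels_t == 0) < plan$k) {
      return(base |> mutate(estimable = FALSE))
    }
    cv <- cross_validated_scores(gm, labels_t,
      covariates = covariates,
      grid = grid, plan = plan, selection = selection, fold_data = fold_data
    )
    fs <- fold_statistics(cv)
    sm <- summarize_folds(fs)
    pct_full <- if (length(other_channels) > 0) {
      in_others <- rowSums(pheno[, other_channels, drop = FALSE]) == length(other_channels)
      100 * sum(labels_t == 1 & in_others) / sum(labels_t)
    } else {
      NA_real_
    }
    bind_cols(base, sm) |>
      mutate(
        best_threshold = cv$best_threshold,
        pct_full_overlap = pct_full, estimable = TRUE
      )
  }) |> bind_rows()
}
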