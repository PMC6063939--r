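#' Read a pipeline run configuration
#'
#' A flat YAML document describing one end-to-end run: the cohort generator
#' block (any [sim_config()] field, with `channels` as a named map of
#' `{sensitivity, specificity}` blocks), and optional `qc`, `pcs`, `grid`,
#' `folds`, `billing_thresholds` blocks. Unknown fields are rejected and
#' missing channel parameters are reported by name.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return A validated `run_config` list with elements `sim` (a
#'   [sim_config()]), `qc`, `pcs`, `grid`, `folds`, `billing_thresholds`,
#'   `selection`.
#' @export
read_run_config <- function(config) {
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(raw)) abort("config must be a YAML mapping or a named list.")
  known <- c(
    "n_samples", "n_variants", "maf_low", "maf_high", "n_causal",
    "h2_liability", "prevalence", "n_subpops", "fst", "channels",
    "billing_count_params", "missing_rate", "seed",
    "qc", "pcs", "grid", "folds", "billing_thresholds", "selection"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  sim_args <- raw[intersect(names(raw), c(
    "n_samples", "n_variants", "maf_low", "maf_high", "n_causal",
    "h2_liability", "prevalence", "n_subpops", "fst",
    "billing_count_params", "missing_rate", "seed"
  ))]
  if (!is.null(raw$billing_count_params)) {
    sim_args$billing_count_params <- unlist(raw$billing_count_params)
  }
  if (!is.null(raw$channels)) {
    chans <- purrr::imap(raw$channels, function(ch, nm) {
      for (fld in c("sensitivity", "specificity")) {
        if (is.null(ch[[fld]])) {
          abort(sprintf("channel `%s` is missing field `%s`.", nm, fld))
        }
      }
      channel_spec(nm, ch$sensitivity, ch$specificity)
    })
    sim_args$channels <- chans
  }
  sim <- do.call(sim_config, sim_args)
  qc_defaults <- list(
    maf_min = 0.01, callrate_min = 0.90, hwe_alpha = 1e-6,
    window = 50, step = 5, vif_max = 10, passes = 3
  )
  qc <- utils::modifyList(qc_defaults, raw$qc %||% list())
  grid_defaults <- list(p_min = 5e-5, p_max = 0.1, n = 12)
  grid <- utils::modifyList(grid_defaults, raw$grid %||% list())
  structure(
    list(
      sim = sim, qc = qc, pcs = raw$pcs %||% 2L,
      grid = do.call(threshold_grid, grid),
      folds = raw$folds %||% 5L,
      billing_thresholds = raw$billing_thresholds %||% c(1, 2, 3),
      selection = raw$selection %||% "test-auc"
    ),
    class = "run_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the full pipeline: simulate, QC, associate, score, evaluate
#'
#' One call executes the whole benchmark from a single config: cohort
#' simulation, marker QC with LD pruning, principal components, a shared
#' stratified fold plan, cross-validated thresholded scores per channel, the
#' three-statistic channel comparison, the overlap report and the
#' billing-count sweep. Every artifact is written under `out_dir` as plain
#' text, together with a reproducibility manifest (config snapshot, derived
#' stage seeds, per-stage counts, md5 checksum of every output file) and a
#' timing log. All outputs are pure functions of (config, seed): rerunning
#' with the same seed reproduces identical checksums.
#'
#' @param config a `run_config` (or YAML path / list accepted by
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when supplied.
#' @return Invisibly, a list with the in-memory results (`cohort`, `qc`,
#'   `pca`, `plan`, `eval`, `overlap`, `billing_sweep`, `manifest`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  if (!is.null(seed)) {
    config$sim <- utils::modifyList(config$sim, list(seed = as.integer(seed)))
    class(config$sim) <- "sim_config"
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
      file = log_path, append = TRUE
    )
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
    log_line("stage %-10s done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  sim <- config$sim

  cohort <- stage("simulate", {
    co <- simulate_cohort(sim)
    write_cohort(co, file.path(out_dir, "cohort"))
    co
  })
  qc <- stage("qc", {
    q <- do.call(qc_pipeline, c(list(gm = cohort$genotypes), config$qc))
    write.table(as.data.frame(q$report), file.path(out_dir, "qc_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    q
  })
  pca <- stage("pca", {
    p <- pca_genotypes(qc$genotypes, k = config$pcs)
    if (p$k > 0) {
      write.table(
        data.frame(sample_id = qc$genotypes$samples$sample_id, p$scores),
        file.path(out_dir, "pcs.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    p
  })
  covariates <- if (pca$k > 0) pca$scores else NULL
  chans <- channel_names(cohort)
  plan <- stage("folds", {
    make_folds(cohort$pheno[, chans, drop = FALSE],
      k = config$folds,
      seed = sim$seed + 200L
    )
  })
  eval <- stage("prs", {
    ev <- evaluate_channels(qc$genotypes, cohort$pheno,
      channels = chans,
      grid = config$grid, plan = plan, covariates = covariates,
      selection = config$selection
    )
    write.table(as.data.frame(ev$summary), file.path(out_dir, "eval_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(as.data.frame(ev$fold_stats), file.path(out_dir, "fold_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    for (ch in chans) {
      for (f in seq_len(plan$k)) {
        write_assoc(
          ev$cv[[ch]]$fold_assoc[[f]],
          file.path(out_dir, sprintf("assoc_%s_fold%d.tsv", ch, f))
        )
      }
      write.table(as.data.frame(ev$cv[[ch]]$scores),
        file.path(out_dir, sprintf("scores_%s.tsv", ch)),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    ev
  })
  overlap <- stage("evaluate", {
    ov <- overlap_report(cohort$pheno[, chans, drop = FALSE])
    write.table(as.data.frame(ov$regions), file.path(out_dir, "overlap_regions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(as.data.frame(ov$per_channel), file.path(out_dir, "overlap_channels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    rk <- compare_channels(eval)
    write.table(as.data.frame(rk$ranking), file.path(out_dir, "ranking.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    ov
  })
  sweep <- if ("billing_count" %in% names(cohort$pheno)) {
    stage("billing_sweep", {
      sw <- billing_count_sweep(qc$genotypes, cohort$pheno,
        thresholds = config$billing_thresholds, grid = config$grid,
        plan = plan, covariates = covariates, selection = config$selection
      )
      write.table(as.data.frame(sw), file.path(out_dir, "billing_sweep.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      sw
    })
  } else {
    NULL
  }
  manifest <- stage("manifest", {
    files <- setdiff(list.files(out_dir), c("log.txt", "manifest.json"))
    sums <- tools::md5sum(file.path(out_dir, files))
    names(sums) <- files
    man <- list(
      package_version = as.character(packageVersion("phenoscore")),
      seed = sim$seed,
      stage_seeds = list(
        genotypes = sim$seed, disease = sim$seed + 1L,
        channels = sim$seed + 10L + seq_along(sim$channels),
        billing_counts = sim$seed + 100L, folds = sim$seed + 200L
      ),
      config = config_snapshot(config),
      counts = list(
        n_samples = n_samples(cohort$genotypes),
        n_variants_input = qc$report$n_input,
        n_variants_retained = qc$report$n_retained,
        n_channels = length(chans)
      ),
      checksums = as.list(sums)
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    man
  })
  log_line("run complete: %s", out_dir)
  invisible(list(
    cohort = cohort, qc = qc, pca = pca, plan = plan, eval = eval,
    overlap = overlap, billing_sweep = sweep, manifest = manifest,
    out_dir = out_dir
  ))
}

config_snapshot <- function(config) {
  sim <- config$sim
  sim$channels <- purrr::map(sim$channels, function(ch) {
    list(sensitivity = ch$sensitivity, specificity = ch$specificity)
  })
  list(
    sim = unclass(sim), qc = config$qc, pcs = config$pcs,
    grid = as.numeric(config$grid), folds = config$folds,
    billing_thresholds = as.numeric(config$billing_thresholds),
    selection = config$selection
  )
}
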