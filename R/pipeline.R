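pipeline_defaults <- function() {
  list(
    depth_min = 100, depth_max = 360, maf_min = 0.25,
    third_allele_tol = 0.01,
    tail = 0.001, cluster_gap = 50000, genome_wide_threshold = FALSE,
    ref_depth_min = 70, ref_maf_min = 0.25, min_survivors = 35,
    panel_mode = "low_afd", panel_ref_maf_min = 0.35,
    iterations = 9999, spacing = 50000,
    run_robustness = TRUE
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file of stage parameters, fills unspecified keys with the
#' package defaults (the depth window 100-360x, pooled MAF 0.25, 0.001
#' tail, 50 kb clustering and spacing, 70x reference/survivor depth, 35 of
#' 37 survivor coverage, panel MAF 0.35, 9999 iterations), and rejects
#' unknown keys and out-of-range values.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return Named list of validated parameters, class `"pipeline_config"`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else {
    yaml::read_yaml(path) %||% list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown configuration key(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  config <- utils::modifyList(defaults, user)
  validate_pipeline_config(config)
  structure(config, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  check <- function(cond, msg) if (!cond) abort(sprintf("invalid config: %s", msg))
  check(
    is_scalar_number(config$tail) && config$tail > 0 && config$tail < 1,
    "tail must lie in (0, 1)"
  )
  check(
    config$depth_min <= config$depth_max,
    "depth_min must not exceed depth_max"
  )
  check(
    config$maf_min >= 0 && config$maf_min <= 0.5,
    "maf_min must lie in [0, 0.5]"
  )
  check(
    config$panel_ref_maf_min >= 0 && config$panel_ref_maf_min <= 0.5,
    "panel_ref_maf_min must lie in [0, 0.5]"
  )
  check(
    is_scalar_number(config$iterations) && config$iterations >= 1,
    "iterations must be a positive count"
  )
  check(
    config$panel_mode %in% c("low_afd", "mid_afd", "unrestricted"),
    "panel_mode must be low_afd, mid_afd or unrestricted"
  )
  check(config$cluster_gap > 0, "cluster_gap must be positive")
  check(config$spacing >= 0, "spacing must be non-negative")
  invisible(config)
}

#' Run the full within-generation selection analysis
#'
#' Composes the pipeline stages in order: SNP calling on the natural pools,
#' chromosome-specific AFD thresholds, candidate-region delimitation,
#' target-SNP selection, survivor pooling, frequency shifts with the exact
#' binomial sign test, the matched-MAF neutral resampling null, and
#' (optionally) the robustness-variant suite. Inputs are either a
#' `"synthetic_study"` bundle or the four count tables.
#'
#' @param lake,stream,reference Count-table tibbles, or `lake` may be a
#'   `"synthetic_study"` bundle supplying all four samples.
#' @param survivors Long-format per-individual count tibble.
#' @param config A `"pipeline_config"` from [load_config()] (or a named
#'   list of overrides).
#' @param seed Master seed; stage seeds derive from it.
#' @param quiet Suppress stage progress messages.
#' @return Object of class `"polyshift_report"`: list with `config`,
#'   `seed`, `n_snps`, `thresholds`, `regions`, `targets`, `shifts`,
#'   `sign_test`, `null` (a `"shift_null"`), `robustness` (tibble or
#'   `NULL`), and `summary` (one-row tibble of the headline numbers).
#' @export
run_full_analysis <- function(lake, stream = NULL, reference = NULL,
                              survivors = NULL, config = load_config(),
                              seed = 1, quiet = FALSE) {
  if (inherits(lake, "synthetic_study")) {
    bundle <- lake
    stream <- bundle$counts_stream
    reference <- bundle$counts_reference
    survivors <- bundle$counts_survivors
    lake <- bundle$counts_lake
  }
  if (!inherits(config, "pipeline_config")) {
    config <- structure(
      utils::modifyList(pipeline_defaults(), as.list(config)),
      class = "pipeline_config"
    )
    validate_pipeline_config(config)
  }
  for (nm in c("lake", "stream", "reference", "survivors")) {
    tab <- get(nm)
    if (!is.data.frame(tab)) {
      abort(sprintf("stage input-validation: %s table is missing", nm))
    }
  }
  say <- function(...) if (!quiet) inform(sprintf(...))

  say("stage snp-calling")
  snps <- call_biallelic_snps(
    lake, stream,
    depth_min = config$depth_min, depth_max = config$depth_max,
    maf_min = config$maf_min, third_allele_tol = config$third_allele_tol,
    quiet = quiet
  )
  if (nrow(snps) == 0) abort("stage snp-calling: no SNPs retained")

  say("stage afd-scan")
  surv_pool <- pool_survivor_counts(survivors)
  scan <- afd_scan(
    snps, reference, surv_pool,
    tail = config$tail, cluster_gap = config$cluster_gap,
    ref_depth_min = config$ref_depth_min, ref_maf_min = config$ref_maf_min,
    min_survivors = config$min_survivors,
    genome_wide = config$genome_wide_threshold
  )
  say(
    "  %d SNPs, %d high-differentiation, %d regions, %d targets",
    nrow(snps), nrow(scan$high_snps), nrow(scan$regions), nrow(scan$targets)
  )
  if (nrow(scan$targets) == 0) abort("stage target-selection: no target SNPs passed the filters")

  say("stage shift-test")
  shifts <- compute_frequency_shifts(scan$targets, reference, surv_pool)
  sign_test <- sign_binomial_test(shifts)
  panel_cfg <- robustness_config(
    panel_mode = config$panel_mode, ref_maf_min = config$panel_ref_maf_min
  )
  panel <- build_neutral_panel(
    snps, panel_cfg, reference, surv_pool,
    min_survivors = config$min_survivors, depth_min = config$ref_depth_min
  )
  null <- resample_null_medians(
    panel,
    n_snps = nrow(shifts), iterations = config$iterations,
    spacing = config$spacing, seed = derive_seed(seed, 30L),
    observed_median = median(shifts$shift),
    observed_mean = mean(shifts$shift),
    panel_spec = panel_cfg
  )

  robustness <- NULL
  if (isTRUE(config$run_robustness)) {
    say("stage robustness")
    robustness <- run_robustness_suite(
      snps, scan$targets, reference, surv_pool,
      iterations = config$iterations, seed = seed,
      spacing = config$spacing, min_survivors = config$min_survivors,
      depth_min = config$ref_depth_min
    )
  }

  report <- list(
    config = config, seed = seed,
    n_snps = nrow(snps), thresholds = scan$thresholds,
    regions = scan$regions, targets = scan$targets,
    shifts = shifts, sign_test = sign_test, null = null,
    robustness = robustness,
    summary = tibble(
      n_snps = nrow(snps),
      n_regions = nrow(scan$regions),
      n_targets = nrow(shifts),
      n_positive_shifts = sign_test$n_positive,
      sign_test_p = sign_test$p_two_tailed,
      observed_median_shift = null$observed_median,
      observed_mean_shift = null$observed_mean,
      p_median = null$p_two_tailed_median,
      p_mean = null$p_two_tailed_mean
    )
  )
  class(report) <- "polyshift_report"
  report
}

#' @export
print.polyshift_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "Within-generation polygenic selection analysis\n",
      "  SNPs called: %d; candidate regions: %d; target SNPs: %d\n",
      "  positive shifts: %d of %d (sign test P = %.4g)\n",
      "  observed median shift: %+.4f (resampling P = %.4g)\n",
      "  observed mean shift:   %+.4f (resampling P = %.4g)\n"
    ),
    s$n_snps, s$n_regions, s$n_targets,
    s$n_positive_shifts, s$n_targets, s$sign_test_p,
    s$observed_median_shift, s$p_median,
    s$observed_mean_shift, s$p_mean
  ))
  if (!is.null(x$robustness)) {
    cat("  robustness variants:\n")
    r <- x$robustness
    for (i in seq_len(nrow(r))) {
      cat(sprintf(
        "    %-12s MAF>=%.2f  panel %6d  P(median) = %.4g\n",
        r$panel_mode[i], r$ref_maf_min[i], r$panel_size[i], r$p_median[i]
      ))
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits a JSON report of the headline numbers plus TSV artifacts (targets,
#' per-SNP shifts, null medians) into a run directory.
#'
#' @param report A `"polyshift_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(
      as.list(report$summary),
      list(seed = report$seed, config = unclass(report$config))
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(report$targets, file.path(dir, "targets.tsv"), progress = FALSE)
  readr::write_tsv(
    select(report$shifts, -dplyr::any_of("member_pos")),
    file.path(dir, "shifts.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    tibble(median = report$null$medians, mean = report$null$means),
    file.path(dir, "null_statistics.tsv"),
    progress = FALSE
  )
  if (!is.null(report$robustness)) {
    readr::write_tsv(
      select(report$robustness, -"null"),
      file.path(dir, "robustness.tsv"),
      progress = FALSE
    )
  }
  invisible(dir)
}
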