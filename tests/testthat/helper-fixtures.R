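# In-code fixtures shared across test files.

# A minimal count-table tibble.
count_table <- function(chrom, pos, A = 0, C = 0, G = 0, T = 0, sample_id = NULL) {
  tab <- tibble::tibble(chrom = chrom, pos = as.integer(pos), A = A, C = C, G = G, T = T)
  if (!is.null(sample_id)) tab$sample_id <- sample_id
  tab
}

# A small study bundle shared by several files (cached per session).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config(
        n_chrom = 5, chrom_length = 2.5e6, mean_spacing = 2500,
        scheme = fitness_scheme("multiplicative", 0.1)
      )
      cache <<- generate_study_bundle(cfg, seed = 42)
    }
    cache
  }
})

# Reduced null-calibration bundle and its empirical p-value, the unit of
# the calibration study: planted positions act as unselected target
# stand-ins, survivors are a uniform random subset of the released fish.
null_bundle_p <- function(seed, iterations = 999) {
  cfg <- study_config(
    n_chrom = 5, chrom_length = 2.5e6, mean_spacing = 2500, scheme = "neutral"
  )
  b <- generate_study_bundle(cfg, seed = seed)
  snps <- call_biallelic_snps(b$counts_lake, b$counts_stream, quiet = TRUE)
  surv_pool <- pool_survivor_counts(b$counts_survivors)
  planted <- b$truth[b$truth$planted, c("chrom", "pos")]
  psnps <- dplyr::semi_join(snps, planted, by = c("chrom", "pos"))
  regions <- delimit_candidate_regions(psnps, cluster_gap = 1)
  targets <- select_target_snps(regions, snps, b$counts_reference, surv_pool)
  shifts <- compute_frequency_shifts(targets, b$counts_reference, surv_pool)
  panel <- build_neutral_panel(
    snps, robustness_config("low_afd", 0.35), b$counts_reference, surv_pool
  )
  null <- resample_null_medians(
    panel,
    n_snps = nrow(shifts), iterations = iterations,
    seed = derive_seed(seed, 30L),
    observed_median = median(shifts$shift)
  )
  null$p_two_tailed_median
}
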