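#' Pool individually sequenced survivors into one count table
#'
#' Sums nucleotide counts over all survivor individuals per site, avoiding
#' diploid genotype calling at low individual depth, and records per site
#' how many individuals contributed at least one read.
#'
#' @param individual_tables Long-format count tibble with a `sample_id`
#'   column (one label per survivor), or a list of per-individual tibbles.
#' @return Count-table tibble with columns `chrom`, `pos`, `A`, `C`, `G`,
#'   `T`, `depth`, `contributors`.
#' @export
pool_survivor_counts <- function(individual_tables) {
  if (is.data.frame(individual_tables)) {
    long <- individual_tables
  } else {
    long <- bind_rows(individual_tables)
  }
  assert_columns(long, c("chrom", "pos", NUCLEOTIDES), "survivor table")
  depth <- long$A + long$C + long$G + long$T
  long |>
    mutate(.depth = depth) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      across(all_of(NUCLEOTIDES), sum),
      depth = sum(.data$.depth),
      contributors = sum(.data$.depth >= 1),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos)
}

#' Stream-allele frequency shifts from reference to survivors
#'
#' For each target SNP, computes the frequency of the stream allele in the
#' pooled survivors minus its frequency in the reference pool, both
#' renormalised over the SNP's two alleles.
#'
#' @param targets Target tibble from [select_target_snps()] (needs `chrom`,
#'   `pos`, `stream_allele`, and the partner allele carried via
#'   `freq_reference`; alleles are re-read from the count tables).
#' @param reference Reference-pool count table.
#' @param survivor_pool Pooled survivor count table from
#'   [pool_survivor_counts()].
#' @return `targets` with added columns `shift` (in `[-1, 1]`) and `sign`
#'   (`"+"`, `"-"`, `"0"`); `freq_reference` and `freq_survivors` are
#'   recomputed from the supplied tables.
#' @export
compute_frequency_shifts <- function(targets, reference, survivor_pool) {
  assert_columns(targets, c("chrom", "pos", "stream_allele"))
  if (nrow(targets) == 0) {
    return(mutate(targets, shift = double(), sign = character()))
  }
  other <- other_allele(targets, reference, survivor_pool)
  fr <- two_allele_frequency(reference, targets, other)
  fs <- two_allele_frequency(survivor_pool, targets, other)
  if (any(is.na(fr)) || any(is.na(fs))) {
    bad <- which(is.na(fr) | is.na(fs))[1]
    abort(sprintf(
      "target %s:%d has zero usable depth in the reference or survivor pool; it should have been filtered",
      targets$chrom[bad], targets$pos[bad]
    ))
  }
  targets |>
    mutate(
      freq_reference = fr,
      freq_survivors = fs,
      shift = fs - fr,
      sign = dplyr::case_when(shift > 0 ~ "+", shift < 0 ~ "-", TRUE ~ "0")
    )
}

# The non-stream allele of each target: the other member of the SNP's
# allele pair, identified as the non-stream nucleotide with the most reads
# across the two samples.
other_allele <- function(targets, reference, survivor_pool) {
  key_t <- paste(targets$chrom, targets$pos)
  cr <- as.matrix(reference[NUCLEOTIDES])[
    match(key_t, paste(reference$chrom, reference$pos)), , drop = FALSE
  ]
  cs <- as.matrix(survivor_pool[NUCLEOTIDES])[
    match(key_t, paste(survivor_pool$chrom, survivor_pool$pos)), , drop = FALSE
  ]
  cr[is.na(cr)] <- 0
  cs[is.na(cs)] <- 0
  tot <- cr + cs
  tot[cbind(seq_len(nrow(targets)), match(targets$stream_allele, NUCLEOTIDES))] <- -1
  NUCLEOTIDES[max.col(tot, ties.method = "first")]
}

two_allele_frequency <- function(counts, targets, other) {
  idx <- match(
    paste(targets$chrom, targets$pos),
    paste(counts$chrom, counts$pos)
  )
  cm <- as.matrix(counts[NUCLEOTIDES])[idx, , drop = FALSE]
  a <- cm[cbind(seq_len(nrow(targets)), match(targets$stream_allele, NUCLEOTIDES))]
  b <- cm[cbind(seq_len(nrow(targets)), match(other, NUCLEOTIDES))]
  ifelse(!is.na(a + b) & (a + b) > 0, a / (a + b), NA_real_)
}

#' Exact two-tailed binomial sign test on shift directions
#'
#' Tests whether the number of positive shifts among the nonzero shifts is
#' compatible with a fair coin: with `k` positive of `n` nonzero shifts the
#' two-tailed probability is `min(1, 2 * P(X >= max(k, n - k)))` for
#' `X ~ Binomial(n, 1/2)` (twice the smaller tail, capped at 1; for the
#' symmetric null this equals the exact two-sided test). Zero shifts carry
#' no directional information and are excluded from `n`.
#'
#' @param shifts Tibble with a `shift` column (e.g. from
#'   [compute_frequency_shifts()]), or a numeric vector of shifts.
#' @return Object of class `"sign_test"`: a list with `n_positive`,
#'   `n_negative`, `n_zero`, `n`, and `p_two_tailed`.
#' @export
#' @examples
#' sign_binomial_test(c(rep(0.01, 77), rep(-0.01, 49)))$p_two_tailed
sign_binomial_test <- function(shifts) {
  x <- if (is.data.frame(shifts)) shifts$shift else shifts
  if (!is.numeric(x) || length(x) == 0) {
    abort("shifts must be a numeric vector or a tibble with a shift column")
  }
  k_pos <- sum(x > 0)
  k_neg <- sum(x < 0)
  n <- k_pos + k_neg
  if (n == 0) {
    abort("all shifts are zero; the sign test is undefined")
  }
  k <- max(k_pos, k_neg)
  p <- min(1, 2 * pbinom(k - 1, n, 0.5, lower.tail = FALSE))
  structure(
    list(
      n_positive = k_pos, n_negative = k_neg,
      n_zero = sum(x == 0), n = n, p_two_tailed = p
    ),
    class = "sign_test"
  )
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "Exact binomial sign test: %d positive / %d nonzero shifts (%d zero)\n  two-tailed P = %.4g\n",
    x$n_positive, x$n, x$n_zero, x$p_two_tailed
  ))
  invisible(x)
}

#' Configuration of a neutral-SNP resampling panel
#'
#' The three panel modes restrict the lake-stream differentiation of the
#' neutral SNPs: `low_afd` keeps AFD in `[0, 0.1]` (SNPs assumed little
#' influenced by divergent selection), `mid_afd` keeps AFD in `[0.1, 0.17]`
#' (markers deviating by no more than 25% from the genome-wide median
#' differentiation, a fully independent panel), and `unrestricted` imposes
#' no AFD restriction. `ref_maf_min` matches the minor-allele-frequency
#' spectrum of the panel to that of the high-MAF target SNPs (differentiation
#' magnitude is contingent on MAF, so an unmatched panel would bias the
#' null).
#'
#' @param panel_mode One of `"low_afd"`, `"mid_afd"`, `"unrestricted"`.
#' @param ref_maf_min Minimum reference-sample MAF, default 0.35.
#' @param afd_range Override the AFD interval implied by `panel_mode`.
#' @return Object of class `"robustness_config"`.
#' @export
robustness_config <- function(panel_mode = c("low_afd", "mid_afd", "unrestricted"),
                              ref_maf_min = 0.35, afd_range = NULL) {
  panel_mode <- match.arg(panel_mode)
  if (is.null(afd_range)) {
    afd_range <- switch(panel_mode,
      low_afd = c(0, 0.1),
      mid_afd = c(0.1, 0.17),
      unrestricted = c(0, 1)
    )
  }
  stopifnot(
    is_scalar_number(ref_maf_min), ref_maf_min >= 0, ref_maf_min <= 0.5,
    length(afd_range) == 2, afd_range[1] <= afd_range[2]
  )
  structure(
    list(
      panel_mode = panel_mode, ref_maf_min = ref_maf_min,
      afd_range = afd_range
    ),
    class = "robustness_config"
  )
}

#' Build the panel of neutral SNPs eligible for resampling
#'
#' Applies the same quality standards as for the target SNPs: AFD within the
#' configured range, reference-sample MAF at least `config$ref_maf_min`,
#' read depth at least `depth_min` in both the reference and the pooled
#' survivor sample, and coverage in at least `min_survivors` survivor
#' individuals. The stream-allele reference-to-survivor shift of each
#' eligible SNP is precomputed.
#'
#' @param snps SNP tibble from [call_biallelic_snps()].
#' @param config A [robustness_config()].
#' @param reference Reference-pool count table.
#' @param survivor_pool Pooled survivor count table (with `contributors`).
#' @param min_survivors Minimum survivor individuals with coverage,
#'   default 35.
#' @param depth_min Minimum depth in reference and survivor pool, default 70.
#' @return Tibble of eligible SNPs with stream-allele `freq_reference`,
#'   `freq_survivors`, `shift`, and a `gpos` spacing coordinate.
#' @export
build_neutral_panel <- function(snps, config = robustness_config(),
                                reference, survivor_pool,
                                min_survivors = 35, depth_min = 70) {
  assert_columns(snps, c(
    "chrom", "pos", "allele_hi", "allele_lo",
    "freq_lake", "freq_stream", "afd"
  ))
  assert_columns(survivor_pool, c("chrom", "pos", NUCLEOTIDES, "contributors"))

  cand <- snps |>
    filter(
      .data$afd >= config$afd_range[1],
      .data$afd <= config$afd_range[2],
      # equal lake/stream frequency admits no stream-allele polarization
      .data$freq_stream != .data$freq_lake
    ) |>
    annotate_sample_stats(reference, prefix = "reference") |>
    annotate_sample_stats(survivor_pool, prefix = "survivors")
  cand$contributors <- survivor_pool$contributors[match(
    paste(cand$chrom, cand$pos),
    paste(survivor_pool$chrom, survivor_pool$pos)
  )]
  cand$contributors[is.na(cand$contributors)] <- 0

  panel <- cand |>
    filter(
      !is.na(.data$freq_reference), !is.na(.data$freq_survivors),
      .data$maf_reference >= config$ref_maf_min,
      .data$depth_reference >= depth_min,
      .data$depth_survivors >= depth_min,
      .data$contributors >= min_survivors
    )
  if (nrow(panel) == 0) {
    abort(paste(
      "neutral panel is empty under this configuration;",
      "loosen the AFD range or the reference MAF threshold"
    ))
  }
  # polarize frequencies to the stream allele and precompute shifts
  hi_is_stream <- panel$freq_stream > panel$freq_lake
  flip <- function(f) ifelse(hi_is_stream, f, 1 - f)
  panel |>
    mutate(
      freq_reference = flip(.data$freq_reference),
      freq_survivors = flip(.data$freq_survivors),
      shift = .data$freq_survivors - .data$freq_reference,
      gpos = global_position(.data$chrom, .data$pos)
    ) |>
    select(
      "chrom", "pos", "gpos", "afd", "maf_reference",
      "depth_reference", "depth_survivors", "contributors",
      "freq_reference", "freq_survivors", "shift"
    )
}

#' Resample neutral SNP sets and build the null shift distribution
#'
#' Draws `iterations` random samples of `n_snps` neutral SNPs from the
#' panel and records the median and mean stream-allele shift of each
#' sample. Within one iteration SNPs are drawn without replacement and must
#' respect a pairwise physical spacing greater than `spacing` bp
#' (rejection sampling: candidates violating the spacing against already
#' accepted SNPs are skipped; if an iteration cannot be completed it is
#' restarted); across iterations SNPs are drawn with replacement, so the
#' same SNP may appear in many iterations.
#'
#' @param panel Panel tibble from [build_neutral_panel()].
#' @param n_snps SNPs per resample, default 126 (the target-panel size).
#' @param iterations Number of resampling iterations, default 9999.
#' @param spacing Minimum pairwise distance in bp, default 50000.
#' @param seed Seed for reproducibility.
#' @param observed_median,observed_mean Observed statistics at the target
#'   SNPs; when supplied, empirical two-tailed probabilities are attached.
#' @param panel_spec Optional description of the panel configuration,
#'   recorded in the result.
#' @param keep_draws Record the drawn panel row indices of every iteration
#'   (`iterations` x `n_snps` matrix; used by validity checks).
#' @return Object of class `"shift_null"`: list with `iterations`,
#'   `medians`, `means`, `observed_median`, `observed_mean`,
#'   `p_two_tailed_median`, `p_two_tailed_mean`, `panel_spec`, `n_snps`,
#'   and optionally `draws`.
#' @export
resample_null_medians <- function(panel, n_snps = 126, iterations = 9999,
                                  spacing = 50000, seed = NULL,
                                  observed_median = NULL,
                                  observed_mean = NULL,
                                  panel_spec = NULL, keep_draws = FALSE) {
  assert_columns(panel, c("gpos", "shift"))
  n_panel <- nrow(panel)
  if (n_panel < n_snps) {
    abort(sprintf(
      "panel holds %d SNPs; cannot draw %d distinct SNPs", n_panel, n_snps
    ))
  }
  gpos <- panel$gpos
  shift <- panel$shift
  medians <- numeric(iterations)
  means <- numeric(iterations)
  draws <- if (keep_draws) {
    matrix(NA_integer_, nrow = iterations, ncol = n_snps)
  } else {
    NULL
  }
  restart_cap <- 100L

  with_seed(seed, {
    for (it in seq_len(iterations)) {
      chosen <- NULL
      for (attempt in seq_len(restart_cap)) {
        chosen <- draw_spaced_sample(gpos, n_snps, spacing)
        if (!is.null(chosen)) break
      }
      if (is.null(chosen)) {
        abort(sprintf(
          "could not draw %d SNPs with pairwise spacing > %d bp from this panel (after %d restarts); the panel is too dense or too small",
          n_snps, spacing, restart_cap
        ))
      }
      s <- shift[chosen]
      medians[it] <- median(s)
      means[it] <- mean(s)
      if (keep_draws) draws[it, ] <- chosen
    }
  })

  out <- structure(
    list(
      iterations = iterations, n_snps = n_snps, spacing = spacing,
      medians = medians, means = means,
      observed_median = observed_median, observed_mean = observed_mean,
      p_two_tailed_median = NULL, p_two_tailed_mean = NULL,
      panel_spec = panel_spec, panel_size = n_panel, draws = draws
    ),
    class = "shift_null"
  )
  if (!is.null(observed_median)) {
    out$p_two_tailed_median <- empirical_two_tailed_p(out, observed_median)
  }
  if (!is.null(observed_mean)) {
    out$p_two_tailed_mean <- empirical_two_tailed_p(
      out, observed_mean, statistic = "mean"
    )
  }
  out
}

# One spaced sample: walk a random permutation of the panel, accepting a
# SNP iff it lies > spacing from every already accepted SNP. Returns NULL
# when the permutation is exhausted before n_snps acceptances (caller
# restarts with a fresh permutation).
draw_spaced_sample <- function(gpos, n_snps, spacing) {
  perm <- sample.int(length(gpos))
  acc <- numeric(n_snps)
  acc_idx <- integer(n_snps)
  k <- 0L
  for (cand in perm) {
    g <- gpos[cand]
    if (k == 0L || all(abs(acc[seq_len(k)] - g) > spacing)) {
      k <- k + 1L
      acc[k] <- g
      acc_idx[k] <- cand
      if (k == n_snps) return(acc_idx)
    }
  }
  NULL
}

#' @export
print.shift_null <- function(x, ...) {
  cat(sprintf(
    "Resampled null shift distribution: %d iterations of %d SNPs (panel %d SNPs)\n",
    x$iterations, x$n_snps, x$panel_size
  ))
  if (!is.null(x$observed_median)) {
    cat(sprintf(
      "  observed median shift %.4f, two-tailed P = %.4g\n",
      x$observed_median, x$p_two_tailed_median
    ))
  }
  if (!is.null(x$observed_mean)) {
    cat(sprintf(
      "  observed mean shift   %.4f, two-tailed P = %.4g\n",
      x$observed_mean, x$p_two_tailed_mean
    ))
  }
  invisible(x)
}

#' Empirical two-tailed probability against a resampled null
#'
#' The proportion of null iterations whose statistic is at least as extreme
#' (in absolute value) as the observed one: `count / iterations` by
#' default, or the plus-one-corrected `(count + 1) / (iterations + 1)`.
#'
#' @param null A `"shift_null"` object or a numeric vector of null
#'   statistics.
#' @param observed Observed statistic.
#' @param statistic Which stored statistic to use for a `"shift_null"`
#'   object: `"median"` (default) or `"mean"`.
#' @param plus_one Apply the plus-one correction (guarantees a positive
#'   probability), default `FALSE`.
#' @return A probability in `[0, 1]` (in `(0, 1]` with `plus_one = TRUE`).
#' @export
empirical_two_tailed_p <- function(null, observed,
                                   statistic = c("median", "mean"),
                                   plus_one = FALSE) {
  statistic <- match.arg(statistic)
  x <- if (inherits(null, "shift_null")) {
    if (statistic == "median") null$medians else null$means
  } else {
    null
  }
  if (length(x) == 0) {
    abort("null distribution is empty")
  }
  k <- sum(abs(x) >= abs(observed))
  if (plus_one) (k + 1) / (length(x) + 1) else k / length(x)
}

#' Run the published robustness variants of the resampling test
#'
#' Executes the six panel configurations explored in the robustness checks
#' (AFD 0-0.1 with reference MAF thresholds 0.25, 0.35, 0.40; AFD 0.1-0.17
#' with MAF 0.35; no AFD restriction with MAF 0.25 and 0.35), holding
#' spacing, depth, survivor coverage and iteration count fixed.
#'
#' @param snps SNP tibble from [call_biallelic_snps()].
#' @param targets Target tibble from [select_target_snps()].
#' @param reference Reference-pool count table.
#' @param survivor_pool Pooled survivor count table.
#' @param iterations Resampling iterations per variant, default 9999.
#' @param seed Master seed; each variant derives its own child seed.
#' @param spacing,min_survivors,depth_min As in [resample_null_medians()]
#'   and [build_neutral_panel()].
#' @return Tibble with one row per configuration: `panel_mode`,
#'   `ref_maf_min`, `afd_lo`, `afd_hi`, `panel_size`, `observed_median`,
#'   `observed_mean`, `p_median`, `p_mean`, and the `shift_null` objects in
#'   a `null` list column.
#' @export
run_robustness_suite <- function(snps, targets, reference, survivor_pool,
                                 iterations = 9999, seed = NULL,
                                 spacing = 50000, min_survivors = 35,
                                 depth_min = 70) {
  variants <- tibble(
    panel_mode = c(
      "low_afd", "low_afd", "low_afd",
      "mid_afd", "unrestricted", "unrestricted"
    ),
    ref_maf_min = c(0.25, 0.35, 0.40, 0.35, 0.25, 0.35)
  )
  shifts <- compute_frequency_shifts(targets, reference, survivor_pool)
  obs_median <- median(shifts$shift)
  obs_mean <- mean(shifts$shift)

  res <- purrr::pmap(
    list(variants$panel_mode, variants$ref_maf_min, seq_len(nrow(variants))),
    function(mode, maf, i) {
      cfg <- robustness_config(panel_mode = mode, ref_maf_min = maf)
      panel <- build_neutral_panel(
        snps, cfg, reference, survivor_pool,
        min_survivors = min_survivors, depth_min = depth_min
      )
      null <- resample_null_medians(
        panel,
        n_snps = nrow(shifts), iterations = iterations, spacing = spacing,
        seed = if (is.null(seed)) NULL else derive_seed(seed, 40L, i),
        observed_median = obs_median, observed_mean = obs_mean,
        panel_spec = cfg
      )
      tibble(
        panel_mode = mode, ref_maf_min = maf,
        afd_lo = cfg$afd_range[1], afd_hi = cfg$afd_range[2],
        panel_size = null$panel_size,
        observed_median = obs_median, observed_mean = obs_mean,
        p_median = null$p_two_tailed_median,
        p_mean = null$p_two_tailed_mean,
        null = list(null)
      )
    }
  )
  bind_rows(res)
}
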