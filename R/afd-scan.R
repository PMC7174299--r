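#' Chromosome-specific AFD tail threshold
#'
#' Returns the empirical `1 - tail` quantile of a chromosome's AFD values
#' under the nearest-rank (type 1) definition; a SNP counts as
#' high-differentiation iff `afd >= cutoff`. Thresholds are computed per
#' chromosome because baseline differentiation varies among chromosomes
#' (crossover-rate differences change the local selection density).
#'
#' @param snps SNP tibble from [call_biallelic_snps()].
#' @param chrom Single chromosome identifier, or `NULL` to return a tibble
#'   of thresholds for every chromosome present.
#' @param tail Upper tail fraction, default 0.001 (the top 0.1 percentile).
#' @return A single cutoff when `chrom` is given, otherwise a tibble with
#'   columns `chrom`, `n_snps`, `cutoff`.
#' @export
chromosome_afd_threshold <- function(snps, chrom = NULL, tail = 0.001) {
  assert_columns(snps, c("chrom", "afd"))
  stopifnot(is_scalar_number(tail), tail > 0, tail < 1)
  if (is.null(chrom)) {
    return(
      snps |>
        group_by(.data$chrom) |>
        summarise(
          n_snps = n(),
          cutoff = nearest_rank_quantile(.data$afd, 1 - tail),
          .groups = "drop"
        )
    )
  }
  x <- snps$afd[snps$chrom == chrom]
  if (length(x) == 0) {
    abort(sprintf("no SNPs on chromosome %s", chrom))
  }
  if (length(x) < 1 / tail) {
    warn(sprintf(
      "chromosome %s has %d SNPs; fewer than 1/tail = %g, the %g tail quantile is poorly resolved",
      chrom, length(x), 1 / tail, tail
    ))
  }
  nearest_rank_quantile(x, 1 - tail)
}

# Nearest-rank (type 1) empirical quantile: the ceiling(q * n)-th order
# statistic. Parameter-free and reproducible.
nearest_rank_quantile <- function(x, q) {
  n <- length(x)
  sort(x, method = "quick")[max(1L, ceiling(q * n))]
}

#' Delimit candidate regions from high-differentiation SNPs
#'
#' Single-linkage chaining: consecutive high-differentiation SNPs at most
#' `cluster_gap` apart on the same chromosome join the same region, and
#' regions are maximal (a run of SNPs each within the gap of its neighbour
#' forms one region even when its ends are further apart).
#'
#' @param high_snps Tibble with `chrom` and `pos` (plus any carried columns)
#'   of SNPs exceeding the chromosome threshold.
#' @param cluster_gap Maximum neighbour distance in bp, default 50000.
#' @return Tibble with one row per region: `region_id`, `chrom`, `start`,
#'   `end` (1-based inclusive span of member SNPs), `n_snps`, and
#'   `member_pos` (list column of member positions).
#' @export
delimit_candidate_regions <- function(high_snps, cluster_gap = 50000) {
  assert_columns(high_snps, c("chrom", "pos"))
  if (nrow(high_snps) == 0) {
    return(tibble(
      region_id = integer(), chrom = character(), start = integer(),
      end = integer(), n_snps = integer(), member_pos = list()
    ))
  }
  high_snps |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(.grp = cumsum(c(1, diff(.data$pos) > cluster_gap))) |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(
      start = min(.data$pos),
      end = max(.data$pos),
      n_snps = n(),
      member_pos = list(.data$pos),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = row_number()) |>
    select("region_id", "chrom", "start", "end", "n_snps", "member_pos")
}

#' Select one polarized target SNP per candidate region
#'
#' Within each region, member SNPs must satisfy a read depth of at least
#' `ref_depth_min` and a minor allele frequency of at least `ref_maf_min` in
#' the reference pool, and be sequenced (>= 1 read) in at least
#' `min_survivors` of the survivor individuals. Among passing members the
#' SNP with maximal AFD is chosen (ties broken to the smallest position) and
#' polarized to its stream allele: the allele with the higher relative
#' frequency in the natural stream than the lake sample. Regions with no
#' passing member yield no target.
#'
#' @param regions Region tibble from [delimit_candidate_regions()].
#' @param snps SNP tibble from [call_biallelic_snps()] (provides alleles,
#'   frequencies, and AFD for the member positions).
#' @param reference Reference-pool count table.
#' @param survivors Long-format count table of the individually sequenced
#'   survivors (`sample_id` column), or a pre-pooled table from
#'   [pool_survivor_counts()] carrying a `contributors` column.
#' @param ref_depth_min Minimum reference read depth, default 70.
#' @param ref_maf_min Minimum reference MAF over the SNP's two alleles,
#'   default 0.25.
#' @param min_survivors Minimum number of survivor individuals with coverage,
#'   default 35 (of 37).
#' @return Tibble with one row per tagged region: `chrom`, `pos`,
#'   `stream_allele`, `afd`, stream-allele frequencies `freq_lake`,
#'   `freq_stream`, `freq_reference`, `freq_survivors`, plus
#'   `n_survivors_covered`, `depth_reference`, `depth_survivors`,
#'   `maf_reference`, and `region_id`.
#' @export
select_target_snps <- function(regions, snps, reference, survivors,
                               ref_depth_min = 70, ref_maf_min = 0.25,
                               min_survivors = 35) {
  assert_columns(snps, c(
    "chrom", "pos", "allele_hi", "allele_lo",
    "freq_lake", "freq_stream", "afd"
  ))
  surv_pool <- if ("contributors" %in% names(survivors)) {
    survivors
  } else {
    pool_survivor_counts(survivors)
  }

  members <- regions |>
    select("region_id", "member_pos", "chrom") |>
    tidyr::unnest(member_pos) |>
    dplyr::rename(pos = "member_pos") |>
    inner_join(snps, by = c("chrom", "pos")) |>
    annotate_sample_stats(reference, prefix = "reference") |>
    annotate_sample_stats(surv_pool, prefix = "survivors")
  if (nrow(members) == 0) {
    return(empty_target_table())
  }
  members$n_survivors_covered <-
    surv_pool$contributors[match(
      paste(members$chrom, members$pos),
      paste(surv_pool$chrom, surv_pool$pos)
    )] %||% NA_real_
  members$n_survivors_covered[is.na(members$n_survivors_covered)] <- 0

  passing <- members |>
    filter(
      !is.na(.data$depth_reference),
      .data$depth_reference >= ref_depth_min,
      .data$maf_reference >= ref_maf_min,
      .data$n_survivors_covered >= min_survivors,
      !is.na(.data$freq_survivors)
    )
  if (nrow(passing) == 0) {
    return(empty_target_table())
  }

  passing |>
    group_by(.data$region_id) |>
    arrange(dplyr::desc(.data$afd), .data$pos, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    polarize_to_stream_allele() |>
    arrange(.data$chrom, .data$pos)
}

empty_target_table <- function() {
  tibble(
    chrom = character(), pos = integer(), stream_allele = character(),
    afd = double(), freq_lake = double(), freq_stream = double(),
    freq_reference = double(), freq_survivors = double(),
    n_survivors_covered = double(), depth_reference = double(),
    depth_survivors = double(), maf_reference = double(),
    region_id = integer()
  )
}

# Attach, for each member SNP, the frequency of allele_hi (renormalised over
# the SNP's two alleles), the total depth, and the two-allele MAF observed
# in one count table. Sites absent from the table get NA.
annotate_sample_stats <- function(members, counts, prefix) {
  assert_columns(counts, c("chrom", "pos", NUCLEOTIDES))
  idx <- match(
    paste(members$chrom, members$pos),
    paste(counts$chrom, counts$pos)
  )
  cm <- as.matrix(counts[NUCLEOTIDES])[idx, , drop = FALSE]
  hi <- cm[cbind(seq_len(nrow(members)), match(members$allele_hi, NUCLEOTIDES))]
  lo <- cm[cbind(seq_len(nrow(members)), match(members$allele_lo, NUCLEOTIDES))]
  two <- hi + lo
  members[[paste0("freq_", prefix)]] <- ifelse(two > 0, hi / two, NA_real_)
  members[[paste0("depth_", prefix)]] <- rowSums(cm)
  members[[paste0("maf_", prefix)]] <- ifelse(two > 0, pmin(hi, lo) / two, NA_real_)
  members
}

# Express all frequencies with reference to the stream allele. A SNP with
# freq_stream == freq_lake cannot be polarized; such SNPs are dropped with
# a warning (cannot occur for targets, whose AFD exceeds a positive
# threshold).
polarize_to_stream_allele <- function(members) {
  tied <- members$freq_stream == members$freq_lake
  if (any(tied)) {
    warn(sprintf(
      "%d SNP(s) with equal lake and stream frequency cannot be polarized and were dropped",
      sum(tied)
    ))
    members <- members[!tied, ]
  }
  hi_is_stream <- members$freq_stream > members$freq_lake
  flip <- function(f) ifelse(hi_is_stream, f, 1 - f)
  tibble(
    chrom = members$chrom,
    pos = members$pos,
    stream_allele = ifelse(hi_is_stream, members$allele_hi, members$allele_lo),
    afd = members$afd,
    freq_lake = flip(members$freq_lake),
    freq_stream = flip(members$freq_stream),
    freq_reference = flip(members$freq_reference),
    freq_survivors = flip(members$freq_survivors),
    n_survivors_covered = members$n_survivors_covered,
    depth_reference = members$depth_reference,
    depth_survivors = members$depth_survivors,
    maf_reference = members$maf_reference,
    region_id = members$region_id
  )
}

#' Sliding-window mean AFD profile
#'
#' Averages AFD across SNPs in windows of `window` bp advancing by `step`
#' bp from position 1 on each chromosome (the default 40 kb windows with
#' 20 kb overlap). Windows containing no SNP are omitted.
#'
#' @param snps SNP tibble with `chrom`, `pos`, `afd`.
#' @param window Window width in bp, default 40000.
#' @param step Window step in bp, default 20000; must divide `window`.
#' @return Tibble with `chrom`, `start`, `end`, `midpoint`, `n_snps`,
#'   `mean_afd`.
#' @export
smooth_afd_windows <- function(snps, window = 40000, step = 20000) {
  assert_columns(snps, c("chrom", "pos", "afd"))
  stopifnot(window %% step == 0)
  if (nrow(snps) == 0) {
    return(tibble(
      chrom = character(), start = double(), end = double(),
      midpoint = double(), n_snps = integer(), mean_afd = double()
    ))
  }
  k <- window %/% step
  # each SNP falls into k consecutive windows; window j covers
  # [1 + j*step, j*step + window]
  expanded <- purrr::map_dfr(seq_len(k) - 1L, function(off) {
    j <- (snps$pos - 1L) %/% step - off
    tibble(chrom = snps$chrom, j = j, afd = snps$afd)[
      j >= 0 & snps$pos <= j * step + window,
    ]
  })
  expanded |>
    group_by(.data$chrom, .data$j) |>
    summarise(n_snps = n(), mean_afd = mean(.data$afd), .groups = "drop") |>
    mutate(
      start = .data$j * step + 1,
      end = .data$j * step + window,
      midpoint = .data$start + window / 2
    ) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "midpoint", "n_snps", "mean_afd")
}

#' Run the AFD genome scan end to end
#'
#' Convenience wrapper chaining [chromosome_afd_threshold()],
#' [delimit_candidate_regions()] and [select_target_snps()], using either
#' chromosome-specific thresholds (default) or one genome-wide threshold.
#'
#' @inheritParams select_target_snps
#' @inheritParams chromosome_afd_threshold
#' @inheritParams delimit_candidate_regions
#' @param genome_wide Use a single genome-wide AFD threshold instead of
#'   chromosome-specific ones.
#' @return List with `thresholds`, `high_snps`, `regions`, `targets`.
#' @export
afd_scan <- function(snps, reference, survivors, tail = 0.001,
                     cluster_gap = 50000, ref_depth_min = 70,
                     ref_maf_min = 0.25, min_survivors = 35,
                     genome_wide = FALSE) {
  if (genome_wide) {
    cutoff <- nearest_rank_quantile(snps$afd, 1 - tail)
    thresholds <- tibble(
      chrom = unique(snps$chrom), n_snps = NA_integer_, cutoff = cutoff
    )
  } else {
    thresholds <- chromosome_afd_threshold(snps, tail = tail)
  }
  high <- snps |>
    left_join(select(thresholds, "chrom", "cutoff"), by = "chrom") |>
    filter(.data$afd >= .data$cutoff)
  regions <- delimit_candidate_regions(high, cluster_gap = cluster_gap)
  targets <- select_target_snps(
    regions, snps, reference, survivors,
    ref_depth_min = ref_depth_min, ref_maf_min = ref_maf_min,
    min_survivors = min_survivors
  )
  list(
    thresholds = thresholds, high_snps = high,
    regions = regions, targets = targets
  )
}
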