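#' Read a per-site nucleotide count table
#'
#' Count tables are tab-separated with a header `chrom pos A C G T` and one
#' row per genomic site, giving the number of sequencing reads supporting
#' each nucleotide in one pool (or one individually sequenced fish).
#' Long-format tables holding several individuals additionally carry a
#' `sample_id` column.
#'
#' @param path Path to a TSV file.
#' @param sample_id Optional label attached to every row (ignored when the
#'   file already has a `sample_id` column).
#' @return A tibble with columns `chrom`, `pos`, `A`, `C`, `G`, `T`, `depth`
#'   (row sum of the four counts) and, when available, `sample_id`, sorted
#'   by `(chrom, pos)`.
#' @export
read_count_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("count table not found: %s", path))
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = "c", pos = "d", A = "d", C = "d", G = "d", T = "d",
      .default = readr::col_guess()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  assert_columns(raw, c("chrom", "pos", NUCLEOTIDES), what = basename(path))
  validate_count_table(raw, what = basename(path))
  out <- raw |>
    mutate(
      pos = as.integer(.data$pos),
      depth = .data$A + .data$C + .data$G + .data$T
    )
  if (!is.null(sample_id) && !"sample_id" %in% names(out)) {
    out$sample_id <- sample_id
  }
  sort_cols <- intersect(c("sample_id", "chrom", "pos"), names(out))
  arrange(out, across(all_of(sort_cols)))
}

# Shared invariant checks; errors name the offending data line (header = 1).
validate_count_table <- function(tab, what = "count table") {
  for (nuc in NUCLEOTIDES) {
    if (!is.numeric(tab[[nuc]])) {
      abort(sprintf("%s: column %s is not numeric", what, nuc))
    }
    bad <- which(is.na(tab[[nuc]]) | tab[[nuc]] < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: negative or missing %s count at line %d",
        what, nuc, bad[1] + 1L
      ))
    }
  }
  if (any(is.na(tab$pos)) || any(tab$pos < 1)) {
    bad <- which(is.na(tab$pos) | tab$pos < 1)[1]
    abort(sprintf("%s: invalid position at line %d", what, bad + 1L))
  }
  key <- if ("sample_id" %in% names(tab)) {
    paste(tab$sample_id, tab$chrom, tab$pos)
  } else {
    paste(tab$chrom, tab$pos)
  }
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf(
      "%s: duplicate (chrom, pos) at line %d", what, dup[1] + 1L
    ))
  }
  invisible(tab)
}

#' Write a per-site nucleotide count table
#'
#' Inverse of [read_count_table()]: a write followed by a read reproduces
#' the table exactly (the derived `depth` column is not written).
#'
#' @param counts Count-table tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  assert_columns(counts, c("chrom", "pos", NUCLEOTIDES))
  keep <- intersect(c("chrom", "pos", NUCLEOTIDES, "sample_id"), names(counts))
  readr::write_tsv(counts[keep], path, progress = FALSE)
  invisible(path)
}

#' Per-site allele frequency in one pool
#'
#' @param counts Count-table tibble (any number of rows).
#' @param allele One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return Numeric vector of `count(allele) / depth`, one value per row.
#'   Sites with zero depth raise an error: a frequency is undefined there.
#' @export
#' @examples
#' site_allele_frequency(tibble::tibble(
#'   chrom = "chrI", pos = 1000L, A = 150, C = 0, G = 50, T = 0
#' ), "G")
site_allele_frequency <- function(counts, allele) {
  allele <- match.arg(allele, NUCLEOTIDES)
  assert_columns(counts, NUCLEOTIDES)
  depth <- counts$A + counts$C + counts$G + counts$T
  if (any(depth == 0)) {
    abort("allele frequency undefined at zero-depth site(s)")
  }
  counts[[allele]] / depth
}

#' Call biallelic SNPs and their lake-stream differentiation
#'
#' Joins the two natural-population count tables on `(chrom, pos)` (sites
#' missing in either pool are treated as unsequenced and skipped), applies
#' the pool-seq quality filters, and returns one row per retained SNP with
#' per-pool frequencies of the major allele and the absolute allele
#' frequency difference AFD.
#'
#' Filters, in order: (a) total read depth within `[depth_min, depth_max]`
#' in *each* pool; (b) the site is effectively biallelic: the two most
#' frequent nucleotides over the summed counts of both pools carry at least
#' `1 - third_allele_tol` of all reads, the second-ranked nucleotide has at
#' least one read, and there is no count tie between the second and third
#' ranked nucleotide (ambiguous allele identity); (c) the minor allele
#' frequency over the summed counts of both pools is at least `maf_min`.
#' Frequencies are renormalised over the two retained alleles.
#'
#' @param lake,stream Count-table tibbles for the two natural pools.
#' @param depth_min,depth_max Per-pool depth window (reads), default 100-360.
#' @param maf_min Minimum minor allele frequency across the pooled counts of
#'   both populations, default 0.25.
#' @param third_allele_tol Maximum tolerated fraction of reads on the third
#'   and fourth nucleotide, default 0.01 (absorbs sequencing error).
#' @param quiet Suppress the per-filter drop-count message.
#' @return Tibble with columns `chrom`, `pos`, `allele_hi`, `allele_lo`,
#'   `freq_lake`, `freq_stream` (frequency of `allele_hi`), `depth_lake`,
#'   `depth_stream`, `afd`, `pooled_maf`.
#' @export
call_biallelic_snps <- function(lake, stream,
                                depth_min = 100, depth_max = 360,
                                maf_min = 0.25, third_allele_tol = 0.01,
                                quiet = FALSE) {
  assert_columns(lake, c("chrom", "pos", NUCLEOTIDES), "lake table")
  assert_columns(stream, c("chrom", "pos", NUCLEOTIDES), "stream table")

  joined <- inner_join(
    select(lake, "chrom", "pos", all_of(NUCLEOTIDES)),
    select(stream, "chrom", "pos", all_of(NUCLEOTIDES)),
    by = c("chrom", "pos"), suffix = c("_lake", "_stream")
  )
  n_shared <- nrow(joined)
  if (n_shared == 0) {
    return(empty_snp_table())
  }

  cl <- as.matrix(joined[paste0(NUCLEOTIDES, "_lake")])
  cs <- as.matrix(joined[paste0(NUCLEOTIDES, "_stream")])
  depth_lake <- rowSums(cl)
  depth_stream <- rowSums(cs)

  ok_depth <- depth_lake >= depth_min & depth_lake <= depth_max &
    depth_stream >= depth_min & depth_stream <= depth_max

  total <- cl + cs
  rk <- rank_nucleotides(total)
  # biallelic: top two alleles carry >= 1 - tol of reads, a genuine second
  # allele exists, and rank 2 vs rank 3 is not tied
  ok_biallelic <- rk$v2 > 0 &
    rk$v2 != rk$v3 &
    (rk$v1 + rk$v2) >= (1 - third_allele_tol) * rowSums(total)

  pooled_maf <- ifelse(rk$v1 + rk$v2 > 0, rk$v2 / (rk$v1 + rk$v2), 0)
  ok_maf <- pooled_maf >= maf_min

  keep <- ok_depth & ok_biallelic & ok_maf
  if (!quiet) {
    inform(sprintf(
      paste0(
        "call_biallelic_snps: %d shared sites; dropped %d on depth, ",
        "%d on biallelicity, %d on pooled MAF; %d SNPs retained"
      ),
      n_shared, sum(!ok_depth), sum(ok_depth & !ok_biallelic),
      sum(ok_depth & ok_biallelic & !ok_maf), sum(keep)
    ))
  }
  if (!any(keep)) {
    return(empty_snp_table())
  }

  idx <- which(keep)
  i1 <- cbind(idx, rk$i1[idx])
  i2 <- cbind(idx, rk$i2[idx])
  hi_lake <- cl[i1]; lo_lake <- cl[i2]
  hi_stream <- cs[i1]; lo_stream <- cs[i2]
  # frequencies over the two retained alleles only (renormalised);
  # a pool with zero reads on both retained alleles cannot occur here
  # because the per-pool depth filter and the 1% third-allele rule bound
  # off-allele reads well below total depth
  freq_lake <- hi_lake / (hi_lake + lo_lake)
  freq_stream <- hi_stream / (hi_stream + lo_stream)

  tibble(
    chrom = joined$chrom[idx],
    pos = joined$pos[idx],
    allele_hi = NUCLEOTIDES[rk$i1[idx]],
    allele_lo = NUCLEOTIDES[rk$i2[idx]],
    freq_lake = freq_lake,
    freq_stream = freq_stream,
    depth_lake = depth_lake[idx],
    depth_stream = depth_stream[idx],
    afd = abs(freq_lake - freq_stream),
    pooled_maf = pooled_maf[idx]
  ) |>
    arrange(.data$chrom, .data$pos)
}

empty_snp_table <- function() {
  tibble(
    chrom = character(), pos = integer(),
    allele_hi = character(), allele_lo = character(),
    freq_lake = double(), freq_stream = double(),
    depth_lake = double(), depth_stream = double(),
    afd = double(), pooled_maf = double()
  )
}

# Row-wise ranking of a 4-column count matrix without apply(): repeated
# max.col with masking. Ties between ranks resolved to the lower column
# index, but rank-2/rank-3 count ties are detected by the caller via v2/v3.
rank_nucleotides <- function(m) {
  m1 <- m
  i1 <- max.col(m1, ties.method = "first")
  v1 <- m1[cbind(seq_len(nrow(m)), i1)]
  m1[cbind(seq_len(nrow(m)), i1)] <- -1
  i2 <- max.col(m1, ties.method = "first")
  v2 <- m1[cbind(seq_len(nrow(m)), i2)]
  m1[cbind(seq_len(nrow(m)), i2)] <- -1
  i3 <- max.col(m1, ties.method = "first")
  v3 <- m1[cbind(seq_len(nrow(m)), i3)]
  list(i1 = i1, v1 = v1, i2 = i2, v2 = v2, i3 = i3, v3 = v3)
}

#' Filter sites on read depth in one named sample
#'
#' Restricts a (possibly long-format, multi-sample) count table to the
#' `(chrom, pos)` sites at which the named sample reaches `depth_min` reads.
#' The threshold is inclusive ("at least").
#'
#' @param sites Count-table tibble; either carries a `sample_id` column or
#'   represents the named sample itself.
#' @param sample Sample label to test depth for.
#' @param depth_min Minimum read depth (inclusive).
#' @return The input tibble restricted to retained sites.
#' @export
pool_depth_filter <- function(sites, sample, depth_min) {
  assert_columns(sites, c("chrom", "pos", NUCLEOTIDES))
  if (nrow(sites) == 0) return(sites)
  depth <- sites$A + sites$C + sites$G + sites$T
  if ("sample_id" %in% names(sites)) {
    if (!sample %in% sites$sample_id) {
      abort(sprintf("unknown sample label: %s", sample))
    }
    in_sample <- sites$sample_id == sample
    ok_key <- paste(sites$chrom, sites$pos)[in_sample & depth >= depth_min]
    sites[paste(sites$chrom, sites$pos) %in% ok_key, ]
  } else {
    if (!is.null(attr(sites, "sample_id")) &&
        !identical(attr(sites, "sample_id"), sample)) {
      abort(sprintf("unknown sample label: %s", sample))
    }
    sites[depth >= depth_min, ]
  }
}
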