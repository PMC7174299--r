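test_that("the tail threshold follows the nearest-rank quantile", {
  snps <- tibble::tibble(chrom = "chrI", pos = 1:1000, afd = (1:1000) / 1000)
  cutoff <- chromosome_afd_threshold(snps, "chrI", tail = 0.001)
  expect_equal(cutoff, 0.999)
  expect_equal(sum(snps$afd >= cutoff), 2) # 0.999 and 1.000 qualify

  # degenerate distribution: every SNP qualifies
  flat <- tibble::tibble(chrom = "chrI", pos = 1:2000, afd = 0.2)
  expect_equal(chromosome_afd_threshold(flat, "chrI"), 0.2)

  # single-SNP chromosome: cutoff is that SNP's value, with a warning
  one <- tibble::tibble(chrom = "chrX", pos = 5L, afd = 0.7)
  expect_warning(cut1 <- chromosome_afd_threshold(one, "chrX"), "fewer than")
  expect_equal(cut1, 0.7)

  expect_error(chromosome_afd_threshold(snps, "chrZ"), "no SNPs")
})

test_that("per-chromosome thresholds are computed independently", {
  snps <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = 1:1000, afd = (1:1000) / 1000),
    tibble::tibble(chrom = "chr2", pos = 1:1000, afd = (1:1000) / 2000)
  )
  thr <- chromosome_afd_threshold(snps)
  expect_equal(thr$cutoff[thr$chrom == "chr1"], 0.999)
  expect_equal(thr$cutoff[thr$chrom == "chr2"], 0.4995)
})

test_that("candidate regions chain SNPs within the gap, transitively", {
  r1 <- delimit_candidate_regions(
    tibble::tibble(chrom = "chrI", pos = c(100000, 130000, 200000))
  )
  expect_equal(nrow(r1), 2)
  expect_equal(r1$start, c(100000, 200000))
  expect_equal(r1$end, c(130000, 200000))

  # chained via <= 50 kb neighbour steps although ends are 85 kb apart
  r2 <- delimit_candidate_regions(
    tibble::tibble(chrom = "chrI", pos = c(100000, 140000, 185000))
  )
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_snps, 3)

  r3 <- delimit_candidate_regions(tibble::tibble(chrom = "chrI", pos = 5000))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$start, r3$end)

  # same position on different chromosomes never chains
  r4 <- delimit_candidate_regions(
    tibble::tibble(chrom = c("chrI", "chrII"), pos = c(1000, 1000))
  )
  expect_equal(nrow(r4), 2)
})

test_that("region count is non-increasing in the cluster gap", {
  set.seed(5)
  pos <- sort(sample.int(2e6, 300))
  snps <- tibble::tibble(chrom = "chrI", pos = pos)
  n_regions <- vapply(
    c(1000, 10000, 50000, 200000),
    function(g) nrow(delimit_candidate_regions(snps, cluster_gap = g)),
    numeric(1)
  )
  expect_true(all(diff(n_regions) <= 0))
})

test_that("target selection applies reference and survivor filters per region", {
  # region with two members: higher-AFD SNP fails reference depth,
  # the other passes everything
  snps <- tibble::tibble(
    chrom = "chrI", pos = c(1000L, 2000L),
    allele_hi = "A", allele_lo = "G",
    freq_lake = c(0.2, 0.25), freq_stream = c(0.80, 0.80),
    depth_lake = 200, depth_stream = 200,
    afd = c(0.60, 0.55), pooled_maf = 0.5
  )
  regions <- delimit_candidate_regions(snps)
  expect_equal(nrow(regions), 1)
  reference <- count_table("chrI", c(1000, 2000), A = c(30, 40), G = c(35, 40))
  survivors <- dplyr::bind_rows(lapply(1:36, function(i) {
    count_table("chrI", c(1000, 2000), A = 1, G = 1, sample_id = sprintf("s%02d", i))
  }))
  targets <- select_target_snps(regions, snps, reference, survivors)
  expect_equal(targets$pos, 2000L)
  expect_equal(targets$stream_allele, "A")
  expect_equal(targets$n_survivors_covered, 36)
  expect_equal(targets$freq_reference, 0.5)

  # all members failing filters yield an untagged region, not an error
  ref_low <- count_table("chrI", c(1000, 2000), A = c(30, 20), G = c(35, 20))
  none <- select_target_snps(regions, snps, ref_low, survivors)
  expect_equal(nrow(none), 0)

  # AFD tie with both members passing all filters: the leftmost wins
  snps_tie <- dplyr::mutate(snps, afd = 0.55)
  ref_ok <- count_table("chrI", c(1000, 2000), A = c(40, 40), G = c(40, 40))
  t2 <- select_target_snps(delimit_candidate_regions(snps_tie), snps_tie, ref_ok, survivors)
  expect_equal(t2$pos, 1000L)
})

test_that("targets are polarized to the stream allele", {
  # allele_hi (A) is the LAKE-favored allele here: stream allele is G
  snps <- tibble::tibble(
    chrom = "chrI", pos = 1000L, allele_hi = "A", allele_lo = "G",
    freq_lake = 0.9, freq_stream = 0.3, depth_lake = 200,
    depth_stream = 200, afd = 0.6, pooled_maf = 0.4
  )
  reference <- count_table("chrI", 1000, A = 60, G = 40)
  survivors <- dplyr::bind_rows(lapply(1:37, function(i) {
    count_table("chrI", 1000, A = 2, G = 1, sample_id = sprintf("s%02d", i))
  }))
  tg <- select_target_snps(delimit_candidate_regions(snps), snps, reference, survivors)
  expect_equal(tg$stream_allele, "G")
  expect_equal(tg$freq_lake, 0.1)
  expect_equal(tg$freq_stream, 0.7)
  expect_equal(tg$freq_reference, 0.4)
})

test_that("sliding windows average AFD and omit empty windows", {
  snps <- tibble::tibble(
    chrom = "chrI", pos = c(10000L, 30000L), afd = c(0.1, 0.3)
  )
  win <- smooth_afd_windows(snps)
  first <- win[win$start == 1, ]
  expect_equal(first$mean_afd, 0.2)
  expect_equal(first$n_snps, 2L)
  # the window starting at 20001 holds only the second SNP
  second <- win[win$start == 20001, ]
  expect_equal(second$mean_afd, 0.3)
  # no windows beyond the data
  expect_true(all(win$start <= 30000))

  # a single SNP reports its own AFD in every covering window
  one <- smooth_afd_windows(tibble::tibble(chrom = "chrI", pos = 50000L, afd = 0.42))
  expect_equal(nrow(one), 2)
  expect_true(all(one$mean_afd == 0.42))
  expect_true(all(one$start <= 50000 & one$end >= 50000))
})

test_that("the genome-wide threshold mode uses one cutoff for all chromosomes", {
  b <- small_bundle()
  snps <- call_biallelic_snps(b$counts_lake, b$counts_stream, quiet = TRUE)
  surv_pool <- pool_survivor_counts(b$counts_survivors)
  scan <- afd_scan(snps, b$counts_reference, surv_pool, genome_wide = TRUE)
  expect_equal(length(unique(scan$thresholds$cutoff)), 1)
  expect_true(all(scan$high_snps$afd >= scan$thresholds$cutoff[1]))
  expect_lte(nrow(scan$targets), nrow(scan$regions))
})
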