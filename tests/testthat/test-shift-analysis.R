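test_that("survivor pooling sums counts and tallies contributors", {
  ind <- dplyr::bind_rows(
    count_table("chrI", c(100, 200), A = c(2, 0), G = c(1, 0), sample_id = "s1"),
    count_table("chrI", c(100, 200), A = c(0, 3), G = c(3, 0), sample_id = "s2")
  )
  pool <- pool_survivor_counts(ind)
  expect_equal(pool$A, c(2, 3))
  expect_equal(pool$G, c(4, 0))
  expect_equal(pool$contributors, c(2, 1))
  # conservation: pooled depth equals the sum of individual depths
  expect_equal(sum(pool$depth), sum(ind$A + ind$C + ind$G + ind$T))
})

test_that("shifts are stream-allele survivor minus reference frequencies", {
  targets <- tibble::tibble(
    chrom = "chrI", pos = c(1L, 2L, 3L),
    stream_allele = c("A", "A", "G"), afd = 0.5
  )
  reference <- count_table("chrI", 1:3,
    A = c(523, 50, 10), G = c(477, 50, 90)
  )
  surv <- count_table("chrI", 1:3, A = c(563, 60, 60), G = c(437, 60, 40))
  surv$contributors <- 37
  shifts <- compute_frequency_shifts(targets, reference, surv)
  expect_equal(shifts$shift, c(0.563 - 0.523, 0, 0.4 - 0.9))
  expect_equal(shifts$sign, c("+", "0", "-"))

  # a target with zero usable depth in one sample is a contract violation
  ref0 <- count_table("chrI", 1:3, A = c(523, 0, 10), G = c(477, 0, 90))
  expect_error(compute_frequency_shifts(targets, ref0, surv), "zero usable depth")
})

test_that("the exact binomial sign test matches small-sample enumeration", {
  # 10 of 10 positive: exact two-tailed probability is 2 / 2^10
  res <- sign_binomial_test(rep(0.1, 10))
  expect_equal(res$p_two_tailed, 2 / 1024)

  # perfectly balanced outcome caps at 1
  expect_equal(sign_binomial_test(c(rep(1, 63), rep(-1, 63)))$p_two_tailed, 1)

  # zero shifts are excluded from n
  res2 <- sign_binomial_test(c(rep(0.1, 10), 0, 0))
  expect_equal(res2$n, 10)
  expect_equal(res2$n_zero, 2)
  expect_equal(res2$p_two_tailed, 2 / 1024)

  expect_error(sign_binomial_test(c(0, 0)), "all shifts are zero")

  # agreement with the exact symmetric two-sided binomial test
  for (k in c(7, 9, 10)) {
    expect_equal(
      sign_binomial_test(c(rep(1, k), rep(-1, 12 - k)))$p_two_tailed,
      binom.test(k, 12, 0.5)$p.value
    )
  }
})

test_that("empirical two-tailed probabilities are count over iterations", {
  null <- c(0.05, rep(0.001, 8)) # 1 of 9 at least as extreme as 0.05
  expect_equal(empirical_two_tailed_p(null, 0.05), 1 / 9)
  expect_equal(empirical_two_tailed_p(null, 0.05, plus_one = TRUE), 2 / 10)
  # sign of the observed statistic is irrelevant (two-tailed on magnitude)
  expect_equal(empirical_two_tailed_p(null, -0.05), 1 / 9)
  # observed zero is never exceptional
  expect_equal(empirical_two_tailed_p(null, 0), 1)
  # observed beyond every null value
  expect_equal(empirical_two_tailed_p(null, 1), 0)
  expect_equal(empirical_two_tailed_p(null, 1, plus_one = TRUE), 1 / 10)
})

test_that("the neutral panel honours AFD range, MAF, depth and coverage rules", {
  snps <- tibble::tibble(
    chrom = "chrI", pos = c(1L, 2L, 3L, 4L),
    allele_hi = "A", allele_lo = "G",
    freq_lake = c(0.50, 0.50, 0.50, 0.50),
    freq_stream = c(0.55, 0.62, 0.55, 0.55),
    depth_lake = 200, depth_stream = 200,
    afd = c(0.05, 0.12, 0.05, 0.05), pooled_maf = 0.45
  )
  reference <- count_table("chrI", 1:4,
    A = c(40, 40, 21, 40), G = c(40, 40, 49, 40)
  ) # site 3: reference MAF 0.30
  surv <- count_table("chrI", 1:4, A = c(40, 40, 40, 40), G = c(40, 40, 40, 40))
  surv$contributors <- c(36, 36, 36, 30) # site 4: too few survivors

  low <- build_neutral_panel(snps, robustness_config("low_afd", 0.35), reference, surv)
  expect_equal(low$pos, 1L) # AFD 0.12 excluded; MAF 0.30 excluded; coverage 30 excluded

  mid <- build_neutral_panel(snps, robustness_config("mid_afd", 0.35), reference, surv)
  expect_equal(mid$pos, 2L) # only the AFD 0.12 SNP falls in [0.1, 0.17]

  expect_error(
    build_neutral_panel(
      snps, robustness_config("low_afd", 0.35, afd_range = c(0.3, 0.4)),
      reference, surv
    ),
    "empty"
  )
})

test_that("a stricter reference MAF threshold never enlarges the panel", {
  b <- small_bundle()
  snps <- call_biallelic_snps(b$counts_lake, b$counts_stream, quiet = TRUE)
  surv_pool <- pool_survivor_counts(b$counts_survivors)
  sizes <- vapply(c(0.25, 0.35, 0.40), function(maf) {
    nrow(build_neutral_panel(
      snps, robustness_config("low_afd", maf), b$counts_reference, surv_pool
    ))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("resampling is seed-deterministic and respects the spacing rule", {
  b <- small_bundle()
  snps <- call_biallelic_snps(b$counts_lake, b$counts_stream, quiet = TRUE)
  surv_pool <- pool_survivor_counts(b$counts_survivors)
  panel <- build_neutral_panel(
    snps, robustness_config("low_afd", 0.35), b$counts_reference, surv_pool
  )
  null1 <- resample_null_medians(panel, n_snps = 50, iterations = 60, seed = 99, keep_draws = TRUE)
  null2 <- resample_null_medians(panel, n_snps = 50, iterations = 60, seed = 99)
  expect_identical(null1$medians, null2$medians)
  expect_identical(null1$means, null2$means)

  # every iteration: distinct SNPs, pairwise spacing > 50 kb
  for (it in c(1, 30, 60)) {
    idx <- null1$draws[it, ]
    expect_equal(anyDuplicated(idx), 0)
    g <- sort(panel$gpos[idx])
    expect_true(all(diff(g) > 50000))
  }

  # a panel of all-zero shifts yields an all-zero null
  panel0 <- dplyr::mutate(panel, shift = 0)
  null0 <- resample_null_medians(panel0, n_snps = 50, iterations = 20, seed = 1)
  expect_true(all(null0$medians == 0))

  expect_error(
    resample_null_medians(panel[1:10, ], n_snps = 50, iterations = 5, seed = 1),
    "cannot draw"
  )
})

test_that("median and mean of per-SNP shifts are computed independently", {
  # the median of shifts differs from the difference of median frequencies
  targets <- tibble::tibble(
    chrom = "chrI", pos = 1:3, stream_allele = "A", afd = 0.5
  )
  reference <- count_table("chrI", 1:3, A = c(100, 500, 900), G = c(900, 500, 100))
  surv <- count_table("chrI", 1:3, A = c(520, 300, 560), G = c(480, 700, 440))
  surv$contributors <- 37
  shifts <- compute_frequency_shifts(targets, reference, surv)
  med_of_shifts <- median(shifts$shift)
  diff_of_medians <- median(shifts$freq_survivors) - median(shifts$freq_reference)
  expect_equal(med_of_shifts, -0.2)
  expect_equal(diff_of_medians, 0.52 - 0.5)
  # and the mean is a genuinely different statistic here
  expect_false(isTRUE(all.equal(mean(shifts$shift), med_of_shifts)))
})

test_that("the robustness suite runs all six published panel variants", {
  b <- small_bundle()
  snps <- call_biallelic_snps(b$counts_lake, b$counts_stream, quiet = TRUE)
  surv_pool <- pool_survivor_counts(b$counts_survivors)
  scan <- afd_scan(snps, b$counts_reference, surv_pool)
  suite <- run_robustness_suite(
    snps, scan$targets, b$counts_reference, surv_pool,
    iterations = 99, seed = 5
  )
  expect_equal(nrow(suite), 6)
  expect_equal(
    suite$panel_mode,
    c("low_afd", "low_afd", "low_afd", "mid_afd", "unrestricted", "unrestricted")
  )
  expect_equal(suite$ref_maf_min, c(0.25, 0.35, 0.40, 0.35, 0.25, 0.35))
  expect_true(all(vapply(suite$null, function(n) length(n$medians), numeric(1)) == 99))
  # every variant tests the same observed statistics
  expect_equal(length(unique(suite$observed_median)), 1)
  expect_true(all(suite$p_median >= 0 & suite$p_median <= 1))
})
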