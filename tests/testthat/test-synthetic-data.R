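test_that("genome maps hit the requested SNP density", {
  map <- generate_genome_map(
    n_chrom = 1, chrom_length = 4.4e6, mean_spacing = 440, seed = 2
  )
  n <- nrow(map$snps)
  # ~10000 SNPs within Poisson error
  expect_lt(abs(n - 10000), 4 * sqrt(10000))
  expect_true(all(diff(map$snps$pos) > 0))
  expect_true(all(map$snps$pos <= 4.4e6))

  map2 <- generate_genome_map(
    n_chrom = 1, chrom_length = 4.4e6, mean_spacing = 440, seed = 2
  )
  expect_identical(map$snps, map2$snps)

  map3 <- generate_genome_map(
    n_chrom = 2, chrom_length = 440000, mean_spacing = 440, seed = 5
  )
  counts <- table(map3$snps$chrom)
  expect_true(all(abs(counts - 1000) < 4 * sqrt(1000)))
})

test_that("the divergence scale is tuned to the published median AFD", {
  d <- tune_background_divergence(target_median = 0.139, seed = 3)
  set.seed(4)
  draws <- d * rbeta(2e5, 1.2, 1.5)
  expect_equal(median(draws), 0.139, tolerance = 0.01)
})

test_that("planted loci are symmetric about the centre and well spaced", {
  map <- generate_genome_map(n_chrom = 2, chrom_length = 4e6, mean_spacing = 2000, seed = 6)
  truth <- draw_population_frequencies(
    map,
    n_planted = 40, planted_afd_range = c(0.597, 0.597), seed = 7
  )
  pl <- truth[truth$planted, ]
  expect_equal(nrow(pl), 40)
  expect_equal(pl$freq_lake, rep(0.5 - 0.597 / 2, 40))
  expect_equal(pl$freq_stream, rep(0.5 + 0.597 / 2, 40))
  expect_equal(pl$true_afd, rep(0.597, 40))
  # pairwise spacing > 50 kb within chromosomes
  for (ch in unique(pl$chrom)) {
    expect_true(all(diff(sort(pl$pos[pl$chrom == ch])) > 50000))
  }
  # every frequency strictly inside (0, 1)
  expect_true(all(truth$freq_lake > 0 & truth$freq_lake < 1))
  expect_true(all(truth$freq_stream > 0 & truth$freq_stream < 1))

  # an offset centre reproduces the asymmetric construction
  t2 <- draw_population_frequencies(
    map,
    n_planted = 10, planted_afd_range = c(0.5, 0.5),
    planted_center = 0.5175, seed = 8
  )
  p2 <- t2[t2$planted, ]
  expect_equal(unique(p2$freq_lake + p2$freq_stream) / 2, 0.5175)

  # unattainable planted AFD about an off-centre midpoint errors
  expect_error(
    draw_population_frequencies(
      map,
      n_planted = 1, planted_afd_range = c(0.95, 0.95),
      planted_center = 0.4, seed = 9
    ),
    "unattainable"
  )
})

test_that("a zero divergence scale yields a null background", {
  map <- generate_genome_map(n_chrom = 1, chrom_length = 1e6, mean_spacing = 1000, seed = 10)
  truth <- draw_population_frequencies(map, divergence = 0, n_planted = 0, seed = 11)
  expect_true(all(truth$true_afd == 0))
  expect_true(all(truth$freq_lake == truth$freq_stream))
})

test_that("reference frequencies are intermediate with binomial noise", {
  map <- generate_genome_map(n_chrom = 1, chrom_length = 2e6, mean_spacing = 1000, seed = 12)
  truth <- draw_population_frequencies(map, n_planted = 20, seed = 13)
  truth <- f2_reference_frequencies(truth, n_reference = 510, seed = 14)
  mid <- (truth$freq_lake + truth$freq_stream) / 2
  resid <- truth$freq_reference - mid
  expect_lt(abs(mean(resid)), 0.005)
  expect_lt(max(abs(resid)), 6 * sqrt(0.25 / 1020))
  # planted loci: reference ~ 0.5 by the symmetric construction
  expect_equal(mean(truth$freq_reference[truth$planted]), 0.5, tolerance = 0.02)
})

test_that("survivor cohorts bottleneck the reference gene pool", {
  map <- generate_genome_map(n_chrom = 1, chrom_length = 1e6, mean_spacing = 500, seed = 15)
  truth <- draw_population_frequencies(map, n_planted = 15, seed = 16)
  truth <- f2_reference_frequencies(truth, seed = 17)

  g <- simulate_survivor_cohort(truth, scheme = "neutral", seed = 18)
  expect_equal(dim(g), c(37, nrow(truth)))
  expect_true(all(g %in% 0:2))
  # neutral survivors: per-locus frequencies scatter around the reference
  # frequency with sd ~ sqrt(pq/74)
  fs <- colMeans(g) / 2
  resid <- fs - truth$freq_reference
  expect_lt(abs(mean(resid)), 0.01)
  expect_equal(sd(resid), sqrt(mean(truth$freq_reference * (1 - truth$freq_reference)) / 74),
    tolerance = 0.1
  )

  expect_error(
    simulate_survivor_cohort(truth, n_released = 10, n_survivors = 37),
    "exceed"
  )

  # selection on planted loci shifts them upward, background stays centred
  gs <- simulate_survivor_cohort(
    truth,
    scheme = fitness_scheme("multiplicative", 0.3), seed = 19
  )
  shift_planted <- mean(colMeans(gs[, truth$planted, drop = FALSE]) / 2 -
    truth$freq_reference[truth$planted])
  shift_bg <- mean(colMeans(gs[, !truth$planted, drop = FALSE]) / 2 -
    truth$freq_reference[!truth$planted])
  expect_gt(shift_planted, 0.02)
  expect_lt(abs(shift_bg), 0.01)
})

test_that("pooled count sampling is unbiased with the requested depth", {
  map <- generate_genome_map(n_chrom = 1, chrom_length = 2e6, mean_spacing = 500, seed = 20)
  truth <- draw_population_frequencies(map, n_planted = 0, seed = 21)
  counts <- sample_pooled_counts(truth, mean_depth = 210, seed = 22)
  depth <- counts$A + counts$C + counts$G + counts$T
  expect_equal(mean(depth), 210, tolerance = 0.01)

  # frequency estimates are unbiased around the truth
  ia <- cbind(seq_len(nrow(counts)), match(truth$allele_a, c("A", "C", "G", "T")))
  est <- as.matrix(counts[c("A", "C", "G", "T")])[ia] / depth
  expect_lt(abs(mean(est - truth$freq_lake)), 0.002)

  # no error, frequency 1: every read reports the focal allele
  t1 <- truth[1:50, ]
  t1$freq_lake <- 1
  c1 <- sample_pooled_counts(t1, mean_depth = 100, error_rate = 0, seed = 23)
  d1 <- c1$A + c1$C + c1$G + c1$T
  expect_equal(as.matrix(c1[c("A", "C", "G", "T")])[cbind(1:50, match(t1$allele_a, c("A", "C", "G", "T")))], d1)
})

test_that("individual survivor sequencing matches the published depth profile", {
  map <- generate_genome_map(n_chrom = 1, chrom_length = 1e6, mean_spacing = 500, seed = 24)
  truth <- draw_population_frequencies(map, n_planted = 0, seed = 25)
  truth <- f2_reference_frequencies(truth, seed = 26)
  g <- simulate_survivor_cohort(truth, scheme = "neutral", seed = 27)
  counts <- sample_individual_counts(g, truth, seed = 28)
  expect_equal(length(unique(counts$sample_id)), 37)

  pooled <- pool_survivor_counts(counts)
  # 37 survivors at means uniform in [2.6, 4.4] give ~130x pooled depth
  # (the published combined survivor depth is 115x at mean 3.1)
  expect_equal(mean(pooled$depth), 37 * 3.5, tolerance = 0.1)
  # zero-coverage rate per individual-site ~ E[exp(-mu)]
  frac0 <- mean(counts$A + counts$C + counts$G + counts$T == 0)
  expected0 <- integrate(function(m) exp(-m) / 1.8, 2.6, 4.4)$value
  expect_equal(frac0, expected0, tolerance = 0.15)
  # a genotype of 2 with no error yields only focal-allele reads
  g2 <- matrix(2L, 3, 20)
  t20 <- truth[1:20, ]
  c2 <- sample_individual_counts(g2, t20, error_rate = 0, seed = 29)
  ia <- match(t20$allele_a[match(c2$pos, t20$pos)], c("A", "C", "G", "T"))
  cm <- as.matrix(c2[c("A", "C", "G", "T")])
  expect_equal(cm[cbind(seq_len(nrow(cm)), ia)], rowSums(cm))
})

test_that("study bundles are deterministic and carry a faithful manifest", {
  cfg <- study_config(n_chrom = 2, chrom_length = 1e6, mean_spacing = 2500, n_planted = 15)
  b1 <- generate_study_bundle(cfg, seed = 31)
  b2 <- generate_study_bundle(cfg, seed = 31)
  expect_identical(b1$counts_lake, b2$counts_lake)
  expect_identical(b1$counts_survivors, b2$counts_survivors)
  expect_identical(b1$truth$freq_stream, b2$truth$freq_stream)

  # manifest records the planted loci exactly
  expect_equal(
    b1$manifest$planted$pos,
    b1$truth$pos[b1$truth$planted]
  )

  # a different seed changes the data
  b3 <- generate_study_bundle(cfg, seed = 32)
  expect_false(identical(b1$counts_lake, b3$counts_lake))

  # disk round trip preserves the count tables
  dir <- withr::local_tempdir()
  write_study_bundle(b1, dir)
  lake <- read_count_table(file.path(dir, "lake.tsv"))
  expect_equal(
    lake[c("chrom", "pos", "A", "C", "G", "T")],
    b1$counts_lake[c("chrom", "pos", "A", "C", "G", "T")]
  )
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
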