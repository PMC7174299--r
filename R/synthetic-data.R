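#' Generate a synthetic genome map of SNP positions
#'
#' Places SNPs along each chromosome by a homogeneous point process with
#' mean inter-SNP gap `mean_spacing` (exponential gaps rounded up to at
#' least 1 bp), emulating the observed density of about one SNP per 440 bp.
#'
#' @param n_chrom Number of chromosomes, default 5.
#' @param chrom_length Chromosome length(s) in bp (recycled), default 2 Mb.
#' @param mean_spacing Mean gap between SNPs in bp, default 440.
#' @param seed Seed for reproducibility.
#' @return Object of class `"genome_map"`: list with `chromosomes`
#'   (tibble `chrom`, `length`) and `snps` (tibble `chrom`, `pos`, strictly
#'   increasing within chromosome).
#' @export
generate_genome_map <- function(n_chrom = 5, chrom_length = 2e6,
                                mean_spacing = 440, seed = NULL) {
  chrom_length <- rep_len(chrom_length, n_chrom)
  if (any(chrom_length < 10 * mean_spacing)) {
    abort("chromosomes must be at least 10 x mean_spacing long")
  }
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  with_seed(seed, {
    snps <- purrr::map2_dfr(chroms, chrom_length, function(ch, len) {
      n_max <- ceiling(len / mean_spacing * 1.3) + 50
      gaps <- pmax(1, ceiling(rexp(n_max, rate = 1 / mean_spacing)))
      pos <- cumsum(gaps)
      while (pos[length(pos)] <= len) { # rarely needed top-up
        extra <- pmax(1, ceiling(rexp(50, rate = 1 / mean_spacing)))
        pos <- c(pos, pos[length(pos)] + cumsum(extra))
      }
      tibble(chrom = ch, pos = as.integer(pos[pos <= len]))
    })
    structure(
      list(
        chromosomes = tibble(chrom = chroms, length = chrom_length),
        snps = snps
      ),
      class = "genome_map"
    )
  })
}

# Background lake-stream divergence model: the true AFD of a background SNP
# is divergence * Beta(1.2, 1.5). With divergence tuned so the median true
# AFD is 0.139, about 35% of SNPs fall below measured AFD 0.1 (the published
# neutral-panel share is 38%) and the distribution is bounded at ~0.32, so
# that even with 210x sequencing noise the measured background tail stays
# below 0.477, the least-differentiated real target SNP — a requirement for
# a 0.1-percentile threshold scan to separate divergent loci from
# background, as it evidently did in the real data. The realized mean
# (~0.148 measured) sits slightly below the published 0.165; a fatter-
# tailed shape could match the mean but would push background into the
# target AFD range, contradicting the measured data.
BACKGROUND_AFD_SHAPE <- c(1.2, 1.5)

#' Tune the background divergence parameter by bisection
#'
#' Finds the scale `d` such that the median of `d * Beta(a, b)` draws —
#' the realized background AFD distribution before sequencing noise —
#' matches `target_median`. Bisection on a fixed seeded Monte-Carlo sample.
#'
#' @param target_median Target median background AFD, default 0.139.
#' @param n_draws Monte-Carlo sample size, default 200000.
#' @param tol Bisection tolerance on the median, default 1e-4.
#' @param seed Seed for the Monte-Carlo sample.
#' @return The tuned divergence scale.
#' @export
tune_background_divergence <- function(target_median = 0.139,
                                       n_draws = 2e5, tol = 1e-4,
                                       seed = 1L) {
  b <- with_seed(seed, rbeta(n_draws, BACKGROUND_AFD_SHAPE[1], BACKGROUND_AFD_SHAPE[2]))
  med_b <- median(b)
  lo <- 0
  hi <- 1
  while (hi - lo > tol / med_b) {
    mid <- (lo + hi) / 2
    if (mid * med_b < target_median) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# cached default; median(Beta(1.2, 1.5)) = 0.4286, so d ~= 0.324
default_divergence <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- tune_background_divergence()
    val
  }
})

#' Draw true lake and stream allele frequencies for a genome map
#'
#' Background SNPs receive a common ancestral frequency (uniform on
#' `ancestral_range`) and a signed lake-stream divergence of magnitude
#' `divergence * Beta(0.63, 1.07)` split symmetrically about the ancestral
#' frequency; the ancestral frequency is redrawn when a boundary would be
#' crossed, so the drawn AFD magnitude is preserved. Planted loci are
#' placed pairwise more than `min_gap` apart with target AFD drawn
#' uniformly from `planted_afd_range` and lake/stream frequencies placed
#' symmetrically about `planted_center`.
#'
#' @param map A [generate_genome_map()] result.
#' @param divergence Background divergence scale; `NULL` uses the value
#'   tuned so the median true background AFD is 0.139
#'   ([tune_background_divergence()]). 0 gives a null model in which all
#'   measured differentiation arises from sampling alone.
#' @param n_planted Number of planted divergent loci, default 126; 0 gives
#'   a selection-free map.
#' @param planted_afd_range AFD range of planted loci, default
#'   `c(0.477, 0.934)`.
#' @param planted_center Midpoint of planted lake/stream frequency pairs,
#'   default 0.5 (set to 0.5175 to reproduce the asymmetry of the printed
#'   lake/stream medians 0.219 and 0.816).
#' @param ancestral_range Range of background ancestral frequencies,
#'   default `c(0.15, 0.85)`.
#' @param min_gap Minimum pairwise distance between planted loci in bp,
#'   default 50000.
#' @param seed Seed for reproducibility.
#' @return Object of class `"frequency_truth"`: tibble with `chrom`, `pos`,
#'   `planted`, `allele_a`, `allele_b` (the SNP's two nucleotides, with
#'   `allele_a` the focal/stream-favored one), `freq_lake`, `freq_stream`
#'   (frequencies of `allele_a`), `true_afd`; attribute `divergence`.
#' @export
draw_population_frequencies <- function(map, divergence = NULL,
                                        n_planted = 126,
                                        planted_afd_range = c(0.477, 0.934),
                                        planted_center = 0.5,
                                        ancestral_range = c(0.15, 0.85),
                                        min_gap = 50000, seed = NULL) {
  stopifnot(inherits(map, "genome_map"))
  if (is.null(divergence)) divergence <- default_divergence()
  snps <- map$snps
  n <- nrow(snps)
  with_seed(seed, {
    planted_idx <- if (n_planted > 0) {
      choose_spaced_positions(snps, n_planted, min_gap)
    } else {
      integer(0)
    }
    planted <- logical(n)
    planted[planted_idx] <- TRUE

    # background truth
    mag <- divergence * rbeta(n, BACKGROUND_AFD_SHAPE[1], BACKGROUND_AFD_SHAPE[2])
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    p0 <- runif(n, ancestral_range[1], ancestral_range[2])
    bad <- which(p0 - mag / 2 < 0.02 | p0 + mag / 2 > 0.98)
    while (length(bad) > 0) {
      p0[bad] <- runif(length(bad), ancestral_range[1], ancestral_range[2])
      bad <- bad[p0[bad] - mag[bad] / 2 < 0.02 | p0[bad] + mag[bad] / 2 > 0.98]
    }
    freq_lake <- p0 - sgn * mag / 2
    freq_stream <- p0 + sgn * mag / 2

    # planted truth: symmetric about planted_center, stream > lake
    if (n_planted > 0) {
      afd_t <- runif(n_planted, planted_afd_range[1], planted_afd_range[2])
      lk <- planted_center - afd_t / 2
      st <- planted_center + afd_t / 2
      if (any(lk <= 0 | st >= 1)) {
        abort("planted AFD unattainable about this center: frequencies leave (0, 1)")
      }
      freq_lake[planted_idx] <- lk
      freq_stream[planted_idx] <- st
    }

    # two nucleotides per SNP; allele_a is the focal allele whose
    # frequencies are stored. Vectorized uniform unordered pair: first
    # allele uniform on 4, second a uniform nonzero offset from it.
    i1 <- sample.int(4, n, replace = TRUE)
    i2 <- ((i1 - 1 + sample.int(3, n, replace = TRUE)) %% 4) + 1
    out <- tibble(
      chrom = snps$chrom, pos = snps$pos, planted = planted,
      allele_a = NUCLEOTIDES[i1], allele_b = NUCLEOTIDES[i2],
      freq_lake = freq_lake, freq_stream = freq_stream,
      true_afd = abs(freq_stream - freq_lake)
    )
    attr(out, "divergence") <- divergence
    class(out) <- c("frequency_truth", class(out))
    out
  })
}

# Greedy spaced subset: walk a random permutation of SNP rows, accept a row
# iff it lies > min_gap from every accepted row; error if the map cannot
# host n_pick such loci.
choose_spaced_positions <- function(snps, n_pick, min_gap) {
  gpos <- global_position(snps$chrom, snps$pos)
  idx <- draw_spaced_sample(gpos, n_pick, min_gap)
  if (is.null(idx)) {
    abort(sprintf(
      "cannot place %d loci pairwise > %d bp apart on this map", n_pick, min_gap
    ))
  }
  sort(idx)
}

#' True F2 reference frequencies from the parental truth
#'
#' The F2 hybrid cross mixes the two parental gene pools equally, so the
#' expected reference frequency at every SNP is the lake/stream midpoint;
#' the finite reference sample of `n_reference` diploid individuals adds
#' binomial noise over `2 * n_reference` allele draws.
#'
#' @param truth A [draw_population_frequencies()] result.
#' @param n_reference Individuals in the reference sample, default 510.
#' @param seed Seed for reproducibility.
#' @return `truth` with an added `freq_reference` column (frequency of
#'   `allele_a` in the reference sample's gene pool).
#' @export
f2_reference_frequencies <- function(truth, n_reference = 510, seed = NULL) {
  mid <- (truth$freq_lake + truth$freq_stream) / 2
  with_seed(seed, {
    truth$freq_reference <- rbinom(nrow(truth), 2 * n_reference, mid) /
      (2 * n_reference)
  })
  truth
}

#' Simulate the released cohort and draw the survivors
#'
#' Draws `n_released` diploid individuals at Hardy-Weinberg expectations
#' from the reference frequencies, applies viability selection acting on
#' the planted loci only (or none, under `scheme = "neutral"`), and keeps
#' the genotypes of the `n_survivors` drawn via [draw_survivors()]. Because
#' loci are unlinked and fitness ignores background loci, background-locus
#' genotypes of the survivors are drawn directly at Hardy-Weinberg
#' expectations — the exact distribution of the drift through the
#' 37-fish bottleneck — without materialising the full release cohort at
#' every background site.
#'
#' @param truth Truth tibble with a `freq_reference` column (see
#'   [f2_reference_frequencies()]).
#' @param n_released Released individuals, default 3000.
#' @param n_survivors Recaptured survivors, default 37.
#' @param scheme `"neutral"` (survivors are a uniform random subset) or a
#'   [fitness_scheme()] applied to the planted loci.
#' @param seed Seed for reproducibility.
#' @return `n_survivors` x `nrow(truth)` dosage matrix of the focal allele
#'   (`allele_a`), with attribute `survivor_ids`.
#' @export
simulate_survivor_cohort <- function(truth, n_released = 3000, n_survivors = 37,
                                     scheme = "neutral", seed = NULL) {
  if (n_survivors > n_released) {
    abort("n_survivors cannot exceed n_released")
  }
  n_snp <- nrow(truth)
  planted_idx <- which(truth$planted)
  with_seed(seed, {
    if (identical(scheme, "neutral") || length(planted_idx) == 0) {
      g_surv_planted <- matrix(
        rbinom(n_survivors * length(planted_idx), 2L,
          rep(truth$freq_reference[planted_idx], each = n_survivors)
        ),
        nrow = n_survivors
      )
    } else {
      stopifnot(inherits(scheme, "fitness_scheme"))
      p_ref <- truth$freq_reference[planted_idx]
      g_rel <- matrix(
        rbinom(n_released * length(planted_idx), 2L, rep(p_ref, each = n_released)),
        nrow = n_released
      )
      pop <- structure(
        list(
          genotypes = g_rel, n = n_released, l = length(planted_idx),
          freq_init = colMeans(g_rel) / 2
        ),
        class = "sim_population"
      )
      w <- individual_fitness(pop, scheme)
      surv <- draw_survivors(pop, w, n_survivors = n_survivors)
      g_surv_planted <- g_rel[surv, , drop = FALSE]
    }
    # unlinked background loci: survivor genotypes are iid HWE draws at the
    # reference frequencies regardless of who survived
    g <- matrix(
      rbinom(n_survivors * n_snp, 2L,
        rep(truth$freq_reference, each = n_survivors)
      ),
      nrow = n_survivors
    )
    if (length(planted_idx) > 0) {
      g[, planted_idx] <- g_surv_planted
    }
    attr(g, "survivor_ids") <- sprintf("survivor%02d", seq_len(n_survivors))
    g
  })
}

#' Sample pooled sequencing counts from true allele frequencies
#'
#' Per site, the read depth is Poisson with the given mean and each read
#' reports the focal allele with probability equal to its true frequency;
#' a fraction `error_rate` of reads is redistributed uniformly to the
#' other three nucleotides (sequencing error).
#'
#' @param truth Truth tibble; the column named by `freq_column` supplies
#'   the focal-allele (`allele_a`) frequency.
#' @param mean_depth Mean read depth (210 for the natural pools, 127 for
#'   the reference pool).
#' @param error_rate Per-read error rate, default 0.001.
#' @param freq_column Which frequency column to sequence from.
#' @param seed Seed for reproducibility.
#' @return Count-table tibble (`chrom`, `pos`, `A`, `C`, `G`, `T`).
#' @export
sample_pooled_counts <- function(truth, mean_depth, error_rate = 0.001,
                                 freq_column = "freq_lake", seed = NULL) {
  assert_columns(truth, c("chrom", "pos", "allele_a", "allele_b", freq_column))
  stopifnot(mean_depth > 0)
  with_seed(seed, {
    depth <- rpois(nrow(truth), mean_depth)
    counts_from_reads(truth, depth, truth[[freq_column]], error_rate)
  })
}

#' Sample per-individual survivor sequencing counts
#'
#' Each survivor receives its own mean depth, drawn uniformly from
#' `depth_range` (published mean 3.1x, range 2.6-4.4x); per site the depth
#' is Poisson around that mean (zero-depth sites are expected and drive
#' the 35-of-37 coverage filter) and reads are drawn from the individual's
#' genotype frequency `dosage / 2` with the same error model as
#' [sample_pooled_counts()].
#'
#' @param genotypes Survivor dosage matrix from
#'   [simulate_survivor_cohort()].
#' @param truth Truth tibble (site coordinates and alleles).
#' @param depth_range Range of per-individual mean depths, default
#'   `c(2.6, 4.4)`.
#' @param error_rate Per-read error rate, default 0.001.
#' @param seed Seed for reproducibility.
#' @return Long-format count tibble with a `sample_id` column.
#' @export
sample_individual_counts <- function(genotypes, truth,
                                     depth_range = c(2.6, 4.4),
                                     error_rate = 0.001, seed = NULL) {
  n_ind <- nrow(genotypes)
  ids <- attr(genotypes, "survivor_ids") %||% sprintf("survivor%02d", seq_len(n_ind))
  with_seed(seed, {
    ind_mean <- runif(n_ind, depth_range[1], depth_range[2])
    purrr::map_dfr(seq_len(n_ind), function(i) {
      depth <- rpois(nrow(truth), ind_mean[i])
      tab <- counts_from_reads(truth, depth, genotypes[i, ] / 2, error_rate)
      tab$sample_id <- ids[i]
      tab
    })
  })
}

# Shared read-sampling core: depth reads per site, focal-allele probability
# f, then an error_rate fraction of reads lands uniformly on the other
# three nucleotides. Implemented as sequential binomial splits of the
# 4-nucleotide multinomial.
counts_from_reads <- function(truth, depth, f, error_rate) {
  n <- length(depth)
  e <- error_rate
  # per-nucleotide probabilities: focal a, partner b, two error nucleotides
  p_a <- f * (1 - e) + (1 - f) * (e / 3)
  p_b <- (1 - f) * (1 - e) + f * (e / 3)
  p_e <- e / 3 # each of the two remaining nucleotides

  x_a <- rbinom(n, depth, p_a)
  rest <- depth - x_a
  x_b <- rbinom(n, rest, ifelse(p_a < 1, p_b / (1 - p_a), 0))
  rest <- rest - x_b
  x_e1 <- rbinom(n, rest, ifelse(p_a + p_b < 1, p_e / (1 - p_a - p_b), 0))
  x_e2 <- rest - x_e1

  m <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, NUCLEOTIDES))
  ia <- match(truth$allele_a, NUCLEOTIDES)
  ib <- match(truth$allele_b, NUCLEOTIDES)
  # the two error nucleotides are the complement of {allele_a, allele_b}
  ie <- matrix(0L, nrow = n, ncol = 2)
  for (j in 1:4) {
    is_other <- ia != j & ib != j
    first_free <- is_other & ie[, 1] == 0
    ie[first_free, 1] <- j
    ie[is_other & !first_free, 2] <- j
  }
  rows <- seq_len(n)
  m[cbind(rows, ia)] <- x_a
  m[cbind(rows, ib)] <- x_b
  m[cbind(rows, ie[, 1])] <- x_e1
  m[cbind(rows, ie[, 2])] <- x_e2
  tibble(
    chrom = truth$chrom, pos = truth$pos,
    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"]
  )
}

#' Configuration of a synthetic study bundle
#'
#' Defaults emulate the published study design at a scale that runs in
#' minutes: a 5 x 2 Mb genome at one SNP per 440 bp (~22,700 SNPs), 126
#' planted divergent loci with AFD uniform in 0.477-0.934, natural pools
#' sequenced at 210x, an F2 reference of 510 fish at 127x, and 37
#' survivors out of 3000 released fish sequenced individually at means
#' uniform in 2.6-4.4x.
#'
#' @param n_chrom,chrom_length,mean_spacing Genome map parameters.
#' @param n_planted,planted_afd_range,planted_center Planted-locus model.
#' @param divergence Background divergence scale (`NULL` = tuned to median
#'   AFD 0.139).
#' @param depth_lake,depth_stream,depth_reference Mean pool depths.
#' @param survivor_depth_range Per-survivor mean depth range.
#' @param error_rate Sequencing error rate, default 0.001.
#' @param n_reference,n_released,n_survivors Sample sizes.
#' @param scheme `"neutral"` or a [fitness_scheme()] acting on the planted
#'   loci during the release year.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(n_chrom = 5, chrom_length = 2e6, mean_spacing = 440,
                         n_planted = 126, planted_afd_range = c(0.477, 0.934),
                         planted_center = 0.5, divergence = NULL,
                         depth_lake = 210, depth_stream = 210,
                         depth_reference = 127,
                         survivor_depth_range = c(2.6, 4.4),
                         error_rate = 0.001,
                         n_reference = 510, n_released = 3000,
                         n_survivors = 37, scheme = "neutral") {
  structure(
    list(
      n_chrom = n_chrom, chrom_length = chrom_length,
      mean_spacing = mean_spacing, n_planted = n_planted,
      planted_afd_range = planted_afd_range,
      planted_center = planted_center, divergence = divergence,
      depth_lake = depth_lake, depth_stream = depth_stream,
      depth_reference = depth_reference,
      survivor_depth_range = survivor_depth_range,
      error_rate = error_rate, n_reference = n_reference,
      n_released = n_released, n_survivors = n_survivors, scheme = scheme
    ),
    class = "study_config"
  )
}

#' Generate a complete synthetic study bundle
#'
#' Chains the generator stages: genome map, true lake/stream frequencies
#' with planted loci, F2 reference frequencies, survivor cohort (neutral or
#' selected), and sequencing count tables for all four samples. All
#' randomness derives from `seed` through [derive_seed()], so a bundle is
#' fully reproducible; the manifest records every parameter and child
#' seed. With `dir` set, the bundle is also written to disk as TSV count
#' tables plus a JSON truth manifest.
#'
#' @param config A [study_config()].
#' @param seed Master seed (required for a reproducible bundle).
#' @param dir Optional output directory.
#' @return Object of class `"synthetic_study"`: list with `map`, `truth`,
#'   `counts_lake`, `counts_stream`, `counts_reference`,
#'   `survivor_genotypes`, `counts_survivors` (long format), and
#'   `manifest`.
#' @export
generate_study_bundle <- function(config = study_config(), seed = 1, dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seeds <- list(
    map = derive_seed(seed, 1L), truth = derive_seed(seed, 2L),
    reference = derive_seed(seed, 3L), survivors = derive_seed(seed, 4L),
    seq_lake = derive_seed(seed, 5L), seq_stream = derive_seed(seed, 6L),
    seq_reference = derive_seed(seed, 7L), seq_survivors = derive_seed(seed, 8L)
  )
  map <- generate_genome_map(
    n_chrom = config$n_chrom, chrom_length = config$chrom_length,
    mean_spacing = config$mean_spacing, seed = seeds$map
  )
  truth <- draw_population_frequencies(
    map,
    divergence = config$divergence, n_planted = config$n_planted,
    planted_afd_range = config$planted_afd_range,
    planted_center = config$planted_center, seed = seeds$truth
  )
  truth <- f2_reference_frequencies(
    truth,
    n_reference = config$n_reference, seed = seeds$reference
  )
  genotypes <- simulate_survivor_cohort(
    truth,
    n_released = config$n_released, n_survivors = config$n_survivors,
    scheme = config$scheme, seed = seeds$survivors
  )
  bundle <- list(
    map = map,
    truth = truth,
    counts_lake = sample_pooled_counts(
      truth, config$depth_lake, config$error_rate, "freq_lake", seeds$seq_lake
    ),
    counts_stream = sample_pooled_counts(
      truth, config$depth_stream, config$error_rate, "freq_stream",
      seeds$seq_stream
    ),
    counts_reference = sample_pooled_counts(
      truth, config$depth_reference, config$error_rate, "freq_reference",
      seeds$seq_reference
    ),
    survivor_genotypes = genotypes,
    counts_survivors = sample_individual_counts(
      genotypes, truth,
      depth_range = config$survivor_depth_range,
      error_rate = config$error_rate, seed = seeds$seq_survivors
    ),
    manifest = list(
      config = unclass(config)[!vapply(unclass(config), is.function, TRUE)],
      master_seed = seed, seeds = seeds,
      scheme = if (inherits(config$scheme, "fitness_scheme")) {
        list(kind = config$scheme$kind, s = config$scheme$s)
      } else {
        "neutral"
      },
      planted = truth[truth$planted, c("chrom", "pos", "true_afd")]
    )
  )
  class(bundle) <- "synthetic_study"
  if (!is.null(dir)) {
    write_study_bundle(bundle, dir)
  }
  bundle
}

#' Write a synthetic study bundle to disk
#'
#' @param bundle A `"synthetic_study"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(bundle$counts_lake, file.path(dir, "lake.tsv"))
  write_count_table(bundle$counts_stream, file.path(dir, "stream.tsv"))
  write_count_table(bundle$counts_reference, file.path(dir, "reference.tsv"))
  write_count_table(bundle$counts_survivors, file.path(dir, "survivors.tsv"))
  manifest <- bundle$manifest
  manifest$config$scheme <- NULL
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  readr::write_tsv(
    bundle$truth, file.path(dir, "truth.tsv"),
    progress = FALSE
  )
  invisible(dir)
}
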