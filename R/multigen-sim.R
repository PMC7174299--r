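#' Configuration of the multi-generation simulation
#'
#' Constant-size forward simulation of polygenic fertility selection:
#' `k` hermaphroditic diploid individuals, `l_sel` unlinked selected loci,
#' `l_neu` unlinked neutral control loci (initial frequencies uniform on
#' `neutral_init` to ensure adequate information content), evolved for
#' `generations` generations in `replicates` replicate runs.
#'
#' @param k Constant population size, default 5000; must be even so that
#'   `k/2` matings with `offspring_per_mating = 2` reconstitute exactly `k`.
#' @param l_sel Selected loci, default 100.
#' @param l_neu Neutral loci, default 20.
#' @param scheme A [fitness_scheme()]; the published runs use
#'   multiplicative `s = 0.1` or additive `s = 0.01`.
#' @param generations Generations to evolve, default 500.
#' @param replicates Replicate simulations, default 40.
#' @param neutral_init Range of initial neutral-allele frequencies,
#'   default `c(0.2, 0.8)`.
#' @param offspring_per_mating Offspring produced per mating, default 2;
#'   `k` must be divisible by it.
#' @return Object of class `"multigen_config"`.
#' @export
multigen_config <- function(k = 5000, l_sel = 100, l_neu = 20,
                            scheme = fitness_scheme("multiplicative", 0.1),
                            generations = 500, replicates = 40,
                            neutral_init = c(0.2, 0.8),
                            offspring_per_mating = 2) {
  stopifnot(
    is_scalar_number(k), k >= 2,
    k %% offspring_per_mating == 0,
    inherits(scheme, "fitness_scheme"),
    is_scalar_number(generations), generations >= 1,
    is_scalar_number(replicates), replicates >= 1,
    length(neutral_init) == 2, neutral_init[1] < neutral_init[2]
  )
  if (k %% 2 != 0) {
    abort("k must be even (k/2 matings x 2 offspring reconstitute k)")
  }
  structure(
    list(
      k = k, l_sel = l_sel, l_neu = l_neu, scheme = scheme,
      generations = generations, replicates = replicates,
      neutral_init = neutral_init,
      offspring_per_mating = offspring_per_mating
    ),
    class = "multigen_config"
  )
}

#' Produce the next generation under fertility selection
#'
#' Each generation consists of `k / offspring_per_mating` matings. For each
#' mating, two parents are drawn independently with probability
#' proportional to fitness (with replacement across matings — individuals
#' are hermaphrodites and may be drawn repeatedly, including self-mating),
#' and each mating yields `offspring_per_mating` offspring. At every locus
#' an offspring receives one allele from each parent, chosen uniformly from
#' the parent's two alleles, independently across loci (unlinked Mendelian
#' transmission). Fitness is computed from the selected loci only and
#' negative additive fitness is clamped to zero before parent sampling.
#'
#' @param genotypes `k` x (`l_sel + l_neu`) dosage matrix.
#' @param scheme A [fitness_scheme()].
#' @param l_sel Number of leading columns under selection.
#' @param offspring_per_mating Offspring per mating, default 2.
#' @param seed Seed for reproducibility.
#' @return Dosage matrix of the next generation (exactly `k` rows).
#' @export
reproduce_generation <- function(genotypes, scheme, l_sel,
                                 offspring_per_mating = 2, seed = NULL) {
  k <- nrow(genotypes)
  l_tot <- ncol(genotypes)
  pop_sel <- structure(
    list(
      genotypes = genotypes[, seq_len(l_sel), drop = FALSE],
      n = k, l = l_sel
    ),
    class = "sim_population"
  )
  w <- individual_fitness(pop_sel, scheme)
  if (all(w == 0)) {
    abort("extinction: no individual with positive fitness",
      class = "polyshift_extinction"
    )
  }
  with_seed(seed, {
    m <- k %/% offspring_per_mating
    parent1 <- sample.int(k, m, replace = TRUE, prob = w)
    parent2 <- sample.int(k, m, replace = TRUE, prob = w)
    pa <- rep(parent1, times = offspring_per_mating)
    pb <- rep(parent2, times = offspring_per_mating)
    # transmission probability of the favorable allele is dosage / 2
    matrix(
      rbinom(k * l_tot, 1L, genotypes[pa, ] / 2) +
        rbinom(k * l_tot, 1L, genotypes[pb, ] / 2),
      nrow = k, ncol = l_tot
    )
  })
}

#' Run replicate multi-generation simulations
#'
#' Each replicate initialises selected loci from `freq_source` and neutral
#' loci from the configured uniform range (both at Hardy-Weinberg
#' expectations), then evolves the population with
#' [reproduce_generation()]. Per generation the median favorable-allele
#' frequency across selected loci and the grand median focal-allele
#' frequency across neutral loci are recorded; generation 0 rows hold the
#' initialised state, and the fraction of generation-0 individuals with
#' negative pre-clamp additive fitness is recorded per replicate.
#'
#' @param config A [multigen_config()].
#' @param freq_source Initial favorable-allele frequency spectrum, default
#'   [default_spectrum()].
#' @param seed Master seed; replicate `r` uses `derive_seed(seed, 50, r)`.
#' @return Object of class `"multigen_sim"`: a long tibble with columns
#'   `replicate`, `generation` (0-based), `median_selected`,
#'   `median_neutral`, `extinct`; attributes `config` and
#'   `neg_fitness_frac_gen0` (per-replicate vector).
#' @export
run_multigen <- function(config = multigen_config(),
                         freq_source = default_spectrum(), seed = NULL) {
  stopifnot(inherits(config, "multigen_config"))
  neg_frac <- numeric(config$replicates)
  rows <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, 50L, r)
    rows[[r]] <- with_seed(rep_seed, {
      g_sel <- init_population(
        n = config$k, l = config$l_sel, freq_source = freq_source
      )$genotypes
      p_neu <- runif(config$l_neu, config$neutral_init[1], config$neutral_init[2])
      g_neu <- matrix(
        rbinom(config$k * config$l_neu, 2L, rep(p_neu, each = config$k)),
        nrow = config$k
      )
      g <- cbind(g_sel, g_neu)

      # pre-clamp additive fitness sign at generation 0
      u0 <- rowSums(2 - g_sel)
      neg_frac[r] <- if (config$scheme$kind == "additive") {
        s0 <- config$scheme$s
        mean(1 - (if (length(s0) == 1) s0 * u0 else as.vector((2 - g_sel) %*% s0)) < 0)
      } else {
        0
      }

      med_sel <- numeric(config$generations + 1)
      med_neu <- numeric(config$generations + 1)
      extinct_at <- NA_integer_
      med_sel[1] <- median(colMeans(g_sel) / 2)
      med_neu[1] <- median(colMeans(g_neu) / 2)
      for (t in seq_len(config$generations)) {
        g <- tryCatch(
          reproduce_generation(
            g, config$scheme, config$l_sel,
            offspring_per_mating = config$offspring_per_mating
          ),
          polyshift_extinction = function(e) NULL
        )
        if (is.null(g)) {
          extinct_at <- t
          med_sel[(t + 1):(config$generations + 1)] <- NA_real_
          med_neu[(t + 1):(config$generations + 1)] <- NA_real_
          break
        }
        med_sel[t + 1] <- median(colMeans(g[, seq_len(config$l_sel), drop = FALSE]) / 2)
        med_neu[t + 1] <- median(colMeans(g[, -seq_len(config$l_sel), drop = FALSE]) / 2)
      }
      tibble(
        replicate = r,
        generation = 0:config$generations,
        median_selected = med_sel,
        median_neutral = med_neu,
        extinct = !is.na(extinct_at) & 0:config$generations >= extinct_at
      )
    })
  }
  out <- bind_rows(rows)
  class(out) <- c("multigen_sim", class(out))
  attr(out, "config") <- config
  attr(out, "neg_fitness_frac_gen0") <- neg_frac
  out
}

#' Per-generation envelope across replicates
#'
#' Summarises a [run_multigen()] result: per generation, the minimum,
#' median, and maximum across replicates of the selected-loci median
#' frequency (the full-range band), and the grand median neutral
#' frequency.
#'
#' @param sim A `"multigen_sim"` tibble.
#' @return Tibble with `generation`, `selected_min`, `selected_median`,
#'   `selected_max`, `neutral_median`.
#' @export
multigen_envelope <- function(sim) {
  sim |>
    filter(!.data$extinct) |>
    group_by(.data$generation) |>
    summarise(
      selected_min = min(.data$median_selected),
      selected_median = median(.data$median_selected),
      selected_max = max(.data$median_selected),
      neutral_median = median(.data$median_neutral),
      .groups = "drop"
    )
}

#' Deterministic per-locus frequency recursion under multiplicative fitness
#'
#' Analytic oracle for the simulators: in an infinite population at
#' Hardy-Weinberg proportions, one generation of multiplicative selection
#' with coefficient `s` moves the favorable-allele frequency from `p` to
#' `p / (p + (1 - p)(1 - s))`. Iterating `t` times gives the expected
#' drift-free trajectory.
#'
#' @param p0 Initial frequency in `(0, 1)`.
#' @param s Selection coefficient in `[0, 1)`.
#' @param t Number of generations (0 returns `p0`).
#' @param trajectory Return the whole length `t + 1` path instead of the
#'   final frequency.
#' @return Frequency after `t` generations, or the full path.
#' @export
#' @examples
#' deterministic_expected_frequency(0.5, 0.1, 1) # 0.5263...
deterministic_expected_frequency <- function(p0, s, t, trajectory = FALSE) {
  stopifnot(p0 > 0, p0 < 1, s >= 0, s < 1, t >= 0)
  path <- numeric(t + 1)
  path[1] <- p0
  p <- p0
  for (i in seq_len(t)) {
    p <- p / (p + (1 - p) * (1 - s))
    path[i + 1] <- p
  }
  if (trajectory) path else p
}
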