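#' Default favorable-allele frequency spectrum
#'
#' Stand-in for the empirical spectrum of stream-allele frequencies at the
#' target SNPs in the reference sample, used to initialise simulated loci
#' when no empirical frequencies are supplied: 126 deterministic quantiles
#' of a Beta(2.2, 1.9) distribution rescaled to `[0.25, 0.75]` (the support
#' implied by the MAF >= 0.25 ascertainment), with median 0.522 and mean
#' 0.518 — matching the published median reference frequency of 0.523.
#'
#' @param n Number of spectrum values, default 126.
#' @return Numeric vector of frequencies in `(0.25, 0.75)`.
#' @export
default_spectrum <- function(n = 126) {
  0.25 + 0.5 * qbeta(ppoints(n), 2.2, 1.9)
}

#' Multilocus fitness scheme
#'
#' Two mappings from the number of unfavored alleles `n` carried by an
#' individual to its fitness: multiplicative `(1 - s)^n` (each allele acts
#' independently of the genetic background; fitness stays positive for
#' `s < 1`) and additive `1 - s * n` (allelic effects combine on the
#' absolute scale; negative values are clamped to zero, which turns strong
#' additive selection into truncation selection). `s` may be a single
#' coefficient shared by all loci or a per-locus vector.
#'
#' @param kind `"multiplicative"` or `"additive"`.
#' @param s Selection coefficient(s); scalar or length-L vector, all >= 0,
#'   and < 1 for the multiplicative scheme.
#' @return Object of class `"fitness_scheme"`.
#' @export
fitness_scheme <- function(kind = c("multiplicative", "additive"), s) {
  kind <- match.arg(kind)
  if (!is.numeric(s) || length(s) < 1 || any(!is.finite(s)) || any(s < 0)) {
    abort("s must be finite and non-negative")
  }
  if (kind == "multiplicative" && any(s >= 1)) {
    abort("multiplicative selection requires s < 1")
  }
  structure(list(kind = kind, s = s), class = "fitness_scheme")
}

#' Initialise a diploid population under Hardy-Weinberg expectations
#'
#' Per-locus favorable-allele frequencies are sampled with replacement from
#' `freq_source`, and each individual's dosage at each locus is the sum of
#' two independent allele draws at that frequency.
#'
#' @param n Number of diploid individuals, default 1000.
#' @param l Number of unlinked biallelic codominant loci, default 100.
#' @param freq_source Frequencies to sample locus frequencies from; all must
#'   lie strictly inside `(0, 1)` (a monomorphic locus cannot respond to
#'   selection). Defaults to [default_spectrum()].
#' @param seed Seed for reproducibility.
#' @return Object of class `"sim_population"`: list with `genotypes`
#'   (`n` x `l` dosage matrix in `{0, 1, 2}`), `freq_drawn` (the sampled
#'   per-locus frequencies), `freq_init` (the realized pre-selection
#'   frequencies, i.e. column means / 2), `n`, `l`.
#' @export
init_population <- function(n = 1000, l = 100, freq_source = default_spectrum(),
                            seed = NULL) {
  if (length(freq_source) == 0) {
    abort("freq_source is empty")
  }
  if (any(freq_source <= 0 | freq_source >= 1)) {
    abort("freq_source must lie strictly within (0, 1)")
  }
  with_seed(seed, {
    p <- sample(freq_source, l, replace = TRUE)
    g <- matrix(
      rbinom(n * l, 2L, rep(p, each = n)),
      nrow = n, ncol = l
    )
    structure(
      list(
        genotypes = g, freq_drawn = p,
        freq_init = colMeans(g) / 2, n = n, l = l
      ),
      class = "sim_population"
    )
  })
}

#' Multilocus fitness of every individual
#'
#' With `u_il` the unfavorable dosage of individual `i` at locus `l`
#' (`2 - genotype`), multiplicative fitness is `prod_l (1 - s_l)^u_il` and
#' additive fitness is `max(0, 1 - sum_l s_l * u_il)`; with a scalar `s`
#' these reduce to `(1 - s)^n_i` and `max(0, 1 - s * n_i)` for the total
#' unfavored-allele count `n_i`.
#'
#' @param pop A `"sim_population"`.
#' @param scheme A [fitness_scheme()].
#' @return Length-`n` numeric vector of fitness values.
#' @export
individual_fitness <- function(pop, scheme) {
  stopifnot(inherits(pop, "sim_population"), inherits(scheme, "fitness_scheme"))
  s <- scheme$s
  if (length(s) != 1 && length(s) != pop$l) {
    abort("s must be scalar or one value per locus")
  }
  u <- 2 - pop$genotypes
  if (scheme$kind == "multiplicative") {
    if (length(s) == 1) {
      (1 - s)^rowSums(u)
    } else {
      exp(as.vector(u %*% log(1 - s)))
    }
  } else {
    load <- if (length(s) == 1) s * rowSums(u) else as.vector(u %*% s)
    pmax(0, 1 - load)
  }
}

#' Draw survivors with fitness-proportional probability
#'
#' Weighted sampling *without* replacement: survivors are selected as by
#' successive draws, each individual chosen with probability proportional
#' to its fitness among those not yet selected, until `n_survivors` are
#' drawn. Implemented via exponential races (`rexp(n) / fitness`, keep the
#' `n_survivors` smallest keys), which yields exactly the successive-draw
#' distribution in O(n log n). Individuals with zero fitness cannot
#' survive; if fewer than `n_survivors` individuals have positive fitness
#' the population cannot furnish the survivor cohort and an extinction
#' condition (class `"polyshift_extinction"`) is signalled.
#'
#' @param pop A `"sim_population"` (used for its size).
#' @param fitness Length-`n` non-negative fitness vector.
#' @param n_survivors Number of survivors to draw, default 40.
#' @param seed Seed for reproducibility.
#' @return Integer vector of survivor row indices.
#' @export
draw_survivors <- function(pop, fitness, n_survivors = 40, seed = NULL) {
  stopifnot(length(fitness) == pop$n, all(fitness >= 0))
  alive <- which(fitness > 0)
  if (length(alive) < n_survivors) {
    abort(
      sprintf(
        "extinction: only %d individuals with positive fitness, %d survivors required",
        length(alive), n_survivors
      ),
      class = "polyshift_extinction"
    )
  }
  with_seed(seed, {
    keys <- rexp(length(alive)) / fitness[alive]
    alive[order(keys)[seq_len(n_survivors)]]
  })
}

#' Simulate one generation of viability selection at locus resolution
#'
#' Initialises nothing: applies `scheme` to an existing population, draws
#' the survivor cohort, and reports per-locus frequencies before and after
#' selection. The pre-selection frequency is the *realized* frequency of
#' the population (not the drawn target), so the reported shift measures
#' selection and survivor sampling only.
#'
#' @inheritParams draw_survivors
#' @param scheme A [fitness_scheme()].
#' @return Tibble with columns `locus`, `freq_init`, `freq_survivors`,
#'   `shift`; attributes `truncated` (any zero-fitness individual present)
#'   and `survivors` (the drawn indices).
#' @export
simulate_one_generation <- function(pop, scheme, n_survivors = 40, seed = NULL) {
  w <- individual_fitness(pop, scheme)
  surv <- draw_survivors(pop, w, n_survivors = n_survivors, seed = seed)
  fs <- colMeans(pop$genotypes[surv, , drop = FALSE]) / 2
  out <- tibble(
    locus = seq_len(pop$l),
    freq_init = pop$freq_init,
    freq_survivors = fs,
    shift = fs - pop$freq_init
  )
  attr(out, "truncated") <- any(w == 0)
  attr(out, "survivors") <- surv
  out
}

#' Median allele-frequency shift of one selection replicate
#'
#' The median over loci of (survivor favorable-allele frequency minus
#' realized initial frequency), the replicate-level statistic summarised by
#' [run_selection_grid()].
#'
#' @inheritParams simulate_one_generation
#' @return Single numeric median shift, with attribute `truncated`.
#' @export
replicate_median_shift <- function(pop, scheme, n_survivors = 40, seed = NULL) {
  gen <- simulate_one_generation(pop, scheme, n_survivors = n_survivors, seed = seed)
  structure(median(gen$shift), truncated = attr(gen, "truncated"))
}

#' Selection-coefficient grid of single-generation replicates
#'
#' For every combination of fitness scheme and selection coefficient, runs
#' `replicates` independent single-generation simulations (each with a
#' freshly initialised population) and summarises the distribution of
#' replicate median shifts: its grand median, the 2.5 and 97.5 percentiles,
#' the fraction of replicates in which at least one individual had zero
#' fitness (truncation), and the fraction in which the survivor cohort
#' could not be drawn (extinction; such replicates are excluded from the
#' shift statistics).
#'
#' @param s_multiplicative,s_additive Selection-coefficient grids. The
#'   defaults span the published ranges: 0.0005-0.1 (multiplicative) and
#'   0.0005-0.012 (additive).
#' @param n,l Individuals and loci per replicate, defaults 1000 and 100
#'   (robustness variants: `n = 3000`, `l = 200`).
#' @param n_survivors Survivors drawn per replicate, default 40.
#' @param replicates Replicates per grid point, default 10000.
#' @param freq_source Initial-frequency spectrum, default
#'   [default_spectrum()].
#' @param s_distribution `"fixed"` (all loci share `s`) or `"exponential"`
#'   (per-locus coefficients drawn from an exponential distribution with
#'   rate `1/s`; multiplicative draws at or above 1 are redrawn).
#' @param seed Master seed. Each replicate draws its own RNG stream via
#'   [derive_seed()] with a stage code built from the scheme and `s`, so
#'   every grid point is reproducible independently of which other grid
#'   points are run.
#' @return Object of class `"selection_grid"`: a tibble with one row per
#'   `(scheme, s)`: `scheme`, `s`, `replicates`, `grand_median`, `q2.5`,
#'   `q97.5`, `truncation_fraction`, `extinction_fraction`.
#' @export
run_selection_grid <- function(s_multiplicative = c(
                                 0.0005, 0.001, 0.0025, 0.005, 0.01,
                                 0.02, 0.04, 0.06, 0.08, 0.1
                               ),
                               s_additive = c(0.0005, seq(0.001, 0.012, by = 0.001)),
                               n = 1000, l = 100, n_survivors = 40,
                               replicates = 10000,
                               freq_source = default_spectrum(),
                               s_distribution = c("fixed", "exponential"),
                               seed = NULL) {
  s_distribution <- match.arg(s_distribution)
  grid <- bind_rows(
    tibble(scheme = "multiplicative", s = s_multiplicative),
    tibble(scheme = "additive", s = s_additive)
  )
  rows <- purrr::pmap(
    list(grid$scheme, grid$s, seq_len(nrow(grid))),
    function(kind, s, i) {
      # stage code depends on (scheme, s) only, not on the grid layout
      stage <- round(s * 1e6) + if (kind == "additive") 1e7 else 2e7
      meds <- numeric(replicates)
      trunc <- logical(replicates)
      extinct <- logical(replicates)
      for (r in seq_len(replicates)) {
        rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, stage, r)
        res <- with_seed(rep_seed, {
          pop <- init_population(n = n, l = l, freq_source = freq_source)
          sch <- realize_scheme(kind, s, l, s_distribution)
          tryCatch(
            replicate_median_shift(pop, sch, n_survivors = n_survivors),
            polyshift_extinction = function(e) NA_real_
          )
        })
        if (is.na(res)) {
          extinct[r] <- TRUE
          meds[r] <- NA_real_
        } else {
          meds[r] <- as.numeric(res)
          trunc[r] <- isTRUE(attr(res, "truncated"))
        }
      }
      ok <- !extinct
      tibble(
        scheme = kind, s = s, replicates = replicates,
        grand_median = if (any(ok)) median(meds[ok]) else NA_real_,
        q2.5 = if (any(ok)) unname(quantile(meds[ok], 0.025)) else NA_real_,
        q97.5 = if (any(ok)) unname(quantile(meds[ok], 0.975)) else NA_real_,
        truncation_fraction = mean(trunc[ok]),
        extinction_fraction = mean(extinct)
      )
    }
  )
  out <- bind_rows(rows)
  class(out) <- c("selection_grid", class(out))
  out
}

# Materialise the per-replicate fitness scheme, drawing per-locus
# coefficients when an exponential distribution of effects is requested.
realize_scheme <- function(kind, s, l, s_distribution) {
  if (s_distribution == "fixed" || s == 0) {
    return(fitness_scheme(kind, s))
  }
  sv <- rexp(l, rate = 1 / s)
  if (kind == "multiplicative") {
    while (any(sv >= 1)) {
      sv[sv >= 1] <- rexp(sum(sv >= 1), rate = 1 / s)
    }
  }
  fitness_scheme(kind, sv)
}
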