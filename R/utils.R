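#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows n row_number across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median quantile rbinom rpois rexp rbeta runif qbeta
#'   pbinom rmultinom setNames ppoints
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")

# Lehmer / Park-Miller step; exact in double arithmetic (48271 * 2^31 < 2^53).
lcg_step <- function(x) {
  (48271 * (x %% 2147483647)) %% 2147483647
}

#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the package draws its own seed from a single
#' master seed through this documented derivation, so stages (and individual
#' replicates within a stage) can be re-run independently yet reproducibly.
#' The derivation walks a Park-Miller multiplicative congruential generator:
#' once on `master + stage`, once more on the result plus `index`.
#'
#' @param master Integer master seed.
#' @param stage Integer stage code (each pipeline stage uses a fixed code).
#' @param index Integer replicate/iteration index within the stage.
#' @return An integer seed in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, 3, 42)
derive_seed <- function(master, stage = 0L, index = 0L) {
  x <- lcg_step(abs(as.numeric(master)) + as.numeric(stage) + 1)
  x <- lcg_step(x + as.numeric(index))
  as.integer(x %% 2147483646) + 1L
}

# Run code with a locally set seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Encode (chrom, pos) as a single numeric so that |g1 - g2| > gap tests
# physical spacing: positions on different chromosomes differ by >= 1e10 bp,
# i.e. are always "far apart".
global_position <- function(chrom, pos) {
  as.numeric(factor(chrom)) * 1e10 + as.numeric(pos)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
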