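#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline geom_histogram geom_ribbon geom_segment labs theme_minimal
#'   facet_wrap scale_x_log10
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a resampled null distribution
#'
#' @param x A `"shift_null"` object.
#' @param ... Unused.
#' @return Tibble with one row per iteration: `iteration`, `median`,
#'   `mean`.
#' @export
tidy.shift_null <- function(x, ...) {
  tibble(
    iteration = seq_len(x$iterations),
    median = x$medians,
    mean = x$means
  )
}

#' One-row summary of a resampled null distribution
#'
#' @param x A `"shift_null"` object.
#' @param ... Unused.
#' @return One-row tibble: iterations, panel size, observed statistics and
#'   their empirical two-tailed probabilities (NA when no observed value
#'   was supplied).
#' @export
glance.shift_null <- function(x, ...) {
  tibble(
    iterations = x$iterations,
    n_snps = x$n_snps,
    panel_size = x$panel_size,
    observed_median = x$observed_median %||% NA_real_,
    observed_mean = x$observed_mean %||% NA_real_,
    p_two_tailed_median = x$p_two_tailed_median %||% NA_real_,
    p_two_tailed_mean = x$p_two_tailed_mean %||% NA_real_
  )
}

#' @export
tidy.sign_test <- function(x, ...) {
  tibble(
    n_positive = x$n_positive, n_negative = x$n_negative,
    n_zero = x$n_zero, n = x$n, p_two_tailed = x$p_two_tailed
  )
}

#' @export
glance.polyshift_report <- function(x, ...) {
  x$summary
}

#' Plot a resampled null shift distribution
#'
#' Histogram of the per-iteration median (or mean) neutral shifts with the
#' observed target-SNP statistic marked in red and the grand null median
#' in blue.
#'
#' @param object A `"shift_null"` object.
#' @param statistic `"median"` or `"mean"`.
#' @param bins Histogram bins, default 60.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_null <- function(object, statistic = c("median", "mean"),
                                bins = 60, ...) {
  statistic <- match.arg(statistic)
  df <- tidy(object)
  obs <- if (statistic == "median") object$observed_median else object$observed_mean
  p <- ggplot(df, aes(x = .data[[statistic]])) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    geom_vline(
      xintercept = median(df[[statistic]]),
      colour = "blue", linetype = "dashed"
    ) +
    labs(
      x = sprintf("%s stream-allele shift across resampled neutral SNPs", statistic),
      y = "iterations"
    ) +
    theme_minimal()
  if (!is.null(obs)) {
    p <- p + geom_vline(xintercept = obs, colour = "red", linetype = "dashed")
  }
  p
}

#' Plot a single-generation selection grid
#'
#' Grand median replicate shift against the selection coefficient (log
#' scale) per fitness scheme, with the 95-percentile band; an optional
#' horizontal reference line marks an empirically observed shift.
#'
#' @param object A `"selection_grid"` tibble.
#' @param observed_shift Optional reference shift to mark (e.g. 0.025).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_grid <- function(object, observed_shift = NULL, ...) {
  p <- ggplot(object, aes(x = .data$s, y = .data$grand_median)) +
    geom_ribbon(aes(ymin = .data$q2.5, ymax = .data$q97.5),
      fill = "steelblue", alpha = 0.3
    ) +
    geom_line(colour = "steelblue") +
    facet_wrap(~scheme, scales = "free_x") +
    scale_x_log10() +
    labs(
      x = "per-locus selection coefficient s",
      y = "median favorable-allele frequency shift"
    ) +
    theme_minimal()
  if (!is.null(observed_shift)) {
    p <- p + geom_hline(
      yintercept = observed_shift, colour = "red", linetype = "dashed"
    )
  }
  p
}

#' Plot multi-generation allele-frequency trajectories
#'
#' Replicate envelope (full range) of the selected-loci median frequency
#' per generation, with the grand median neutral-locus frequency as a
#' black line.
#'
#' @param object A `"multigen_sim"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multigen_sim <- function(object, ...) {
  env <- multigen_envelope(object)
  ggplot(env, aes(x = .data$generation)) +
    geom_ribbon(aes(ymin = .data$selected_min, ymax = .data$selected_max),
      fill = "steelblue", alpha = 0.3
    ) +
    geom_line(aes(y = .data$selected_median), colour = "steelblue") +
    geom_line(aes(y = .data$neutral_median), colour = "black") +
    labs(x = "generation", y = "median allele frequency") +
    theme_minimal()
}

#' Plot an AFD genome scan along one chromosome
#'
#' Per-SNP AFD values, the sliding-window mean profile, the chromosome
#' threshold, and the selected target SNPs.
#'
#' @param snps SNP tibble from [call_biallelic_snps()].
#' @param chrom Chromosome to plot.
#' @param scan Optional [afd_scan()] result supplying thresholds and
#'   targets.
#' @param window,step Sliding-window parameters, defaults 40 kb / 20 kb.
#' @return A ggplot object.
#' @export
plot_afd_scan <- function(snps, chrom, scan = NULL,
                          window = 40000, step = 20000) {
  sub <- filter(snps, .data$chrom == !!chrom)
  win <- smooth_afd_windows(sub, window = window, step = step)
  p <- ggplot(sub, aes(x = .data$pos, y = .data$afd)) +
    geom_point(colour = "grey70", size = 0.4) +
    geom_line(
      data = win, aes(x = .data$midpoint, y = .data$mean_afd),
      colour = "blue"
    ) +
    geom_hline(yintercept = median(sub$afd), colour = "black") +
    labs(x = sprintf("position on %s (bp)", chrom), y = "AFD") +
    theme_minimal()
  if (!is.null(scan)) {
    thr <- scan$thresholds$cutoff[scan$thresholds$chrom == chrom]
    if (length(thr) == 1) {
      p <- p + geom_hline(yintercept = thr, colour = "red", linetype = "dashed")
    }
    tg <- filter(scan$targets, .data$chrom == !!chrom)
    if (nrow(tg) > 0) {
      p <- p + geom_point(
        data = tg, aes(x = .data$pos, y = .data$afd),
        colour = "red", shape = 17, size = 2
      )
    }
  }
  p
}

#' Plot the distribution of target-SNP frequency shifts
#'
#' Histogram of per-target stream-allele shifts with the median marked.
#'
#' @param shifts Tibble from [compute_frequency_shifts()].
#' @param bins Histogram bins, default 30.
#' @return A ggplot object.
#' @export
plot_shift_distribution <- function(shifts, bins = 30) {
  ggplot(shifts, aes(x = .data$shift)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    geom_vline(
      xintercept = median(shifts$shift), colour = "red", linetype = "dashed"
    ) +
    labs(x = "stream-allele frequency shift (reference to survivors)",
         y = "target SNPs") +
    theme_minimal()
}
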