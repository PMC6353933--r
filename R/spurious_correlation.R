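# Spurious self-correlation: ratio-vs-denominator slopes under independence.

#' Monte-Carlo experiment on the null ratio slope
#'
#' When virus abundance is statistically independent of host abundance
#' (exponent alpha = 0), regressing `log10(virus/host)` on `log10(host)` is
#' equivalent to fitting `1/x` versus `x` on log axes and the expected slope
#' is -1 — spurious self-correlation of a ratio with its own denominator.
#' This experiment generates independent synthetic pairs under that null and
#' summarises the fitted ratio slopes across replicates.
#'
#' @param n_replicates number of independent pairs to generate (>= 1).
#' @param config a [synthetic_config()] with `alpha = 0` (anything else is a
#'   configuration error: this experiment is the null by definition).
#'   Zero-inflated sites are filtered out before fitting.
#' @param seed master seed for the experiment (defaults to `config$seed`).
#' @return A `spurious_slope_summary`: list with `n_replicates`, `n_sites`,
#'   `mean_beta_hat`, `sd_beta_hat`, `mean_alpha_hat`, `beta_hat` (the
#'   per-replicate slopes) and `config`.
#' @examples
#' cfg <- synthetic_config(alpha = 0, noise_sd = 0.5, zero_rate = 0, seed = 7)
#' null_ratio_slope_experiment(50, cfg)
#' @export
null_ratio_slope_experiment <- function(n_replicates, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!identical(as.numeric(config$alpha), 0))
    stop_config("null_ratio_slope_experiment() requires config$alpha = 0; ",
                "the -1 ratio slope is the independence null")
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop_config("n_replicates must be >= 1")
  if (is.null(seed)) seed <- config$seed
  betas <- vapply(seq_len(n_replicates), function(i) {
    d <- generate_pair(config, pair_id = sprintf("null%05d", i),
                       seed = derive_seed(seed, i))
    d <- filter_zero_sites(d)$dataset
    ratio_fit(d)$beta_hat
  }, numeric(1))
  structure(
    list(n_replicates = as.integer(n_replicates), n_sites = config$n_sites,
         mean_beta_hat = mean(betas), sd_beta_hat = stats::sd(betas),
         mean_alpha_hat = mean(betas) + 1, beta_hat = betas,
         config = config),
    class = "spurious_slope_summary"
  )
}

#' @export
print.spurious_slope_summary <- function(x, ...) {
  cat(sprintf(
    "<spurious_slope_summary> %d replicates of %d sites\n  mean beta_hat = %.4f (sd %.4f); mean alpha_hat = %.4f\n",
    x$n_replicates, x$n_sites, x$mean_beta_hat, x$sd_beta_hat,
    x$mean_alpha_hat))
  invisible(x)
}

#' Abundance and ratio scatter with the -1 guide line
#'
#' Two-panel scatter across a collection: log10 virus abundance versus log10
#' host abundance, and log10 virus-host ratio (VHR) versus log10 host
#' abundance with a slope -1 reference line. If virus and host abundances
#' are unrelated, the direct panel shows no trend while the ratio panel hugs
#' the -1 guide.
#'
#' @param datasets an `abundance_collection` or list of [abundance_pair()];
#'   pairs are zero-filtered before plotting.
#' @return A [ggplot2::ggplot] object, or `NULL` (with a warning) if nothing
#'   survives filtering.
#' @export
guide_line_overlay <- function(datasets) {
  pts <- lapply(datasets, function(d) {
    d <- filter_zero_sites(d)$dataset
    if (d$n_sites == 0L) return(NULL)
    lx <- log10(d$host_abundance)
    ly <- log10(d$virus_abundance)
    data.frame(pair_id = d$pair_id,
               log10_host = c(lx, lx),
               value = c(ly, ly - lx),
               panel = rep(c("log10 virus abundance", "log10 VHR"),
                           each = d$n_sites),
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L) {
    warning("no sites left after filtering; nothing to plot")
    return(invisible(NULL))
  }
  pts$panel <- factor(pts$panel,
                      levels = c("log10 virus abundance", "log10 VHR"))
  guide <- data.frame(panel = factor("log10 VHR",
                                     levels = levels(pts$panel)))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log10_host, y = .data$value,
                                    colour = .data$pair_id)) +
    ggplot2::geom_point(alpha = 0.6, show.legend = length(datasets) <= 12) +
    ggplot2::geom_abline(data = guide,
                         ggplot2::aes(slope = -1, intercept = 0),
                         linetype = "dashed", colour = "black") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "log10 host abundance", y = NULL, colour = "pair") +
    ggplot2::theme_bw()
}

#' Violin plots of permutation null slopes
#'
#' One violin per pair showing the permutation null distribution of the
#' statistic, with dark marks at the 2.5, 50 and 97.5 percentiles (the
#' randomized 95% CI) and the observed statistic as a red dashed line.
#' Pairs with `p < 0.05` are drawn in blue, others in gray.
#'
#' @param results a list of `permutation_result`.
#' @return A [ggplot2::ggplot] object, or `NULL` (with a warning) if
#'   `results` is empty.
#' @export
plot_null_violins <- function(results) {
  if (length(results) == 0L) {
    warning("no permutation results; nothing to plot")
    return(invisible(NULL))
  }
  nulls <- do.call(rbind, lapply(results, function(r)
    data.frame(pair = sprintf("%s (%d)", r$pair_id, r$n),
               value = r$null_values,
               significant = r$p_two_tailed < 0.05,
               stringsAsFactors = FALSE)))
  marks <- do.call(rbind, lapply(results, function(r)
    data.frame(pair = sprintf("%s (%d)", r$pair_id, r$n),
               observed = r$observed, ci_low = r$ci_low,
               ci_median = r$ci_median, ci_high = r$ci_high,
               stringsAsFactors = FALSE)))
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$pair, y = .data$value,
                                      fill = .data$significant)) +
    ggplot2::geom_violin(colour = NA, scale = "width") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "gray70", `TRUE` = "steelblue"),
      labels = c(`FALSE` = "p >= 0.05", `TRUE` = "p < 0.05"),
      name = NULL) +
    ggplot2::geom_segment(
      data = marks,
      ggplot2::aes(x = as.numeric(factor(.data$pair)) - 0.35,
                   xend = as.numeric(factor(.data$pair)) + 0.35,
                   y = .data$ci_low, yend = .data$ci_low),
      inherit.aes = FALSE, linewidth = 0.5) +
    ggplot2::geom_segment(
      data = marks,
      ggplot2::aes(x = as.numeric(factor(.data$pair)) - 0.35,
                   xend = as.numeric(factor(.data$pair)) + 0.35,
                   y = .data$ci_median, yend = .data$ci_median),
      inherit.aes = FALSE, linewidth = 0.5) +
    ggplot2::geom_segment(
      data = marks,
      ggplot2::aes(x = as.numeric(factor(.data$pair)) - 0.35,
                   xend = as.numeric(factor(.data$pair)) + 0.35,
                   y = .data$ci_high, yend = .data$ci_high),
      inherit.aes = FALSE, linewidth = 0.5) +
    ggplot2::geom_segment(
      data = marks,
      ggplot2::aes(x = as.numeric(factor(.data$pair)) - 0.45,
                   xend = as.numeric(factor(.data$pair)) + 0.45,
                   y = .data$observed, yend = .data$observed),
      inherit.aes = FALSE, colour = "red", linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "permutation null statistic") +
    ggplot2::theme_bw()
}
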