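# Log-log slope and correlation estimation for virus-host abundance pairs.

.statistic_kinds <- c("pm_slope", "pearson_r", "spearman_rho",
                      "theil_sen_slope")

# Shared validation: strictly positive abundances, n >= 2, log-host variance.
.check_fit_input <- function(dataset) {
  stopifnot(inherits(dataset, "abundance_pair"))
  if (dataset$n_sites < 2L)
    stop("pair '", dataset$pair_id, "': at least 2 sites are needed for a ",
         "slope", call. = FALSE)
  if (any(dataset$host_abundance <= 0) || any(dataset$virus_abundance <= 0))
    stop("pair '", dataset$pair_id, "': nonpositive abundances; apply ",
         "filter_zero_sites() before fitting", call. = FALSE)
  lx <- log10(dataset$host_abundance)
  if (stats::var(lx) == 0)
    stop("pair '", dataset$pair_id, "': degenerate fit, zero variance in ",
         "log host abundance", call. = FALSE)
  lx
}

.new_fit <- function(dataset, alpha_hat, intercept_hat, beta_hat, r, rho,
                     statistic_kind = "pm_slope") {
  structure(
    list(pair_id = dataset$pair_id, level = dataset$level,
         statistic_kind = statistic_kind, alpha_hat = alpha_hat,
         intercept_hat = intercept_hat, beta_hat = beta_hat,
         r = r, rho = rho, n = dataset$n_sites),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> %s [%s] n=%d  alpha=%.4f  beta=%.4f  r=%s  rho=%s\n",
    x$pair_id, x$level, x$n, x$alpha_hat, x$beta_hat,
    ifelse(is.na(x$r), "NA", sprintf("%.4f", x$r)),
    ifelse(is.na(x$rho), "NA", sprintf("%.4f", x$rho))))
  invisible(x)
}

#' Least-squares power-law fit of virus on host abundance
#'
#' Fits the line `log10(virus) = intercept + alpha * log10(host)` by ordinary
#' least squares; under the power-law model \eqn{y \sim x^\alpha} the slope
#' estimates the exponent. Also reports the product-moment correlation `r` of
#' the log10 values and the Spearman rank correlation `rho` (average ranks on
#' ties), which is invariant to the log transform.
#'
#' If the virus abundances are constant the least-squares solution is the
#' flat line, so `alpha_hat = 0` with `r` and `rho` returned as `NA`
#' (undefined rather than fabricated).
#'
#' @param dataset a strictly positive [abundance_pair()] with `n >= 2` sites
#'   and non-constant host abundance.
#' @return A `power_law_fit` with fields `alpha_hat`, `intercept_hat`,
#'   `beta_hat` (`= alpha_hat - 1`), `r`, `rho`, `n`.
#' @examples
#' loglog_fit(abundance_pair("p", c(1, 10, 100), c(2, 20, 200)))
#' @export
loglog_fit <- function(dataset) {
  lx <- .check_fit_input(dataset)
  ly <- log10(dataset$virus_abundance)
  cx <- lx - mean(lx)
  alpha <- sum(cx * ly) / sum(cx^2)
  intercept <- mean(ly) - alpha * mean(lx)
  if (stats::var(ly) == 0) {
    r <- NA_real_
    rho <- NA_real_
    alpha <- 0
    intercept <- mean(ly)
  } else {
    r <- stats::cor(lx, ly)
    rho <- stats::cor(lx, ly, method = "spearman")
  }
  .new_fit(dataset, alpha, intercept, alpha - 1, r, rho)
}

#' Least-squares fit of the virus-host ratio on host abundance
#'
#' Regresses `log10(virus/host)` on `log10(host)`. Under the power-law model
#' the ratio obeys \eqn{y/x \sim x^\beta} with \eqn{\beta = \alpha - 1}; when
#' virus and host abundances are unrelated the expected ratio slope is -1
#' (spurious self-correlation: the fit reduces to `1/x` versus `x`). The
#' slope here is computed from the actual ratio regression, so the identity
#' `beta_hat = loglog_fit(d)$alpha_hat - 1` holds only up to round-off and is
#' a meaningful numerical check.
#'
#' @inheritParams loglog_fit
#' @return A `power_law_fit` whose `beta_hat` is the fitted ratio slope and
#'   whose `alpha_hat` is `beta_hat + 1`; `r` and `rho` are the correlations
#'   of `log10(virus/host)` with `log10(host)`.
#' @examples
#' ratio_fit(abundance_pair("p", c(1, 10, 100), c(5, 5, 5)))  # beta = -1
#' @export
ratio_fit <- function(dataset) {
  lx <- .check_fit_input(dataset)
  lr <- log10(dataset$virus_abundance / dataset$host_abundance)
  cx <- lx - mean(lx)
  beta <- sum(cx * lr) / sum(cx^2)
  intercept <- mean(lr) - beta * mean(lx)
  if (stats::var(lr) == 0) {
    r <- NA_real_
    rho <- NA_real_
  } else {
    r <- stats::cor(lx, lr)
    rho <- stats::cor(lx, lr, method = "spearman")
  }
  .new_fit(dataset, beta + 1, intercept, beta, r, rho)
}

#' Theil-Sen nonparametric slope on log10 abundances
#'
#' Median of the pairwise slopes `(log10 y_j - log10 y_i) / (log10 x_j -
#' log10 x_i)` over all site pairs with distinct host abundance; a robust
#' nonparametric companion to the least-squares exponent.
#'
#' @inheritParams loglog_fit
#' @return The median pairwise slope (a single number).
#' @examples
#' # log-points (0,0), (1,1), (2,0): pairwise slopes 1, 0, -1 -> median 0
#' theil_sen_slope(abundance_pair("p", c(1, 10, 100), c(1, 10, 1)))
#' @export
theil_sen_slope <- function(dataset) {
  lx <- .check_fit_input(dataset)
  ly <- log10(dataset$virus_abundance)
  .theil_sen(lx, ly)
}

# Core Theil-Sen on already-logged coordinates; pairs with equal x skipped.
.theil_sen <- function(lx, ly) {
  dx <- outer(lx, lx, "-")
  dy <- outer(ly, ly, "-")
  keep <- upper.tri(dx) & dx != 0
  if (!any(keep))
    stop("degenerate fit: no site pairs with distinct host abundance",
         call. = FALSE)
  stats::median(dy[keep] / dx[keep])
}

# Fast statistic evaluation used by the permutation machinery. Takes
# pre-logged (or pre-ranked) vectors; returns a single number.
.compute_statistic <- function(lx, ly, kind) {
  switch(kind,
    pm_slope = {
      cx <- lx - mean(lx)
      sum(cx * ly) / sum(cx^2)
    },
    pearson_r = stats::cor(lx, ly),
    spearman_rho = stats::cor(lx, ly, method = "spearman"),
    theil_sen_slope = .theil_sen(lx, ly),
    stop_config("unknown statistic_kind: ", kind)
  )
}

#' Tabulate fits for a collection
#'
#' Runs [loglog_fit()], [ratio_fit()] and [theil_sen_slope()] on every pair.
#'
#' @param datasets an `abundance_collection` or list of [abundance_pair()].
#' @return A data frame with one row per pair: `pair_id`, `level`, `n`,
#'   `alpha_hat`, `intercept_hat`, `beta_hat`, `r`, `rho`, `theil_sen`.
#' @export
fit_collection <- function(datasets) {
  rows <- lapply(datasets, function(d) {
    f <- loglog_fit(d)
    b <- ratio_fit(d)
    data.frame(pair_id = f$pair_id, level = f$level, n = f$n,
               alpha_hat = f$alpha_hat, intercept_hat = f$intercept_hat,
               beta_hat = b$beta_hat, r = f$r, rho = f$rho,
               theil_sen = theil_sen_slope(d), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), level = character(), n = integer(),
               alpha_hat = numeric(), intercept_hat = numeric(),
               beta_hat = numeric(), r = numeric(), rho = numeric(),
               theil_sen = numeric())
  rownames(out) <- NULL
  out
}
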