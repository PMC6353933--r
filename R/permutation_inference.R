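# Permutation null distributions, two-tailed p-values, randomized CIs.

#' Two-tailed randomized permutation test for a virus-host pair
#'
#' Builds the permutation null for the chosen statistic by repeatedly
#' permuting the virus abundances without replacement while holding the host
#' abundances fixed, recomputing the statistic each time. The two-tailed
#' p-value uses the add-one convention
#' \deqn{p = (1 + \#\{|s_{null}| \ge |s_{obs}|\}) / (1 + n_{perm}),}
#' which avoids p = 0 from finite resampling. The 2.5/50/97.5 percentiles of
#' the null (the randomized 95% CI) are computed by linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' Each pair draws from its own RNG substream derived from `(seed, pair_id)`,
#' so adding or removing pairs does not shift other pairs' results.
#'
#' @param dataset a filtered, strictly positive [abundance_pair()].
#' @param statistic_kind one of `"pm_slope"` (least-squares log-log slope,
#'   the default), `"pearson_r"`, `"spearman_rho"`, `"theil_sen_slope"`.
#' @param n_perm number of random permutations (default 10000).
#' @param seed master integer seed.
#' @return A `permutation_result` with fields `pair_id`, `level`,
#'   `statistic_kind`, `observed`, `null_values` (length `n_perm`), `n_perm`,
#'   `p_two_tailed`, `ci_low`, `ci_median`, `ci_high`, `seed`.
#' @examples
#' d <- abundance_pair("p", c(1, 3, 10, 30, 100), c(2, 5, 4, 20, 15))
#' permutation_test(d, n_perm = 200, seed = 42)
#' @export
permutation_test <- function(dataset, statistic_kind = "pm_slope",
                             n_perm = 10000L, seed = 1L) {
  statistic_kind <- match.arg(statistic_kind, .statistic_kinds)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1)
    stop_config("n_perm must be a single integer >= 1")
  n_perm <- as.integer(n_perm)
  lx <- .check_fit_input(dataset)
  ly <- log10(dataset$virus_abundance)
  if (statistic_kind != "pm_slope" && stats::var(ly) == 0)
    stop("pair '", dataset$pair_id, "': degenerate statistic, zero variance ",
         "in log virus abundance", call. = FALSE)
  n <- dataset$n_sites

  observed <- .compute_statistic(lx, ly, statistic_kind)
  pair_seed <- derive_seed(seed, dataset$pair_id)
  null_values <- with_seed(pair_seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    .null_statistics(lx, ly, idx, statistic_kind)
  })
  .new_permutation_result(dataset, statistic_kind, observed, null_values,
                          n_perm, seed)
}

# Vectorised null evaluation over a matrix of permutation indices
# (n x n_perm). pm_slope and pearson_r share one crossprod because the
# marginal standard deviations are permutation-invariant; Spearman permutes
# the ranks (ranking commutes with permutation).
.null_statistics <- function(lx, ly, idx, statistic_kind) {
  n_perm <- ncol(idx)
  if (statistic_kind == "theil_sen_slope")
    return(vapply(seq_len(n_perm),
                  function(i) .theil_sen(lx, ly[idx[, i]]), numeric(1)))
  if (statistic_kind == "spearman_rho") {
    lx <- rank(lx)
    ly <- rank(ly)
  }
  cx <- lx - mean(lx)
  ssx <- sum(cx^2)
  perm <- matrix(ly[idx], nrow = length(ly))
  slopes <- as.vector(crossprod(perm, cx)) / ssx
  if (statistic_kind == "pm_slope") return(slopes)
  # correlation = slope * sd(x) / sd(y), both sds permutation-invariant
  slopes * sqrt(ssx / sum((ly - mean(ly))^2))
}

.new_permutation_result <- function(dataset, statistic_kind, observed,
                                    null_values, n_perm, seed) {
  # exceedance counted with a tiny relative slack so that permutations tied
  # with the observed statistic (e.g. the identity) are not lost to last-bit
  # rounding between the vectorised and scalar evaluation paths
  tol <- 1e-9 * max(1, abs(observed))
  p <- (1 + sum(abs(null_values) >= abs(observed) - tol)) / (1 + n_perm)
  ci <- stats::quantile(null_values, c(0.025, 0.5, 0.975), names = FALSE,
                        type = 7)
  structure(
    list(pair_id = dataset$pair_id, level = dataset$level,
         statistic_kind = statistic_kind, n = dataset$n_sites,
         observed = observed,
         null_values = null_values, n_perm = n_perm, p_two_tailed = p,
         ci_low = ci[1], ci_median = ci[2], ci_high = ci[3],
         seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s [%s] %s  obs=%.4f  p=%.4g  null 95%% CI [%.4f, %.4f]\n",
    x$pair_id, x$level, x$statistic_kind, x$observed, x$p_two_tailed,
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Exhaustive permutation null for small pairs
#'
#' Evaluates the statistic on all `n!` permutations of the virus vector
#' (host fixed); the brute-force oracle against which the Monte-Carlo
#' permutation test is validated. Limited to `n <= 8` (40320 permutations).
#'
#' @inheritParams permutation_test
#' @return A numeric vector of length `factorial(n)`.
#' @export
exhaustive_null <- function(dataset, statistic_kind = "pm_slope") {
  statistic_kind <- match.arg(statistic_kind, .statistic_kinds)
  lx <- .check_fit_input(dataset)
  ly <- log10(dataset$virus_abundance)
  n <- dataset$n_sites
  if (n > 8L)
    stop("exhaustive_null() is limited to n <= 8 sites (factorial growth); ",
         "got n = ", n, call. = FALSE)
  perms <- .all_permutations(n)
  vapply(seq_len(ncol(perms)),
         function(i) .compute_statistic(lx, ly[perms[, i]], statistic_kind),
         numeric(1))
}

# All permutations of 1..n as an n x n! integer matrix (lexicographic).
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .all_permutations(n - 1L)
  cols <- lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    rbind(rep(k, ncol(sub)), matrix(rest[sub], nrow = n - 1L))
  })
  do.call(cbind, cols)
}

#' Randomized percentile confidence interval of a permutation null
#'
#' @param result a `permutation_result` from [permutation_test()].
#' @param lower,upper percentile bounds in (0, 100), default 2.5 and 97.5.
#' @return A numeric vector `(lower, median, upper)` of the requested
#'   percentiles of the null distribution, by linear interpolation between
#'   order statistics.
#' @export
randomized_ci <- function(result, lower = 2.5, upper = 97.5) {
  stopifnot(inherits(result, "permutation_result"))
  if (!is.numeric(lower) || !is.numeric(upper) ||
      lower <= 0 || upper >= 100 || lower >= upper)
    stop_config("percentile bounds must satisfy 0 < lower < upper < 100")
  stats::quantile(result$null_values, c(lower, 50, upper) / 100,
                  names = FALSE, type = 7)
}

#' Permutation tests for a whole collection
#'
#' @param datasets an `abundance_collection` or list of [abundance_pair()].
#' @inheritParams permutation_test
#' @return A list of `permutation_result`, one per pair, named by `pair_id`.
#' @export
permute_collection <- function(datasets, statistic_kind = "pm_slope",
                               n_perm = 10000L, seed = 1L) {
  out <- lapply(datasets, permutation_test, statistic_kind = statistic_kind,
                n_perm = n_perm, seed = seed)
  names(out) <- vapply(out, `[[`, character(1), "pair_id")
  out
}

#' Flatten permutation results to a data frame
#'
#' @param results a list of `permutation_result`.
#' @return A data frame with one row per pair: `pair_id`, `level`,
#'   `statistic_kind`, `n`, `observed`, `p_two_tailed`, `ci_low`,
#'   `ci_median`, `ci_high`, `n_perm`, `seed`.
#' @export
permutation_table <- function(results) {
  rows <- lapply(results, function(r)
    data.frame(pair_id = r$pair_id, level = r$level,
               statistic_kind = r$statistic_kind, n = r$n,
               observed = r$observed, p_two_tailed = r$p_two_tailed,
               ci_low = r$ci_low, ci_median = r$ci_median,
               ci_high = r$ci_high, n_perm = r$n_perm, seed = r$seed,
               stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), level = character(),
               statistic_kind = character(), n = integer(),
               observed = numeric(), p_two_tailed = numeric(),
               ci_low = numeric(), ci_median = numeric(),
               ci_high = numeric(), n_perm = integer(), seed = integer())
  rownames(out) <- NULL
  out
}
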