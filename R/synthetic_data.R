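# Synthetic virus-host abundance collections with known power-law coupling.

#' Configuration for the synthetic abundance generator
#'
#' The generator draws site-level host log10-abundances from a normal
#' distribution (i.e. lognormal abundances, the standard null for abundance
#' data) and couples virus abundances as a power law with lognormal noise:
#' \deqn{h_i \sim N(\mu_h, \sigma_h), \quad x_i = 10^{h_i}, \quad
#'       y_i = 10^{\alpha h_i + c + e_i}, \quad e_i \sim N(0, \sigma_e).}
#' Each abundance is then independently zeroed with probability `zero_rate`
#' to emulate detection limits, so the zero-site filtering rule is exercised.
#'
#' @param alpha true power-law exponent (log10 virus vs log10 host slope);
#'   either a single value used for every pair or a length-2 range from which
#'   per-pair exponents are drawn uniformly.
#' @param intercept log10 offset `c` of the virus abundance.
#' @param n_sites sampling sites per pair (default 39, the typical number of
#'   distinct sites per pair in marine metagenome surveys of this design).
#' @param host_log_mean,host_log_sd mean and sd of host log10-abundance;
#'   defaults (-3, 1) span relative abundances around 1e-3.
#' @param noise_sd sd of the lognormal noise on virus abundance (log10
#'   scale), `>= 0`.
#' @param zero_rate per-site probability, in `[0, 1)`, that each of the host
#'   and virus abundances is independently set to 0.
#' @param n_pairs number of virus-host pairs in a generated collection
#'   (default 64, the family size of the motivating comparison set).
#' @param level taxonomic level label attached to generated pairs.
#' @param seed master integer seed; per-pair substreams are derived from it
#'   so collections are reproducible under reordering.
#' @return A `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(alpha = 0.5, noise_sd = 0.2, seed = 1)
#' generate_pair(cfg, "pairA")
#' @export
synthetic_config <- function(alpha = 0, intercept = 0, n_sites = 39L,
                             host_log_mean = -3, host_log_sd = 1,
                             noise_sd = 0.5, zero_rate = 0.1,
                             n_pairs = 64L, level = "genus", seed = 1L) {
  if (!is.numeric(alpha) || !length(alpha) %in% 1:2 || anyNA(alpha))
    stop_config("alpha must be a single exponent or a length-2 range")
  if (length(alpha) == 2L && alpha[1] > alpha[2])
    stop_config("alpha range must be nondecreasing")
  if (!is.numeric(n_sites) || n_sites < 1)
    stop_config("n_sites must be >= 1")
  if (!is.numeric(host_log_sd) || host_log_sd <= 0)
    stop_config("host_log_sd must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be >= 0")
  if (!is.numeric(zero_rate) || zero_rate < 0 || zero_rate >= 1)
    stop_config("zero_rate must lie in [0, 1)")
  if (!is.numeric(n_pairs) || n_pairs < 1)
    stop_config("n_pairs must be >= 1")
  level <- match.arg(level, .levels)
  structure(
    list(alpha = as.numeric(alpha), intercept = as.numeric(intercept),
         n_sites = as.integer(n_sites),
         host_log_mean = as.numeric(host_log_mean),
         host_log_sd = as.numeric(host_log_sd),
         noise_sd = as.numeric(noise_sd), zero_rate = as.numeric(zero_rate),
         n_pairs = as.integer(n_pairs), level = level,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Draw one pair given a scalar alpha and an already-derived seed.
.generate_pair_core <- function(config, pair_id, alpha, seed) {
  with_seed(seed, {
    h <- stats::rnorm(config$n_sites, config$host_log_mean, config$host_log_sd)
    e <- if (config$noise_sd > 0)
      stats::rnorm(config$n_sites, 0, config$noise_sd) else
      numeric(config$n_sites)
    host <- 10^h
    virus <- 10^(alpha * h + config$intercept + e)
    if (config$zero_rate > 0) {
      host[stats::runif(config$n_sites) < config$zero_rate] <- 0
      virus[stats::runif(config$n_sites) < config$zero_rate] <- 0
    }
    abundance_pair(pair_id, host, virus, level = config$level)
  })
}

#' Generate one synthetic virus-host pair
#'
#' @param config a [synthetic_config()]; if `alpha` is a range its lower
#'   bound is used (ranges are resolved per pair by [generate_collection()]).
#' @param pair_id label for the generated pair.
#' @param seed optional seed override; by default a substream is derived from
#'   `config$seed` and `pair_id`, so the same (config, pair_id) always yields
#'   the same data.
#' @return An [abundance_pair()] with `config$n_sites` sites (before any
#'   zero-site filtering).
#' @export
generate_pair <- function(config, pair_id = "pair1", seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- derive_seed(config$seed, pair_id)
  .generate_pair_core(config, pair_id, config$alpha[1], seed)
}

#' Generate a synthetic collection with a ground-truth table
#'
#' Generates `config$n_pairs` pairs. If `config$alpha` is a single value all
#' pairs share it; if it is a range, each pair's exponent is drawn uniformly
#' from the range (on its own substream) and recorded in the truth table.
#'
#' @param config a [synthetic_config()].
#' @return A list with `datasets` (an `abundance_collection`) and `truth`, a
#'   data frame with columns `pair_id`, `alpha`, `beta` where
#'   `beta = alpha - 1` exactly.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- sprintf("pair%03d", seq_len(config$n_pairs))
  alphas <- if (length(config$alpha) == 1L)
    rep(config$alpha, config$n_pairs)
  else
    vapply(seq_len(config$n_pairs), function(i)
      with_seed(derive_seed(config$seed, paste0("alpha:", ids[i])),
                stats::runif(1, config$alpha[1], config$alpha[2])),
      numeric(1))
  datasets <- lapply(seq_len(config$n_pairs), function(i)
    .generate_pair_core(config, ids[i], alphas[i],
                        derive_seed(config$seed, ids[i])))
  names(datasets) <- ids
  truth <- data.frame(pair_id = ids, alpha = alphas, beta = alphas - 1,
                      stringsAsFactors = FALSE)
  list(datasets = structure(datasets, class = "abundance_collection"),
       truth = truth)
}
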