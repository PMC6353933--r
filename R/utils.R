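# Internal helpers: deterministic seed substreams and scoped RNG use.

#' Derive a deterministic 31-bit substream seed
#'
#' Combines a master seed with a key (pair id or pair index) so that each
#' virus-host pair gets its own reproducible RNG stream: adding or removing
#' pairs never shifts another pair's draws.
#'
#' @param master integer master seed.
#' @param key character label or integer index identifying the substream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  codes <- if (is.character(key)) utf8ToInt(key) else as.integer(key)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  # keep every intermediate below 2^53 so double arithmetic is exact
  as.integer((abs(master) %% 2147483647 + h * 2 + 1) %% 2147483647)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Format doubles so a write/read round-trip is exact to the last bit.
format_full <- function(x) sprintf("%.17g", x)

stop_config <- function(...) stop(..., call. = FALSE)
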