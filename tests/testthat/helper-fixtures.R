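# Shared fixture builders for the test suite.

# A pair with lognormal host abundances and power-law-coupled virus
# abundances, built directly (independent of the package generator).
make_random_pair <- function(n = 10, alpha = 0.5, noise_sd = 0.3,
                             pair_id = "fix", level = "genus") {
  h <- rnorm(n, -3, 1)
  e <- rnorm(n, 0, noise_sd)
  abundance_pair(pair_id, 10^h, 10^(alpha * h + e), level = level)
}

# Write a long-format abundance table + manifest for a list of pairs given
# as plain data; returns the two paths.
write_fixture_tables <- function(pairs, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixtab")
    dir.create(dir)
  }
  rows <- do.call(rbind, lapply(pairs, function(p)
    data.frame(pair_id = p$pair_id, site_id = p$site_ids,
               host_abundance = sprintf("%.17g", p$host_abundance),
               virus_abundance = sprintf("%.17g", p$virus_abundance))))
  man <- data.frame(
    pair_id = vapply(pairs, `[[`, character(1), "pair_id"),
    level = vapply(pairs, `[[`, character(1), "level"),
    host_name = "h", virus_name = "v")
  table_path <- file.path(dir, "abundance.tsv")
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(rows, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(man, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(table = table_path, manifest = manifest_path)
}

# Exhaustive two-tailed permutation p-value from a full null vector.
exact_two_tailed_p <- function(null_values, observed) {
  mean(abs(null_values) >= abs(observed))
}
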