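# End-to-end study pipeline: filter -> fit -> permute -> correct -> plot.

#' Assemble a pipeline configuration
#'
#' Either `table` + `manifest` (paths to the long-format TSV inputs) or
#' `synthetic` (a [synthetic_config()]) must be given.
#'
#' @param table,manifest input TSV paths (see [read_abundance_table()]), or
#'   `NULL` to run on synthetic data.
#' @param synthetic a [synthetic_config()], or `NULL` to read from files.
#' @param min_sites minimum positive-site count per pair (default 5).
#' @param n_perm permutations per pair (default 10000).
#' @param statistic_kind permutation statistic, default `"pm_slope"`.
#' @param family_alpha family-wise rate for Bonferroni (default 0.05).
#' @param significance_levels nominal levels to flag, default
#'   `c(0.05, 0.01)`.
#' @param seed master seed for permutations (and generation when synthetic).
#' @param out_dir output directory; created if absent.
#' @param make_plots write figure files (default `TRUE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(table = NULL, manifest = NULL, synthetic = NULL,
                            min_sites = 5L, n_perm = 10000L,
                            statistic_kind = "pm_slope",
                            family_alpha = 0.05,
                            significance_levels = c(0.05, 0.01),
                            seed = 1L, out_dir = tempfile("vhratio_study_"),
                            make_plots = TRUE) {
  if (is.null(synthetic) && (is.null(table) || is.null(manifest)))
    stop_config("either synthetic data or both table and manifest paths ",
                "are required")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!is.numeric(n_perm) || n_perm < 1) stop_config("n_perm must be >= 1")
  statistic_kind <- match.arg(statistic_kind, .statistic_kinds)
  structure(
    list(table = table, manifest = manifest, synthetic = synthetic,
         min_sites = as.integer(min_sites), n_perm = as.integer(n_perm),
         statistic_kind = statistic_kind, family_alpha = family_alpha,
         significance_levels = significance_levels, seed = as.integer(seed),
         out_dir = out_dir, make_plots = isTRUE(make_plots)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; a `synthetic:` mapping is passed to
#'   [synthetic_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  do.call(pipeline_config, raw)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_full)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full virus-host abundance study
#'
#' Filters the input collection (zero sites, minimum-site rule), fits
#' log-log and ratio slopes per pair, runs the two-tailed permutation test,
#' tallies significance with Bonferroni correction pooled over all tested
#' pairs, and writes tabular and graphical artifacts plus a run manifest
#' (seed, permutations, package version, input checksums).
#'
#' Pairs that survive filtering but are degenerate for the chosen statistic
#' (for instance constant virus abundance under a correlation statistic)
#' appear in the report with status `"untested"` rather than being dropped,
#' so `n_tested` is auditable against the input pair count.
#'
#' @param config a `pipeline_config` (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with `report` (the `study_report`), `fits`,
#'   `filter_reports`, `results` and `out_dir`. On an empty input the
#'   report is empty and a warning is raised.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  checksums <- NULL
  if (!is.null(config$synthetic)) {
    datasets <- generate_collection(config$synthetic)$datasets
  } else {
    datasets <- read_abundance_table(config$table, config$manifest)
    checksums <- tools::md5sum(c(config$table, config$manifest))
  }

  filt <- filter_collection(datasets, min_sites = config$min_sites)
  .write_tsv(filt$reports, file.path(config$out_dir, "filter_report.tsv"))
  if (length(filt$datasets) == 0L) {
    warning("no virus-host pairs retained after filtering; empty report")
    empty <- tally_significance(list(),
                                levels = config$significance_levels,
                                family_alpha = config$family_alpha)
    .write_tsv(empty$per_pair, file.path(config$out_dir, "study_report.tsv"))
    return(invisible(list(report = empty, fits = fit_collection(list()),
                          filter_reports = filt$reports, results = list(),
                          out_dir = config$out_dir)))
  }

  # statistic-degenerate pairs are reported as untested, not dropped
  testable <- vapply(filt$datasets, function(d)
    stats::var(log10(d$virus_abundance)) > 0 &&
      stats::var(log10(d$host_abundance)) > 0, logical(1))
  status <- ifelse(testable, "tested", "untested")

  fits <- fit_collection(filt$datasets[testable])
  results <- permute_collection(filt$datasets[testable],
                                statistic_kind = config$statistic_kind,
                                n_perm = config$n_perm, seed = config$seed)
  report <- tally_significance(results,
                               levels = config$significance_levels,
                               family_alpha = config$family_alpha,
                               fits = fits)

  per_pair <- report$per_pair
  if (any(!testable)) {
    skipped <- data.frame(
      pair_id = vapply(filt$datasets[!testable], `[[`, character(1),
                       "pair_id"),
      level = vapply(filt$datasets[!testable], `[[`, character(1), "level"),
      stringsAsFactors = FALSE)
    for (cn in setdiff(names(per_pair), names(skipped)))
      skipped[[cn]] <- NA
    per_pair <- rbind(per_pair, skipped[names(per_pair)])
  }
  per_pair$status <- c(status[testable], status[!testable])

  .write_tsv(fits, file.path(config$out_dir, "fits.tsv"))
  .write_tsv(per_pair, file.path(config$out_dir, "study_report.tsv"))
  .write_tsv(report$counts, file.path(config$out_dir, "summary.tsv"))
  .write_tsv(permutation_table(results),
             file.path(config$out_dir, "permutation_results.tsv"))

  if (config$make_plots) {
    p1 <- guide_line_overlay(filt$datasets)
    if (!is.null(p1))
      ggplot2::ggsave(file.path(config$out_dir, "fig_abundance.png"), p1,
                      width = 8, height = 4, dpi = 150)
    p2 <- plot_null_violins(results)
    if (!is.null(p2))
      ggplot2::ggsave(file.path(config$out_dir, "fig_null_violins.png"), p2,
                      width = 7, height = max(3, 0.35 * length(results)),
                      dpi = 150, limitsize = FALSE)
  }

  manifest <- list(
    package = "vhratio",
    version = as.character(utils::packageVersion("vhratio")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed, n_perm = config$n_perm,
    statistic_kind = config$statistic_kind,
    min_sites = config$min_sites, family_alpha = config$family_alpha,
    n_pairs_input = length(datasets),
    n_pairs_tested = sum(testable),
    input_md5 = as.list(checksums)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yaml"))

  invisible(list(report = report, fits = fits,
                 filter_reports = filt$reports, results = results,
                 out_dir = config$out_dir, per_pair = per_pair))
}
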