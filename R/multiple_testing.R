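# Family-wise correction and significance tallies across virus-host pairs.

#' Bonferroni significance threshold
#'
#' @param family_alpha family-wise error rate, in (0, 1); default 0.05.
#' @param m number of comparisons in the family (all tested pairs pooled
#'   across taxonomic levels).
#' @return `family_alpha / m`. For display, round to 2 significant figures
#'   with [display_threshold()]: 0.05 / 64 prints as `"0.00078"`.
#' @examples
#' bonferroni_threshold(0.05, 64)  # 0.00078125
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop_config("m must be a single integer >= 1")
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1)
    stop_config("family_alpha must lie in (0, 1)")
  family_alpha / m
}

#' Format a significance threshold for display
#'
#' @param x a threshold (e.g. from [bonferroni_threshold()]).
#' @return The value rounded to 2 significant figures, as fixed-notation
#'   character.
#' @export
display_threshold <- function(x) formatC(signif(x, 2), format = "fg")

#' Tally significance across all tested pairs
#'
#' Flags each pair at the requested nominal levels (strict inequality
#' `p < level`) and at the Bonferroni threshold computed over the pooled
#' family of all tested pairs (genus + phylum together, the default) or per
#' taxonomic level.
#'
#' @param results a list of `permutation_result` (see [permutation_test()]),
#'   one per pair; `pair_id`s must be unique.
#' @param levels nominal significance levels to flag, default `c(0.05, 0.01)`.
#' @param family_alpha family-wise rate for the Bonferroni criterion.
#' @param per_level_correction if `TRUE`, compute a separate Bonferroni
#'   threshold within each taxonomic level instead of pooling (off by
#'   default).
#' @param fits optional data frame from [fit_collection()]; if supplied,
#'   `alpha_hat`/`beta_hat` are taken from it, otherwise they are derived
#'   from the observed statistic when it is the log-log slope.
#' @return A `study_report`: list with `per_pair` (data frame of per-pair
#'   estimates, p-values, CI and significance flags), `m_comparisons`,
#'   `bonferroni_threshold`, `counts` (per-level tallies), `family_alpha`,
#'   `levels`.
#' @export
tally_significance <- function(results, levels = c(0.05, 0.01),
                               family_alpha = 0.05,
                               per_level_correction = FALSE, fits = NULL) {
  tab <- permutation_table(results)
  if (anyDuplicated(tab$pair_id))
    stop("duplicate pair_id in results: ",
         paste(unique(tab$pair_id[duplicated(tab$pair_id)]), collapse = ", "),
         call. = FALSE)
  m <- nrow(tab)
  bf <- if (m > 0) bonferroni_threshold(family_alpha, m) else NA_real_

  if (!is.null(fits)) {
    i <- match(tab$pair_id, fits$pair_id)
    tab$alpha_hat <- fits$alpha_hat[i]
    tab$beta_hat <- fits$beta_hat[i]
  } else {
    tab$alpha_hat <- ifelse(tab$statistic_kind == "pm_slope", tab$observed,
                            NA_real_)
    tab$beta_hat <- tab$alpha_hat - 1
  }

  levels <- sort(unique(levels), decreasing = TRUE)
  for (l in levels) {
    col <- paste0("significant_", sub("^0\\.", "", format(l)))
    tab[[col]] <- tab$p_two_tailed < l
  }
  if (per_level_correction && m > 0) {
    tab$significant_bonferroni <- FALSE
    for (lv in unique(tab$level)) {
      sel <- tab$level == lv
      tab$significant_bonferroni[sel] <-
        tab$p_two_tailed[sel] < bonferroni_threshold(family_alpha, sum(sel))
    }
  } else {
    tab$significant_bonferroni <- tab$p_two_tailed < bf
  }

  counts <- do.call(rbind, lapply(.levels, function(lv) {
    sel <- tab$level == lv
    data.frame(
      level = lv, n_tested = sum(sel),
      n_significant_05 = sum(sel & tab$p_two_tailed < 0.05),
      n_significant_01 = sum(sel & tab$p_two_tailed < 0.01),
      n_significant_bonferroni = sum(sel & tab$significant_bonferroni),
      bonferroni_threshold = bf, stringsAsFactors = FALSE
    )
  }))
  rownames(counts) <- NULL

  structure(
    list(per_pair = tab, m_comparisons = m, bonferroni_threshold = bf,
         counts = counts, family_alpha = family_alpha, levels = levels),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d comparisons, Bonferroni threshold %s\n",
    x$m_comparisons,
    ifelse(is.na(x$bonferroni_threshold), "NA",
           display_threshold(x$bonferroni_threshold))))
  print(x$counts)
  invisible(x)
}
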