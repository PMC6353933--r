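# Reading, validating, filtering and partitioning virus-host abundance tables.

.levels <- c("genus", "phylum")

#' Construct a virus-host abundance pair dataset
#'
#' One putative virus-host pair observed across sampling sites: a host
#' abundance and a virus abundance (relative-abundance proxies, nonnegative)
#' per site.
#'
#' @param pair_id character label for the pair (e.g. the host genus name).
#' @param host_abundance,virus_abundance nonnegative numeric vectors of equal
#'   length, one entry per site.
#' @param level taxonomic level of the pairing, `"genus"` or `"phylum"`.
#' @param site_ids optional character site labels (unique); defaults to
#'   `s1, s2, ...`.
#' @return An object of class `abundance_pair` with fields `pair_id`, `level`,
#'   `site_ids`, `host_abundance`, `virus_abundance`, `n_sites`.
#' @examples
#' abundance_pair("Synechococcus", c(1, 10, 100), c(2, 20, 200))
#' @export
abundance_pair <- function(pair_id, host_abundance, virus_abundance,
                           level = "genus", site_ids = NULL) {
  stopifnot(is.character(pair_id), length(pair_id) == 1L)
  level <- match.arg(level, .levels)
  host_abundance <- as.numeric(host_abundance)
  virus_abundance <- as.numeric(virus_abundance)
  if (length(host_abundance) != length(virus_abundance))
    stop("host and virus abundance vectors must have equal length for pair '",
         pair_id, "'", call. = FALSE)
  if (anyNA(host_abundance) || anyNA(virus_abundance))
    stop("missing abundance values in pair '", pair_id, "'", call. = FALSE)
  if (any(host_abundance < 0) || any(virus_abundance < 0))
    stop("negative abundance values in pair '", pair_id, "'", call. = FALSE)
  if (is.null(site_ids)) site_ids <- paste0("s", seq_along(host_abundance))
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids))
    stop("duplicate site_ids in pair '", pair_id, "'", call. = FALSE)
  structure(
    list(pair_id = pair_id, level = level, site_ids = site_ids,
         host_abundance = host_abundance, virus_abundance = virus_abundance,
         n_sites = length(host_abundance)),
    class = "abundance_pair"
  )
}

#' @export
print.abundance_pair <- function(x, ...) {
  cat(sprintf("<abundance_pair> %s [%s], %d sites\n",
              x$pair_id, x$level, x$n_sites))
  invisible(x)
}

#' Read a long-format virus-host abundance table
#'
#' Reads a tab-separated abundance table (one row per pair x site) and a pairs
#' manifest mapping each `pair_id` to its taxonomic level, and assembles one
#' [abundance_pair()] per pair. The expected dialect is TSV with a header,
#' UTF-8, `.` decimal separator.
#'
#' @param path path to the abundance TSV with columns `pair_id`, `site_id`,
#'   `host_abundance`, `virus_abundance`.
#' @param manifest path to the manifest TSV with columns `pair_id`, `level`
#'   (and optionally `host_name`, `virus_name`).
#' @return A named list of `abundance_pair` objects (class
#'   `abundance_collection`), one per `pair_id`, in first-appearance order.
#'   An empty table yields an empty collection.
#' @export
read_abundance_table <- function(path, manifest) {
  for (p in c(path, manifest))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  man <- utils::read.delim(manifest, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("pair_id", "site_id", "host_abundance", "virus_abundance")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("abundance table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(c("pair_id", "level"), names(man))
  if (length(miss))
    stop("manifest is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(man$level), .levels)
  if (length(bad))
    stop("unknown level label(s) in manifest: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(man$pair_id))
    stop("duplicate pair_id in manifest", call. = FALSE)
  if (nrow(tab) == 0L)
    return(structure(list(), class = "abundance_collection"))

  for (col in c("host_abundance", "virus_abundance")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("non-numeric ", col, " at row ",
           which(is.na(v))[1L], call. = FALSE)
    if (any(v < 0))
      stop("negative ", col, " at row ", which(v < 0)[1L], call. = FALSE)
    tab[[col]] <- v
  }
  unknown <- setdiff(unique(tab$pair_id), man$pair_id)
  if (length(unknown))
    stop("pair(s) absent from manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  lev <- stats::setNames(man$level, man$pair_id)
  ids <- unique(tab$pair_id)
  out <- lapply(ids, function(id) {
    rows <- tab[tab$pair_id == id, , drop = FALSE]
    abundance_pair(id, rows$host_abundance, rows$virus_abundance,
                   level = lev[[id]], site_ids = rows$site_id)
  })
  names(out) <- ids
  structure(out, class = "abundance_collection")
}

#' Drop sites with zero virus or zero host abundance
#'
#' Sites where either the virus or the host abundance is zero are excluded
#' jointly (paired statistics require paired positivity); the order and values
#' of retained sites are untouched.
#'
#' @param dataset an [abundance_pair()].
#' @param min_sites minimum number of positive sites for the pair to be
#'   retained (used only for the report's `retained` flag here; see
#'   [apply_min_sites()]).
#' @return A list with `dataset` (the filtered `abundance_pair`, possibly with
#'   zero sites) and `report`, a one-row data frame with columns `pair_id`,
#'   `level`, `n_sites_raw`, `n_sites_zero_dropped`, `n_sites_kept`,
#'   `retained`.
#' @export
filter_zero_sites <- function(dataset, min_sites = 5L) {
  stopifnot(inherits(dataset, "abundance_pair"))
  keep <- dataset$host_abundance > 0 & dataset$virus_abundance > 0
  out <- dataset
  out$site_ids <- dataset$site_ids[keep]
  out$host_abundance <- dataset$host_abundance[keep]
  out$virus_abundance <- dataset$virus_abundance[keep]
  out$n_sites <- sum(keep)
  report <- data.frame(
    pair_id = dataset$pair_id, level = dataset$level,
    n_sites_raw = dataset$n_sites,
    n_sites_zero_dropped = dataset$n_sites - out$n_sites,
    n_sites_kept = out$n_sites,
    retained = out$n_sites >= min_sites,
    stringsAsFactors = FALSE
  )
  list(dataset = out, report = report)
}

#' Apply the minimum-sites inclusion rule
#'
#' A pair is analysed only if at least `min_sites` sampling sites have
#' strictly positive virus and host abundance (default 5). The hard floor is
#' 2, below which a slope is undefined.
#'
#' @param dataset an [abundance_pair()] that has already passed
#'   [filter_zero_sites()].
#' @param min_sites integer threshold, `>= 2`.
#' @return A one-row `FilterReport` data frame as in [filter_zero_sites()],
#'   with `retained = n_sites >= min_sites`.
#' @export
apply_min_sites <- function(dataset, min_sites = 5L) {
  stopifnot(inherits(dataset, "abundance_pair"))
  if (!is.numeric(min_sites) || length(min_sites) != 1L || min_sites < 2)
    stop_config("min_sites must be a single integer >= 2 (a slope needs at ",
                "least 2 points)")
  if (any(dataset$host_abundance <= 0) || any(dataset$virus_abundance <= 0))
    stop("apply_min_sites() expects a zero-filtered dataset; run ",
         "filter_zero_sites() first", call. = FALSE)
  data.frame(
    pair_id = dataset$pair_id, level = dataset$level,
    n_sites_raw = dataset$n_sites, n_sites_zero_dropped = 0L,
    n_sites_kept = dataset$n_sites,
    retained = dataset$n_sites >= min_sites,
    stringsAsFactors = FALSE
  )
}

#' Filter a whole collection
#'
#' Convenience wrapper: applies [filter_zero_sites()] then the `min_sites`
#' rule to every pair in a collection.
#'
#' @param datasets an `abundance_collection` or list of [abundance_pair()].
#' @param min_sites minimum positive-site count for retention.
#' @return A list with `datasets` (retained, filtered pairs) and `reports`
#'   (the row-bound `FilterReport` for all input pairs, retained or not).
#' @export
filter_collection <- function(datasets, min_sites = 5L) {
  res <- lapply(datasets, filter_zero_sites, min_sites = min_sites)
  reports <- do.call(rbind, lapply(res, `[[`, "report"))
  rownames(reports) <- NULL
  kept <- lapply(res[reports$retained], `[[`, "dataset")
  list(datasets = structure(kept, class = "abundance_collection"),
       reports = reports)
}

#' Partition a collection by taxonomic level
#'
#' @param datasets an `abundance_collection` or list of [abundance_pair()].
#' @return A list with elements `genus` and `phylum`, each an
#'   `abundance_collection`; every input pair appears in exactly one.
#' @export
partition_by_level <- function(datasets) {
  levs <- vapply(datasets, function(d) d$level, character(1))
  bad <- setdiff(unique(levs), .levels)
  if (length(bad))
    stop("unknown level label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- lapply(.levels, function(l)
    structure(datasets[levs == l], class = "abundance_collection"))
  names(out) <- .levels
  out
}

#' Write a collection back to the long TSV format
#'
#' Values are written with 17 significant digits so a write/read round-trip
#' reproduces every double exactly.
#'
#' @param datasets an `abundance_collection` or list of [abundance_pair()].
#' @param path output TSV path for the abundance table.
#' @param manifest_path optional output path for the pairs manifest.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(datasets, path, manifest_path = NULL) {
  rows <- lapply(datasets, function(d) {
    data.frame(pair_id = d$pair_id, site_id = d$site_ids,
               host_abundance = format_full(d$host_abundance),
               virus_abundance = format_full(d$virus_abundance),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), site_id = character(),
               host_abundance = character(), virus_abundance = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path)) {
    man <- data.frame(
      pair_id = vapply(datasets, `[[`, character(1), "pair_id"),
      level = vapply(datasets, `[[`, character(1), "level"),
      host_name = vapply(datasets, `[[`, character(1), "pair_id"),
      virus_name = paste0(vapply(datasets, `[[`, character(1), "pair_id"),
                          "_virus"),
      stringsAsFactors = FALSE
    )
    utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
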