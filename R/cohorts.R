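#' Build a cohort table from metadata and taxon calls
#'
#' Groups samples into cohorts keyed by (location, year, month, taxon)
#' and counts them. Cohorts below `min_size` are flagged
#' `included = FALSE` — excluded from diversity/FST statistics but kept
#' in composition tables. Every sample must have a taxon call (possibly
#' `unassigned`).
#'
#' @param metadata sample metadata data.frame (needs `sample_id`,
#'   `location`, `year`, `month`; `latitude`/`longitude` carried through
#'   when present).
#' @param taxon_calls either a data.frame with `sample_id` and
#'   `taxon_call` (as from [assign_taxa()]) or a character vector aligned
#'   with `metadata`; `NULL` marks every sample `unassigned`.
#' @param min_size minimum cohort size for statistics (default 8).
#' @return data.frame of class `CohortTable`: `location`, `latitude`,
#'   `longitude`, `year`, `month`, `taxon`, `n`, `included`, ordered by
#'   (location, year, month, taxon).
#' @export
build_cohorts <- function(metadata, taxon_calls = NULL, min_size = 8L) {
  taxon <- if (is.null(taxon_calls)) {
    rep("unassigned", nrow(metadata))
  } else if (is.data.frame(taxon_calls)) {
    m <- match(metadata$sample_id, taxon_calls$sample_id)
    .assert(!anyNA(m), "taxon calls missing for: ",
            paste(head(metadata$sample_id[is.na(m)]), collapse = ", "))
    taxon_calls$taxon_call[m]
  } else rep_len(as.character(taxon_calls), nrow(metadata))
  taxon[is.na(taxon) | taxon == ""] <- "unassigned"
  key <- data.frame(location = metadata$location, year = metadata$year,
                    month = metadata$month, taxon = taxon,
                    stringsAsFactors = FALSE)
  agg <- aggregate(list(n = rep(1L, nrow(key))), key, sum)
  if (!is.null(metadata$latitude)) {
    ll <- unique(metadata[, c("location", "latitude", "longitude")])
    agg <- merge(agg, ll, by = "location", all.x = TRUE, sort = FALSE)
  } else {
    agg$latitude <- NA_real_; agg$longitude <- NA_real_
  }
  agg <- agg[order(agg$location, agg$year, agg$month, agg$taxon), ]
  agg$included <- agg$n >= min_size
  rownames(agg) <- NULL
  structure(agg[, c("location", "latitude", "longitude", "year", "month",
                    "taxon", "n", "included")],
            class = c("CohortTable", "data.frame"))
}

#' Taxon composition totals and per-cohort percentages
#'
#' @param cohort_table a [build_cohorts()]-style table (needs `location`,
#'   `year`, `month`, `taxon`, `n`).
#' @return list with `taxon_totals` (named vector across all cohorts),
#'   `total` (grand total), and `composition`: per (location, year,
#'   month) cohort and taxon, the count, cohort total, and percentage
#'   (full precision; display rounding is left to the caller).
#'   Percentages are `NA`-flagged for empty cohorts.
#' @export
taxon_composition <- function(cohort_table) {
  .assert(nrow(cohort_table) > 0, "empty cohort table")
  ct <- as.data.frame(cohort_table)
  totals <- tapply(ct$n, ct$taxon, sum)
  gkey <- paste(ct$location, ct$year, ct$month, sep = "|")
  gtot <- tapply(ct$n, gkey, sum)
  comp <- data.frame(location = ct$location, year = ct$year,
                     month = ct$month, taxon = ct$taxon, n = ct$n,
                     total = as.integer(gtot[gkey]),
                     stringsAsFactors = FALSE)
  comp$pct <- ifelse(comp$total > 0, 100 * comp$n / comp$total, NA_real_)
  list(taxon_totals = c(totals), total = sum(ct$n), composition = comp)
}

#' Read a wide-format cohort count table
#'
#' Reads a TSV with columns `location`, `latitude`, `longitude`, `year`,
#' `month` and one count column per taxon, and converts it to the long
#' [build_cohorts()] layout. The packaged example
#' (`system.file("extdata", "table_t1.tsv", package = "aimpop")`)
#' transcribes the published sampling table of a Kenyan *An. gambiae*
#' s.l. survey: five sites, 2006-2021, 564 sequenced mosquitoes across
#' four taxa.
#'
#' @param path TSV file; `#` lines are treated as comments.
#' @param min_size minimum cohort size for the `included` flag.
#' @return a `CohortTable` (see [build_cohorts()]).
#' @export
read_cohort_counts <- function(path, min_size = 8L) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  fixed <- c("location", "latitude", "longitude", "year", "month")
  .assert(all(fixed %in% names(tab)), "missing required columns")
  taxa <- setdiff(names(tab), fixed)
  .assert(length(taxa) > 0, "no taxon count columns")
  long <- do.call(rbind, lapply(taxa, function(tx)
    data.frame(location = tab$location, latitude = tab$latitude,
               longitude = tab$longitude, year = tab$year,
               month = tab$month, taxon = tx, n = as.integer(tab[[tx]]),
               stringsAsFactors = FALSE)))
  long <- long[order(long$location, long$year, long$month, long$taxon), ]
  long$included <- long$n >= min_size
  rownames(long) <- NULL
  structure(long, class = c("CohortTable", "data.frame"))
}

#' Cohort sample groupings
#'
#' Named list of sample indices per (location, year, month, taxon)
#' cohort, the unit of every frequency and diversity computation.
#'
#' @param metadata sample metadata.
#' @param taxon_calls as in [build_cohorts()].
#' @param min_size cohorts below this size are dropped from the list
#'   (set to 0 to keep all).
#' @return named list of integer vectors; names are
#'   `location|year|month|taxon`.
#' @export
cohort_sample_groups <- function(metadata, taxon_calls = NULL,
                                 min_size = 8L) {
  taxon <- if (is.null(taxon_calls)) rep("unassigned", nrow(metadata))
  else if (is.data.frame(taxon_calls))
    taxon_calls$taxon_call[match(metadata$sample_id,
                                 taxon_calls$sample_id)]
  else rep_len(as.character(taxon_calls), nrow(metadata))
  key <- paste(metadata$location, metadata$year, metadata$month, taxon,
               sep = "|")
  groups <- split(seq_len(nrow(metadata)), key)
  groups[vapply(groups, length, 1L) >= min_size]
}
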