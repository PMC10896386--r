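#' Genotype dataset container
#'
#' The shared substrate of every analysis in the package: a diploid
#' genotype call array together with its variant table, sample metadata,
#' contig lengths, and (optionally) the accessibility mask used to define
#' which sites are analysable.
#'
#' @param gt integer array of dimension variants x samples x 2 holding
#'   allele indices (0 = reference, 1.. = alternate alleles, -1 = missing).
#' @param variants data.frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated for multiallelic sites) and logical
#'   `pass` (accessibility flag).
#' @param samples data.frame of sample metadata; must contain `sample_id`
#'   in the same order as the second dimension of `gt`.
#' @param contigs named integer vector of contig lengths.
#' @param mask optional `GRanges` of accessible intervals (used as the
#'   denominator for per-base diversity statistics); `NULL` means the whole
#'   genome is treated as accessible.
#'
#' @return An object of class `GenotypeDataset`.
#' @export
genotype_dataset <- function(gt, variants, samples, contigs, mask = NULL) {
  .assert(is.array(gt) && length(dim(gt)) == 3L && dim(gt)[3] == 2L,
          "gt must be a variants x samples x 2 array")
  .assert(nrow(variants) == dim(gt)[1], "variant table / gt mismatch")
  .assert(nrow(samples) == dim(gt)[2], "sample table / gt mismatch")
  .assert(!is.null(samples$sample_id), "samples must have a sample_id column")
  .assert(anyDuplicated(samples$sample_id) == 0, "duplicate sample ids")
  # positions strictly increasing within contig
  for (ct in unique(variants$contig)) {
    p <- variants$pos[variants$contig == ct]
    .assert(all(diff(p) > 0), "positions must be strictly increasing within ",
            ct)
  }
  if (is.null(variants$pass)) variants$pass <- TRUE
  structure(list(gt = gt, variants = variants, samples = samples,
                 contigs = contigs, mask = mask),
            class = "GenotypeDataset")
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat("<GenotypeDataset>\n")
  cat(sprintf("  %d variants x %d samples (diploid)\n",
              nrow(x$variants), nrow(x$samples)))
  cat(sprintf("  contigs: %s\n",
              paste(sprintf("%s (%s bp)", names(x$contigs),
                            format(x$contigs, big.mark = ",")),
                    collapse = ", ")))
  n_miss <- sum(x$gt[, , 1] < 0L)
  cat(sprintf("  pass sites: %d | missing calls: %d (%.2f%%)\n",
              sum(x$variants$pass), n_miss,
              100 * n_miss / prod(dim(x$gt)[1:2])))
  invisible(x)
}

#' @rdname genotype_dataset
#' @param x a `GenotypeDataset`.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname genotype_dataset
#' @export
n_samples <- function(x) nrow(x$samples)

#' Per-sample allele dosage matrix
#'
#' Counts copies of a given allele index per variant and sample. Missing
#' genotype calls yield `NA`.
#'
#' @param dataset a [GenotypeDataset].
#' @param allele allele index to count (default 1, the first alternate).
#' @param variants optional integer vector of variant indices.
#' @param samples optional integer vector of sample indices.
#' @return numeric matrix (variants x samples) with entries 0, 1, 2 or NA.
#' @export
genotype_dosage <- function(dataset, allele = 1L, variants = NULL,
                            samples = NULL) {
  vi <- variants %||% seq_len(n_variants(dataset))
  si <- samples %||% seq_len(n_samples(dataset))
  a1 <- dataset$gt[vi, si, 1, drop = FALSE][, , 1, drop = TRUE]
  a2 <- dataset$gt[vi, si, 2, drop = FALSE][, , 1, drop = TRUE]
  a1 <- matrix(a1, nrow = length(vi)); a2 <- matrix(a2, nrow = length(vi))
  d <- (a1 == allele) + (a2 == allele)
  d[a1 < 0L | a2 < 0L] <- NA_real_
  dimnames(d) <- list(NULL, dataset$samples$sample_id[si])
  d
}

#' @rdname genotype_dataset
#' @param dataset a `GenotypeDataset`.
#' @export
is_biallelic <- function(dataset) {
  alt <- dataset$variants$alt
  !is.na(alt) & alt != "" & alt != "." & !grepl(",", alt, fixed = TRUE)
}

# number of alleles (ref + alts) per variant
.n_alleles <- function(dataset) {
  alt <- dataset$variants$alt
  n_alt <- ifelse(is.na(alt) | alt %in% c("", "."), 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  1L + n_alt
}

# indices of variants matching (contig, pos) pairs; NA where absent
.match_sites <- function(dataset, contig, pos) {
  match(.key(contig, pos), .key(dataset$variants$contig, dataset$variants$pos))
}

# variant indices falling inside a region list(contig=, start=, end=)
.region_variants <- function(dataset, region) {
  v <- dataset$variants
  which(v$contig == region$contig & v$pos >= region$start &
          v$pos <= region$end)
}

#' Subset a genotype dataset
#'
#' @param dataset a [GenotypeDataset].
#' @param variants integer vector of variant indices (default all).
#' @param samples integer vector of sample indices (default all).
#' @return a new [GenotypeDataset] restricted to the requested rows.
#' @export
subset_dataset <- function(dataset, variants = NULL, samples = NULL) {
  vi <- variants %||% seq_len(n_variants(dataset))
  si <- samples %||% seq_len(n_samples(dataset))
  genotype_dataset(dataset$gt[vi, si, , drop = FALSE],
                   dataset$variants[vi, , drop = FALSE],
                   dataset$samples[si, , drop = FALSE],
                   dataset$contigs, dataset$mask)
}

#' Allele counts per cohort
#'
#' Tallies, for every variant and every cohort, how many copies of each
#' allele are observed among called genotypes. Missing calls are excluded.
#' This reduction feeds all frequency and diversity statistics.
#'
#' @param dataset a [GenotypeDataset].
#' @param cohorts named list; each element is a vector of sample indices or
#'   sample ids defining one cohort. Cohorts may overlap.
#' @return An object of class `AlleleCounts`: a named list of integer
#'   matrices (variants x alleles), one per cohort, with columns
#'   `allele_0`, `allele_1`, ...
#' @export
allele_counts_by_cohort <- function(dataset, cohorts) {
  .assert(is.list(cohorts) && length(cohorts) > 0,
          "cohorts must be a non-empty named list")
  n_all <- max(.n_alleles(dataset))
  out <- lapply(cohorts, function(members) {
    si <- .resolve_samples(dataset, members)
    .assert(length(si) > 0, "empty cohort")
    allele_counts(dataset, si, n_all)
  })
  structure(out, class = "AlleleCounts")
}

#' @rdname allele_counts_by_cohort
#' @param samples vector of sample indices or ids (one cohort).
#' @param n_alleles number of allele columns to tabulate (default: maximum
#'   across the dataset).
#' @export
allele_counts <- function(dataset, samples = NULL, n_alleles = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(dataset)) else
    .resolve_samples(dataset, samples)
  n_all <- n_alleles %||% max(.n_alleles(dataset))
  g1 <- dataset$gt[, si, 1, drop = FALSE]
  g2 <- dataset$gt[, si, 2, drop = FALSE]
  ac <- vapply(seq_len(n_all) - 1L, function(a) {
    rowSums(g1 == a, dims = 1) + rowSums(g2 == a, dims = 1)
  }, numeric(n_variants(dataset)))
  ac <- matrix(as.integer(ac), nrow = n_variants(dataset))
  colnames(ac) <- paste0("allele_", seq_len(n_all) - 1L)
  ac
}

.resolve_samples <- function(dataset, members) {
  if (is.character(members)) {
    si <- match(members, dataset$samples$sample_id)
    .assert(!anyNA(si), "unknown sample ids: ",
            paste(members[is.na(si)], collapse = ", "))
    si
  } else as.integer(members)
}
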