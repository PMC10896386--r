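#' Nucleotide diversity (theta-pi) from allele counts
#'
#' Mean pairwise difference per accessible base:
#' `sum_sites [ sum_{a<b} c_a c_b / C(n_s, 2) ] / L`, where `c_a` are the
#' per-allele counts among called genotypes at a site and `n_s` their
#' total. Sites with fewer than two called alleles are skipped.
#'
#' @param ac integer matrix of allele counts (variants x alleles) for one
#'   cohort, as produced by [allele_counts()].
#' @param accessible_bases denominator `L` (> 0): accessible bases for a
#'   per-base estimate, or the number of analysed sites for a per-site
#'   estimate.
#' @return theta-pi (numeric scalar).
#' @export
nucleotide_diversity <- function(ac, accessible_bases) {
  .assert(accessible_bases > 0, "accessible_bases must be > 0")
  n_s <- rowSums(ac)
  use <- n_s >= 2
  if (!any(use)) return(0)
  num <- (n_s[use]^2 - rowSums(ac[use, , drop = FALSE]^2)) / 2
  pi_site <- num / choose(n_s[use], 2)
  sum(pi_site) / accessible_bases
}

#' Watterson's theta from allele counts
#'
#' `theta_w = S / (a1 * L)` with `S` the number of segregating sites
#' (>= 2 distinct alleles observed) and `a1 = sum_{i=1}^{n-1} 1/i`. With
#' missing data the sample size `n` entering `a1` is the median called
#' allele count across included sites, keeping the classical constant
#' valid under a single-n convention.
#'
#' @inheritParams nucleotide_diversity
#' @param n optional sample size (called allele count) override.
#' @return theta-w (numeric scalar).
#' @export
watterson_theta <- function(ac, accessible_bases, n = NULL) {
  .assert(accessible_bases > 0, "accessible_bases must be > 0")
  n_s <- rowSums(ac)
  use <- n_s >= 2
  S <- sum(rowSums(ac[use, , drop = FALSE] > 0) >= 2)
  if (S == 0) return(0)
  n <- n %||% round(median(n_s[use]))
  .assert(n >= 2, "need at least two called alleles")
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * accessible_bases)
}

#' Tajima's D from allele counts
#'
#' Normalised difference between the mean pairwise diversity and the
#' scaled number of segregating sites:
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the classical
#' constants `a1, a2, b1, b2, c1, c2, e1, e2` evaluated at a single
#' sample size `n` (median called allele count across sites unless
#' overridden). Negative values indicate an excess of rare variants.
#'
#' @inheritParams watterson_theta
#' @return list of class `TajimaD` with elements `D`, `S`, `pi_total`,
#'   `n`. `D` is `NA` (flagged, not zero) when `S = 0` or `n < 4`.
#' @export
tajimas_d <- function(ac, n = NULL) {
  n_s <- rowSums(ac)
  use <- n_s >= 2
  seg <- rowSums(ac[use, , drop = FALSE] > 0) >= 2
  S <- sum(seg)
  num <- (n_s[use]^2 - rowSums(ac[use, , drop = FALSE]^2)) / 2
  pi_total <- sum(num / choose(n_s[use], 2))
  n <- n %||% (if (any(use)) round(median(n_s[use])) else 0L)
  if (S == 0 || n < 4) {
    return(structure(list(D = NA_real_, S = S, pi_total = pi_total, n = n,
                          reason = if (S == 0) "no segregating sites"
                          else "fewer than 4 called alleles"),
                     class = "TajimaD"))
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(list(D = D, S = S, pi_total = pi_total, n = n), class = "TajimaD")
}

#' @export
print.TajimaD <- function(x, ...) {
  if (is.na(x$D))
    cat(sprintf("Tajima's D: undefined (%s; S = %d, n = %d)\n",
                x$reason, x$S, x$n))
  else
    cat(sprintf("Tajima's D = %.4f (S = %d, n = %d, pi_total = %.4f)\n",
                x$D, x$S, x$n, x$pi_total))
  invisible(x)
}

#' Hudson's FST between two cohorts (ratio of averages)
#'
#' Per biallelic site, with alternate-allele frequencies `p1, p2` and
#' called allele counts `n1, n2`:
#' numerator `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `Den = p1(1-p2) + p2(1-p1)`. The estimate is the ratio of
#' the summed numerators to the summed denominators across sites (never
#' an average of per-site ratios). Sites with fewer than two called
#' alleles in either cohort, more than two observed alleles, or zero
#' denominator (monomorphic for the same allele in both cohorts) are
#' excluded from the sums.
#'
#' @param ac1,ac2 allele-count matrices (variants x alleles) for the two
#'   cohorts over the same variants.
#' @return object of class `FstResult`: list with `fst`, `num_sum`,
#'   `den_sum`, `n_sites`. `fst` is `NA` (flagged) when no site
#'   contributes.
#' @export
hudson_fst <- function(ac1, ac2) {
  .assert(nrow(ac1) == nrow(ac2), "cohorts must share the variant set")
  if (ncol(ac1) < 2 || ncol(ac2) < 2) {
    return(structure(list(fst = NA_real_, num_sum = 0, den_sum = 0,
                          n_sites = 0L,
                          reason = "no polymorphic biallelic sites"),
                     class = "FstResult"))
  }
  # restrict to sites biallelic across the pooled sample
  pooled <- ac1 + ac2
  n_obs_alleles <- rowSums(pooled > 0)
  n1 <- rowSums(ac1); n2 <- rowSums(ac2)
  use <- n_obs_alleles <= 2 & n1 >= 2 & n2 >= 2
  # allele 1 defined as the first alternate column where present
  p1 <- ifelse(n1 > 0, ac1[, 2] / n1, NA_real_)
  p2 <- ifelse(n2 > 0, ac2[, 2] / n2, NA_real_)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- use & !is.na(den) & den > 0
  if (!any(use)) {
    return(structure(list(fst = NA_real_, num_sum = 0, den_sum = 0,
                          n_sites = 0L,
                          reason = "no polymorphic biallelic sites"),
                     class = "FstResult"))
  }
  num_sum <- sum(num[use]); den_sum <- sum(den[use])
  structure(list(fst = num_sum / den_sum, num_sum = num_sum,
                 den_sum = den_sum, n_sites = sum(use)),
            class = "FstResult")
}

#' @export
print.FstResult <- function(x, ...) {
  if (is.na(x$fst)) cat("Hudson FST: undefined (", x$reason, ")\n")
  else cat(sprintf("Hudson FST = %.5f over %d sites\n", x$fst, x$n_sites))
  invisible(x)
}

#' Diversity summary for one cohort
#'
#' Computes theta-pi, Watterson's theta, Tajima's D, the segregating-site
#' count `S`, the denominator `L` and the working sample size `n` for a
#' cohort of samples over an optional region. The per-base denominator
#' comes from the accessibility mask (`per = "mask_bases"`); the
#' alternative `per = "segregating_sites"` divides by the number of
#' analysed variant sites instead, matching the convention in which
#' diversity is quoted per selected SNP.
#'
#' @param dataset a [GenotypeDataset].
#' @param samples sample indices or ids forming the cohort.
#' @param region optional list (`contig`, `start`, `end`) restricting the
#'   computation.
#' @param per denominator convention, `"mask_bases"` (default) or
#'   `"segregating_sites"`.
#' @param cohort_id label copied into the output row.
#' @return one-row data.frame: `cohort`, `region`, `theta_pi`, `theta_w`,
#'   `tajima_d`, `S`, `L`, `n`.
#' @export
diversity_stats <- function(dataset, samples, region = NULL,
                            per = c("mask_bases", "segregating_sites"),
                            cohort_id = "cohort") {
  per <- match.arg(per)
  vi <- if (is.null(region)) which(dataset$variants$pass) else
    intersect(.region_variants(dataset, region),
              which(dataset$variants$pass))
  si <- .resolve_samples(dataset, samples)
  sub <- subset_dataset(dataset, variants = vi, samples = si)
  ac <- allele_counts(sub)
  n_s <- rowSums(ac)
  L <- if (per == "mask_bases") .mask_bases(dataset, region) else
    sum(n_s >= 2)
  .assert(L > 0, "denominator L is zero")
  td <- tajimas_d(ac)
  data.frame(cohort = cohort_id,
             region = if (is.null(region)) "genome" else
               sprintf("%s:%d-%d", region$contig, region$start,
                       region$end),
             theta_pi = nucleotide_diversity(ac, L),
             theta_w = watterson_theta(ac, L),
             tajima_d = td$D, S = td$S, L = L, n = td$n,
             stringsAsFactors = FALSE)
}

.mask_bases <- function(dataset, region = NULL) {
  if (is.null(dataset$mask)) {
    if (is.null(region)) return(sum(as.numeric(dataset$contigs)))
    return(region$end - region$start + 1)
  }
  m <- dataset$mask
  if (!is.null(region)) {
    r <- GenomicRanges::GRanges(region$contig,
                                IRanges::IRanges(region$start, region$end))
    m <- GenomicRanges::intersect(m, r)
  }
  sum(as.numeric(BiocGenerics::width(m)))
}

#' Windowed diversity statistics
#'
#' Applies [diversity_stats()] in fixed-width windows along one contig.
#' The genome-wide value is the ratio of summed components (use
#' [diversity_stats()] directly), not the mean of windows.
#'
#' @inheritParams diversity_stats
#' @param contig contig to tile.
#' @param width window width in bp.
#' @return data.frame with one row per window.
#' @export
windowed_diversity <- function(dataset, samples, contig, width = 50000L,
                               per = c("mask_bases", "segregating_sites"),
                               cohort_id = "cohort") {
  per <- match.arg(per)
  wins <- tile_windows(dataset$contigs[contig], width)
  out <- lapply(seq_len(nrow(wins)), function(i) {
    reg <- list(contig = wins$contig[i], start = wins$start[i],
                end = wins$end[i])
    vi <- intersect(.region_variants(dataset, reg),
                    which(dataset$variants$pass))
    if (!length(vi))
      return(data.frame(cohort = cohort_id,
                        region = sprintf("%s:%d-%d", reg$contig,
                                         reg$start, reg$end),
                        theta_pi = NA_real_, theta_w = NA_real_,
                        tajima_d = NA_real_, S = 0L, L = NA_real_,
                        n = NA_integer_, stringsAsFactors = FALSE))
    diversity_stats(dataset, samples, reg, per, cohort_id)
  })
  do.call(rbind, out)
}

#' Pairwise Hudson FST matrix between cohorts
#'
#' @param dataset a [GenotypeDataset].
#' @param cohorts named list of sample index/id vectors.
#' @param variants optional variant indices (e.g. a structure SNP
#'   selection); defaults to all PASS biallelic variants.
#' @return list with `fst` (symmetric matrix) and `pairs` (long-format
#'   data.frame with site counts).
#' @export
fst_matrix <- function(dataset, cohorts, variants = NULL) {
  vi <- variants %||% which(dataset$variants$pass & is_biallelic(dataset))
  sub <- subset_dataset(dataset, variants = vi)
  acs <- allele_counts_by_cohort(sub, cohorts)
  k <- length(acs)
  m <- matrix(NA_real_, k, k, dimnames = list(names(acs), names(acs)))
  diag(m) <- 0
  pairs <- NULL
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- hudson_fst(acs[[i]], acs[[j]])
      m[i, j] <- m[j, i] <- r$fst
      pairs <- rbind(pairs, data.frame(cohort1 = names(acs)[i],
                                       cohort2 = names(acs)[j],
                                       fst = r$fst, n_sites = r$n_sites,
                                       stringsAsFactors = FALSE))
    }
  }
  list(fst = m, pairs = pairs)
}
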