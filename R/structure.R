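#' Select SNPs for structure analyses
#'
#' Applies the standard filters for population-structure SNP sets — PASS
#' accessibility, biallelic, minor allele frequency above a floor, no
#' missing calls — and then thins to a target count by equal rank-spacing
#' along the genome (rank `ceiling(stride * k)` for `k = 1..n_target`
#' with `stride = n_qualifying / n_target`), which guarantees exactly
#' `n_target` sites whenever enough qualify. If fewer qualify, all are
#' returned and the shortfall is logged.
#'
#' @param dataset a [GenotypeDataset].
#' @param contigs optional character vector restricting the selection to
#'   these contigs (e.g. the inversion-free chromosome).
#' @param n_target number of SNPs to select.
#' @param maf_min minor-allele-frequency floor (exclusive; default 0.002,
#'   i.e. MAF > 0.2%).
#' @param samples optional sample subset over which MAF and missingness
#'   are evaluated (default: all samples).
#' @return object of class `SnpSelection`: list with `idx` (variant
#'   indices into `dataset`) and `log` (filter counts).
#' @export
select_structure_snps <- function(dataset, contigs = NULL, n_target,
                                  maf_min = 0.002, samples = NULL) {
  .assert(n_target >= 1, "n_target must be >= 1")
  si <- if (is.null(samples)) seq_len(n_samples(dataset)) else
    .resolve_samples(dataset, samples)
  vi <- seq_len(n_variants(dataset))
  if (!is.null(contigs)) {
    .assert(all(contigs %in% names(dataset$contigs)), "unknown contig")
    vi <- vi[dataset$variants$contig[vi] %in% contigs]
  }
  bi <- vi[dataset$variants$pass[vi] & is_biallelic(dataset)[vi]]
  d <- genotype_dosage(dataset, 1L, variants = bi, samples = si)
  n_called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)
  pass_maf <- bi[!is.na(maf) & maf > maf_min]
  complete <- pass_maf[rowSums(is.na(
    d[match(pass_maf, bi), , drop = FALSE])) == 0]
  .assert(length(complete) > 0, "no qualifying SNPs")
  nq <- length(complete)
  if (nq <= n_target) {
    sel <- complete
  } else {
    stride <- nq / n_target
    sel <- complete[ceiling(stride * seq_len(n_target))]
  }
  structure(list(idx = sel,
                 log = list(n_region = length(vi),
                            n_biallelic = length(bi),
                            n_maf = length(pass_maf),
                            n_complete = nq,
                            n_selected = length(sel),
                            shortfall = nq < n_target)),
            class = "SnpSelection")
}

#' @export
print.SnpSelection <- function(x, ...) {
  cat(sprintf(paste0("<SnpSelection> %d SNPs (from %d in region, %d ",
                     "biallelic PASS, %d above MAF floor, %d complete)%s\n"),
              x$log$n_selected, x$log$n_region, x$log$n_biallelic,
              x$log$n_maf, x$log$n_complete,
              if (x$log$shortfall) " [fewer qualified than requested]"
              else ""))
  invisible(x)
}

# samples x variants alternate-dosage matrix for a selection
.dosage_matrix <- function(dataset, selection, samples = NULL) {
  idx <- if (inherits(selection, "SnpSelection")) selection$idx else
    selection
  t(genotype_dosage(dataset, 1L, variants = idx, samples = samples))
}

#' Principal component analysis on allele dosages
#'
#' Centres the per-variant alternate-allele dosages (0/1/2) and, by
#' default, applies the drift-variance scaling `1/sqrt(p(1-p))`
#' (Patterson) before the decomposition. Variants that are constant
#' across the analysed samples are dropped with a log entry. Results are
#' deterministic up to the sign of each component.
#'
#' @param dataset a [GenotypeDataset].
#' @param selection a [select_structure_snps()] result or a vector of
#'   variant indices (sites must have no missing calls among the analysed
#'   samples).
#' @param k number of components to return (must be < number of
#'   samples).
#' @param scale `"patterson"` (default) or `"none"`.
#' @param samples optional sample subset.
#' @return object of class `PcaResult`: list with `coords` (samples x k),
#'   `explained` (variance fractions, non-increasing), `n_dropped`
#'   (constant variants removed).
#' @export
pca_dosage <- function(dataset, selection, k = 10,
                       scale = c("patterson", "none"), samples = NULL) {
  scale <- match.arg(scale)
  x <- .dosage_matrix(dataset, selection, samples)
  .assert(!anyNA(x), "PCA requires complete dosages; filter missing calls first")
  .assert(k < nrow(x), "k must be smaller than the number of samples")
  p <- colMeans(x) / 2
  keep <- apply(x, 2, function(col) var(col) > 0)
  n_dropped <- sum(!keep)
  x <- x[, keep, drop = FALSE]; p <- p[keep]
  .assert(ncol(x) > 0, "all selected variants are constant")
  x <- sweep(x, 2, colMeans(x))
  if (scale == "patterson")
    x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(x, nu = k, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("PC", seq_len(k))
  explained <- sv$d^2 / sum(sv$d^2)
  structure(list(coords = coords, explained = explained[seq_len(k)],
                 n_dropped = n_dropped),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat(sprintf("<PcaResult> %d samples, %d components\n", nrow(x$coords),
              ncol(x$coords)))
  cat("  explained:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Unrooted neighbour-joining tree on cityblock distances
#'
#' Computes pairwise cityblock (L1) distances between sample dosage
#' vectors (unscaled allele counts) and agglomerates them with the
#' Saitou-Nei neighbour-joining algorithm. Negative branch lengths, a
#' known artefact of NJ on non-additive matrices, are clamped to zero and
#' counted in the log.
#'
#' @param dataset a [GenotypeDataset] (ignored when `d` is supplied).
#' @param selection variant selection as in [pca_dosage()].
#' @param samples optional sample subset.
#' @param d optional precomputed `dist` or distance matrix, bypassing the
#'   dosage computation.
#' @return object of class `TreeResult`: list with `tree` (an `ape`
#'   `phylo`), `newick` (serialised string), `n_clamped`.
#' @export
nj_tree <- function(dataset = NULL, selection = NULL, samples = NULL,
                    d = NULL) {
  if (is.null(d)) {
    x <- .dosage_matrix(dataset, selection, samples)
    .assert(!anyNA(x), "NJ requires complete dosages")
    d <- dist(x, method = "manhattan")
  }
  dm <- as.matrix(d)
  .assert(nrow(dm) >= 3, "need at least 3 samples for a tree")
  tree <- ape::nj(as.dist(dm))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 n_clamped = n_clamped),
            class = "TreeResult")
}

#' @export
print.TreeResult <- function(x, ...) {
  cat(sprintf("<TreeResult> unrooted NJ tree, %d leaves%s\n",
              length(x$tree$tip.label),
              if (x$n_clamped) sprintf(" (%d negative branches clamped)",
                                       x$n_clamped) else ""))
  invisible(x)
}

#' Inversion-karyotype clustering by region-restricted PCA
#'
#' Restricts a dosage PCA to an inversion region and partitions the
#' samples into at most three clusters along PC1 — the expected
#' configuration for 0/1/2 copies of an inversion arrangement. The
#' cluster count is chosen from the gaps between consecutive sorted PC1
#' values: a gap larger than `gap_frac` of the PC1 range marks a cluster
#' boundary (at most two boundaries are used, the largest first). Final
#' assignments come from 1-D k-means seeded at the gap-segment means, so
#' the procedure is deterministic; cluster labels are ordered by mean
#' PC1.
#'
#' @param dataset a [GenotypeDataset].
#' @param region list (`contig`, `start`, `end`) of the inversion.
#' @param samples optional sample subset.
#' @param min_snps minimum qualifying SNPs required in the region
#'   (default 50).
#' @param gap_frac boundary threshold as a fraction of the PC1 range
#'   (default 0.25).
#' @return list with `cluster` (named integer vector, labels `0..k-1`),
#'   `k`, `pca` (the [pca_dosage()] result), `selection`.
#' @export
karyotype_pca <- function(dataset, region, samples = NULL, min_snps = 50L,
                          gap_frac = 0.25) {
  vi <- .region_variants(dataset, region)
  si <- if (is.null(samples)) seq_len(n_samples(dataset)) else
    .resolve_samples(dataset, samples)
  d <- genotype_dosage(dataset, 1L, variants = vi, samples = si)
  qual <- vi[dataset$variants$pass[vi] & is_biallelic(dataset)[vi]]
  qual <- qual[rowSums(is.na(d[match(qual, vi), , drop = FALSE])) == 0]
  # polymorphic among analysed samples
  dq <- d[match(qual, vi), , drop = FALSE]
  qual <- qual[apply(dq, 1, function(r) var(r) > 0)]
  .assert(length(qual) >= min_snps,
          sprintf("region contains %d qualifying SNPs (need >= %d)",
                  length(qual), min_snps))
  pca <- pca_dosage(dataset, qual, k = min(2L, length(si) - 1L),
                    samples = si)
  pc1 <- pca$coords[, 1]
  r <- diff(range(pc1))
  if (r < sqrt(.Machine$double.eps)) {
    cl <- setNames(rep(0L, length(pc1)), names(pc1))
    return(list(cluster = cl, k = 1L, pca = pca, selection = qual,
                log = "all samples identical in region"))
  }
  o <- order(pc1)
  gaps <- diff(pc1[o])
  big <- which(gaps > gap_frac * r)
  big <- big[order(gaps[big], decreasing = TRUE)]
  big <- sort(head(big, 2L))
  k <- length(big) + 1L
  if (k == 1L) {
    cl <- setNames(rep(0L, length(pc1)), names(pc1))
    return(list(cluster = cl, k = 1L, pca = pca, selection = qual))
  }
  seg <- findInterval(seq_along(pc1[o]), c(1, big + 1))
  centers <- tapply(pc1[o], seg, mean)
  km <- kmeans(pc1, centers = matrix(sort(centers), ncol = 1))
  lab <- rank(km$centers[, 1]) - 1L   # ordered by mean PC1
  cl <- setNames(as.integer(lab[km$cluster]), names(pc1))
  list(cluster = cl, k = k, pca = pca, selection = qual)
}
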