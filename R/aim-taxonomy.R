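#' Ancestry-informative marker panel
#'
#' A set of genomic sites whose alleles are diagnostic between two taxa.
#' By convention a panel named `"<A>_vs_<B>"` has `allele_a` diagnostic
#' for taxon A and `allele_b` for taxon B; compound group names such as
#' `"gambcolu"` (= *gambiae* + *coluzzii*) are understood by the
#' simulator and classifier.
#'
#' @param sites data.frame with columns `contig`, `pos`, `allele_a`,
#'   `allele_b`.
#' @param taxon_a,taxon_b the taxa (or taxon groups) the two diagnostic
#'   alleles belong to.
#' @param name panel name; defaults to `"<A>_vs_<B>"`.
#' @return object of class `AimPanel` (a data.frame with taxon
#'   attributes).
#' @export
aim_panel <- function(sites, taxon_a, taxon_b,
                      name = paste0(taxon_a, "_vs_", taxon_b)) {
  .assert(all(c("contig", "pos", "allele_a", "allele_b") %in% names(sites)),
          "panel must have contig, pos, allele_a, allele_b")
  .assert(all(sites$allele_a != sites$allele_b),
          "diagnostic alleles must differ")
  .assert(anyDuplicated(.key(sites$contig, sites$pos)) == 0,
          "duplicate panel positions")
  structure(as.data.frame(sites), taxon_a = taxon_a, taxon_b = taxon_b,
            panel_name = name,
            class = c("AimPanel", "data.frame"))
}

#' @rdname aim_panel
#' @param x an `AimPanel`.
#' @export
panel_taxa <- function(x) c(attr(x, "taxon_a"), attr(x, "taxon_b"))

#' Per-sample AIM allele fraction
#'
#' For each sample, the fraction of alleles at called panel sites that
#' match the diagnostic allele of `target_taxon`:
#' `fraction = (target-diagnostic alleles carried) / (2 x called sites)`.
#' Sites where the sample's genotype is missing do not contribute to
#' either numerator or denominator; samples with zero called panel sites
#' get `NA` fractions.
#'
#' @param dataset a [GenotypeDataset].
#' @param panel an [aim_panel()].
#' @param target_taxon one of the two taxa of the panel.
#' @return data.frame with columns `sample_id`, `n_sites` (called panel
#'   sites) and `fraction`.
#' @export
compute_aim_fraction <- function(dataset, panel, target_taxon) {
  taxa <- panel_taxa(panel)
  .assert(target_taxon %in% taxa,
          "target_taxon must be one of: ", paste(taxa, collapse = ", "))
  idx <- .match_sites(dataset, panel$contig, panel$pos)
  found <- !is.na(idx)
  .assert(any(found), "panel does not intersect the dataset")
  idx <- idx[found]
  base <- if (target_taxon == taxa[1]) panel$allele_a[found] else
    panel$allele_b[found]
  # allele index of the diagnostic base at each matched variant
  v <- dataset$variants[idx, ]
  alts <- strsplit(ifelse(is.na(v$alt) | v$alt == ".", "", v$alt), ",",
                   fixed = TRUE)
  t_idx <- vapply(seq_along(idx), function(i) {
    if (base[i] == v$ref[i]) return(0L)
    m <- match(base[i], alts[[i]])
    if (is.na(m)) -9L else m    # -9: diagnostic allele absent at variant
  }, integer(1))
  g1 <- matrix(dataset$gt[idx, , 1], nrow = length(idx))
  g2 <- matrix(dataset$gt[idx, , 2], nrow = length(idx))
  called <- g1 >= 0L & g2 >= 0L
  hits <- (g1 == t_idx) + (g2 == t_idx)
  hits[!called] <- 0
  n_sites <- colSums(called)
  frac <- ifelse(n_sites > 0, colSums(hits) / (2 * n_sites), NA_real_)
  data.frame(sample_id = dataset$samples$sample_id, n_sites = n_sites,
             fraction = frac, stringsAsFactors = FALSE)
}

#' Classification thresholds for AIM taxon calls
#'
#' @param t_arab arabiensis-fraction threshold: above it a sample is
#'   called *An. arabiensis* (default 0.6).
#' @param t_col_lo coluzzii-fraction threshold below which a sample is
#'   called *An. gambiae* (default 0.12).
#' @param t_col_hi coluzzii-fraction threshold above which a sample is
#'   called *An. coluzzii* (default 0.9).
#' @param min_sites minimum called panel sites for a fraction to be
#'   trusted; below it a sample is left unassigned (default 10).
#' @return list of thresholds.
#' @export
aim_thresholds <- function(t_arab = 0.6, t_col_lo = 0.12, t_col_hi = 0.9,
                           min_sites = 10L) {
  list(t_arab = t_arab, t_col_lo = t_col_lo, t_col_hi = t_col_hi,
       min_sites = as.integer(min_sites))
}

#' Two-panel taxon classification
#'
#' Applies the decision procedure used for species assignment within the
#' *An. gambiae* complex: the arabiensis panel is evaluated first and is
#' decisive (`arab_fraction > t_arab` => *arabiensis*); remaining samples
#' are split on the coluzzii fraction (`> t_col_hi` => *coluzzii*,
#' `< t_col_lo` => *gambiae*, otherwise `intermediate`). Missing
#' fractions give `unassigned`, never a silent drop.
#'
#' @param arab_fraction numeric vector of arabiensis AIM fractions (may
#'   contain `NA`).
#' @param coluzzii_fraction numeric vector of coluzzii AIM fractions.
#' @param thresholds an [aim_thresholds()] list.
#' @return character vector of calls in
#'   `{arabiensis, gambiae, coluzzii, intermediate, unassigned}`.
#' @export
classify_taxon <- function(arab_fraction, coluzzii_fraction,
                           thresholds = aim_thresholds()) {
  n <- max(length(arab_fraction), length(coluzzii_fraction))
  af <- rep_len(arab_fraction, n); cf <- rep_len(coluzzii_fraction, n)
  .assert(all(is.na(af) | (af >= 0 & af <= 1)), "fractions must be in [0,1]")
  .assert(all(is.na(cf) | (cf >= 0 & cf <= 1)), "fractions must be in [0,1]")
  out <- rep("unassigned", n)
  known_arab <- !is.na(af)
  out[known_arab & af > thresholds$t_arab] <- "arabiensis"
  rest <- known_arab & af <= thresholds$t_arab & !is.na(cf)
  out[rest & cf > thresholds$t_col_hi] <- "coluzzii"
  out[rest & cf < thresholds$t_col_lo] <- "gambiae"
  out[rest & cf >= thresholds$t_col_lo & cf <= thresholds$t_col_hi] <-
    "intermediate"
  out
}

#' Assign every sample to a taxon from two AIM panels
#'
#' Convenience wrapper: computes the arabiensis fraction on the
#' gambiae/coluzzii-vs-arabiensis panel and the coluzzii fraction on the
#' gambiae-vs-coluzzii panel, applies [classify_taxon()], and enforces the
#' `min_sites` rule.
#'
#' @param dataset a [GenotypeDataset].
#' @param panels named list of [aim_panel()]s containing
#'   `gambcolu_vs_arabiensis` and `gambiae_vs_coluzzii`.
#' @param thresholds an [aim_thresholds()] list.
#' @return data.frame (`AimResult`): `sample_id`, `arab_fraction`,
#'   `arab_n`, `coluzzii_fraction`, `coluzzii_n`, `taxon_call`.
#' @export
assign_taxa <- function(dataset, panels, thresholds = aim_thresholds()) {
  .assert(all(c("gambcolu_vs_arabiensis", "gambiae_vs_coluzzii") %in%
                names(panels)), "need both AIM panels")
  fa <- compute_aim_fraction(dataset, panels$gambcolu_vs_arabiensis,
                             "arabiensis")
  fc <- compute_aim_fraction(dataset, panels$gambiae_vs_coluzzii,
                             "coluzzii")
  af <- ifelse(fa$n_sites >= thresholds$min_sites, fa$fraction, NA_real_)
  cf <- ifelse(fc$n_sites >= thresholds$min_sites, fc$fraction, NA_real_)
  data.frame(sample_id = fa$sample_id,
             arab_fraction = af, arab_n = fa$n_sites,
             coluzzii_fraction = cf, coluzzii_n = fc$n_sites,
             taxon_call = classify_taxon(af, cf, thresholds),
             stringsAsFactors = FALSE)
}

#' Windowed introgression profile and per-sample region calls
#'
#' Computes, per genomic window and per sample, the mean dosage of the
#' donor taxon's diagnostic alleles over called panel sites (0 = no donor
#' ancestry, 0.5 = heterozygous, 1 = homozygous donor), and calls an
#' introgression state for a focal region from the region-mean dosage
#' `d`: `d >= hom_min` => homozygous, `het_min <= d < hom_min` =>
#' heterozygous, otherwise none. The thresholds default to the midpoints
#' between the expected dosages 0, 0.5 and 1.
#'
#' @param dataset a [GenotypeDataset].
#' @param panel an [aim_panel()]; `donor` must be one of its taxa.
#' @param region list with `contig`, `start`, `end`: the focal block.
#' @param windows optional data.frame of windows (`contig`, `start`,
#'   `end`); defaults to 50 kb tiles of the contigs carrying panel sites.
#' @param donor donor taxon (default: taxon A of the panel).
#' @param samples optional sample indices/ids to restrict to.
#' @param het_min,hom_min dosage thresholds (defaults 0.25 and 0.75).
#' @return list with `windows` (the window table), `dosage` (windows x
#'   samples matrix of mean donor dosage; `NaN` where a window has no
#'   called site), `calls` (per-sample data.frame with `region_dosage`,
#'   `n_sites`, `state`), and `state_pct` (percentage of samples in each
#'   state).
#' @export
introgression_profile <- function(dataset, panel, region, windows = NULL,
                                  donor = panel_taxa(panel)[1],
                                  samples = NULL,
                                  het_min = 0.25, hom_min = 0.75) {
  si <- if (is.null(samples)) seq_len(n_samples(dataset)) else
    .resolve_samples(dataset, samples)
  sub <- subset_dataset(dataset, samples = si)
  .assert(donor %in% panel_taxa(panel), "donor must be a panel taxon")
  # per-site donor dosage for panel sites
  idx <- .match_sites(sub, panel$contig, panel$pos)
  found <- !is.na(idx)
  .assert(any(found), "panel does not intersect the dataset")
  pan <- panel[found, , drop = FALSE]
  idx <- idx[found]
  taxa <- panel_taxa(panel)
  base <- if (donor == taxa[1]) pan$allele_a else pan$allele_b
  v <- sub$variants[idx, ]
  alts <- strsplit(ifelse(is.na(v$alt) | v$alt == ".", "", v$alt), ",",
                   fixed = TRUE)
  t_idx <- vapply(seq_along(idx), function(i) {
    if (base[i] == v$ref[i]) 0L
    else { m <- match(base[i], alts[[i]]); if (is.na(m)) -9L else m }
  }, integer(1))
  g1 <- matrix(sub$gt[idx, , 1], nrow = length(idx))
  g2 <- matrix(sub$gt[idx, , 2], nrow = length(idx))
  called <- g1 >= 0L & g2 >= 0L
  dos <- ((g1 == t_idx) + (g2 == t_idx)) / 2
  dos[!called] <- NA_real_
  site_contig <- v$contig; site_pos <- v$pos

  if (is.null(windows)) {
    cts <- unique(site_contig)
    windows <- tile_windows(dataset$contigs[cts], 50000L)
  }
  wmat <- matrix(NA_real_, nrow(windows), ncol(dos))
  for (w in seq_len(nrow(windows))) {
    in_w <- site_contig == windows$contig[w] &
      site_pos >= windows$start[w] & site_pos <= windows$end[w]
    if (any(in_w))
      wmat[w, ] <- colMeans(dos[in_w, , drop = FALSE], na.rm = TRUE)
  }
  colnames(wmat) <- sub$samples$sample_id

  in_r <- site_contig == region$contig & site_pos >= region$start &
    site_pos <= region$end
  .assert(any(in_r), "region contains no panel sites")
  rd <- colMeans(dos[in_r, , drop = FALSE], na.rm = TRUE)
  rn <- colSums(!is.na(dos[in_r, , drop = FALSE]))
  state <- ifelse(rn == 0, NA_character_,
                  ifelse(rd >= hom_min, "hom",
                         ifelse(rd >= het_min, "het", "none")))
  calls <- data.frame(sample_id = sub$samples$sample_id,
                      region_dosage = rd, n_sites = rn, state = state,
                      stringsAsFactors = FALSE)
  called_states <- factor(state[!is.na(state)],
                          levels = c("none", "het", "hom"))
  state_pct <- 100 * table(called_states) / max(1L, length(called_states))
  list(windows = windows, dosage = wmat, calls = calls,
       state_pct = c(state_pct))
}
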