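#' Annotate coding effects of variants in target genes
#'
#' For every variant falling inside a gene's CDS, mutates the reference
#' codon with each alternate allele (reverse-complementing on
#' minus-strand genes), translates with the standard genetic code, and
#' emits a substitution label `<refAA><codon><altAA>` where the codon
#' number is `ceiling(cds_pos / 3) + offset`. Variants outside all CDS
#' are reported as `non_coding`; same-amino-acid changes as
#' `synonymous`. Variants whose REF allele disagrees with the reference
#' sequence are excluded with a warning.
#'
#' @param dataset a [GenotypeDataset].
#' @param gene_models named list of [gene_model()] objects.
#' @param reference reference genome: a `DNAStringSet`, a FASTA path, or
#'   the simulator's list of per-contig base vectors.
#' @return data.frame with one row per variant x alternate allele:
#'   `variant`, `contig`, `pos`, `allele`, `gene`, `codon`, `ref_aa`,
#'   `alt_aa`, `label`, `effect`.
#' @export
annotate_coding_effects <- function(dataset, gene_models, reference) {
  genome <- .as_base_list(reference)
  v <- dataset$variants
  out <- list()
  for (g in gene_models) {
    .assert(g$contig %in% names(genome), "reference lacks contig ", g$contig)
    span <- c(min(g$cds$start), max(g$cds$end))
    vi <- which(v$contig == g$contig & v$pos >= span[1] & v$pos <= span[2])
    if (!length(vi)) next
    cds_pos <- genomic_to_cds(g, v$pos[vi])
    in_cds <- !is.na(cds_pos)
    vi <- vi[in_cds]; cds_pos <- cds_pos[in_cds]
    if (!length(vi)) next
    ref_ok <- mapply(function(ct, p, r) genome[[ct]][p] == r,
                     v$contig[vi], v$pos[vi], v$ref[vi])
    if (any(!ref_ok)) {
      warning(sprintf("%d variant(s) in %s rejected: REF disagrees with reference sequence",
                      sum(!ref_ok), g$gene_id))
      vi <- vi[ref_ok]; cds_pos <- cds_pos[ref_ok]
    }
    if (!length(vi)) next
    codon_num <- (cds_pos - 1L) %/% 3L + 1L
    within <- (cds_pos - 1L) %% 3L + 1L
    for (i in seq_along(vi)) {
      coords <- codon_genomic_coords(g, codon_num[i])
      bases <- genome[[g$contig]][coords]
      if (g$strand == "-") bases <- .comp(bases)
      ref_codon <- paste(bases, collapse = "")
      ref_aa <- .translate_codon(ref_codon)
      alts <- strsplit(v$alt[vi[i]], ",", fixed = TRUE)[[1]]
      for (a in seq_along(alts)) {
        if (!alts[a] %in% DNA_BASES4) next
        mut <- bases
        mut[within[i]] <- if (g$strand == "+") alts[a] else .comp(alts[a])
        alt_aa <- .translate_codon(paste(mut, collapse = ""))
        lab_codon <- codon_num[i] + g$offset
        out[[length(out) + 1L]] <- data.frame(
          variant = vi[i], contig = g$contig, pos = v$pos[vi[i]],
          allele = a, gene = g$gene_id, codon = lab_codon,
          ref_aa = ref_aa, alt_aa = alt_aa,
          label = paste0(ref_aa, lab_codon, alt_aa),
          effect = if (identical(ref_aa, alt_aa)) "synonymous"
          else "non_synonymous",
          stringsAsFactors = FALSE)
      }
    }
  }
  coding <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = integer(0), contig = character(0),
               pos = integer(0), allele = integer(0), gene = character(0),
               codon = integer(0), ref_aa = character(0),
               alt_aa = character(0), label = character(0),
               effect = character(0), stringsAsFactors = FALSE)
  # non-coding rows for the remaining variants (first alt only, as a
  # placeholder classification)
  nc <- setdiff(seq_len(nrow(v)), unique(coding$variant))
  if (length(nc)) {
    coding <- rbind(coding, data.frame(
      variant = nc, contig = v$contig[nc], pos = v$pos[nc], allele = 1L,
      gene = NA_character_, codon = NA_integer_, ref_aa = NA_character_,
      alt_aa = NA_character_, label = NA_character_,
      effect = "non_coding", stringsAsFactors = FALSE))
  }
  coding[order(coding$variant, coding$allele), , drop = FALSE]
}

.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.as_base_list <- function(reference) {
  if (is.list(reference) && !is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  .assert(is(reference, "DNAStringSet"), "unsupported reference type")
  out <- lapply(seq_along(reference), function(i)
    strsplit(as.character(reference[[i]]), "")[[1]])
  names(out) <- sub("\\s.*", "", names(reference))
  out
}

#' Per-cohort amino-acid substitution frequencies
#'
#' For every non-synonymous substitution and cohort, the alternate-allele
#' frequency among called alleles. Multiple variants producing the same
#' substitution have their frequencies summed. Substitutions whose
#' frequency does not exceed the retention threshold in at least one
#' cohort are dropped unless `full = TRUE` (then kept with
#' `retained = FALSE`).
#'
#' @param dataset a [GenotypeDataset].
#' @param effects an [annotate_coding_effects()] table.
#' @param cohorts named list of sample index/id vectors.
#' @param retention frequency threshold (strictly greater-than; default
#'   0.05).
#' @param full keep non-retained rows?
#' @return data.frame (`SubstitutionFrequencyTable`): `gene`,
#'   `substitution`, `positions`, `cohort`, `frequency`, `n_called`,
#'   `retained`. `frequency` is `NA` (flagged) for cohorts with zero
#'   called alleles.
#' @export
substitution_frequencies <- function(dataset, effects, cohorts,
                                     retention = 0.05, full = FALSE) {
  .assert(length(cohorts) >= 1, "need at least one cohort")
  ns <- effects[effects$effect == "non_synonymous", , drop = FALSE]
  if (!nrow(ns))
    return(data.frame(gene = character(0), substitution = character(0),
                      positions = character(0), cohort = character(0),
                      frequency = numeric(0), n_called = integer(0),
                      retained = logical(0), stringsAsFactors = FALSE))
  rows <- list()
  for (key in unique(paste(ns$gene, ns$label))) {
    sel <- ns[paste(ns$gene, ns$label) == key, , drop = FALSE]
    positions <- paste(sprintf("%s:%d", sel$contig, sel$pos),
                       collapse = ";")
    for (cn in names(cohorts)) {
      si <- .resolve_samples(dataset, cohorts[[cn]])
      freq <- 0; n_called_min <- NA_integer_; any_called <- FALSE
      for (r in seq_len(nrow(sel))) {
        dos <- genotype_dosage(dataset, sel$allele[r],
                               variants = sel$variant[r], samples = si)
        called <- sum(!is.na(dos))
        if (called == 0) next
        any_called <- TRUE
        freq <- freq + sum(dos, na.rm = TRUE) / (2 * called)
        n_called_min <- min(n_called_min, 2L * called, na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sel$gene[1], substitution = sel$label[1],
        positions = positions, cohort = cn,
        frequency = if (any_called) freq else NA_real_,
        n_called = if (any_called) n_called_min else 0L,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$gene, tab$substitution)
  max_f <- tapply(tab$frequency, key, function(f)
    if (all(is.na(f))) 0 else max(f, na.rm = TRUE))
  tab$retained <- unname(max_f[key] > retention)
  if (!full) tab <- tab[tab$retained, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Joint frequency of a linked substitution pair
#'
#' Unphased joint allele-frequency estimate for a pair of substitutions
#' (e.g. the coupled kdr pair Vgsc-V402L + I1527T): per cohort, the mean
#' over samples of `min(dosage1, dosage2) / 2`, which is exact when the
#' two alleles are in complete coupling. Samples missing either genotype
#' are excluded. Marginal frequencies and the number of samples carrying
#' both alleles are reported alongside.
#'
#' @param dataset a [GenotypeDataset].
#' @param effects an [annotate_coding_effects()] table.
#' @param pair character vector of two substitution labels.
#' @param cohorts named list of sample index/id vectors.
#' @param gene optional gene id disambiguating the labels.
#' @return data.frame: `cohort`, `joint_frequency`, `marginal1`,
#'   `marginal2`, `n_samples`, `n_carrying_both`.
#' @export
double_mutant_frequency <- function(dataset, effects, pair, cohorts,
                                    gene = NULL) {
  .assert(length(pair) == 2, "pair must name two substitutions")
  ns <- effects[effects$effect == "non_synonymous", , drop = FALSE]
  if (!is.null(gene)) ns <- ns[ns$gene == gene, , drop = FALSE]
  find <- function(lab) ns[ns$label == lab, , drop = FALSE]
  e1 <- find(pair[1]); e2 <- find(pair[2])
  missing_lab <- pair[c(nrow(e1) == 0, nrow(e2) == 0)]
  if (length(missing_lab)) {
    warning("substitution(s) absent from dataset: ",
            paste(missing_lab, collapse = ", "),
            "; joint frequency reported as 0")
    return(data.frame(cohort = names(cohorts), joint_frequency = 0,
                      marginal1 = NA_real_, marginal2 = NA_real_,
                      n_samples = vapply(cohorts, length, 1L),
                      n_carrying_both = 0L, stringsAsFactors = FALSE))
  }
  rows <- lapply(names(cohorts), function(cn) {
    si <- .resolve_samples(dataset, cohorts[[cn]])
    d1 <- as.vector(genotype_dosage(dataset, e1$allele[1],
                                    variants = e1$variant[1],
                                    samples = si))
    d2 <- as.vector(genotype_dosage(dataset, e2$allele[1],
                                    variants = e2$variant[1],
                                    samples = si))
    ok <- !is.na(d1) & !is.na(d2)
    data.frame(cohort = cn,
               joint_frequency = if (any(ok))
                 mean(pmin(d1[ok], d2[ok])) / 2 else NA_real_,
               marginal1 = if (any(ok)) mean(d1[ok]) / 2 else NA_real_,
               marginal2 = if (any(ok)) mean(d2[ok]) / 2 else NA_real_,
               n_samples = sum(ok),
               n_carrying_both = sum(d1[ok] > 0 & d2[ok] > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
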