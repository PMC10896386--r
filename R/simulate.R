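#' Default sampling design for simulations
#'
#' One arid-zone sampling site observed at three time points, with cohort
#' sizes mirroring a Kenyan *An. gambiae* s.l. survey in which a minority
#' *An. coluzzii* population was discovered alongside *An. arabiensis* and
#' *An. gambiae* (25, 64 and 131 mosquitoes per time point).
#'
#' @return data.frame with columns `location`, `latitude`, `longitude`,
#'   `year`, `month`, `taxon`, `n`.
#' @export
default_cohorts <- function() {
  data.frame(
    location = "Turkana", latitude = 3.717, longitude = 34.857,
    year = c(2006, 2006, 2006, 2019, 2019, 2019, 2019),
    month = c(2, 2, 2, 1, 1, 9, 9),
    taxon = c("arabiensis", "coluzzii", "gambiae",
              "arabiensis", "coluzzii", "arabiensis", "coluzzii"),
    n = c(19L, 5L, 1L, 51L, 13L, 123L, 8L),
    stringsAsFactors = FALSE)
}

#' Default resistance-allele planting plan
#'
#' Non-synonymous substitutions planted into the synthetic resistance
#' genes, at the frequencies reported for East African *An. coluzzii*:
#' Vgsc-L995F (kdr) at 62%, the coupled Vgsc-V402L + I1527T pair at 38%
#' (planted on the same simulated haplotype indicator, reflecting their
#' near-complete coupling in nature), Gste2-I114T at 67%, the Rdl 296/345
#' pair at 5%, and Ace1-G280S absent (frequency 0). `ref_codon` and
#' `alt_base` are in mRNA (sense-strand) space; `codon_pos` is the mutated
#' position within the codon.
#'
#' @return data.frame, one row per planted substitution.
#' @export
default_resistance_plan <- function() {
  data.frame(
    gene = c("Vgsc", "Vgsc", "Vgsc", "Gste2", "Rdl", "Rdl", "Ace1"),
    label = c("L995F", "V402L", "I1527T", "I114T", "A296G", "T345M", "G280S"),
    codon = c(995L, 402L, 1527L, 114L, 296L, 345L, 280L),
    ref_codon = c("CTT", "GTG", "ATA", "ATT", "GCT", "ACG", "GGT"),
    codon_pos = c(1L, 1L, 2L, 2L, 2L, 2L, 1L),
    alt_base = c("T", "C", "C", "C", "G", "T", "A"),
    freq = c(0.62, 0.38, 0.38, 0.67, 0.05, 0.05, 0),
    link_group = c(NA, "vgsc_402_1527", "vgsc_402_1527", NA,
                   "rdl_296_345", "rdl_296_345", NA),
    taxon = "coluzzii",
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every dial of the synthetic genotype generator. Defaults
#' reproduce the study conditions the package is designed around: three
#' taxa separated by fixed AIM differences, weak background
#' differentiation between temporal cohorts (FST 0.006), an introgressed
#' block at the 2L centromere segregating in *An. coluzzii* at
#' none/het/hom proportions 0.16/0.46/0.38, and resistance alleles planted
#' per [default_resistance_plan()].
#'
#' @param cohorts sampling design data.frame (see [default_cohorts()]).
#' @param contigs named integer vector of synthetic contig lengths.
#' @param n_background number of neutral background SNPs.
#' @param n_aims named integer vector: AIM sites per panel. Names follow
#'   the `"<taxonA>_vs_<taxonB>"` convention of [aim_panel()].
#' @param background_fst Balding-Nichols differentiation between
#'   geographic/temporal cohorts, in `[0, 1)`.
#' @param ancestral_maf lower/upper bounds of the uniform ancestral
#'   minor-allele-frequency distribution, in `(0, 0.5]`.
#' @param introgression_region list with `contig`, `start`, `end`
#'   (1-based inclusive): the donor-haplotype block.
#' @param introgression_proportions fractions of recipient (*coluzzii*)
#'   samples that are none/het/hom for the introgressed block; must sum
#'   to 1. Counts are apportioned exactly (largest remainder) and states
#'   assigned to samples at random.
#' @param resistance_plan data.frame per [default_resistance_plan()].
#' @param gene_models named list of [gene_model()] objects.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer RNG seed; all outputs are reproducible given it.
#' @return object of class `SimulationConfig` (a validated list).
#' @export
sim_config <- function(cohorts = default_cohorts(),
                       contigs = c(`2L` = 500000L, `2R` = 500000L,
                                   `3L` = 500000L, `3R` = 500000L,
                                   X = 200000L),
                       n_background = 4000L,
                       n_aims = c(gambcolu_vs_arabiensis = 260L,
                                  gambiae_vs_coluzzii = 160L),
                       background_fst = 0.006,
                       ancestral_maf = c(0.05, 0.5),
                       introgression_region = list(contig = "2L",
                                                   start = 1L,
                                                   end = 100000L),
                       introgression_proportions = c(none = 0.16,
                                                     het = 0.46,
                                                     hom = 0.38),
                       resistance_plan = default_resistance_plan(),
                       gene_models = default_gene_models(),
                       missing_rate = 0,
                       seed = 1L) {
  .assert(all(c("location", "year", "month", "taxon", "n") %in%
                names(cohorts)), "cohorts is missing required columns")
  .assert(all(cohorts$n >= 0), "cohort sizes must be non-negative")
  .assert(background_fst >= 0 && background_fst < 1,
          "background_fst must be in [0, 1)")
  .assert(length(ancestral_maf) == 2 && ancestral_maf[1] > 0 &&
            ancestral_maf[2] <= 0.5 && ancestral_maf[1] <= ancestral_maf[2],
          "ancestral_maf bounds must lie in (0, 0.5]")
  .assert(missing_rate >= 0 && missing_rate <= 1,
          "missing_rate must be a fraction")
  .assert(abs(sum(introgression_proportions) - 1) < 1e-9,
          "introgression proportions must sum to 1")
  .assert(all(introgression_proportions >= 0),
          "introgression proportions must be non-negative")
  .assert(introgression_region$contig %in% names(contigs) &&
            introgression_region$start >= 1 &&
            introgression_region$end <=
              contigs[[introgression_region$contig]],
          "introgression region outside simulated contigs")
  if (!is.null(resistance_plan) && nrow(resistance_plan)) {
    .assert(all(resistance_plan$gene %in% names(gene_models)),
            "resistance plan refers to unknown genes")
    .assert(all(resistance_plan$freq >= 0 & resistance_plan$freq <= 1),
            "resistance frequencies must be fractions")
    for (i in seq_len(nrow(resistance_plan))) {
      g <- gene_models[[resistance_plan$gene[i]]]
      .assert(resistance_plan$codon[i] <= n_codons(g),
              "planted codon beyond gene ", g$gene_id)
    }
  }
  structure(list(cohorts = cohorts, contigs = contigs,
                 n_background = as.integer(n_background),
                 n_aims = n_aims, background_fst = background_fst,
                 ancestral_maf = ancestral_maf,
                 introgression_region = introgression_region,
                 introgression_proportions = introgression_proportions,
                 resistance_plan = resistance_plan,
                 gene_models = gene_models,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population allele frequencies around an ancestral frequency
#' `p` with differentiation `F`: each population's frequency is
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, independently per site and population.
#' This is the minimal one-parameter model for weak background structure.
#'
#' @param ancestral_freqs vector of ancestral allele frequencies, all in
#'   (0, 1).
#' @param fst differentiation parameter in `[0, 1)`; `0` returns the
#'   ancestral frequencies unchanged for every population.
#' @param n_pops number of populations.
#' @param seed optional integer seed (deterministic output when fixed).
#' @return matrix sites x populations.
#' @export
simulate_population_frequencies <- function(ancestral_freqs, fst, n_pops,
                                            seed = NULL) {
  .assert(all(ancestral_freqs > 0 & ancestral_freqs < 1),
          "ancestral frequencies must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (fst == 0)
    return(matrix(ancestral_freqs, nrow = length(ancestral_freqs),
                  ncol = n_pops))
  .assert(fst > 0 && fst < 1, "fst must lie in [0, 1)")
  n <- length(ancestral_freqs)
  a <- ancestral_freqs * (1 - fst) / fst
  b <- (1 - ancestral_freqs) * (1 - fst) / fst
  matrix(rbeta(n * n_pops, rep(a, n_pops), rep(b, n_pops)), nrow = n)
}

#' Simulate a genotype dataset with known ground truth
#'
#' Generates a diploid [GenotypeDataset] under a [sim_config()]:
#' \itemize{
#'   \item AIM sites are fixed differences between the relevant taxa
#'     (perfectly informative before introgression planting);
#'   \item background SNPs are drawn binomially from Balding-Nichols
#'     population frequencies (populations = geographic/temporal cohorts);
#'   \item one donor haplotype is drawn for the introgression region and
#'     planted into recipient (*coluzzii*) samples at 0/1/2 copies
#'     according to the configured zygosity proportions — AIM sites in the
#'     region carry the donor taxon's diagnostic alleles, emulating
#'     adaptive introgression of a swept block;
#'   \item resistance substitutions are planted at the requested allele
#'     frequencies (rounded to the nearest achievable count; alleles are
#'     then distributed among samples at random, with linked pairs sharing
#'     one haplotype indicator);
#'   \item genotypes are masked to missing at `missing_rate`.
#' }
#'
#' @param config a [sim_config()].
#' @return object of class `SimulatedDataset`: list with elements
#'   `dataset` ([GenotypeDataset]), `truth` (list of `samples` and `loci`
#'   data.frames), `genome` (list of per-contig base vectors), `panels`
#'   (named list of [aim_panel()]s), `gene_models`, and `config`.
#' @export
simulate_genotype_dataset <- function(config) {
  .assert(inherits(config, "SimulationConfig"), "config must be a sim_config()")
  set.seed(config$seed)
  contigs <- config$contigs
  contig_names <- names(contigs)

  ## reference genome, with resistance codons planted
  genome <- lapply(contigs, function(L)
    sample(DNA_BASES4, L, replace = TRUE))
  plan <- config$resistance_plan
  res_sites <- NULL
  if (!is.null(plan) && nrow(plan)) {
    res_rows <- lapply(seq_len(nrow(plan)), function(i) {
      g <- config$gene_models[[plan$gene[i]]]
      coords <- codon_genomic_coords(g, plan$codon[i])  # translation order
      bases <- strsplit(plan$ref_codon[i], "")[[1]]
      if (g$strand == "-") bases <- .comp(bases)
      genome[[g$contig]][coords] <<- bases
      pos <- coords[plan$codon_pos[i]]
      alt_genomic <- if (g$strand == "+") plan$alt_base[i] else
        .comp(plan$alt_base[i])
      data.frame(contig = g$contig, pos = pos,
                 ref = genome[[g$contig]][pos], alt = alt_genomic,
                 plan_row = i, stringsAsFactors = FALSE)
    })
    res_sites <- do.call(rbind, res_rows)
    .assert(anyDuplicated(.key(res_sites$contig, res_sites$pos)) == 0,
            "resistance plan plants colliding positions")
  }

  ## site positions: AIMs and background, avoiding collisions
  occupied <- lapply(contig_names, function(ct)
    res_sites$pos[res_sites$contig == ct])
  names(occupied) <- contig_names
  draw_positions <- function(n_total) {
    per <- .quota_counts(contigs / sum(contigs), n_total)
    out <- NULL
    for (j in seq_along(contig_names)) {
      ct <- contig_names[j]
      if (per[j] == 0) next
      pos <- sample.int(contigs[[ct]], per[j] + length(occupied[[ct]]))
      pos <- setdiff(pos, occupied[[ct]])[seq_len(per[j])]
      occupied[[ct]] <<- c(occupied[[ct]], pos)
      out <- rbind(out, data.frame(contig = ct, pos = pos,
                                   stringsAsFactors = FALSE))
    }
    out
  }
  panel_names <- names(config$n_aims)
  aim_sites <- lapply(panel_names, function(pn)
    cbind(draw_positions(config$n_aims[[pn]]), panel = pn))
  names(aim_sites) <- panel_names
  bg_sites <- draw_positions(config$n_background)

  ## assemble variant table
  site_tab <- rbind(
    if (!is.null(res_sites))
      data.frame(contig = res_sites$contig, pos = res_sites$pos,
                 kind = "resistance", panel = NA_character_,
                 plan_row = res_sites$plan_row, stringsAsFactors = FALSE),
    do.call(rbind, lapply(aim_sites, function(s)
      data.frame(contig = s$contig, pos = s$pos, kind = "aim",
                 panel = s$panel, plan_row = NA_integer_,
                 stringsAsFactors = FALSE))),
    data.frame(contig = bg_sites$contig, pos = bg_sites$pos,
               kind = "background", panel = NA_character_,
               plan_row = NA_integer_, stringsAsFactors = FALSE))
  ord <- order(match(site_tab$contig, contig_names), site_tab$pos)
  site_tab <- site_tab[ord, , drop = FALSE]
  rownames(site_tab) <- NULL
  nv <- nrow(site_tab)
  ref <- mapply(function(ct, p) genome[[ct]][p], site_tab$contig,
                site_tab$pos, USE.NAMES = FALSE)
  alt <- character(nv)
  is_res <- site_tab$kind == "resistance"
  if (any(is_res))
    alt[is_res] <- res_sites$alt[match(site_tab$plan_row[is_res],
                                       res_sites$plan_row)]
  need_alt <- !is_res
  alt[need_alt] <- vapply(ref[need_alt], function(r)
    sample(setdiff(DNA_BASES4, r), 1L), "")
  variants <- data.frame(contig = site_tab$contig, pos = site_tab$pos,
                         ref = ref, alt = alt, pass = TRUE,
                         stringsAsFactors = FALSE)

  ## samples
  co <- config$cohorts
  samples <- co[rep(seq_len(nrow(co)), co$n),
                setdiff(names(co), "n"), drop = FALSE]
  rownames(samples) <- NULL
  ns <- nrow(samples)
  taxon_truth <- samples$taxon
  samples_meta <- data.frame(sample_id = sprintf("KE-%04d", seq_len(ns)),
                             location = samples$location,
                             latitude = samples$latitude %||% NA_real_,
                             longitude = samples$longitude %||% NA_real_,
                             year = as.integer(samples$year),
                             month = as.integer(samples$month),
                             taxon = NA_character_,
                             stringsAsFactors = FALSE)
  pop <- as.integer(factor(paste(samples$location, samples$year,
                                 samples$month)))
  n_pops <- max(pop)

  gt <- array(0L, dim = c(nv, ns, 2L))

  ## background sites: Balding-Nichols + binomial sampling
  bg_idx <- which(site_tab$kind == "background")
  p_anc <- runif(length(bg_idx), config$ancestral_maf[1],
                 config$ancestral_maf[2])
  pmat <- simulate_population_frequencies(p_anc, config$background_fst,
                                          n_pops)
  for (j in seq_len(n_pops)) {
    sj <- which(pop == j)
    if (!length(sj)) next
    d <- matrix(rbinom(length(bg_idx) * length(sj), 2L,
                       rep(pmat[, j], length(sj))),
                nrow = length(bg_idx))
    gt[bg_idx, sj, 1] <- as.integer(d == 2L)
    gt[bg_idx, sj, 2] <- as.integer(d >= 1L)
  }

  ## AIM sites: fixed differences between taxa
  panels <- list()
  for (pn in panel_names) {
    taxa <- strsplit(pn, "_vs_", fixed = TRUE)[[1]]
    rows <- which(site_tab$kind == "aim" & site_tab$panel == pn)
    # randomly orient which diagnostic allele is REF
    a_is_ref <- sample(c(TRUE, FALSE), length(rows), replace = TRUE)
    allele_a <- ifelse(a_is_ref, variants$ref[rows], variants$alt[rows])
    allele_b <- ifelse(a_is_ref, variants$alt[rows], variants$ref[rows])
    ia <- as.integer(!a_is_ref)   # allele index of diagnostic-A base
    ib <- 1L - ia
    in_a <- .taxon_in_group(taxon_truth, taxa[1])
    in_b <- .taxon_in_group(taxon_truth, taxa[2])
    gt[rows, in_a, 1] <- ia; gt[rows, in_a, 2] <- ia
    gt[rows, in_b, 1] <- ib; gt[rows, in_b, 2] <- ib
    other <- which(!(seq_len(ns) %in% c(in_a, in_b)))
    if (length(other)) {   # taxa outside the panel: unstructured 50/50
      d <- matrix(rbinom(length(rows) * length(other), 2L, 0.5),
                  nrow = length(rows))
      gt[rows, other, 1] <- as.integer(d == 2L)
      gt[rows, other, 2] <- as.integer(d >= 1L)
    }
    panels[[pn]] <- aim_panel(
      data.frame(contig = site_tab$contig[rows], pos = site_tab$pos[rows],
                 allele_a = allele_a, allele_b = allele_b,
                 stringsAsFactors = FALSE),
      taxon_a = taxa[1], taxon_b = taxa[2], name = pn)
  }

  ## resistance sites: exact-count allele planting in the target taxon
  planted_freq <- rep(NA_real_, nrow(plan %||% data.frame()))
  if (!is.null(plan) && nrow(plan)) {
    groups <- ifelse(is.na(plan$link_group),
                     paste0(".solo", seq_len(nrow(plan))), plan$link_group)
    for (grp in unique(groups)) {
      rows_in_plan <- which(groups == grp)
      target <- which(taxon_truth == plan$taxon[rows_in_plan[1]])
      n_t <- length(target)
      f <- plan$freq[rows_in_plan[1]]
      if (n_t == 0 || f == 0) { planted_freq[rows_in_plan] <- 0; next }
      k <- round(f * 2 * n_t)
      if (k == 0 && f > 0) {
        warning(sprintf(
          "target frequency %.3g for %s not achievable with %d samples; rounded to 0",
          f, paste(plan$label[rows_in_plan], collapse = "+"), n_t))
      }
      alleles <- sample(c(rep(1L, k), rep(0L, 2L * n_t - k)))
      dos <- alleles[seq(1L, 2L * n_t, by = 2L)] +
        alleles[seq(2L, 2L * n_t, by = 2L)]
      for (i in rows_in_plan) {
        vrow <- which(site_tab$plan_row == i)
        gt[vrow, target, 1] <- as.integer(dos == 2L)
        gt[vrow, target, 2] <- as.integer(dos >= 1L)
        planted_freq[i] <- k / (2 * n_t)
      }
    }
  }

  ## introgression: one donor haplotype planted into recipient samples
  region <- config$introgression_region
  donor_panel <- "gambiae_vs_coluzzii"
  intro_state <- rep("none", ns)
  if (donor_panel %in% panel_names) {
    recip <- which(taxon_truth == "coluzzii")
    if (length(recip)) {
      counts <- .quota_counts(config$introgression_proportions,
                              length(recip))
      states <- sample(rep(c("none", "het", "hom"), counts))
      intro_state[recip] <- states
      in_region <- site_tab$contig == region$contig &
        site_tab$pos >= region$start & site_tab$pos <= region$end
      # donor haplotype: diagnostic donor (taxon A = gambiae) alleles at
      # panel sites, one random draw from the ancestral frequency at
      # background sites
      hap_rows <- integer(0); hap_allele <- integer(0)
      pr <- which(in_region & site_tab$kind == "aim" &
                    site_tab$panel == donor_panel)
      if (length(pr)) {
        pan <- panels[[donor_panel]]
        m <- match(.key(site_tab$contig[pr], site_tab$pos[pr]),
                   .key(pan$contig, pan$pos))
        donor_allele <- as.integer(pan$allele_a[m] != variants$ref[pr])
        hap_rows <- c(hap_rows, pr); hap_allele <- c(hap_allele, donor_allele)
      } else if (any(intro_state != "none")) {
        warning("no donor-panel AIM sites fall inside the introgression region")
      }
      br <- which(in_region & site_tab$kind == "background")
      if (length(br)) {
        p_here <- p_anc[match(br, bg_idx)]
        hap_rows <- c(hap_rows, br)
        hap_allele <- c(hap_allele, rbinom(length(br), 1L, p_here))
      }
      if (length(hap_rows)) {
        het <- recip[states == "het"]; hom <- recip[states == "hom"]
        if (length(het))
          gt[hap_rows, het, 2] <- matrix(hap_allele, length(hap_rows),
                                         length(het))
        if (length(hom)) {
          gt[hap_rows, hom, 1] <- matrix(hap_allele, length(hap_rows),
                                         length(hom))
          gt[hap_rows, hom, 2] <- matrix(hap_allele, length(hap_rows),
                                         length(hom))
        }
      }
    }
  }

  ## missingness
  if (config$missing_rate > 0) {
    miss <- matrix(runif(nv * ns) < config$missing_rate, nv, ns)
    idx <- which(miss, arr.ind = TRUE)
    if (nrow(idx)) {
      gt[cbind(idx, 1L)] <- -1L
      gt[cbind(idx, 2L)] <- -1L
    }
  }

  mask <- GenomicRanges::GRanges(
    contig_names, IRanges::IRanges(1L, unname(contigs)))
  dataset <- genotype_dataset(gt, variants, samples_meta, contigs, mask)

  truth_samples <- data.frame(sample_id = samples_meta$sample_id,
                              taxon = taxon_truth,
                              introgression_state = intro_state,
                              stringsAsFactors = FALSE)
  truth_loci <- data.frame(
    contig = site_tab$contig, pos = site_tab$pos, kind = site_tab$kind,
    panel = site_tab$panel,
    gene = ifelse(is.na(site_tab$plan_row), NA_character_,
                  plan$gene[site_tab$plan_row]),
    label = ifelse(is.na(site_tab$plan_row), NA_character_,
                   plan$label[site_tab$plan_row]),
    target_freq = ifelse(is.na(site_tab$plan_row), NA_real_,
                         plan$freq[site_tab$plan_row]),
    planted_freq = ifelse(is.na(site_tab$plan_row), NA_real_,
                          planted_freq[site_tab$plan_row]),
    stringsAsFactors = FALSE)

  structure(list(dataset = dataset,
                 truth = list(samples = truth_samples, loci = truth_loci),
                 genome = genome, panels = panels,
                 gene_models = config$gene_models, config = config),
            class = "SimulatedDataset")
}

# membership of a taxon label in a (possibly compound) panel group such as
# "gambcolu" = gambiae + coluzzii
.taxon_in_group <- function(taxa, group) {
  members <- switch(group,
                    gambcolu = c("gambiae", "coluzzii"),
                    group)
  which(taxa %in% members)
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat("<SimulatedDataset>\n")
  print(x$dataset)
  tab <- table(x$truth$samples$taxon)
  cat("  truth taxa:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
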