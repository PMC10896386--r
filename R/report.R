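#' Configuration for a full surveillance report
#'
#' Bundles the inputs and stage parameters consumed by [run_report()].
#' Either `bundle` (a directory or `FixtureBundle` from
#' [write_fixture_bundle()]) or the individual file paths must be given.
#' Optional stages (`structure`, `karyotype`, `resistance`) are skipped
#' when set to `NULL`.
#'
#' @param out_dir output directory for the report artifacts.
#' @param bundle fixture bundle directory or object.
#' @param vcf,metadata,mask,aims,gff3,fasta individual input paths
#'   (overridden by `bundle`).
#' @param thresholds [aim_thresholds()] for taxon classification.
#' @param introgression_region focal region for introgression calls
#'   (`NULL` skips the stage).
#' @param structure list(`contigs`, `n_snps`, `maf_min`, `k`) for the
#'   PCA/NJT stage.
#' @param karyotype list(`region`, `min_snps`) for inversion-karyotype
#'   clustering (restricted to *coluzzii* samples).
#' @param resistance list(`pairs` = list of label pairs,
#'   `retention`) for the resistance stage; requires `gff3` + `fasta`.
#' @param diversity list(`per`) denominator convention.
#' @param min_cohort_size cohorts below this size are excluded from
#'   diversity/FST (composition always reports everything).
#' @param seed integer seed controlling every stochastic step.
#' @return list of class `ReportConfig`.
#' @export
report_config <- function(out_dir, bundle = NULL, vcf = NULL,
                          metadata = NULL, mask = NULL, aims = NULL,
                          gff3 = NULL, fasta = NULL,
                          thresholds = aim_thresholds(),
                          introgression_region = list(contig = "2L",
                                                      start = 1L,
                                                      end = 100000L),
                          structure = list(contigs = c("3L", "3R"),
                                           n_snps = 2000L,
                                           maf_min = 0.002, k = 6L),
                          karyotype = list(region = list(contig = "2L",
                                                         start = 1L,
                                                         end = 100000L),
                                           min_snps = 50L),
                          resistance = list(pairs = list(c("V402L",
                                                           "I1527T")),
                                            retention = 0.05),
                          diversity = list(per = "mask_bases"),
                          min_cohort_size = 8L, seed = 1L) {
  if (!is.null(bundle)) {
    if (is.character(bundle)) {
      d <- bundle
      vcf <- file.path(d, "genotypes.vcf.gz")
      metadata <- file.path(d, "metadata.tsv")
      mask <- file.path(d, "mask.bed")
      aims <- file.path(d, "aims.tsv")
      gff3 <- file.path(d, "genes.gff3")
      fasta <- file.path(d, "reference.fa")
    } else {
      vcf <- bundle$vcf; metadata <- bundle$metadata
      mask <- bundle$mask; aims <- bundle$aims
      gff3 <- bundle$gff3; fasta <- bundle$fasta
    }
  }
  for (p in c(vcf, metadata, aims))
    .assert(file.exists(p), "input file not found: ", p)
  structure(list(out_dir = out_dir, vcf = vcf, metadata = metadata,
                 mask = mask, aims = aims, gff3 = gff3, fasta = fasta,
                 thresholds = thresholds,
                 introgression_region = introgression_region,
                 structure = structure, karyotype = karyotype,
                 resistance = resistance, diversity = diversity,
                 min_cohort_size = min_cohort_size,
                 seed = as.integer(seed)),
            class = "ReportConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

#' Run the full surveillance pipeline and write a consolidated report
#'
#' Executes classify -> cohorts -> diversity -> FST -> structure ->
#' karyotype -> resistance on the configured inputs, writing TSV
#' artifacts, a newick tree, and a machine-readable `summary.json`
#' (config snapshot, seed and headline numbers included). A failure in
#' any stage aborts with a stage-named diagnostic. Outputs contain no
#' timestamps, so a re-run with the same config and seed is
#' byte-identical.
#'
#' @param config a [report_config()].
#' @return list of class `ReportBundle` with all in-memory tables and
#'   the output paths, invisibly.
#' @export
run_report <- function(config) {
  .assert(inherits(config, "ReportConfig"), "config must be a report_config()")
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  dataset <- .stage("load", read_genotype_dataset(config$vcf,
                                                  config$metadata,
                                                  config$mask))
  panels <- .stage("load", read_aim_panels(config$aims))

  ## taxon classification
  aim_results <- .stage("classify",
                        assign_taxa(dataset, panels, config$thresholds))
  intro <- NULL
  if (!is.null(config$introgression_region) &&
      "gambiae_vs_coluzzii" %in% names(panels)) {
    colu <- which(aim_results$taxon_call == "coluzzii")
    if (length(colu))
      intro <- .stage("introgression", introgression_profile(
        dataset, panels$gambiae_vs_coluzzii,
        region = config$introgression_region, samples = colu))
  }
  aim_out <- aim_results
  if (!is.null(intro)) {
    m <- match(aim_out$sample_id, intro$calls$sample_id)
    aim_out$introgression_state <- intro$calls$state[m]
  }
  paths$aim_results <- .write_tsv(aim_out, config$out_dir,
                                  "aim_results.tsv")

  ## cohorts and composition
  cohort_table <- .stage("cohorts",
                         build_cohorts(dataset$samples, aim_results,
                                       config$min_cohort_size))
  comp <- .stage("cohorts", taxon_composition(cohort_table))
  paths$cohorts <- .write_tsv(cohort_table, config$out_dir, "cohorts.tsv")
  comp_out <- comp$composition
  comp_out$pct <- round(comp_out$pct, 1)   # display rounding only
  paths$composition <- .write_tsv(comp_out, config$out_dir,
                                  "composition.tsv")

  groups <- cohort_sample_groups(dataset$samples, aim_results,
                                 config$min_cohort_size)

  ## diversity
  diversity <- NULL
  if (length(groups)) {
    diversity <- .stage("diversity", do.call(rbind, lapply(
      names(groups), function(g)
        diversity_stats(dataset, groups[[g]],
                        per = config$diversity$per, cohort_id = g))))
    paths$diversity <- .write_tsv(diversity, config$out_dir,
                                  "diversity.tsv")
  }

  ## structure SNP selection, FST, PCA, NJT
  fst <- NULL; pca <- NULL; tree <- NULL; selection <- NULL
  if (!is.null(config$structure)) {
    st <- config$structure
    selection <- .stage("structure", select_structure_snps(
      dataset, contigs = st$contigs, n_target = st$n_snps,
      maf_min = st$maf_min))
    if (length(groups) >= 2) {
      fst <- .stage("fst", fst_matrix(dataset, groups, selection$idx))
      paths$fst <- .write_tsv(fst$pairs, config$out_dir, "fst.tsv")
    }
    pca <- .stage("structure", pca_dosage(
      dataset, selection, k = min(st$k, n_samples(dataset) - 1L)))
    coords <- data.frame(sample_id = rownames(pca$coords), pca$coords,
                         stringsAsFactors = FALSE)
    paths$pca <- .write_tsv(coords, config$out_dir, "pca_coords.tsv")
    tree <- .stage("structure", nj_tree(dataset, selection))
    paths$tree <- file.path(config$out_dir, "tree.nwk")
    writeLines(tree$newick, paths$tree)
  }

  ## inversion karyotype (coluzzii samples)
  karyo <- NULL
  if (!is.null(config$karyotype)) {
    colu <- which(aim_results$taxon_call == "coluzzii")
    if (length(colu) >= 4) {
      karyo <- .stage("karyotype", karyotype_pca(
        dataset, config$karyotype$region, samples = colu,
        min_snps = config$karyotype$min_snps))
      kt <- data.frame(sample_id = names(karyo$cluster),
                       cluster = karyo$cluster, stringsAsFactors = FALSE)
      paths$karyotype <- .write_tsv(kt, config$out_dir, "karyotype.tsv")
    }
  }

  ## resistance
  res_tab <- NULL; doubles <- NULL
  if (!is.null(config$resistance) && !is.null(config$gff3) &&
      !is.null(config$fasta) && file.exists(config$gff3) &&
      file.exists(config$fasta)) {
    models <- .stage("resistance", read_gene_models_gff3(config$gff3))
    effects <- .stage("resistance", annotate_coding_effects(
      dataset, models, config$fasta))
    if (length(groups)) {
      res_tab <- .stage("resistance", substitution_frequencies(
        dataset, effects, groups,
        retention = config$resistance$retention %||% 0.05))
      paths$resistance <- .write_tsv(res_tab, config$out_dir,
                                     "resistance.tsv")
      for (pair in config$resistance$pairs %||% list()) {
        dd <- .stage("resistance", double_mutant_frequency(
          dataset, effects, pair, groups))
        dd$pair <- paste(pair, collapse = "+")
        doubles <- rbind(doubles, dd)
      }
      if (!is.null(doubles))
        paths$double_mutants <- .write_tsv(doubles, config$out_dir,
                                           "double_mutants.tsv")
    }
  }

  summary <- list(
    seed = config$seed,
    n_samples = n_samples(dataset),
    n_variants = n_variants(dataset),
    taxon_totals = as.list(comp$taxon_totals),
    n_cohorts = nrow(cohort_table),
    introgression_state_pct = if (!is.null(intro))
      as.list(intro$state_pct) else NULL,
    retained_substitutions = if (!is.null(res_tab))
      sort(unique(paste(res_tab$gene, res_tab$substitution))) else NULL)
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(structure(list(dataset = dataset, aim_results = aim_out,
                           cohort_table = cohort_table,
                           composition = comp, diversity = diversity,
                           fst = fst, pca = pca, tree = tree,
                           selection = selection, karyotype = karyo,
                           introgression = intro, resistance = res_tab,
                           double_mutants = doubles, paths = paths),
                      class = "ReportBundle"))
}
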