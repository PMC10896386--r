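#' Write a simulated dataset to a fixture bundle on disk
#'
#' Serialises a [simulate_genotype_dataset()] result to
#' standards-conformant files: VCF 4.2 (diploid GT), reference FASTA
#' consistent with the VCF REF alleles, GFF3 gene models, BED
#' accessibility mask (0-based half-open), TSV sample metadata, AIM panel
#' TSV and truth tables. Reading the bundle back with
#' [read_fixture_bundle()] reproduces the in-memory dataset exactly.
#'
#' @param sim a `SimulatedDataset`.
#' @param out_dir output directory (created if absent).
#' @return object of class `FixtureBundle`: named list of file paths.
#' @export
write_fixture_bundle <- function(sim, out_dir) {
  .assert(inherits(sim, "SimulatedDataset"), "sim must be a SimulatedDataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset

  # REF alleles must agree with the reference sequence
  ref_in_fasta <- mapply(function(ct, p) sim$genome[[ct]][p],
                         ds$variants$contig, ds$variants$pos)
  .assert(all(ref_in_fasta == ds$variants$ref),
          "REF allele mismatch between VCF and FASTA")

  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf.gz"),
    metadata = file.path(out_dir, "metadata.tsv"),
    aims = file.path(out_dir, "aims.tsv"),
    gff3 = file.path(out_dir, "genes.gff3"),
    fasta = file.path(out_dir, "reference.fa"),
    mask = file.path(out_dir, "mask.bed"),
    truth_samples = file.path(out_dir, "truth_samples.tsv"),
    truth_loci = file.path(out_dir, "truth_loci.tsv"))

  .write_vcf(ds, paths$vcf)
  write.table(ds$samples, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_aim_panels(sim$panels, paths$aims)
  write_gene_models_gff3(sim$gene_models, paths$gff3)
  seqs <- Biostrings::DNAStringSet(vapply(sim$genome, paste,
                                          collapse = "", ""))
  names(seqs) <- names(sim$genome)
  Biostrings::writeXStringSet(seqs, paths$fasta)
  rtracklayer::export(ds$mask, paths$mask, format = "bed")
  write.table(sim$truth$samples, paths$truth_samples, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$loci, paths$truth_loci, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  structure(paths, class = "FixtureBundle")
}

# minimal VCF 4.2 emitter (GT-only FORMAT) through vcfR
.write_vcf <- function(ds, path) {
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", names(ds$contigs),
                    unname(ds$contigs)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- cbind(CHROM = ds$variants$contig,
               POS = as.character(ds$variants$pos),
               ID = ".", REF = ds$variants$ref, ALT = ds$variants$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  a1 <- ds$gt[, , 1]; a2 <- ds$gt[, , 2]
  gstr <- matrix(paste(ifelse(a1 < 0L, ".", a1),
                       ifelse(a2 < 0L, ".", a2), sep = "/"),
                 nrow = nrow(a1))
  colnames(gstr) <- ds$samples$sample_id
  gt <- cbind(FORMAT = "GT", gstr)
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a genotype dataset from VCF + metadata (+ optional mask)
#'
#' Loads diploid GT calls into the package's array data model. Missing
#' and half-called genotypes (`./.`, `0/.`) are stored as fully missing
#' `(-1, -1)`; phase separators are accepted but phase is ignored.
#' Multiallelic sites are retained (downstream analyses filter to
#' biallelic sites where required). The `pass` flag of each variant is
#' its membership in the accessibility mask (all-pass when no mask is
#' given).
#'
#' @param vcf_path VCF file (optionally bgzipped/gzipped).
#' @param metadata_path TSV with header
#'   `sample_id, location, latitude, longitude, year, month, taxon`;
#'   every VCF sample must be present.
#' @param mask_path optional BED file of accessible intervals.
#' @return a [GenotypeDataset].
#' @export
read_genotype_dataset <- function(vcf_path, metadata_path,
                                  mask_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-variant VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- data.frame(contig = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         pass = TRUE, stringsAsFactors = FALSE)
  gt_raw <- v@gt[, -1, drop = FALSE]
  fmt <- v@gt[, 1]
  .assert(all(startsWith(fmt, "GT")), "FORMAT must begin with GT")
  g <- sub(":.*", "", gt_raw)
  a1 <- sub("[/|].*", "", g)
  a2 <- sub(".*[/|]", "", g)
  half <- a1 == "." | a2 == "." | is.na(g)
  a1i <- suppressWarnings(as.integer(a1)); a1i[half] <- -1L
  a2i <- suppressWarnings(as.integer(a2)); a2i[half] <- -1L
  nv <- nrow(variants); ns <- ncol(gt_raw)
  gt <- array(c(a1i, a2i), dim = c(nv, ns, 2L))

  metadata <- read_sample_metadata(metadata_path)
  vcf_samples <- colnames(gt_raw)
  m <- match(vcf_samples, metadata$sample_id)
  .assert(!anyNA(m), "VCF samples absent from metadata: ",
          paste(vcf_samples[is.na(m)], collapse = ", "))
  samples <- metadata[m, , drop = FALSE]
  rownames(samples) <- NULL

  contigs <- .contigs_from_vcf_meta(v@meta)
  if (!length(contigs)) {
    contigs <- tapply(variants$pos, variants$contig, max)
    contigs <- setNames(as.integer(contigs), names(contigs))
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- rtracklayer::import(mask_path, format = "bed")
    vr <- GenomicRanges::GRanges(variants$contig,
                                 IRanges::IRanges(variants$pos,
                                                  variants$pos))
    variants$pass <- GenomicRanges::countOverlaps(vr, mask) > 0
  }
  genotype_dataset(gt, variants, samples, contigs, mask)
}

.contigs_from_vcf_meta <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (!length(lines)) return(integer(0))
  ids <- sub(".*ID=([^,>]+).*", "\\1", lines)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1",
                                          lines)))
  setNames(lens, ids)
}

#' Read sample metadata TSV
#'
#' @param path TSV file with a `sample_id` column.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   comment.char = "#")
  .assert("sample_id" %in% names(md), "metadata must have sample_id")
  .assert(anyDuplicated(md$sample_id) == 0, "duplicate sample ids in metadata")
  if (!is.null(md$taxon)) md$taxon <- as.character(md$taxon)
  for (col in intersect(c("year", "month"), names(md)))
    md[[col]] <- as.integer(md[[col]])
  md
}

#' Read / write AIM panels
#'
#' The on-disk format is a single TSV with header
#' `panel, contig, position, allele_a, allele_b`; panel names follow the
#' `"<A>_vs_<B>"` convention from which the two taxa are recovered.
#'
#' @param path TSV file.
#' @return `read_aim_panels()`: named list of [aim_panel()] objects.
#' @export
read_aim_panels <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  .assert(all(c("panel", "contig", "position", "allele_a", "allele_b")
              %in% names(tab)), "malformed AIM panel file")
  out <- lapply(split(tab, tab$panel), function(p) {
    taxa <- strsplit(p$panel[1], "_vs_", fixed = TRUE)[[1]]
    .assert(length(taxa) == 2, "panel name must be <taxonA>_vs_<taxonB>")
    p <- p[order(match(p$contig, unique(p$contig)), p$position), ]
    aim_panel(data.frame(contig = p$contig, pos = p$position,
                         allele_a = p$allele_a, allele_b = p$allele_b,
                         stringsAsFactors = FALSE),
              taxon_a = taxa[1], taxon_b = taxa[2], name = p$panel[1])
  })
  out
}

#' @rdname read_aim_panels
#' @param panels named list of [aim_panel()] objects.
#' @export
write_aim_panels <- function(panels, path) {
  tab <- do.call(rbind, lapply(panels, function(p)
    data.frame(panel = attr(p, "panel_name"), contig = p$contig,
               position = p$pos, allele_a = p$allele_a,
               allele_b = p$allele_b, stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fixture bundle back into memory
#'
#' @param bundle a `FixtureBundle` (or a directory written by
#'   [write_fixture_bundle()]).
#' @return list with `dataset`, `panels`, `gene_models`, `genome`
#'   (a `DNAStringSet`), and `truth`.
#' @export
read_fixture_bundle <- function(bundle) {
  if (is.character(bundle) && length(bundle) == 1 && dir.exists(bundle)) {
    d <- bundle
    bundle <- list(vcf = file.path(d, "genotypes.vcf.gz"),
                   metadata = file.path(d, "metadata.tsv"),
                   aims = file.path(d, "aims.tsv"),
                   gff3 = file.path(d, "genes.gff3"),
                   fasta = file.path(d, "reference.fa"),
                   mask = file.path(d, "mask.bed"),
                   truth_samples = file.path(d, "truth_samples.tsv"),
                   truth_loci = file.path(d, "truth_loci.tsv"))
  }
  dataset <- read_genotype_dataset(bundle$vcf, bundle$metadata,
                                   bundle$mask)
  truth <- list()
  if (file.exists(bundle$truth_samples))
    truth$samples <- read.table(bundle$truth_samples, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  if (file.exists(bundle$truth_loci))
    truth$loci <- read.table(bundle$truth_loci, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "")
  list(dataset = dataset,
       panels = read_aim_panels(bundle$aims),
       gene_models = read_gene_models_gff3(bundle$gff3),
       genome = Biostrings::readDNAStringSet(bundle$fasta),
       truth = truth)
}
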