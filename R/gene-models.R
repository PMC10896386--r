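#' Gene model for coding-effect annotation
#'
#' A minimal transcript model: ordered CDS intervals on one contig and
#' strand, plus a codon-numbering offset so that community substitution
#' labels can be reproduced regardless of which transcript the numbering
#' was derived from.
#'
#' @param gene_id gene identifier (e.g. `"Vgsc"`).
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame with columns `start`, `end` (1-based inclusive,
#'   genomic ascending order, non-overlapping).
#' @param offset integer added to the internal codon number when labelling
#'   substitutions (default 0).
#' @return object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, contig, strand, cds, offset = 0L) {
  .assert(strand %in% c("+", "-"), "strand must be + or -")
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  .assert(all(cds$end >= cds$start), "invalid CDS interval")
  if (nrow(cds) > 1)
    .assert(all(cds$start[-1] > cds$end[-nrow(cds)]), "overlapping CDS")
  len <- sum(cds$end - cds$start + 1L)
  .assert(len %% 3L == 0L, gene_id, ": CDS length not a multiple of 3")
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 cds = cds, offset = as.integer(offset), cds_length = len),
            class = "GeneModel")
}

#' @rdname gene_model
#' @param gene a `GeneModel`.
#' @export
n_codons <- function(gene) gene$cds_length %/% 3L

# exons in transcription order (minus strand: descending genomic)
.tx_exons <- function(gene) {
  if (gene$strand == "+") gene$cds else gene$cds[rev(seq_len(nrow(gene$cds))), ]
}

#' Map CDS coordinates to genomic coordinates
#'
#' @param gene a [gene_model()].
#' @param cds_pos integer vector of 1-based positions along the spliced CDS
#'   (in translation order).
#' @return integer vector of genomic positions.
#' @export
cds_to_genomic <- function(gene, cds_pos) {
  .assert(all(cds_pos >= 1 & cds_pos <= gene$cds_length), "CDS position out of range")
  ex <- .tx_exons(gene)
  w <- ex$end - ex$start + 1L
  cum <- cumsum(w)
  idx <- findInterval(cds_pos - 1L, c(0L, cum), rightmost.closed = FALSE)
  within <- cds_pos - c(0L, cum)[idx]   # 1-based offset within exon
  if (gene$strand == "+") ex$start[idx] + within - 1L
  else ex$end[idx] - within + 1L
}

#' Map genomic coordinates to CDS coordinates
#'
#' @param gene a [gene_model()].
#' @param pos integer vector of genomic positions.
#' @return integer vector of CDS positions (translation order); `NA` for
#'   positions outside the CDS.
#' @export
genomic_to_cds <- function(gene, pos) {
  ex <- .tx_exons(gene)
  w <- ex$end - ex$start + 1L
  before <- c(0L, cumsum(w))[seq_len(nrow(ex))]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    inside <- pos >= ex$start[i] & pos <= ex$end[i]
    if (!any(inside)) next
    out[inside] <- if (gene$strand == "+")
      before[i] + (pos[inside] - ex$start[i]) + 1L
    else before[i] + (ex$end[i] - pos[inside]) + 1L
  }
  out
}

#' Genomic coordinates of one codon
#'
#' @param gene a [gene_model()].
#' @param codon internal codon number (1-based, before `offset`).
#' @return integer vector of the three genomic positions in translation
#'   order (descending for minus-strand genes).
#' @export
codon_genomic_coords <- function(gene, codon) {
  cds_to_genomic(gene, (3L * codon - 2L):(3L * codon))
}

#' Default synthetic gene models for the four resistance genes
#'
#' Compact stand-ins for the insecticide-resistance target genes (Vgsc,
#' Gste2, Rdl, Ace1) used by the simulator and annotation examples. They
#' are synthetic: coordinates live on the simulator's contigs and CDS
#' lengths are just large enough to contain the community codon numbers of
#' interest (Vgsc 402/995/1527, Gste2 114, Rdl 296/345, Ace1 280), with
#' codon numbering offset 0. Gste2 is placed on the minus strand to
#' exercise strand-aware annotation.
#'
#' @return named list of [gene_model()] objects.
#' @export
default_gene_models <- function() {
  list(
    Vgsc = gene_model("Vgsc", "2L", "+",
                      data.frame(start = c(250001L, 251001L),
                                 end = c(250600L, 254984L))),
    Rdl = gene_model("Rdl", "2L", "+",
                     data.frame(start = 300001L, end = 301200L)),
    Ace1 = gene_model("Ace1", "2R", "+",
                      data.frame(start = 100001L, end = 100900L)),
    Gste2 = gene_model("Gste2", "3R", "-",
                       data.frame(start = 200001L, end = 200720L))
  )
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/CDS features with phase, suitable for round-tripping
#' through [read_gene_models_gff3()].
#'
#' @param models named list of [gene_model()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  rows <- lapply(models, function(g) {
    ex <- .tx_exons(g)
    w <- ex$end - ex$start + 1L
    before <- c(0L, cumsum(w))[seq_len(nrow(ex))]
    phase <- as.integer((3L - before %% 3L) %% 3L)
    span <- c(min(g$cds$start), max(g$cds$end))
    data.frame(
      contig = g$contig,
      type = c("gene", "mRNA", rep("CDS", nrow(ex))),
      start = c(span[1], span[1], ex$start),
      end = c(span[2], span[2], ex$end),
      strand = g$strand,
      phase = c(NA_integer_, NA_integer_, phase),
      ID = c(g$gene_id, paste0(g$gene_id, ".t1"),
             paste0(g$gene_id, ".cds", seq_len(nrow(ex)))),
      Parent = c(NA_character_, g$gene_id,
                 rep(paste0(g$gene_id, ".t1"), nrow(ex))),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  attrs <- ifelse(is.na(tab$Parent), paste0("ID=", tab$ID),
                  paste0("ID=", tab$ID, ";Parent=", tab$Parent))
  lines <- sprintf("%s\taimpop\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   tab$contig, tab$type, tab$start, tab$end, tab$strand,
                   ifelse(is.na(tab$phase), ".", as.character(tab$phase)),
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reconstructs [gene_model()] objects from gene/mRNA/CDS features.
#' Codon-numbering offsets can be supplied per gene (they are not a GFF3
#' concept).
#'
#' @param path GFF3 file.
#' @param offsets optional named integer vector of codon offsets by gene id.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models_gff3 <- function(path, offsets = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gff)
  is_cds <- md$type == "CDS"
  parent <- vapply(md$Parent[is_cds], function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  mrna <- md$ID[md$type == "mRNA"]
  mrna_parent <- vapply(md$Parent[md$type == "mRNA"], function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  gene_of_tx <- setNames(mrna_parent, mrna)
  cds_gene <- unname(gene_of_tx[parent])
  cds_gene[is.na(cds_gene)] <- parent[is.na(cds_gene)]  # CDS direct on gene
  out <- list()
  for (gid in unique(cds_gene)) {
    sel <- which(is_cds)[cds_gene == gid]
    out[[gid]] <- gene_model(
      gid,
      as.character(GenomicRanges::seqnames(gff))[sel][1],
      as.character(BiocGenerics::strand(gff))[sel][1],
      data.frame(start = BiocGenerics::start(gff)[sel],
                 end = BiocGenerics::end(gff)[sel]),
      offset = if (!is.null(offsets) && gid %in% names(offsets))
        offsets[[gid]] else 0L)
  }
  out
}
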