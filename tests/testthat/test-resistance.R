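# tiny plus-strand gene on a 60 bp contig: CDS 10..27 (6 codons)
tiny_gene_setup <- function() {
  seq <- strsplit(paste0("AAAAAAAAA",          # 1-9 upstream
                         "ATGCTTGGTATTACGTAA", # 10-27 CDS: M L G I T *
                         paste(rep("A", 33), collapse = "")), "")[[1]]
  genome <- list(chr = seq)
  gene <- gene_model("toy", "chr", "+",
                     data.frame(start = 10L, end = 27L))
  list(genome = genome, gene = gene)
}

test_that("coding effects are annotated with correct labels, synonymy and strand", {
  x <- tiny_gene_setup()
  dos <- matrix(1, 4, 2)
  ds <- manual_dataset(dos, contig = "chr",
                       pos = c(13L, 18L, 19L, 40L),
                       ref = c("C", "T", "A", "A"),
                       alt = c("T", "A", "G", "G"))
  eff <- annotate_coding_effects(ds, list(toy = x$gene), x$genome)
  # codon 2 CTT -> TTT : L2F
  expect_equal(eff$label[eff$variant == 1], "L2F")
  expect_equal(eff$effect[eff$variant == 1], "non_synonymous")
  # codon 3 GGT -> GGA : synonymous third position
  expect_equal(eff$effect[eff$variant == 2], "synonymous")
  # codon 4 ATT -> GTT : I4V
  expect_equal(eff$label[eff$variant == 3], "I4V")
  # outside any CDS
  expect_equal(eff$effect[eff$variant == 4], "non_coding")
})

test_that("minus-strand annotation mirrors the plus-strand construction", {
  x <- tiny_gene_setup()
  # the same CDS encoded on the minus strand of another contig
  mrna <- x$genome$chr[10:27]
  minus_seq <- c(rep("A", 9), rev(unname(
    c(A = "T", C = "G", G = "C", T = "A")[mrna])), rep("A", 33))
  genome <- list(chr = x$genome$chr, rev = minus_seq)
  gene_rev <- gene_model("toy_rev", "rev", "-",
                         data.frame(start = 10L, end = 27L))
  # mRNA position 13 (codon 2, first base) sits at genomic 27-(13-10)=24
  ds <- manual_dataset(matrix(1, 1, 2), contig = "rev", pos = 24L,
                       ref = "G", alt = "A")   # complement of C>T
  eff <- annotate_coding_effects(ds, list(toy_rev = gene_rev), genome)
  expect_equal(eff$label[eff$effect == "non_synonymous"], "L2F")
})

test_that("REF alleles disagreeing with the reference are rejected with a warning", {
  x <- tiny_gene_setup()
  ds <- manual_dataset(matrix(1, 1, 2), contig = "chr", pos = 13L,
                       ref = "G", alt = "T")   # reference has C at 13
  expect_warning(eff <- annotate_coding_effects(ds, list(toy = x$gene),
                                                x$genome),
                 "REF disagrees")
  expect_false(any(eff$effect == "non_synonymous"))
})

test_that("all planted resistance substitutions annotate to their designed labels", {
  sim <- default_sim()
  eff <- annotate_coding_effects(sim$dataset, sim$gene_models, sim$genome)
  tr <- sim$truth$loci[sim$truth$loci$kind == "resistance", ]
  m <- merge(tr, eff, by = c("contig", "pos"))
  expect_equal(nrow(m), nrow(tr))
  expect_identical(m$label.y, m$label.x)   # includes minus-strand Gste2
  expect_true(all(m$effect == "non_synonymous"))
})

test_that("substitution frequencies match a per-sample brute-force tally", {
  sim <- default_sim()
  eff <- annotate_coding_effects(sim$dataset, sim$gene_models, sim$genome)
  tr <- sim$truth$samples
  colu <- which(tr$taxon == "coluzzii")
  small <- colu[1:18]
  tab <- substitution_frequencies(sim$dataset, eff,
                                  list(colu = small), full = TRUE)
  loci <- sim$truth$loci
  for (lab in c("L995F", "I114T", "G280S")) {
    row <- tab[tab$substitution == lab, ]
    site <- which(loci$label == lab)
    v <- which(sim$dataset$variants$contig == loci$contig[site] &
                 sim$dataset$variants$pos == loci$pos[site])
    # brute force from the genotype array
    g <- sim$dataset$gt[v, small, , drop = FALSE]
    expect_equal(row$frequency, sum(g == 1L) / sum(g >= 0L))
  }
})

test_that("the retention filter keeps substitutions above 5% in any one cohort", {
  x <- tiny_gene_setup()
  # variant at codon 2 (L2F) with cohort frequencies 0.04 / 0.06 / 0.04,
  # and a second variant at codon 4 (I4V) at 0.04 everywhere
  dos <- rbind(c(rep(1, 2), rep(0, 23), rep(1, 3), rep(0, 22),
                 rep(1, 2), rep(0, 23)),
               c(rep(1, 2), rep(0, 23), rep(1, 2), rep(0, 23),
                 rep(1, 2), rep(0, 23)))
  ds <- manual_dataset(dos, contig = "chr", pos = c(13L, 19L),
                       ref = c("C", "A"), alt = c("T", "G"))
  eff <- annotate_coding_effects(ds, list(toy = x$gene), x$genome)
  cohorts <- list(c1 = 1:25, c2 = 26:50, c3 = 51:75)
  tab <- substitution_frequencies(ds, eff, cohorts)
  expect_true(all(tab$substitution == "L2F"))   # I4V dropped everywhere
  expect_equal(nrow(tab), 3)                    # retained row kept per cohort
  full <- substitution_frequencies(ds, eff, cohorts, full = TRUE)
  expect_false(any(full$retained[full$substitution == "I4V"]))
})

test_that("joint frequency of a coupled pair is exact under complete coupling", {
  sim <- deep_sim()
  eff <- annotate_coding_effects(sim$dataset, sim$gene_models, sim$genome)
  colu <- which(sim$truth$samples$taxon == "coluzzii")
  dd <- double_mutant_frequency(sim$dataset, eff, c("V402L", "I1527T"),
                                list(colu = colu), gene = "Vgsc")
  expect_equal(dd$joint_frequency, 0.38)
  expect_equal(dd$marginal1, 0.38)
  # marginals always bound the joint estimate
  expect_true(dd$joint_frequency <= dd$marginal1 + 1e-12)
  expect_true(dd$joint_frequency <= dd$marginal2 + 1e-12)
})

test_that("double-mutant edge cases: disjoint carriers, fixation, absence", {
  x <- tiny_gene_setup()
  # L2F carried by samples 1-2, I4V by samples 3-4: disjoint
  dos <- rbind(c(2, 2, 0, 0), c(0, 0, 2, 2))
  ds <- manual_dataset(dos, contig = "chr", pos = c(13L, 19L),
                       ref = c("C", "A"), alt = c("T", "G"))
  eff <- annotate_coding_effects(ds, list(toy = x$gene), x$genome)
  dd <- double_mutant_frequency(ds, eff, c("L2F", "I4V"),
                                list(all = 1:4))
  expect_equal(dd$joint_frequency, 0)
  expect_equal(dd$n_carrying_both, 0L)
  # both fixed -> joint 1
  ds2 <- manual_dataset(rbind(rep(2, 4), rep(2, 4)), contig = "chr",
                        pos = c(13L, 19L), ref = c("C", "A"),
                        alt = c("T", "G"))
  eff2 <- annotate_coding_effects(ds2, list(toy = x$gene), x$genome)
  dd2 <- double_mutant_frequency(ds2, eff2, c("L2F", "I4V"),
                                 list(all = 1:4))
  expect_equal(dd2$joint_frequency, 1)
  # absent substitution -> warning and zero
  expect_warning(
    dd3 <- double_mutant_frequency(ds2, eff2, c("L2F", "Q9X"),
                                   list(all = 1:4)),
    "absent")
  expect_equal(dd3$joint_frequency, 0)
})
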