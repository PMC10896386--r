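test_that("structure SNP selection filters and thins by equal rank-spacing", {
  # 12 variants: 10 qualify, one has a missing call, one fails MAF
  dos <- matrix(rep(c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1), each = 12), 12, 10)
  dos[5, 3] <- NA                      # missing call -> excluded
  dos[9, ] <- c(1, rep(0, 9))          # MAF 0.05
  ds <- manual_dataset(dos)
  sel <- select_structure_snps(ds, n_target = 5, maf_min = 0.06)
  qualifying <- setdiff(1:12, c(5, 9))
  expect_equal(sel$idx, qualifying[c(2, 4, 6, 8, 10)])  # every 2nd rank
  expect_equal(sel$log$n_complete, 10)
  expect_equal(sel$log$n_selected, 5)
  # filter log agrees with a brute-force recount
  n_maf_bf <- sum(vapply(1:12, function(v) {
    x <- dos[v, ][!is.na(dos[v, ])]
    p <- sum(x) / (2 * length(x)); min(p, 1 - p) > 0.06
  }, TRUE))
  expect_equal(sel$log$n_maf, n_maf_bf)
  expect_error(select_structure_snps(ds, n_target = 5, maf_min = 0.49),
               "no qualifying")
})

test_that("SNP selection is idempotent on its own output", {
  sim <- default_sim()
  sel <- select_structure_snps(sim$dataset, contigs = c("3L", "3R"),
                               n_target = 300)
  sub <- subset_dataset(sim$dataset, variants = sel$idx)
  sel2 <- select_structure_snps(sub, n_target = 300)
  expect_equal(sel2$idx, seq_along(sel$idx))
})

test_that("dosage PCA separates planted clusters and respects duplicates", {
  set.seed(6)
  # two clusters differing at 30 sites, plus 20 noise sites
  sig <- rbind(matrix(0, 30, 8), matrix(rbinom(20 * 8, 2, 0.5), 20, 8))
  sig[1:30, 5:8] <- 2
  sig[, 8] <- sig[, 7]                  # sample 8 duplicates sample 7
  ds <- manual_dataset(sig)
  pca <- pca_dosage(ds, 1:50, k = 3)
  pc1 <- pca$coords[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) ||
                min(pc1[1:4]) > max(pc1[5:8]))
  expect_equal(pca$coords[7, ], pca$coords[8, ], ignore_attr = TRUE)
  # explained-variance fractions are non-increasing and in [0, 1]
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_true(all(pca$explained >= 0 & pca$explained <= 1))
})

test_that("rank-1 dosage data loads onto a single component", {
  ds <- manual_dataset(matrix(rep(c(0, 1, 2), each = 6), 6, 3))
  pca <- pca_dosage(ds, 1:6, k = 1, scale = "none")
  expect_gt(pca$explained[1], 0.999)
})

test_that("PCA coordinates are invariant to sample order up to sign", {
  sim <- default_sim()
  sel <- select_structure_snps(sim$dataset, contigs = c("3L", "3R"),
                               n_target = 500)
  p1 <- pca_dosage(sim$dataset, sel, k = 2)
  perm <- sample(n_samples(sim$dataset))
  p2 <- pca_dosage(subset_dataset(sim$dataset, samples = perm), sel,
                   k = 2)
  back <- p2$coords[order(perm), ]
  for (k in 1:2) {
    expect_true(isTRUE(all.equal(back[, k], p1$coords[, k],
                                 check.attributes = FALSE)) ||
                  isTRUE(all.equal(-back[, k], p1$coords[, k],
                                   check.attributes = FALSE)))
  }
})

test_that("neighbour-joining reproduces an additive 4-taxon metric exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)) as a distance matrix
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 7
  D["A", "D"] <- D["D", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 8
  D["B", "D"] <- D["D", "B"] <- 9
  D["C", "D"] <- D["D", "C"] <- 9
  tr <- nj_tree(d = D)
  induced <- ape::cophenetic.phylo(tr$tree)[rownames(D), colnames(D)]
  expect_equal(induced, D)
  expect_equal(tr$n_clamped, 0)
})

test_that("three leaves give the closed-form star tree", {
  D <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d = D)
  lens <- sort(tr$tree$edge.length)
  expect_equal(lens, c(2, 3, 5))  # (5+7-8)/2, (5+8-7)/2, (7+8-5)/2
  # equal distances resolve deterministically
  E <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(E) <- 0
  expect_identical(nj_tree(d = E)$newick, nj_tree(d = E)$newick)
})

test_that("NJ on simulated taxa clusters conspecific samples together", {
  sim <- default_sim()
  tr <- sim$truth$samples
  keep <- c(which(tr$taxon == "arabiensis")[1:6],
            which(tr$taxon == "coluzzii")[1:6])
  sel <- select_structure_snps(sim$dataset, n_target = 400,
                               samples = keep)
  res <- nj_tree(sim$dataset, sel, samples = keep)
  expect_s3_class(res$tree, "phylo")
  # the taxon split is a bipartition of the unrooted tree
  ids <- sim$dataset$samples$sample_id[keep]
  arab <- ids[1:6]
  expect_true(ape::is.monophyletic(res$tree, arab) ||
                ape::is.monophyletic(res$tree, setdiff(ids, arab)))
})

test_that("karyotype PCA recovers the three introgression dosage groups", {
  sim <- default_sim()
  tr <- sim$truth$samples
  colu <- which(tr$taxon == "coluzzii")
  ka <- karyotype_pca(sim$dataset, sim$config$introgression_region,
                      samples = colu)
  expect_equal(ka$k, 3)
  truth <- tr$introgression_state[colu]
  tab <- table(ka$cluster, truth)
  # each cluster is pure and each state maps to exactly one cluster
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # heterozygotes sit midway: their cluster is the middle one on PC1
  mid <- names(which.max(tab[2, , drop = FALSE][1, ]))
  expect_equal(mid, "het")
})

test_that("a structure-free region yields a single karyotype cluster", {
  sim <- default_sim()
  tr <- sim$truth$samples
  arab <- which(tr$taxon == "arabiensis")
  ka <- karyotype_pca(sim$dataset, sim$config$introgression_region,
                      samples = arab)
  expect_equal(ka$k, 1)
  expect_true(all(ka$cluster == 0))
  # too few SNPs is an error, not a silent answer
  expect_error(karyotype_pca(sim$dataset,
                             list(contig = "X", start = 1, end = 2000),
                             samples = arab), "qualifying")
})
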