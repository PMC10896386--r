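test_that("nucleotide diversity matches enumeration of pairwise differences", {
  # no segregating sites
  expect_equal(nucleotide_diversity(cbind(c(4, 4), c(0, 0)), 10), 0)
  # one site, counts (2,2), n = 4, L = 1: 2*2 / C(4,2) = 2/3
  expect_equal(nucleotide_diversity(matrix(c(2L, 2L), 1), 1), 2 / 3)
  # random instances against the brute-force haplotype-pair oracle
  set.seed(8)
  for (rep in 1:6) {
    ns <- sample(2:8, 1); nv <- sample(5:50, 1); L <- sample(50:500, 1)
    dos <- matrix(rbinom(nv * ns, 2, runif(nv, 0.1, 0.9)), nv, ns)
    ds <- manual_dataset(dos)
    ac <- allele_counts(ds)
    expect_equal(nucleotide_diversity(ac, L), pi_bruteforce(dos, L))
  }
  expect_error(nucleotide_diversity(matrix(c(2L, 2L), 1), 0),
               "accessible_bases")
})

test_that("Watterson's theta scales segregating sites by the harmonic number", {
  expect_equal(watterson_theta(cbind(c(5, 5), c(0, 0)), 100), 0)
  # S = 3, n = 5, L = 1000: a1 = 1 + 1/2 + 1/3 + 1/4 = 25/12
  ac <- cbind(c(3, 3, 3), c(2, 2, 2))
  expect_equal(watterson_theta(ac, 1000), 3 / (25 / 12) / 1000)
  expect_equal(watterson_theta(ac, 2000), watterson_theta(ac, 1000) / 2)
})

test_that("Tajima's D has the right zeros, signs, and constants", {
  # construction with pi_total = S/a1 exactly (n = 4): three (2,2) sites
  # and eight (1,3) sites give pi = 6 = 11 / (11/6)
  ac0 <- rbind(matrix(c(2L, 2L), 3, 2, byrow = TRUE),
               matrix(c(3L, 1L), 8, 2, byrow = TRUE))
  expect_equal(tajimas_d(ac0)$D, 0)
  # an excess of singletons drives D negative
  ac_neg <- matrix(c(9L, 1L), 5, 2, byrow = TRUE)
  expect_lt(tajimas_d(ac_neg)$D, 0)
  # no segregating sites: undefined and flagged, not zero
  d_undef <- tajimas_d(cbind(c(6, 6), c(0, 0)))
  expect_true(is.na(d_undef$D))
  expect_match(d_undef$reason, "segregating")
  # double-entry check: independent transcription of the constants
  set.seed(12)
  for (rep in 1:5) {
    nv <- sample(10:40, 1); n <- sample(c(6, 10, 20), 1)
    alt <- rbinom(nv, n, runif(nv, 0.05, 0.6))
    ac <- cbind(n - alt, alt)
    expect_equal(tajimas_d(ac)$D, tajima_oracle(ac))
  }
})

test_that("Hudson's FST is 1 at fixed differences and symmetric", {
  ac1 <- cbind(rep(0L, 10), rep(20L, 10))
  ac2 <- cbind(rep(20L, 10), rep(0L, 10))
  expect_equal(hudson_fst(ac1, ac2)$fst, 1)
  # symmetry and allele-label invariance on random counts
  set.seed(3)
  a1 <- rbinom(200, 30, 0.3); a2 <- rbinom(200, 40, 0.4)
  x <- cbind(30 - a1, a1); y <- cbind(40 - a2, a2)
  expect_equal(hudson_fst(x, y)$fst, hudson_fst(y, x)$fst)
  expect_equal(hudson_fst(x[, 2:1], y[, 2:1])$fst, hudson_fst(x, y)$fst)
  # all-monomorphic input is flagged undefined
  expect_true(is.na(hudson_fst(cbind(4L, 0L), cbind(6L, 0L))$fst))
})

test_that("identical cohorts drawn from one population give FST within the permutation null", {
  set.seed(21)
  p <- runif(400, 0.1, 0.5)
  dos <- matrix(rbinom(400 * 40, 2, rep(p, 40)), 400, 40)
  counts <- function(cols) {
    alt <- rowSums(dos[, cols, drop = FALSE])
    cbind(2 * length(cols) - alt, alt)
  }
  fst0 <- hudson_fst(counts(1:20), counts(21:40))$fst
  null <- replicate(200, {
    perm <- sample(40)
    hudson_fst(counts(perm[1:20]), counts(perm[21:40]))$fst
  })
  expect_lt(abs(fst0 - mean(null)), 3 * sd(null))
})

test_that("Hudson's FST recovers a simulated Balding-Nichols differentiation of 0.006", {
  set.seed(31)
  p <- runif(100000, 0.05, 0.5)
  pops <- simulate_population_frequencies(p, 0.006, 2)
  n_alleles <- 80    # 40 diploid samples per population
  alt1 <- rbinom(100000, n_alleles, pops[, 1])
  alt2 <- rbinom(100000, n_alleles, pops[, 2])
  fst <- hudson_fst(cbind(n_alleles - alt1, alt1),
                    cbind(n_alleles - alt2, alt2))$fst
  expect_gt(fst, 0.004)
  expect_lt(fst, 0.009)
})

test_that("diversity statistics are invariant to variant and sample order", {
  sim <- default_sim()
  ds <- sim$dataset
  cohort <- which(sim$truth$samples$taxon == "arabiensis")[1:20]
  base <- diversity_stats(ds, cohort)
  perm_v <- sample(n_variants(ds))
  # reorder variants (positions no longer sorted, so rebuild via counts)
  ac <- allele_counts(subset_dataset(ds, samples = cohort))
  ac_perm <- ac[perm_v, ]
  L <- 2200000
  expect_equal(nucleotide_diversity(ac_perm, L),
               nucleotide_diversity(ac, L))
  expect_equal(tajimas_d(ac_perm)$D, tajimas_d(ac)$D)
  perm_s <- sample(cohort)
  expect_equal(diversity_stats(ds, perm_s), base)
})

test_that("per-base and per-site denominators are both available", {
  sim <- default_sim()
  cohort <- which(sim$truth$samples$taxon == "arabiensis")
  a <- diversity_stats(sim$dataset, cohort, per = "mask_bases")
  b <- diversity_stats(sim$dataset, cohort, per = "segregating_sites")
  expect_equal(a$L, sum(as.numeric(sim$config$contigs)))
  expect_true(b$L <= n_variants(sim$dataset))
  expect_equal(a$theta_pi * a$L, b$theta_pi * b$L)
})

test_that("windowed statistics tile the contig and flag empty windows", {
  sim <- default_sim()
  cohort <- which(sim$truth$samples$taxon == "arabiensis")
  w <- windowed_diversity(sim$dataset, cohort, "X", width = 50000L)
  expect_equal(nrow(w), 4)
  expect_true(all(w$S[!is.na(w$theta_pi)] >= 0))
})
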