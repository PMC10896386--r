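test_that("Balding-Nichols frequency simulation behaves at its limits and is reproducible", {
  p <- rep(0.5, 500)
  # zero drift: fst = 0 returns the ancestral frequencies unchanged
  m0 <- simulate_population_frequencies(p, 0, 3, seed = 1)
  expect_equal(m0, matrix(0.5, 500, 3))
  # near-zero drift concentrates tightly around the ancestral value
  m <- simulate_population_frequencies(p, 1e-6, 2, seed = 1)
  expect_lt(max(abs(m - 0.5)), 0.02)
  # determinism under a fixed seed
  expect_identical(
    simulate_population_frequencies(rep(0.3, 50), 0.01, 2, seed = 5),
    simulate_population_frequencies(rep(0.3, 50), 0.01, 2, seed = 5))
  # invalid inputs are rejected
  expect_error(simulate_population_frequencies(c(0, 0.5), 0.01, 2),
               "strictly")
  expect_error(simulate_population_frequencies(rep(0.3, 5), 1.2, 2),
               "fst")
})

test_that("realized differentiation of simulated frequency pairs matches the FST dial", {
  # p = 0.3, F = 0.01, 2 populations, 10,000 sites: the Hudson
  # ratio-of-averages over the frequency pairs themselves (infinite
  # sample size) should sit near 0.01
  m <- simulate_population_frequencies(rep(0.3, 10000), 0.01, 2, seed = 2)
  num <- (m[, 1] - m[, 2])^2
  den <- m[, 1] * (1 - m[, 2]) + m[, 2] * (1 - m[, 1])
  fst_hat <- sum(num) / sum(den)
  expect_gt(fst_hat, 0.005)
  expect_lt(fst_hat, 0.02)
})

test_that("AIM sites are perfectly informative fixed differences before introgression", {
  cfg <- sim_config(seed = 11,
                    introgression_proportions = c(none = 1, het = 0,
                                                  hom = 0))
  sim <- simulate_genotype_dataset(cfg)
  tr <- sim$truth$samples
  fc <- compute_aim_fraction(sim$dataset, sim$panels$gambiae_vs_coluzzii,
                             "coluzzii")
  expect_true(all(fc$fraction[tr$taxon == "coluzzii"] == 1))
  expect_true(all(fc$fraction[tr$taxon == "gambiae"] == 0))
  fa <- compute_aim_fraction(sim$dataset,
                             sim$panels$gambcolu_vs_arabiensis,
                             "arabiensis")
  expect_true(all(fa$fraction[tr$taxon == "arabiensis"] == 1))
  expect_true(all(fa$fraction[tr$taxon != "arabiensis"] == 0))
})

test_that("introgression states follow the configured zygosity proportions", {
  cfg <- deep_cfg(seed = 33)
  sim <- simulate_genotype_dataset(cfg)
  st <- sim$truth$samples$introgression_state[
    sim$truth$samples$taxon == "coluzzii"]
  counts <- table(factor(st, levels = c("none", "het", "hom")))
  # exact apportionment of 100 recipients at 0.16/0.46/0.38
  expect_equal(unname(c(counts)), c(16L, 46L, 38L))
  # and trivially inside the 99% binomial envelope of the proportions
  expect_true(abs(counts[["het"]] - 46) <=
                3 * sqrt(100 * 0.46 * 0.54))
})

test_that("missingness dial plants exactly what it promises", {
  expect_true(all(default_sim()$dataset$gt >= 0L))
  gt <- missing_sim()$dataset$gt
  rate <- mean(gt[, , 1] < 0L)
  expect_gt(rate, 0.04); expect_lt(rate, 0.06)
  # missing calls are fully missing: both alleles or neither
  expect_identical(gt[, , 1] < 0L, gt[, , 2] < 0L)
})

test_that("planted resistance allele frequencies are achieved in the target cohort", {
  sim <- deep_sim()
  tr <- sim$truth
  colu <- which(tr$samples$taxon == "coluzzii")
  loci <- tr$loci[tr$loci$kind == "resistance" & tr$loci$target_freq > 0, ]
  for (i in seq_len(nrow(loci))) {
    vi <- which(sim$dataset$variants$contig == loci$contig[i] &
                  sim$dataset$variants$pos == loci$pos[i])
    d <- genotype_dosage(sim$dataset, 1L, variants = vi, samples = colu)
    realized <- sum(d) / (2 * length(colu))
    expect_equal(realized, loci$planted_freq[i])
    # within 3 binomial SE of the requested target
    se <- sqrt(loci$target_freq[i] * (1 - loci$target_freq[i]) /
                 (2 * length(colu)))
    expect_lt(abs(realized - loci$target_freq[i]), max(3 * se, 1e-12))
  }
  # linked pair shares one haplotype indicator: identical dosages
  v402 <- which(tr$loci$label == "V402L")
  v1527 <- which(tr$loci$label == "I1527T")
  d1 <- genotype_dosage(sim$dataset, 1L, variants = v402, samples = colu)
  d2 <- genotype_dosage(sim$dataset, 1L, variants = v1527, samples = colu)
  expect_equal(unname(d1), unname(d2))
})

test_that("unachievable resistance frequencies warn and round to zero", {
  cfg <- sim_config(
    cohorts = data.frame(location = "S", latitude = 0, longitude = 0,
                         year = 2020L, month = 1L,
                         taxon = c("gambiae", "coluzzii"), n = c(5L, 2L),
                         stringsAsFactors = FALSE),
    resistance_plan = within(
      default_resistance_plan()[default_resistance_plan()$label ==
                                  "L995F", ],
      freq <- 0.05),
    seed = 5)
  expect_warning(simulate_genotype_dataset(cfg), "not achievable")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_genotype_dataset(sim_config(seed = 77))
  b <- simulate_genotype_dataset(sim_config(seed = 77))
  expect_identical(a$dataset$gt, b$dataset$gt)
  expect_identical(a$dataset$variants, b$dataset$variants)
  expect_identical(a$truth, b$truth)
})
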