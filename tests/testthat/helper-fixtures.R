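# Shared fixtures, memoised so expensive simulations run once per suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (!exists(key, envir = .fixture_env)) assign(key, maker(),
                                                 envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# study-condition simulation (defaults), no missingness
default_sim <- function() fixture("default_sim", function()
  simulate_genotype_dataset(sim_config(seed = 101)))

# same conditions with missingness planted
missing_sim <- function() fixture("missing_sim", function()
  simulate_genotype_dataset(sim_config(seed = 101, missing_rate = 0.05)))

# large single-site cohort used for frequency-recovery checks
deep_cfg <- function(seed = 202, ...) {
  sim_config(
    cohorts = data.frame(
      location = "Turkana", latitude = 3.717, longitude = 34.857,
      year = 2019L, month = 1L,
      taxon = c("arabiensis", "gambiae", "coluzzii"),
      n = c(40L, 30L, 100L), stringsAsFactors = FALSE),
    seed = seed, ...)
}

deep_sim <- function() fixture("deep_sim", function()
  simulate_genotype_dataset(deep_cfg()))

# realistic low-missingness simulation used for on-disk / end-to-end runs
# (complete-case SNP selection over 220 samples needs a low per-call rate)
bundle_sim <- function() fixture("bundle_sim", function()
  simulate_genotype_dataset(sim_config(seed = 303, missing_rate = 0.005)))

# on-disk bundle of the low-missingness simulation
bundle_dir <- function() fixture("bundle_dir", function() {
  d <- file.path(tempdir(), "aimpop-fixture-bundle")
  write_fixture_bundle(bundle_sim(), d)
  d
})

# hand-built biallelic dataset from a dosage matrix (variants x samples);
# NA dosages become missing genotype calls
manual_dataset <- function(dos, contig = "chr1", pos = NULL, ref = NULL,
                           alt = NULL, contig_len = 1000000L) {
  nv <- nrow(dos); ns <- ncol(dos)
  contig <- rep_len(contig, nv)
  pos <- pos %||% unlist(lapply(split(seq_len(nv), contig)[unique(contig)],
                                function(i) seq_along(i) * 100L))
  ref <- ref %||% rep("A", nv)
  alt <- alt %||% rep("T", nv)
  gt <- array(0L, c(nv, ns, 2L))
  gt[, , 1] <- ifelse(is.na(dos), -1L, as.integer(dos == 2))
  gt[, , 2] <- ifelse(is.na(dos), -1L, as.integer(dos >= 1))
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(ns)),
                        location = "SiteA", year = 2020L, month = 1L,
                        stringsAsFactors = FALSE)
  genotype_dataset(gt,
                   data.frame(contig = contig, pos = pos, ref = ref,
                              alt = alt, pass = TRUE,
                              stringsAsFactors = FALSE),
                   samples,
                   setNames(rep(as.integer(contig_len),
                                length(unique(contig))), unique(contig)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mean pairwise difference per base between haplotypes
pi_bruteforce <- function(dos, L) {
  # dos: variants x samples dosage of the alternate allele, no missing
  haps <- do.call(cbind, lapply(seq_len(ncol(dos)), function(s)
    cbind(as.integer(dos[, s] == 2), as.integer(dos[, s] >= 1))))
  n <- ncol(haps)
  total <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + sum(haps[, i] != haps[, j])
    pairs <- pairs + 1
  }
  total / pairs / L
}

# independent transcription of the Tajima 1989 constants and statistic
tajima_oracle <- function(ac) {
  n_s <- rowSums(ac)
  keep <- n_s >= 2
  ac <- ac[keep, , drop = FALSE]; n_s <- n_s[keep]
  S <- 0; pi_total <- 0
  for (r in seq_len(nrow(ac))) {
    cc <- ac[r, ]
    if (sum(cc > 0) >= 2) S <- S + 1
    acc <- 0
    for (a in seq_along(cc)) for (b in seq_along(cc)) {
      if (a < b) acc <- acc + cc[a] * cc[b]
    }
    pi_total <- pi_total + acc / (n_s[r] * (n_s[r] - 1) / 2)
  }
  n <- round(median(n_s))
  if (S == 0 || n < 4) return(NA_real_)
  h <- sum(1 / seq_len(n - 1)); g <- sum(1 / seq_len(n - 1)^2)
  vD <- ((n + 1) / (3 * (n - 1)) - 1 / h) / h * S +
    ((2 * (n^2 + n + 3)) / (9 * n * (n - 1)) - (n + 2) / (h * n) +
       g / h^2) / (h^2 + g) * S * (S - 1)
  unname((pi_total - S / h) / sqrt(vD))
}
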