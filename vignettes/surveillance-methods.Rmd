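---
title: "Methods: AIM taxon assignment and population genomics for Anopheles surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AIM taxon assignment and population genomics for Anopheles surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models
and procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the field's conventions leave the design open.

## The problem

Members of the *Anopheles gambiae* species complex are morphologically
indistinguishable, and single-locus diagnostic PCR can misassign or
simply fail on taxa it was not designed for. Whole-genome SNP data
solve this by aggregating thousands of ancestry-informative markers
(AIMs), and simultaneously support the downstream questions that matter
for vector control: is a newly detected population connected to
conspecific populations elsewhere (population structure,
differentiation, diversity), and what insecticide-resistance alleles
does it carry? `aimpop` implements that analysis chain over a simple
diploid genotype data model (variants × samples × 2 allele indices,
with −1 for missing) read from VCF, with the accessibility mask, AIM
panels, gene models and sample metadata as side inputs.

## Taxon assignment

For a panel of sites with alleles diagnostic between taxa A and B, a
sample's AIM fraction for taxon A is the proportion of its alleles at
called panel sites that match A's diagnostic allele. Missing genotypes
are excluded from numerator and denominator; half-calls are treated as
fully missing (a conservative reading of diploid GT fields).

Classification is a two-stage decision. The arabiensis panel
(*gambiae*/*coluzzii* vs *arabiensis*) is evaluated first and is
decisive: arabiensis fraction > `t_arab` calls *An. arabiensis*. The
remaining samples are split on the coluzzii fraction of the
*gambiae*-vs-*coluzzii* panel: > `t_col_hi` calls *An. coluzzii*,
< `t_col_lo` calls *An. gambiae*, anything between is reported as
`intermediate`. Samples whose fractions cannot be computed (no called
panel sites, or fewer than `min_sites = 10`) are `unassigned`, never
silently dropped.

Defaults are `t_arab = 0.6`, `t_col_lo = 0.12`, `t_col_hi = 0.9`.
Published analyses of this design sometimes quote stricter operational
cutoffs (arabiensis > 0.85, coluzzii < 0.1) when describing results;
we treat the procedural definition as the default and expose every
threshold in `aim_thresholds()`, taking no position on which variant
was "intended" where sources disagree.

## Introgression profiling

Adaptive introgression — here, the *gambiae*-derived block near the 2L
centromere that carries pyrethroid target-site resistance — appears in
AIM space as a run of donor-diagnostic alleles in an otherwise
recipient genome. `introgression_profile()` computes per-window mean
donor-allele dosage (0, 0.5, 1 per site for none/het/hom) and calls a
zygosity state for a focal region from its mean dosage *d*: hom when
*d* ≥ 0.75, het when 0.25 ≤ *d* < 0.75, else none. The 0.25/0.75
thresholds are our choice — midpoints between the expected dosages
{0, 0.5, 1} — since no standard cutoffs exist; they are arguments, not
constants.

## Diversity and differentiation

Per-site components are accumulated from cohort allele counts and
divided once at the end (ratio of sums, never mean of ratios):

* θπ: `Σ_sites [Σ_{a<b} c_a c_b / C(n_s, 2)] / L`
* θw: `S / (a1 L)`, `a1 = Σ_{i<n} 1/i`
* Tajima's D with the classical 1989 constants; `D` is `NA`-flagged
  (never coerced to zero) when `S = 0` or `n < 4`
* Hudson's FST with the small-sample numerator correction, sites with
  < 2 called alleles in either cohort, > 2 observed alleles, or zero
  denominator excluded from the sums.

Two conventions are deliberately exposed rather than resolved:

* **Sample size under missingness.** The classical constants assume one
  `n` across sites. We use the median called allele count over included
  sites (overridable), keeping the constants valid without per-site
  reweighting machinery.
* **The denominator L.** Diversity per accessible base (mask length)
  and diversity per analysed site differ by orders of magnitude and
  both appear in the surveillance literature; published headline values
  of order 0.02–0.03 are on the per-site scale of a selected SNP set.
  `diversity_stats(per = "mask_bases")` (default) and
  `per = "segregating_sites"` implement both; neither is asserted as
  canonical.

Windowed variants of the statistics exist (`windowed_diversity()`),
with the genome-wide value always computed from pooled components, not
by averaging windows.

## Population structure

Structure SNPs are PASS, biallelic, MAF > 0.2% and free of missing
calls, thinned to the target count by *equal rank spacing* (rank
`ceiling(k·n_qual/n_target)`): we interpret "equally distributed" by
rank rather than physical distance because it guarantees the requested
count exactly and matches common practice; the selection is idempotent.
PCA runs on centred dosages with Patterson scaling `1/√(p(1−p))` by
default; constant sites are dropped with a log. Neighbour-joining uses
cityblock (L1) distances on *raw* dosages (no scaling), matching the
convention that the tree metric operates on allele counts; NJ's
occasional negative branch lengths are clamped to zero and counted.

Inversion-karyotype clustering restricts the PCA to the inversion
region and partitions PC1 into at most three clusters (0/1/2 copies of
the arrangement). The cluster count comes from the gaps between
consecutive sorted PC1 values: a gap larger than 25% of the PC1 range
marks a boundary, at most two boundaries are used, and final labels
come from 1-D k-means seeded at the gap-segment means — deterministic,
and reduced to a single cluster when the region carries no structure.
The 25% gap fraction is a package choice (no published rule exists) and
is exposed as `gap_frac`.

## Resistance annotation and frequencies

Each SNP inside a gene's CDS is evaluated against the reference codon
independently: the codon is fetched from the reference sequence
(reverse-complemented for minus-strand genes), the alternate base
substituted, and both codons translated with the standard genetic code;
labels are `<refAA><codon><altAA>` with a per-gene codon-numbering
offset so community labels (L995F, I114T, G280S, the Rdl 296/345 pair)
can be reproduced for any transcript numbering. No multi-nucleotide
codon haplotypes are reconstructed — a known limitation when two
substitutions hit one codon. Variants whose REF disagrees with the
reference sequence are rejected with a warning, and CDS lengths must be
multiples of 3.

Per-cohort substitution frequencies are alternate-allele counts over
called alleles; variants producing the same amino-acid change have
their frequencies summed; substitutions must exceed 5% (strict) in at
least one cohort to be retained. For coupled pairs the unphased joint
estimator `mean(min(d1, d2))/2` is used; it is exact under complete
coupling, which is the empirical situation for Vgsc-V402L + I1527T, and
an upper bound otherwise — marginals are always reported alongside.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analyses
assume, with defaults set to the study conditions the package is
designed around:

* **Sampling design**: one arid-zone site at three time points with
  25/64/131 mosquitoes (`default_cohorts()`), three taxa present.
* **AIMs**: two panels (260 and 160 sites by default, a desk-scale
  version of the published 2612/700-site panels) planted as fixed
  differences — perfectly informative before introgression.
* **Background differentiation**: Balding–Nichols per-population
  frequencies around a uniform ancestral MAF in [0.05, 0.5], with one
  FST dial (default 0.006, the weak differentiation typical of
  connected *coluzzii* populations). Balding–Nichols was chosen as the
  minimal single-parameter model; it has no linkage, no mutation-rate
  heterogeneity and no demography.
* **Introgression**: a single donor haplotype spanning the 2L block
  (diagnostic donor alleles at panel sites, one Bernoulli draw per
  background site) planted at 0/1/2 copies per recipient at
  none/het/hom proportions 0.16/0.46/0.38. Whole-block replacement with
  no internal recombination breakpoints mirrors a recent adaptive sweep
  and makes zygosity recovery exactly decidable at zero missingness.
* **Resistance alleles**: planted at exact achievable counts —
  the requested frequency is rounded to the nearest multiple of
  1/(2n), alleles are distributed among samples at random, and linked
  pairs share one haplotype indicator. Exact-count planting (rather
  than per-sample binomial draws) makes the generator's dial faithful:
  the realized cohort frequency equals the requested one, and only the
  assignment of carriers is random. Frequencies that round to zero
  trigger a warning.
* **Missingness**: independent per-genotype masking at `missing_rate`
  (default 0 — several exactness guarantees hold only without
  missingness, and tests that need missing data set the rate
  explicitly).

What the generator does **not** emulate: linkage disequilibrium outside
the introgressed block, site-frequency-spectrum realism (so absolute
θπ/θw/D values from synthetic data are not comparable to field
estimates), sequencing error, batch effects, or cross-contamination.
Passing tests therefore demonstrate the correctness of the estimators
and decision rules, not robustness to artefacts the generator does not
produce.

Coordinates are 1-based inclusive everywhere in memory; BED is written
and read 0-based half-open at the file boundary. All randomness flows
from a single integer seed; under a fixed seed every output is
bit-reproducible.

## Problem sizes

The default simulated genome is five contigs totalling 2.2 Mb with
4,000 background SNPs and 220 samples — large enough for every decision
boundary and statistic to be exercised, small enough that the full test
suite and an end-to-end `run_report()` run complete in well under a
minute each. The Hudson-FST recovery experiment uses 100,000 sites and
40 diploid samples per population, the scale at which an FST of 0.006
is estimated with comfortable precision; frequency-recovery experiments
use a 100-sample cohort, at which the planted 62%/67%/38% resistance
frequencies are exactly achievable (124, 134 and 76 of 200 alleles).

## Known limitations

* No phasing: all haplotype-level quantities are unphased estimators.
* Single-transcript gene models; codon numbering differences between
  transcripts are handled only through the per-gene offset.
* The karyotype cluster-count rule assumes clusters separate on PC1;
  inversions with frequency near 0 or 1 in the cohort collapse to
  fewer clusters by design.
* No *An. quadriannulatus* (or other outgroup) call is attempted from
  AIMs alone; such samples surface as `intermediate`/`unassigned` and
  are expected to be resolved by the PCA/NJT stage, as in practice.
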