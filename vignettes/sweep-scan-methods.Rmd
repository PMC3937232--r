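---
title: "Detecting classic selective sweeps in phased haplotype panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting classic selective sweeps in phased haplotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sweepscan` re-implements, as a tested and reusable pipeline, the analysis
stack of a whole-genome resequencing selection scan in livestock: complementary
sweep statistics on a phased, polarized SNP haplotype panel; genome-wide
empirical p-values over 40-kb windows; top-percentile candidate region
calling; LD-decay profiling with SNP-array ascertainment comparisons; a
two-population F_ST scan; a mixed-model GWAS; and a permutation test for
overlap between association hits and sweep candidates. A forward
Wright–Fisher simulator supplies panels with known ground truth, so every
stage is testable without any external download.

# The model and the statistics

A *classic (hard) selective sweep* is the rapid frequency increase of a new
beneficial allele. It leaves three correlated footprints the pipeline
targets:

1. **Reduced local variation** — windowed heterozygosity (`ZHet`) and the
   site frequency spectrum statistics.
2. **A distorted SFS** — excess rare *and* excess high-frequency derived
   alleles. Tajima's D contrasts mean pairwise diversity with the number of
   segregating sites, `D = (π − S/a₁)/√(e₁S + e₂S(S−1))`; Fay & Wu's
   `H = θ_π − θ_H` is driven negative by high-frequency derived classes and
   requires polarization. The composite likelihood ratio (CLR) formalizes
   the SFS skew as a likelihood contrast (below).
3. **Extended haplotype homozygosity** — around an ongoing sweep the rising
   allele sits on an unusually long shared haplotype. EHH at a site is the
   probability that two random carriers of the core allele are identical
   over the whole stretch from the core to that site. iHH integrates EHH
   against physical distance out to the 0.05 crossing, and
   `iHS_raw = ln(iHH_ancestral/iHH_derived)` is standardized to mean 0 /
   SD 1 within derived-allele-frequency bins of width 0.025 (sample SD,
   bins under 20 sites merged with their nearest occupied neighbor). `nSL`
   replaces physical distance by counts of segregating sites, making it
   robust to recombination-rate variation; it shares the standardization.

The two headline statistics are deliberately complementary: |iHS| has most
power while the selected allele segregates at intermediate frequency, the
CLR right after fixation. The power tests in `test-acceptance.R`
operationalize exactly this split (sweeps stopped at derived frequency 0.7
for iHS, completed sweeps for CLR).

## The CLR sweep model

The background model draws each site's derived count from the genome-wide
spectrum (conditioned on polymorphism). Under a sweep of intensity `α` at
distance `d`, each of the `n` sampled lineages *escapes* the sweep
independently with probability `p_e = 1 − exp(−α·d)`. Conditional on `k`
escapees, the post-sweep sample is equivalent to `k + 1` draws from the
pre-sweep population — the `n − k` trapped lineages all inherit the allele
of one ancestral lineage. Pre-sweep draws at reduced sample size come from
the background spectrum by hypergeometric downsampling. The per-site
transformed spectrum mixes over `k` binomially; the implementation verifies
it against a 10⁶-draw Monte-Carlo lineage simulation.

`clr = 2(max_α log CL_sweep − log CL_background)` at each grid position,
with sites within a 100-kb radius contributing. α is maximized over 30
log-spaced points in `[10⁻⁸, 10⁻²]` per bp plus golden-section refinement;
boundary hits are flagged. Since `α → ∞` recovers the background model,
`clr ≥ 0` everywhere.

Numerical choices worth knowing:

* **Pseudocount smoothing (0.5 per class).** A finite calibration panel can
  leave derived-count classes empty that a scanned region populates; a
  zero-probability class makes the ratio infinite. The pseudocount is the
  standard Bayesian floor and is configurable.
* **Grid trimming (`trim_to_data`).** Grid positions beyond the observed
  site span see a one-sided, shrinking site set; in sweep simulations the
  argmax landed past the data in roughly one replicate in seven purely
  through this artifact. Positions are therefore restricted to the span of
  usable sites per chromosome (the cited scan tool behaves the same way);
  the flag restores untrimmed grids.
* **Conditioning on polymorphism, and the substitution mode.** By default
  both models renormalize over the polymorphic classes `1..n−1`; whether
  the original analysis included invariant sites is not stated. A completed
  sweep, however, pushes its trapped lineages entirely to the derived
  allele, so much of the post-fixation evidence sits in *substitutions*
  (sample-fixed derived sites, class `n`) that the polymorphic-only
  convention discards. `background_sfs(…, include_fixed = TRUE)` on panels
  built with `keep_monomorphic = TRUE` models class `n` explicitly and
  conditions on "observed as a variant record" (classes `1..n`); in the
  embedded-sweep genome test this raises the fixed-sweep per-segment CLR
  maxima from parity with neutral noise to roughly four times the neutral
  median.
* **Exact shortcuts.** Sites with `p_e` within 10⁻⁶ of 1 are scored by the
  background directly (their log-ratio contribution is ~0), and for
  `p_e < 0.1` the binomial mixture is truncated at `k = 30` (< 10⁻¹² mass
  lost). Both shortcuts are exact to well below the likelihood tolerance.

## Windows, empirical p-values and regions

Site scores are averaged (|iHS|) in non-overlapping 40-kb windows anchored
at coordinate 0 per chromosome; windows with fewer than 10 scored sites are
reported missing (variance control). Empirical p-values come from
genome-wide ranking: `emp_p = rank/N` with ties sharing the maximal rank —
the best of 100 windows gets 0.01, and rank 18 among 62,196 windows gives
0.00029, the magnitude of the published per-window p-values (this is why
`rank/N` rather than `rank/(N+1)` was chosen). Candidate regions are maximal
runs of retained (`emp_p ≤ 1 − percentile`) windows, merged only when
adjacent (`merge_gap = 0`) — the simplest rule consistent with two
single-statistic region lists combining into a union list; overlapping
spans from different statistics merge into union regions. The
window-coherence check compares the mean within-window variance of |score|
against score permutations that preserve the window size distribution.

## LD, ascertainment and F_ST

`r²` is the squared correlation of allele indicators on haplotypes, computed
from the 2×2 haplotype table. The decay profile samples sites per segment
(seeded), bins pairs by distance (default 20 × 5-kb bins to 100 kb plus
coarse bins to 250 kb, mirroring the inner-plot domain of the study's LD
figure), retains pair-level values (capped at 10,000 per bin) and compares
two profiles bin-wise with a Wilcoxon rank test — the study's own test is
unnamed, so a rank test is our documented choice. Array-like ascertainment
is emulated by MAF filtering plus spacing thinning (highest-MAF site per
bin); because `r²`'s expectation rises with allele frequency, ascertained
panels show inflated LD, reproducing the direction of the array-vs-sequence
comparison.

F_ST uses the two-population variance-components estimator on haploid allele
counts (`MSP`, `MSG`, `n_c` as printed in the cited formulation); negative
estimates are reported as-is (truncation behind a flag), and 3-SNP sliding
means with a top-0.1% cutoff reproduce the two-breed contrast display.

## Mixed-model GWAS and the overlap test

The GWAS fits `y = μ + s·b + u + e` with `u ~ N(0, σ²_a G)`, `G` the realized
genomic relationship matrix `ZZ'/Σ2p(1−p)` on centered dosages. Variance
components are estimated once by REML under the null (eigendecomposition of
`G`, 1-D search in the variance ratio) and reused for every per-SNP GLS —
the EMMAX approximation. A `σ²_a → 0` boundary fit degrades gracefully to
OLS and is flagged. Per-SNP Wald tests use a t reference with `n − 2`
degrees of freedom: at 43 individuals the normal approximation is visibly
anticonservative and fails the type-I calibration band the test suite
enforces. Per-QTL variance explained uses the single-SNP form
`2p(1−p)β²/var(y)`.

The overlap test counts GWAS hits (`p < 10⁻⁶`, the study's Bonferroni-style
threshold) inside top-1% selection windows and permutes p-values across
units (SNPs, or windows carrying each window's minimum SNP p — the study's
wording is ambiguous about what is permuted; we permute the GWAS labels and
expose the unit choice). `emp_p = (#{perm ≥ obs} + 1)/(n_perm + 1)`, so
10,000 permutations bottom out at ~10⁻⁴ — the resolution behind "no
randomized dataset more extreme".

# The synthetic world

The generator is a forward Wright–Fisher simulation (diploid, additive
fitness 1, 1+s, 1+2s; crossover recombination; infinite-sites mutation with
re-drawn collisions), burn-in 10·N generations from a monomorphic start,
compiled in C++ with all randomness through R's RNG (bit-reproducible under
`set.seed`). Sweeps inject one copy after burn-in and are conditioned on
reaching `end_freq` by rejection (restart on loss; error after 1000
attempts).

Defaults define the stated desk-scale world and are not tuned:

| parameter | default | why |
|---|---|---|
| `n_diploids` | 200 | desk-scale population; 2Ns = 40 at s = 0.1 |
| `sample_hap` | 86 | the analogue of 43 resequenced diploids |
| `seq_len` | 200 kb | the power-test region size |
| `mu`, `rho` | 1.25×10⁻⁶ /bp/gen | scaled so θ_L = ρ_L = 200: ~1000 SNPs per panel, one per ~200 bp — the density of the real sequence panel (~178 bp spacing); ρ ≈ μ as in cattle |
| `s` | 0 (neutral) / 0.1 in power tests | hard-sweep regime of the acceptance criteria |
| `end_freq` | 1 | completed sweep |

What the generator emulates: neutral drift-mutation-recombination
equilibrium, hitchhiking diversity loss whose footprint narrows with ρ,
array-like ascertainment, and polygenic-plus-major-QTL phenotypes
(`y = Σβ·dosage + g + e` with the polygenic variance scaled to a target
heritability of the residual part). What it does not: demography
(bottlenecks, growth, structure), soft sweeps from standing variation,
background selection, genotyping error, or imputation noise. A green power
test therefore establishes correctness of the machinery under the hard-sweep
model, not field performance on real cattle data.

# Design choices where the design was open

* **Ancestral states are a required user input** for real data (the study
  does not say how alleles were polarized in cattle); simulated panels are
  polarized by construction. Sites with unknown ancestral state are kept for
  folded statistics (Tajima's D, Het, r², F_ST) and excluded from polarized
  ones (iHS, nSL, H, unfolded SFS/CLR).
* **Het** is expected heterozygosity `2p̂q̂` from haplotype frequencies over
  polymorphic sites (the panel is phased; "observed heterozygosity" is not
  further defined in the source); a diploid observed-het mode and an
  all-sites denominator sit behind flags.
* **iHS tuning** (EHH cutoff 0.05, min DAF 0.05, bin width 0.025, max gap
  100 kb — motivated by LD not extending past ~100 kb) follows the cited
  method's conventional defaults; the study names the statistic but not its
  settings. Sides censored by an edge or gap are integrated to the
  truncation point and flagged, with an option to drop censored scores.
* **Coordinates**: interval arithmetic is half-open; SNP positions stay
  1-based as in VCF and a site at position p belongs to window [start, end)
  iff start ≤ p < end. Window grids anchor at 0 per chromosome so the grid
  does not depend on the SNP subset.

# Limitations

Window statistics assume complete panels (frequency denominators use
non-missing haplotypes, but per-window sample sizes are not re-derived per
site); multiallelic sites and indels are skipped at ingest; sex chromosomes
are out of scope; the CLR uses physical distance (no genetic map), and the
simulator's rejection conditioning makes very small `s` expensive. The
supplementary-data validation of the region-calling rule runs only when the
published per-window score files are placed under
`tests/testthat/extdata/`; offline, that acceptance test reports its
absence as a failure rather than silently skipping.
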