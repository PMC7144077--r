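---
title: "Coverage-based ploidy inference and population genomics for Camelina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based ploidy inference and population genomics for Camelina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camelpop)
```

## The problem

*Camelina sativa*, the cultivated false flax, is an allohexaploid: its 20
chromosomes comprise three ancestral subgenomes (SG1, SG2, SG3) of 6, 7 and
7 chromosomes. Its wild relatives form a ploidy series — diploids with 6 or
7 chromosome pairs, a tetraploid combining two subgenomes, and hexaploids
that either match the reference organization or carry a divergent,
"cryptic" third subgenome. When reduced-representation (GBS) reads from
such an accession are aligned to the hexaploid reference, the pattern of
read depth along the 20 chromosomes is itself a karyotype assay: a diploid
relative of SG1 covers only six chromosomes; a tetraploid covers thirteen;
a cryptic hexaploid covers the same thirteen but with the first subgenome
at roughly double depth, because reads from its unrepresented third
subgenome cross-map onto their closest homoeologs.

`camelpop` turns that observation into a tested pipeline: karyotype
classification from binned depth, inference of the chromosome-to-subgenome
map from a diploid/tetraploid ladder, and the downstream population
genomics (diversity, distances, ordination, AMOVA-based differentiation,
minor-allele cataloguing, admixture classification) and homoeolog
expression-dominance analysis. Every input can be produced by a seeded
simulator with known truth, so the whole chain is verifiable without any
external download.

## Coverage model and karyotype rules

Read counts are taken in 100-kb bins (BED convention, 0-based half-open).
`normalize_coverage()` converts counts to per-bp depth and divides by the
**median depth of nonzero bins**; the median, rather than the mean, keeps
the scaling honest when a third of the genome is absent, and zero bins stay
exactly zero. The result is unit-free and invariant to sequencing effort.

`chromosome_presence()` calls a chromosome present when more than
`frac_present` (default 0.5) of its bins reach `depth_floor` (default 0.25)
normalized depth — at least half the chromosome covered at a quarter of
typical depth. There is no principled closed-form value for either threshold, so both are
package decisions, exposed as arguments and recorded in each call's
evidence.

`classify_karyotype()` applies ordered rules over the presence set and the
per-subgenome median depths:

1. present set within SG1, at least 5 of 6 → `DIPLOID_SG1`;
2. at least 12 of the 13 SG1+SG2 chromosomes (at most one stray other
   sequence) and SG1:SG2 depth ratio `< ratio_hi` → `TETRAPLOID_SG1SG2`;
3. same presence, ratio `>= ratio_hi` → `HEXAPLOID_TYPE2`;
4. everything present at balanced depth → `HEXAPLOID_REFERENCE`;
5. otherwise, more than `affinity_min` (default 0.5) of reads on SG3 →
   `DIPLOID_SG3_AFFINE` (the *C. hispida* pattern, ~57% of reads drawn to
   the third subgenome despite diffuse mapping);
6. otherwise `AMBIGUOUS` — a value, not an error.

`ratio_hi = 1.5` sits midway between the 1:1 depth expected of a balanced
tetraploid and the ~2:1 expected when a cryptic subgenome cross-maps onto
SG1. The affinity rule is deliberately affinity- rather than
presence-based: a diverged SG3 relative maps diffusely, not cleanly, onto
seven chromosomes.

The subgenome map itself follows the step-wise origin argument implemented
in `infer_subgenome_map()`: SG1 is the diploid representative's presence
set, SG2 what the tetraploid adds, SG3 the remainder. One discordant
chromosome is tolerated (flagged `UNPLACED` with a warning); more aborts
inference. `detect_anomalies()` then screens each sequence's median depth
against its subgenome's median, on a robust MAD scale floored at 0.05
normalized-depth units — the floor is what lets a fully absent subgenome
(whose medians are identically zero) still expose a scaffold riding at
foreign depth, the signature used to flag a likely mis-assembled scaffold.

## Variant statistics

`filter_variants()` applies, in a fixed logged order, a missingness cap
(≤ 20%), a strict minor-allele-frequency floor (> 1%, over all samples from
non-missing calls) and indel removal — the filter ladder typical of published *Camelina* GBS
analyses (on the order of 10^5 raw calls reduced to a few thousand
high-confidence SNPs), with the count after each step logged. Gene diversity is Nei's
\(H_e = 1 - \sum_i p_i^2\) (biallelic maximum 0.5) and PIC is Botstein's
\(1 - \sum_i p_i^2 - \sum_i\sum_{j>i} 2p_i^2 p_j^2\) (maximum 0.375);
both are checked in the tests against direct evaluation of these sums.

Individual-level distance is Nei's (1983) \(D_A\), treating each diploid
genotype as an allele-frequency vector (0, ½, 1):
\(D_A = 1 - \frac{1}{L}\sum_{l}\sum_{a}\sqrt{x_a y_a}\), with loci missing
in either member of a pair skipped and \(L\) adjusted. Trees use
neighbor-joining (via **ape**; on additive matrices the unrooted tree
reproduces all path lengths, which the tests verify to 1e-9), and
ordination uses classical PCoA (Gower double-centering via
`stats::cmdscale`), with negative eigenvalues reported but excluded from
the variance-fraction denominator.

Population differentiation is the distance-based AMOVA
\(\Phi_{PT} = \sigma^2_{among}/(\sigma^2_{among}+\sigma^2_{within})\)
computed from squared Euclidean distances on codominant genotype codes —
the estimator family produced by GenAlEx-style codominant AMOVA, so that
published pairwise values of this kind are reproducible with the same
definition. Components use the standard
unbalanced-design coefficient \(n_0\); estimates are deterministic and
p-values come from seeded label permutations. `fst_scan()` repeats the
estimate in non-overlapping windows (default 1 Mb), the device for
exposing localized differentiation — a selective-sweep-like signal
confined to a few Mb of one chromosome — against a modest genome-wide
background.

Minor alleles follow the "less than 5% homozygous" convention, which we
read as: within a species group, an allele whose homozygote
carrier fraction (among non-missing calls) is strictly between 0 and 0.05.
The allele-frequency reading of the same phrase is available via
`criterion = "allele_freq"`. Admixture classification assigns a sample to
its top ancestry component iff that component reaches the Q cutoff
(default 0.70), else `ADMIXED`.

## Dominance ANOVA

For each homoeolog triplet and tissue, expression is analyzed on
`log2(TPM + 0.01)` — the floor value doubles as the pseudocount; a raw-scale
analysis is available by flag. The model is a randomized complete block:
subgenome fixed (3 levels), replicate as block, which for this balanced
design gives the identical F statistic to a one-way model with random
replicate effects, without iterative fitting. All sums of squares are
evaluated in closed form across triplets simultaneously; the unit tests
verify exact agreement with per-triplet `aov()` fits. When the omnibus test
rejects at α = 0.05, the top subgenome is contrasted against each of the
other two with the pooled error term (unadjusted, matching the raw
p < 0.05 convention; Benjamini–Hochberg available); dominance requires the
top mean to strictly exceed both others with both contrasts significant.
Counts per tissue are tested against 1:1:1 by χ² (df 2) and summarized with
the pairwise dominant-count ratios SG3/SG1, SG3/SG2, SG2/SG1, defined here as ratios of dominant-triplet
counts between subgenome pairs.

Degenerate cases: zero residual variance with unequal means is decided by
the means with p recorded as 0 and flagged; a fully constant triplet is
`NONE`. The expression floor drops a triplet when any homoeolog has all
replicates below 0.01 TPM — a triplet needs all three homoeologs, so the
per-homoeolog and per-triplet readings of the filter coincide.

## What the simulators emulate — and what they do not

`simulate_coverage()` draws per-bin counts negative-binomially (Poisson in
the zero-dispersion limit) around class-dosage means, with configurable bin
dropout; GBS depth is overdispersed, hence the NB default in the acceptance
settings (dispersion 0.1). `simulate_genotypes()` uses the F-model:
ancestral frequencies uniform on (0.1, 0.9), population frequencies
Beta-distributed around them with divergence F, genotypes binomial within
populations. Because \(\Phi_{PT}\) on codominant codes under this model is
\(2F/(1+F)\) in expectation (among-population variance of the mean code is
\(4pqF\), within-population \(2pq(1-F)\)), a requested target φ is
converted to \(F = \varphi/(2-\varphi)\) — an analytic calibration, checked
empirically by the acceptance suite at φ = 0.05 and 0.30. Admixed samples
draw per-locus ancestry from a Dirichlet Q vector constrained below the
0.70 cutoff; private minor alleles are planted as single homozygote
carriers confined to one group. `simulate_triplets()` injects dominance as
a fixed log2 effect on one subgenome with Gaussian replicate and residual
effects.

None of this models linkage, allele-frequency spectra under selection,
mapping bias between homoeologs, or GBS locus dropout correlated with
divergence — so passing tests demonstrate that the estimators recover what
they are defined to estimate, not that real *Camelina* data are this
well-behaved. Reproducing published numbers for real *Camelina* panels (filtered SNP
counts, pairwise F_ST tables, minor-allele partitions, PCoA variance
fractions) requires the corresponding archived variant data as input; the
pipeline accepts either raw or pre-filtered call sets through
`read_vcf()`.

## Numerical choices and problem sizes

The scaled-down synthetic reference uses 2-Mb chromosomes (20 bins each;
Csa11 at 3 Mb mirrors the real karyotype's larger fused chromosome, so
length normalization is always exercised); a ~30-Mb "paper" preset exists
for realism checks, and the windowed-scan checks use 30-Mb chromosomes so
a 3-Mb divergent region against a 1-Mb window mirrors the real geometry.
The test and acceptance problem sizes — 200 accessions for karyotype
recovery, 100 random 6/7/7 partitions, 20 replicates of n = 60 × 2,000
loci for ΦPT, 50 8-taxon trees, 100 scan replicates, 10,000 null triplets —
were chosen as the smallest sizes at which each property is sharp (Monte
Carlo error well inside the stated tolerance), and the full suite runs in
well under a minute per file.

Ties in maximum-Q assignment and in the top-subgenome choice break to the
first index for reproducibility. ΦPT is clamped to [0, 1] with the raw
(possibly slightly negative) estimate retained alongside. Multi-allelic
VCF records are split by default into one biallelic locus per alternate
allele (codes count copies of the focal allele); `multiallelic = "drop"`
discards them instead. Missing genotypes are a dedicated `NA` sentinel
throughout and are never conflated with homozygous reference.
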