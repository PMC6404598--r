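---
title: "Bayesian dosage calling from allelic read depth: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian dosage calling from allelic read depth: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosecall)
```

## The problem

Genotyping-by-sequencing (GBS) and RAD-seq genotype many individuals at
thousands of restriction-site-associated loci, but read depth is low and
very uneven: some loci receive hundreds of reads per individual, others
almost none. At low depth a heterozygote is easily sequenced on only one
allele and miscalled homozygous, and in polyploids the allele copy number
(dosage, 0..k for ploidy k) of a heterozygote is genuinely ambiguous —
seven reads of A and three of B in a tetraploid are compatible with
dosage 2 as well as 3. dosecall treats genotypes as latent variables:
every genotype gets a posterior probability distribution over copy
number, and downstream analyses can consume either the posterior mean
(a continuous dosage in [0, k]) or the posterior mode (a hard call).

## The model

For one individual and one allele at a locus, let `a` be the reads
matching the allele and `b` the reads of the locus's other alleles. Each
read is a Bernoulli trial whose success probability under copy number
`i` is

    pi_i = (1 - c) * i / k + c * p,

where `c` is the cross-sample contamination rate and `p` the allele's
population frequency: with probability `1 - c` the read comes from the
individual's own template, with probability `c` it is a contaminant drawn
at the population frequency. `c` is estimated from no-template (blank
barcode) controls as the ratio of mean blank depth to mean sample depth
(`estimate_contamination()`), and is held constant across loci — most
contamination arises during library preparation, not sequencing.

Read counts are overdispersed relative to the binomial (unequal
per-sample contamination, cut-site variation, size selection), so the
likelihood of `(a, b)` given copy number `i` is beta-binomial with mean
`pi_i` and precision `d`:

    L(a, b | G_i) = C(a+b, a) * B(d*pi_i + a, d*(1-pi_i) + b) / B(d*pi_i, d*(1-pi_i)).

Smaller `d` means more overdispersion; as `d` grows the distribution
converges to the binomial. The default `d = 9` reflects the
overdispersion typical of GBS libraries; `test_overdispersion()` selects
`d` from candidates by scoring randomized quantiles of the observed
counts against uniformity (below). Posteriors follow by Bayes' theorem
with genotype priors `P(G_i)`, and the exported quantities are the
posterior mean genotype `pmg = sum_i i * P(G_i | a, b)` and the
posterior mode. A genotype with zero reads has a flat likelihood, so its
posterior *is* its prior: missing data are imputed by the same mechanism
that calls observed data, with no separate imputation step.

## Priors

* **Hardy-Weinberg** (`iterate_hwe()`): Binomial(k, p), with `p`
  re-estimated from the posterior mean genotypes each iteration until
  the largest frequency change drops below `tol` (default 1e-3, maximum
  50 iterations). Frequencies are initialized from raw depth ratios,
  floored at `1/(2nk)`.
* **Partial selfing** (`s > 0`): the prior is the stationary
  distribution of a population where a fraction `s` of offspring arise
  by selfing — the fixed point of
  `v <- (1 - s) * Binomial(k, p) + s * Self(v)`, where `Self` draws two
  independent polysomic gametes (k/2 chromosomes hypergeometrically,
  no double reduction) from the same parent. Iterated to 1e-9 (at most
  100 steps). Selfing moves mass toward homozygotes but preserves the
  mean `k * p`. For allopolyploid hypotheses the fixed point is computed
  per subgenome with disomic gametes and the subgenome distributions
  convolved; selfing with odd ploidy is an error. Fixed points are
  memoized on frequencies rounded to 1e-5.
* **Population structure** (`iterate_popstruct()`): individuals in a
  structured panel do not share one `p`. The current posterior mean
  genotypes, scaled to [0, 1], are decomposed by PCA; each allele's
  scaled dosage is regressed on the leading axis scores, and the fitted
  value for each individual — clamped to `[eps, 1 - eps]` with
  `eps = 1/(2nk)` and renormalized within each locus — is that
  individual's personal allele frequency, giving a per-individual
  binomial prior. The first iteration uses HWE priors to obtain initial
  genotypes (uniform priors would give a constant genotype matrix and a
  degenerate PCA).
* **Linkage** (`use_ld = TRUE`): for each allele, up to `max_neighbors`
  alleles at *other* loci within `ld_distance` bp with the strongest
  genotype correlation predict the target dosage by least squares; the
  prior becomes the mixture `(1 - w) * base + w * Binomial(k, q)` with
  the predicted frequency `q` and `w = mix_weight` (default 0.5). The
  regression is fitted on individuals with reads at the target locus and
  predicts for all — fitting on all rows would dilute the slope with
  prior-mean-only rows and weaken imputation. Alleles without neighbors
  keep their base prior.
* **Mapping populations** (`run_mapping()`): parents are called by
  maximum likelihood from their own depth under uniform priors (no
  population information, avoiding circularity), and progeny priors are
  the cross's segregation distribution: F1 = convolution of the two
  parental gamete distributions (polysomic hypergeometric gametes;
  allopolyploid gametes average over all consistent assignments of
  parental copies to subgenomes, since phase is unknown), then any
  backcross, intermating and selfing generations applied in that order
  as transitions on the genotype distribution. Generations beyond the
  F1 are supported for polysomic hypotheses only — the marginal dosage
  distribution cannot track per-subgenome state. Loci with a
  zero-depth parent, or where both parents are called homozygous for
  the same allele yet the progeny minor-allele frequency exceeds
  `3c` (more minor reads than contamination can explain), are flagged
  non-segregating and fall back to HWE priors from progeny frequencies.
  Allele frequencies are estimated once, not iterated.

### Choosing the number of structure axes

The axis count for the structure prior is chosen by Horn's parallel
analysis: the eigenvalues of the genotype PCA are compared with the
maximum eigenvalues of three column-permuted copies (permutation
destroys covariance but keeps the margins), and the leading run of axes
above that threshold is kept, capped at 10. Two details matter with
noisy low-depth genotypes. First, the PCA uses one allele per locus: a
locus's dosages sum to k, so keeping all alleles adds perfectly
anti-correlated duplicate columns that distort the spectrum. Second, the
count is fixed at the first structure iteration — if it is re-chosen
every iteration, a noise axis that slips in once is reinforced by the
priors it induced and the selection never lets it go. A broken-stick
rule was tried first and systematically over-selected axes on estimated
genotypes (their noise spectrum is flatter than the broken stick), to
the point of making the structure prior *worse* than HWE on a
two-cluster panel; parallel analysis selects the cluster axes and
nothing else, and on a panmictic panel selects zero axes, which reduces
the pipeline exactly to HWE.

### Choosing the overdispersion

`test_overdispersion()` scores each candidate `d` by assigning every
scored genotype its most-likely copy number under that `d`, computing a
randomized quantile of the observed count under the implied
beta-binomial (a uniform draw inside the discrete step makes quantiles
continuous), and measuring the Kolmogorov-Smirnov distance of those
quantiles from Uniform(0, 1); the smallest distance wins, ties going to
the smaller (more conservative) `d`. Only genotypes with at least
`min_depth = 10` reads are scored: at lower depth the assigned copy
number simply tracks the observed ratio and absorbs the overdispersion
being measured, which biases selection toward large `d` (on data
simulated with `d = 9`, scoring all nonzero-depth genotypes selected
14–20; with the depth filter the generating value is recovered across
seeds). Up to 10,000 genotypes are scored, sampled without replacement.

## Ploidy hypotheses

Several inheritance hypotheses (e.g. `4` vs `c(2, 2)`) can be fitted at
once; `select_ploidy()` picks, per locus, the hypothesis with the
largest log marginal likelihood summed over individuals and the locus's
alleles, ties to the first listed. Under pure HWE with no selfing,
auto- and allopolyploid hypotheses of equal total ploidy produce
identical binomial priors (Vandermonde identity) and identical
marginals — the choice is only discriminative with mapping designs or
selfing. This is documented behaviour, not an error; the per-locus
choice exists because inheritance mode can vary along the genome of a
recent polyploid.

## Numerical choices

* All beta-binomial arithmetic is in log space via `lchoose`/`lbeta`.
  Degenerate allelic fractions (`pi = 0` or `1`, which arise for dosage
  0 or k when `c = 0`) are evaluated as the limiting point masses.
* Posterior normalization happens in linear space per genotype vector
  (k + 1 ≤ ~9 entries; no overflow risk). A genotype whose prior mass
  lies entirely on likelihood-zero states keeps its prior, with a
  warning, rather than failing the pipeline.
* Posterior-mode ties break toward the smaller copy number.
* `filter_markers()` iterates locus and allele thresholds to a fixed
  point, so filtering is idempotent; loci reduced to one allele are
  dropped (the "other alleles" count would be identically zero).
* Blank control taxa are excluded from filtering counts and from all
  estimation except the contamination estimate.

## The simulator

`simulate_raddata()` reproduces the read-depth regime of
restriction-enzyme protocols: overall locus depth is
Gamma(shape = 2, scale = 5) (mean 10); an individual's depth at a locus
is a rounded Gamma with shape = locus depth / 10 and scale = 10 — a
highly skewed mixture in which roughly half of all genotypes get fewer
than five reads, emulating the high-missing-data regime of real GBS
panels; allelic counts within the total follow the same
contamination/overdispersion beta-binomial used for inference
(`d = 9`, `c = 0.001` by default), partitioned over a locus's alleles
by sequential conditional beta-binomials so that biallelic loci match
the likelihood model exactly. Truth genotypes come from binomial HWE
sampling, a hierarchical Balding-Nichols model for structured
populations (subpopulation frequencies Beta-distributed around an
ancestral frequency with variance set by the target differentiation),
the partial-selfing equilibrium, or a cross's segregation distribution.
Ancestral frequencies default to Uniform(0.05, 0.95), the typical range
after minor-allele filtering.

What the simulator does *not* emulate: per-locus sequencing error,
allele-specific amplification bias, paralog collapse, or genotyping
batch effects. Tests passing on simulated data therefore demonstrate
that the estimator inverts its own generative model and that the prior
machinery (structure, linkage, segregation) contributes information —
they do not certify accuracy on real panels with model misspecification.

## Problem sizes used in the tests

The test-suite simulations use 200 individuals × 100 loci for parameter
recovery (with the standard filtering step at `min_ind_with_reads =
100`, `min_ind_with_minor_allele = 5` — half the panel and a
proportional minor-allele count, scaled from common practice on larger
panels), 200 × 100 two-subpopulation panels at F_ST 0.3 for the
structure comparison, 150 × 60 paired-locus panels for linkage
imputation, and 200 × 200 for overdispersion selection. These sizes are
large enough for the compared error rates to separate cleanly while
keeping the whole suite around a minute.

## Known limitations

* One genome-wide `c` and `d`; rare loci with locus-specific error
  rates will have miscalibrated homozygote likelihoods.
* No double reduction in polysomic gametes, and no preferential
  pairing model for segmental allopolyploids.
* Mapping designs are limited to two parents plus
  backcross/intermating/selfing generation counts (polysomic
  hypotheses only beyond the F1).
* The structure prior is a linear (PCA-regression) approximation of
  individual allele frequencies; strong admixture clines are handled,
  but family structure within a panel is not modelled explicitly.
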