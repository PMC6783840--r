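---
title: "Haplotype-block discovery and Bayesian genomic prediction with gshap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block discovery and Bayesian genomic prediction with gshap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gshap)
```

# The problem

In tree breeding, candidates are ranked by estimated breeding values.
The classical route uses the pedigree: an animal model whose additive
effects have covariance proportional to Wright's numerator relationship
matrix. Genomic selection replaces (or complements) the pedigree with
genome-wide markers, regressing phenotypes on thousands of SNP dosages
at once. Because outcrossing trees carry discrete runs of strong linkage
disequilibrium (LD) inside an otherwise fast-decaying background,
haplotypes within LD blocks can carry information individual SNPs miss —
a QTL in weak LD with every single marker can be in complete LD with a
haplotype. `gshap` implements both marker representations and the
machinery to compare them.

# Linkage disequilibrium and block discovery

## Two-locus EM

Genotypes are unphased, so two-locus haplotype frequencies are estimated
by EM over the 3×3 genotype table. Only double heterozygotes are
phase-ambiguous; the E-step splits them between the coupling and
repulsion configurations in proportion to the current frequency
products, and the M-step renormalizes. The EM preserves the observed
allele frequencies at every step, so the likelihood maximization is
effectively one-dimensional (over D at fixed margins); the test suite
verifies against a brute-force grid over exactly that family. The EM is
initialized at linkage equilibrium; when every individual is a double
heterozygote, equilibrium is a fixed point and the estimate is D = 0 —
the data genuinely contain no phase information, and this fixed point is
the documented behaviour rather than an error.

## D′, r² and the confidence bounds

From the EM table, `D = p11 p22 − p12 p21`; D′ divides |D| by the
maximum attainable |D| given the allele frequencies (branching on the
sign of D), and r² is the squared allele-frequency correlation. The
confidence bounds on D′ profile the genotype-table likelihood over a
grid of D′ values (step 0.01 by default) with allele frequencies fixed
at their MLEs and the sign of D fixed at the EM estimate; the
exponentiated profile is normalized to unit mass and the one-sided
5%/95% cumulative points are reported. This is the Haploview realization
of the Gabriel scheme, applied directly to unphased genotype likelihoods.

## Gabriel blocks

A marker pair is in *strong LD* when the CI upper limit is at least 0.98
and the lower limit at least 0.70; in *strong recombination* when the
upper limit is below 0.90; pairs with fewer than 20 pairwise-complete
individuals are uninformative (all thresholds configurable via
`gabriel_params()`). A candidate block requires strong-LD endpoints, at
least 95% of its informative pairs strong, and a span within 500 kbp —
a cap wide enough to admit the longest blocks reported for eucalypt
arrays. Final blocks are chosen greedily, longest span first, leftmost
on ties, without overlap. The 0.98/0.70 bounds are the published
algorithm's; the 0.90 recombination bound and the 95% informative
fraction are the algorithm's standard defaults, exposed as
configuration.

## LD extent

The Breseghello–Sorrells critical r² is the squared 95th empirical
percentile (R quantile type 7) of √r² over unlinked (inter-chromosomal)
pairs — all pairs when few, a seeded subsample of 10⁴ otherwise. The
decay profile bins intra-chromosomal pairs by distance; the crossing
distance is the midpoint of the first bin whose 3-bin moving average
falls below the critical value, reported as absent when no bin crosses.

# Haplotype encoding

Blocks are phased by a multi-locus EM that enumerates all haplotype
pairs compatible with each individual's genotypes (hard cap at 15 SNPs
per block, far above the 2–12 range blocks actually take). Individuals
are assigned their maximum-posterior diplotype, ties broken
deterministically toward the smallest variant pair. Copy coding is
0/1/2 copies of each block variant; per-individual copies across a
block's retained variants sum to 2 under complete data. Variants below
frequency 0.01 are dropped from designs by default (a display convention
of standard haplotype software; no published floor exists), leaving rows
that sum below 2 rather than a catch-all column. SNP columns are
oriented so 2 is the common-allele homozygote. Missing entries are
mean-imputed per column — common genomic-selection practice. Each
column records `p = mean/2`; for a multi-variant haplotype column this
treats the variant as a biallelic presence dosage, the only reading
under which the `2p(1−p)` variance weights apply.

# The models

All six models are Gibbs samplers sharing the residual structure
`ε ~ N(0, I σ²_ε)` and flat priors on design-block effects:

* **Animal model** — `a ~ N(0, A σ²_a)`; A⁻¹ is built directly by
  Henderson's rules with Mendelian-sampling variances adjusted for
  inbreeding (Meuwissen–Luo recursion); unknown parents (open-pollinated
  sires) contribute nothing. Additive effects are updated single-site
  using the sparse A⁻¹.
* **BRR** — common marker variance, scaled-inverse-χ² prior.
* **Bayes A** — per-marker variances, scaled-inverse-χ² priors (the
  marginal effect prior is scaled-t).
* **Bayes B / Bayes Cπ** — point mass at zero with probability π, slab
  variance per-marker (B) or common (Cπ); π carries a flat Beta(1,1)
  prior and is sampled unless fixed. Indicators and effects are updated
  jointly from the marginal likelihood ratio.
* **Bayesian LASSO** — double-exponential prior via the
  normal/exponential scale mixture; latent scales update by
  inverse-Gaussian draws and λ² by its Gamma full conditional. The
  Park–Casella rate convention (`τ² ~ Exp(λ²/2)`) is the default; the
  alternative `Exp(λ²)` convention is a switch, since published
  notation is ambiguous between the two.

Hyperparameters follow the usual apportioning: scaled-inverse-χ² df 5
throughout, scales set so the prior mode allocates half the phenotypic
variance to markers (R² = 0.5) and half to the residual; the animal
model sets both prior modes to half the phenotypic variance. These are
weakly informative at the sample sizes involved; the parameter-recovery
tests quantify what they imply in practice.

MCMC defaults are desk-scale — 20,000 iterations, 2,000 burn-in, thin
10 for the animal model and the same `mcmc_settings()` structure for the
genomic models (tests use shorter chains where the check allows it);
production-scale settings (10⁶ / 10⁵ / 50) are available by passing them
explicitly. Chains are driven by R's RNG, so a seed makes them
bit-reproducible. Ordinal scores are fitted as Gaussian on the observed
scale by default — the thresholds in the generator are equal-probability,
so scores are close to a monotone transform of the latent value; a
probit treatment is deliberately out of scope.

# Genomic parameters

Genomic variance is evaluated per retained draw:
`2 σ̂²_m Σ p_i(1−p_i)` for the common-variance models,
`2 Σ p_i(1−p_i) σ̂²_mi` for the per-marker models (Bayes B masks
excluded markers to zero), and `2 Σ τ²_i σ̂²_ε p_i(1−p_i)` for the
LASSO. Heritability is the per-draw ratio `σ²_g/(σ²_g+σ²_ε)`, mirroring
the pedigree form — the ratio form is an interpretation, stated as such.
These formulas assume linkage equilibrium among markers; on maps with
planted perfect-LD segments they double-count shared variance, which is
why the parameter-recovery scenario uses a segment-free map (block
structure is exercised by the block-recovery and encoding checks
instead). Genetic gain divides the selected-fraction mean breeding value
minus the population mean by the phenotypic mean; for ordinal traits the
phenotypic mean is the arithmetic mean of scores by default, with a
normal-score alternative behind a flag.

# Cross-validation and comparisons

Predictive ability repeats random 90/10 splits: fit on training rows,
predict validation GEBVs from training marker effects, correlate with a
reference, and average cycles (20 at desk scale, 100 for production).
The default reference is the whole-data-fit GEBV. For null calibration
this reference is unusable — CV predictions and whole-data GEBVs are
fits of the same noise and correlate strongly even when markers carry
nothing — so the calibration checks use the alternative reference the
package provides, validation phenotypes adjusted for fixed effects,
which are held out of training and give mean PA of zero under the null.
Cycles with zero-variance vectors are skipped and counted, never
averaged silently.

Model comparisons use all-pairs Tukey–Kramer on per-cycle PAs (raw
scale; a Fisher-z option was considered and omitted as the cycle counts
make the difference negligible), with studentized-range critical values
honouring unequal cycle counts, and a compact letter display assigned
from the best mean. Significance of genomic versus pedigree parameter
estimates is flagged by non-overlap of the two 90% credible intervals
(the stricter of the two common readings; exclusion-of-point is the
alternative rule).

# The synthetic generator

`simulate_population()` emulates a progeny-trial design: ~65 families of
~10, half open-pollinated (sire unknown; the pollen parent is a random
founder, unrecorded — matching how A treats unknown parents), a
30-block RCBD with single-tree plots, and traits spanning low to high
heritability including 7- and 6-level ordinal scores
(`study_traits()`). Founder LD is perfect-correlation segments —
within a segment one latent uniform per haplotype generates all alleles,
so D′ = 1 exactly and blocks are recoverable and checkable — scattered
among independent markers. Gametes recombine by Poisson crossovers at
10⁻⁸ per bp without interference. Residual variance is solved from the
realized breeding-value variance so the target heritability holds in
expectation; block effects default to one genetic standard deviation,
and the grand mean defaults to ten phenotypic standard deviations — a
coefficient of variation of ~10%, typical of field growth and wood
traits, which keeps genetic-gain percentages on a realistic scale.
One master seed derives independent per-stage substreams
(`derive_seed()`).

What the generator does *not* emulate: coalescent/demographic LD decay
(a copying-style decay option is out of scope), selection across
generations, genotyping error (quality control happens upstream of the
analysis this package implements), or sex chromosomes. Passing tests
therefore demonstrate correctness of the machinery under a known,
block-structured truth — not field performance on any particular real
population.

# Numerical choices and limitations

* EM convergence: max frequency change below 1e-8 (two-locus) / 1e-6
  (multi-locus); enumeration caps keep the multi-locus EM exact.
* The D′ grid step (0.01) bounds the CI resolution; a 0.001 step is
  available where the profile is steep.
* Pairwise-complete individuals per marker pair; pairs below 20
  individuals are unclassifiable.
* Greedy block selection is deterministic (span, then position), so
  reruns are hash-stable.
* Samplers stop with diagnostics on divergent variances; single-site
  updates of additive effects mix slowly on deep pedigrees — the
  desk-scale chain length was chosen so the parameter-recovery checks
  pass with margin on the simulated designs (a few hundred families,
  shallow pedigree), and longer chains are one argument away.
* Problem sizes in the shipped checks: unrelated panels of 400 for
  block recovery, populations of 650 progeny with 300–1,000 markers for
  model validation — sizes at which every stage completes on one core in
  minutes while leaving the estimators' behaviour visible.
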