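---
title: "Testing panmixia from low-coverage genotype likelihoods"
author: "panmixGL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing panmixia from low-coverage genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Marine species with large, mobile larval stages can in principle form a
single randomly mating population across an entire ocean basin. Deciding
whether a set of geographically dispersed samples is panmictic is a
*null-acceptance* problem: the analysis must be sensitive enough that "no
differentiation found" is informative, and every estimator in the chain
must be calibrated so that the null is not rejected spuriously. The
European eel is the canonical case: hundreds of individuals from localities
spanning a continental range, sequenced at very low coverage
(median ~1.4 reads per site), with the American eel as a diverged sister
species, a ~200-kb inversion-like haplotype segregating at intermediate
frequency everywhere, and a trickle of interspecific introgression.

At 1.4x coverage, genotypes cannot be called. Every inference in this
package therefore works from **genotype likelihoods** (GLs): for each
individual and site, the probability of the observed reads under minor
allele dosage g in {0, 1, 2}, with a single per-run base error rate e
(errors uniform over the three non-true bases):

L(g) = prod over reads [ (1 - g/2) P(base | major) + (g/2) P(base | minor) ],

with P(true base) = 1 - e and each error base e/3. GLs are stored
normalized (per site and individual the max log-likelihood is 0); a
zero-depth individual has a flat triple and is ignored by every estimator.

# The estimators

**Allele frequencies.** `estimateMAF()` maximizes the Hardy-Weinberg
likelihood of the frequency f by EM: expected dosage per individual under
the current f, then f updated as half the mean expected dosage over
covered individuals. Start f0 = 0.1, convergence |df| < 1e-8, at most 200
iterations, all sites vectorized. The observed-data log-likelihood is
non-decreasing (tested), the estimate matches a 1e-3 grid-search oracle,
and depth-0 individuals leave the estimate bit-identical.

**SNP calling and filters.** `callSnps()` forms
LRT = 2 [logL(f-hat) - logL(nearest monomorphic boundary)] with an
upper-tail chi-square(1) p-value. At the f = 0 boundary the statistic is
formally a 1/2 chi2(0) + 1/2 chi2(1) mixture; using chi-square(1) as-is is
conservative and matches common practice in GL pipelines. High-confidence
variants require p < 1e-6; minor-allele-frequency filters at 5% and 10%
are inclusive (>=) after folding to the minor orientation. The major
allele is pinned to the reference; allele ties break lexicographically
(A < C < G < T).

**PCA.** `pcaFromGLs()` iterates the individual-allele-frequency scheme:
posterior expected dosages under per-individual site priors, standardized
by sqrt(2 f (1 - f)), covariance across individuals, and per-individual
priors rebuilt from the top-e eigenvector reconstruction (clamped to
[1e-4, 1 - 1e-4]). The rank e is the largest gap among the leading 10
eigenvalues unless fixed by the caller. On certain (deep-coverage) GLs
the procedure is exactly dosage PCA (tested to 1e-6).

**Selection scan.** For SNP j with standardized dosage vector x_j,
D_j = (x_j' v_k)^2 / lambda_k for principal component k. Because
sum_j (x_j' v_k)^2 = M lambda_k, the statistic has mean exactly 1 over the
scanned sites, and under neutrality it follows chi-square(1); p-values are
upper tail. The scan runs per chromosome, so concatenating chromosomes
changes nothing. The methods text this design follows describes the
p-value as "two-tailed ... lower.tail = TRUE", which is internally
inconsistent; upper-tail outlier p-values are used here and the
discrepancy is noted rather than guessed around.

**Admixture.** `admixtureEM()` maximizes
sum log sum_g GL_g Binom(g; 2, h_ij), h = QF, by EM with multi-start;
F is clamped to [1e-6, 1 - 1e-6]; K = 1 reduces exactly to pooled
frequency estimation (tested). Site lists are downsampled to a cap
(default 2e6) with the run seed.

**Kinship and haplotype genotyping.** `kinshipFromGLs()` returns the
standardized-covariance (genomic-relationship) form
K_ab = mean_j x_aj x_bj over pairwise-covered sites. A per-pair
*correlation* was considered and rejected: the three genotype classes of a
haplotype block lie on one additive axis, and correlation discards the
dosage magnitude that distinguishes heterozygotes from derived
homozygotes — with it, the leading-eigenvector clustering provably merges
two of the three groups. `clusterThreeGroups()` projects individuals on
the leading kinship eigenvector and clusters with *exact* 1-D k-means
(dynamic programming over the sorted projection): deterministic, invariant
to input order, and immune to the initialization failures of iterative
k-means when one class holds most individuals. Clusters are ordered by
mean regional minor dosage (hom1 < het < hom2; haplotype 2 is the minor
regional haplotype); members farther than 3 within-cluster SDs from their
center are left unassigned, and a mean silhouette below 0.2 voids the
clustering with a warning.

**Diversity.** `safPerSite()` convolves per-individual GLs into the
likelihood of each derived-allele count d (binomial weights per
individual, hypergeometric normalization; verified against brute-force
enumeration at n <= 3). `sfsEM()` estimates the spectrum by EM (relative
log-likelihood tolerance 1e-6, at most 500 iterations). `windowThetas()`
computes per-site posteriors under the spectrum prior, sums expected
pairwise diversity and segregating-site indicators in 5-kb windows,
divides by the number of contributing sites, and forms Tajima's D with the
standard 1989 constants at 2n sequences (verified against an independent
textbook implementation to 1e-9; D is reported missing, never zero, when
no variation supports it). Ancestral states come from the outgroup read
consensus (`outgroupConsensus()`: majority pooled allele, N on ties), and
depth filters retain sites with total population depth in [15, 1000]; no
MAF filter is applied to diversity inputs because any frequency cutoff
biases spectrum-based estimators. The original pipeline's fractional
per-individual depth flag has no analogue at the pileup abstraction; an
individual contributes wherever it has at least one read.

**Selection load.** The within-generation selection argument is a
deterministic one-locus recursion under codominant fitnesses
1 : 1 - s/2 : 1 - s, solved in closed form for the s producing a target
one-generation shift (s = dp / (q (p' - p/2))), with survival measured as
mean fitness relative to the fittest genotype and compounded
multiplicatively over independent loci. The parameterization (p0 = 0.5,
survival relative to the fittest multilocus genotype) is a reconstruction
chosen because it reproduces both headline quantities exactly: a 0.05
shift at 10 loci costs 84% mortality, and at 100 loci leaves about 1 in
1e8 alive. A Wright-Fisher cohort simulation (n = 1e6) reproduces the
realized shift and survivor fraction (tested to 0.005 and 0.5%).

# The synthetic-data generator

`SimConfig()` + `simulateStudy()` generate the study conditions the
estimators assume:

* **Sampling design.** 10 localities x 40 diploids plus a 49-individual
  outgroup; Poisson depth with mean 1.4; base error 0.01. The real study
  reports 28-67 individuals per locality; a single `nPerLocality` is
  exposed instead of per-locality counts.
* **Frequencies.** Per-site ancestral-pool frequency uniform on
  [0.05, 0.95]; locality frequencies Balding-Nichols with parameter
  `fstTarget` (0 = panmixia; the Hudson estimator on the emitted table
  recovers the target to ±0.01 at 50k sites). Sites divide into fixed
  interspecific differences (0.15), shared polymorphisms (0.25,
  Balding-Nichols at `divergenceMafShift` = 0.3), outgroup-private
  polymorphisms (0.30, giving the outgroup genome-wide diversity
  comparable to the ingroup), and ingroup-private polymorphisms.
* **Inversion block.** A zero-recombination span (default demo: 200 kb at
  ingroup haplotype frequency 0.29, 0.98 in the outgroup). At 90% of span
  sites the two haplotype classes are diverged — haplotype 1 near-fixed
  (residual frequency U(0.01, 0.10)), the haplotype 2 founder carrying the
  opposite allele — and haplotype 2 adds sparse new mutations
  (rate 0.005/copy/site), so its homozygotes show depressed diversity and
  a more negative Tajima's D. Breakpoints are not modeled; the block is
  simply non-recombining, which is all the downstream analysis uses.
* **Introgression.** In the designated "mid-Atlantic" localities each
  individual carries the configured outgroup ancestry fraction (default
  demo: 3%) in disjoint contiguous segments.

What the generator does **not** emulate: linkage disequilibrium outside
the block (sites are independent draws), per-base quality variation,
mapping artifacts, indels or other structural variants, and coalescent
genealogies (the neutral site-frequency spectrum is therefore not 1/d
genome-wide; spectrum-recovery tests construct 1/d data explicitly).
Passing tests show the estimators are calibrated and mutually consistent
under these conditions, not that real data meet them.

# Numerical choices and problem sizes

Frequencies are clamped away from 0/1 wherever logs are taken
(PCA priors 1e-4, admixture F 1e-6). SAF convolution rescales per
individual to avoid underflow. The pipeline seed fans out to per-stage
child seeds by a fixed affine map, so a stage re-run in isolation sees the
stream it saw in a full run, and identical configurations give
byte-identical reports.

The shipped analysis sizes are chosen for a desk-scale, single-CPU run:
null calibration at 10 x 40 diploids and 20,000 SNPs; the inversion demo
at 5,000 SNPs on a 5-Mb chromosome (about 200 SNPs in the 200-kb block)
across 5 replicate seeds; diversity demos at a few thousand sites. These
sizes are stated here as the package's reference configurations; all of
them scale up by changing `SimConfig` fields.

# Known limitations

* The chi-square(1) boundary convention makes SNP-calling p-values
  conservative near f = 0.
* The selection statistic's chi-square calibration relies on many
  individuals (projections onto the leading eigenvector approach
  normality); with a few dozen individuals the tail is visibly light.
* The 3-SD unassignment rule leaves roughly 1-2% of individuals uncalled
  at 1.4x depth (projection noise is heavier-tailed than Gaussian because
  covered-site counts vary); which individuals are uncalled is
  seed-dependent. Calls that are made are essentially always correct.
* Tajima's D uses 2n sequences for the group regardless of per-site
  missingness; at very low depth within small groups this overstates the
  nominal sample size (the SAF still propagates the uncertainty).
* The load model ignores drift, dominance other than codominance, and
  linkage; it quantifies exactly the argument it supports and nothing
  more.
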