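---
title: "Methods: genotype-likelihood population genomics with pikapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population genomics with pikapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pikapop)
```

## The problem

Reduced-representation sequencing (ddRADseq/GBS) of non-model vertebrates —
the motivating case is the American pika (*Ochotona princeps*), a
dispersal-limited alpine lagomorph sampled across fragmented talus
metapopulations — yields thousands of SNPs at low-to-moderate coverage
(about 6x per individual per locus). At that depth, hard genotype calls are
unreliable, so every stage of this pipeline consumes per-individual,
per-site *genotype likelihoods* `P(reads | g)` for the three diploid
genotypes rather than called genotypes. The pipeline covers:

1. SNP panel filtering (completeness, minor allele frequency, positional
   thinning);
2. Bayesian admixture inference of individual ancestry coefficients `q` and
   the number of clusters `k`, compared by DIC;
3. PCA of posterior genotype dosages and Nei's genetic distance `D` between
   populations;
4. folded-SFS diversity estimation: nucleotide diversity `pi`, Watterson's
   `theta_W`, and Tajima's `D` in genomic windows;
5. landscape genetics: multiple regression on distance matrices (MRM) of
   Nei's `D` on geographic, elevational and climatic predictor distances.

A synthetic-data module generates inputs with known truth so that each
stage can be validated quantitatively without raw sequencing data.

## The central container

`GenotypeLikelihoodSet` extends `RangedSummarizedExperiment`: rows are
sites (a `GRanges` with `ref`/`alt`), columns are individuals, and the
assays are the three likelihood layers plus read depth. Likelihoods are
stored rescaled so the per-cell maximum is 1; every downstream computation
uses likelihood *ratios* only, so this normalization is lossless and avoids
underflow. The class validity enforces the two invariants the statistics
rely on: positions strictly increase within each scaffold, and cells with
zero reads carry flat (equal) likelihoods — no reads, no information.

VCF positions are 1-based inclusive (the format's convention); all window
and block arithmetic inside the package uses half-open, 0-based
`[start, end)` intervals, converted at the boundary. Written VCFs carry
GT (most-likely genotype, `./.` at depth 0), phred-scaled PL, and DP, so a
write/read round trip reproduces depths exactly and likelihoods to phred
quantization (about 12% in the worst case, a factor of `10^0.05`).

## The synthetic-data model

The generator is *not* a coalescent simulator; it reproduces exactly the
statistical structure the downstream estimators assume, which is what makes
it a sharp test instrument:

* **Allele frequencies.** Ancestral frequencies are Beta(`a`, `b`) draws
  truncated to (0.02, 0.98); the truncation avoids degenerate fixed loci
  that interact badly with the MAF filter. Each of `K` source populations
  draws its frequency from the Balding–Nichols Beta
  `Beta(pi(1-F)/F, (1-pi)(1-F)/F)`, so a single `F` per population dials
  divergence and the moments are analytically checkable.
* **Individuals.** Ancestry vectors are Dirichlet(`alpha`) (pure home-
  population ancestry at `alpha = 0`); genotypes are
  `Binomial(2, sum_k q_ik p_kl)` (HWE in the ancestry-mixed frequency).
* **Reads.** Depth is Poisson(`meanDepth`); alternate-read counts are
  binomial with success probability `eps`, `1/2`, or `1-eps` for genotypes
  0/1/2; genotype likelihoods are the corresponding binomial likelihoods.
  The binomial read model is a stated simplification — empirical
  bcftools-style genotype likelihoods include quality-weighted errors the
  generator does not emulate.
* **Sites.** Positions are drawn uniformly without replacement along
  scaffolds. Monomorphic ("invariant") covered sites are emitted alongside
  SNPs — per-site diversity denominators need them — at a configurable
  fraction, default 90% invariant, in the neighbourhood of reduced-
  representation data where most assayed positions are not SNPs.

Defaults mirror the motivating study design: four differentiated clusters
(sample sizes 35/21/28/87, totalling 171 individuals), mean depth 6.2x.
Where the design gives no value we fixed one realistic choice up front:
per-base error 0.005 (typical Illumina), ancestral Beta(0.8, 0.8) (mildly
U-shaped spectrum), divergence `F = 0.3` per cluster (matching the
between-lineage Nei's D scale of 0.2–0.5 observed in range-wide pika data).

A second generator, `simulateSfsSites()`, draws segregating sites whose
allele counts follow an *arbitrary* unfolded SFS (default neutral,
`P(j) proportional to 1/j`), which gives direct control over the quantity
the diversity stack estimates: depleting rare classes must push Tajima's D
positive, inflating singletons negative. `simulateClimateGeography()`
builds 19 bioclim-style variables from two latent gradients — eleven
temperature variables linear in elevation (default lapse rate 6.5 units per
km, the standard environmental lapse rate) and eight precipitation/
seasonality variables on one smooth spatial gradient — plus per-variable
noise, so the climate PCA concentrates variance on two components, as real
bioclim layers do.

**What passing tests do and do not show.** The generator has no linkage
disequilibrium, no demographic history, no inbreeding, and no mapping
artefacts. Tests passing on it demonstrate the *estimators* are correct
under their own assumptions; they do not certify behaviour on real data
where those assumptions fail (LD between nearby RAD loci is the main one —
which is exactly why the thinning filter exists).

## SNP panel filtering

* **Completeness**: a site is kept iff at least `ceiling(t * N)`
  individuals have one or more reads (default `t = 0.92`; with 171
  individuals the required count is 158). The ceiling means a site must
  meet or exceed the fraction; with rounding down, a site below the
  fraction could pass.
* **MAF**: allele frequency is the maximum-likelihood estimate under HWE
  computed from the genotype likelihoods by EM
  (`f' = sum_i E[g_i | f] / 2N`, tolerance 1e-8, 200 iterations) rather
  than from called genotypes, consistent with the genotype-uncertainty
  design of the whole pipeline. Sites with minor allele frequency
  *strictly below* 0.05 are removed; the boundary is kept. A numerical
  slack of 1e-9 keeps exact-boundary sites from being dropped by EM
  convergence error.
* **Thinning**: each scaffold is partitioned into *fixed* half-open
  1000-bp blocks and one SNP per non-empty block is retained uniformly at
  random (seeded). Fixed blocks — rather than sliding windows or
  distance-to-previous-SNP — are the simplest deterministic reading of
  "one SNP per 1000 bp" and make the retained count equal to the number of
  non-empty blocks, an easily auditable invariant.

The stages telescope into a `FilterReport`; diversity estimation must
*not* consume the MAF-filtered panel (removing rare variants biases the
SFS), so `diversitySummary()` is run on the unfiltered-by-MAF site set.

## The admixture model

Each of the two allele copies at `(i, l)` draws an ancestry
`z ~ Categorical(q_i)` and an allele `~ Bernoulli(p_zl)`; priors are
`q_i ~ Dirichlet(1, ..., 1)` and `p_kl ~ Beta(1, 1)`. The Gibbs sweep
samples the genotype from `GL_il(g) x P(g | q_i, p_l)`, then the two copy
ancestries given the genotype, then conjugate Beta/Dirichlet updates — so
genotype uncertainty propagates into `q` instead of being collapsed first.
This is a deliberately reduced form of the entropy-style hierarchical
model: there is no sequencing-error free parameter and no within-cluster
inbreeding coefficient; the quantities used downstream (`q`, genotype
posteriors, DIC over `k`) are all covered.

Chains are initialized from k-means on naive-dosage PC scores followed by
LDA class posteriors (floored at 0.001), which stabilizes mixing; if the
cluster geometry is degenerate (singleton clusters) the initializer falls
back to one-hot k-means labels. Label switching is resolved *across*
chains by greedily matching cluster frequency vectors to the first chain
before averaging; within-chain switching is rare at the divergence levels
where the model is identifiable. DIC is `Dbar + pD` with
`pD = Dbar - D(posterior mean)` and the deviance marginalizes genotypes;
DIC ties in `selectK()` go to the smallest `k` (parsimony) and are
messaged. Exact chain-averaged `q` is reported rather than any single
chain.

Defaults are the full-study chain design (40,000 steps, 10,000 burn-in,
thin 10, 5 chains). The package tests and acceptance script use
scaled-down chains — 2,000 steps, 500 burn-in, thin 5, 2 chains, at
N = 40, L = 500, depth 10 — sizes at which parameter recovery (mean
absolute `q` error < 0.05) and DIC selection of the true `k` are
reproducible in seconds per fit. The sampler core is C++ (Rcpp) and uses
R's RNG, so `set.seed` governs it.

## PCA and Nei's D

PCA of dosages is centered, *unscaled* (dosages share units; scaling would
up-weight rare variants), with a fixed sign convention (largest-magnitude
loading positive per component). Population allele frequencies are mean
posterior dosage over two. Nei's standard distance is computed from the
biallelic identities `J_x`, `J_y`, `J_xy`; `D = -ln(J_xy / sqrt(J_x J_y))`,
with opposite fixation at every locus yielding a flagged `+Inf`. A PHYLIP
export is provided for external tree builders; tree rendering itself is
out of scope.

## Diversity: SAF, folded SFS, thetas, Tajima's D

The per-population site allele-frequency likelihood
`P(reads | j alt alleles among n = 2 n_ind chromosomes)` is computed by
dynamic programming over individuals: convolving each diploid's likelihood
triple weighted by genotype multiplicities (1, 2, 1) and dividing column
`j` by `choose(n, j)`. This equals brute-force enumeration over all `3^n_ind`
genotype configurations (verified exactly in the tests) while costing
`O(n_ind * n)` per site. Rows are renormalized during the pass to avoid
underflow.

The folded SFS `phi` (minor-allele classes `0..floor(n/2)`; fold by adding
SAF entries `j` and `n-j`) is the EM maximizer of
`sum_sites log sum_j phi_j SAF_fold(j)` (tolerance 1e-6, 500 iterations).
With `phi` as an empirical-Bayes prior, the per-site posterior over `j`
gives the expected contributions `E[pi] = sum_j post(j) j(n-j)/C(n,2)` and
`E[theta_W] = P(segregating)/a1`. Both weights are symmetric under
`j <-> n-j`, so the fold ambiguity resolves trivially (symmetrized
posterior, unfolded weights). Sites with no reads in the population are
excluded — they would merely echo the prior — and the per-site rates are
*sites-weighted* means (total contribution over sites with data, variant
and invariant alike); unweighted per-scaffold means can be derived from
the per-site track if wanted, but whether to weight scaffolds is a
genuinely open convention and the weighted form is the one whose
denominator we can state precisely.

Windowed Tajima's D uses fixed non-overlapping 50-kbp windows:
`D = (S_pi - S_theta) / sqrt(e1 S + e2 S(S-1))` with the standard constants
and `S = a1 * S_theta` as the implied segregating-site count. Windows with
`S = 0` (or a non-positive variance term, possible for tiny fractional `S`)
emit no value.

## Landscape genetics

Population coordinates are sample midpoints (mean latitude/longitude).
Geographic distance is haversine on a sphere of radius 6371 km (the
conventional mean radius); elevational distance is `|e_i - e_j|`; climatic
predictors are absolute score differences on the first two climate PCs.
The climate PCA is *scaled* by default because the 19 variables mix units
(degrees, millimetres, indices); a flag disables scaling and both paths
are tested.

MRM unfolds strictly-lower triangles to `n(n-1)/2`-vectors, fits OLS with
intercept, and tests `R^2` (and each `|t|`) by jointly permuting rows and
columns of the *response* matrix — the documented behaviour of the
standard MRM implementations — with `p = (1 + #{perm >= obs}) / (1 + nPerm)`
and a default of 999 permutations (reported with every p-value).
`modelScan()` fits all `2^m - 1` predictor subsets (15 for the canonical
Elevation/Geography/Climate 1/Climate 2 set) and sorts by `R^2`; nested
models necessarily satisfy `R^2(superset) >= R^2(subset)`, which the tests
assert as a structural invariant. Under the null, the permutation test's
rejection rate at `alpha = 0.05` is calibrated (checked over 50 null
replicates at 199 permutations).

## Numerical choices and degenerate inputs

* Likelihood cells are guarded at 1e-300 before logs/divisions; all-zero
  likelihood cells are rejected at construction.
* All-flat sites return EM frequency 0.5 with a warning flag.
* `k > N`, fewer than 2 individuals (PCA, SAF), fewer than 3 sites
  (climate PCA), rank-deficient MRM predictor sets, and non-biallelic VCF
  records are errors (or skipped-with-count where the format makes that
  the only practical policy).
* Every stochastic step takes an explicit seed and restores the caller's
  RNG state; the same seed gives byte-identical simulated VCFs.

## Known limitations

* The admixture model omits the sequencing-error and inbreeding terms of
  the full entropy model; at very low depth with contaminated libraries it
  will be optimistic.
* The generator's independence across sites means uncertainty intervals
  derived from it understate real-data variance where RAD loci are linked.
* Diversity estimates inherit the read model: systematic base errors
  (rather than the independent binomial errors simulated) would inflate
  singleton classes and bias Tajima's D downward.
* MRM inference is marginal per model; no correction is applied across the
  15 models of a scan, matching standard practice for these tables.
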