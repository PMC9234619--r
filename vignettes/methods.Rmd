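---
title: "Methods: genomic selection for heat tolerance in Pacific abalone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic selection for heat tolerance in Pacific abalone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abaloneGS)
```

## The problem

Summer marine heatwaves cause mass mortality in farmed Pacific abalone
(*Haliotis discus hannai*). A practical heat-tolerance phenotype is
**attachment duration** under an acute 32&nbsp;°C challenge: the number of hours an
animal stays attached to its substrate before dropping, censored at the 6-hour
assay length (survivors are recorded at the ceiling). The trait is continuous,
moderately heritable, and apparently controlled by many loci of small effect —
exactly the setting in which genomic selection outperforms marker-assisted
selection. This package implements the full analysis chain for such a program:
SNP quality control, population structure, mixed-model GWAS, genomic
prediction by GBLUP and BayesB, and a cross-validated comparison of
GWAS-ranked versus random low-density SNP panels.

The genotype data behind the original study are not deposited, so the package
ships a synthetic-population generator that emulates the study design
(~1120 offspring of ~400 random-mating broodstock, 18 chromosomes, ~0.8%
missing calls, h² ≈ 0.35–0.42) and every statistical claim the test suite
makes is made against that generator or against closed-form oracles.

## Models

### GBLUP

$$y = Xb + Zg + e, \qquad g \sim N(0, G\sigma_g^2), \quad e \sim N(0, I\sigma_e^2)$$

with $b$ the fixed effects (intercept and rearing batch, plus leading
principal components in the GWAS null model) and $G$ the VanRaden (method 1)
genomic relationship matrix

$$G = \frac{ZZ'}{2\sum_j p_j(1-p_j)}, \qquad Z = M - 2P .$$

Variance components are estimated by REML using the eigendecomposition of
$G$: after rotating by the eigenvectors the covariance is diagonal in the
variance ratio $\lambda = \sigma_g^2/\sigma_e^2$, so the restricted likelihood
profiles to a smooth 1-D function of $\log\lambda$ that we maximize
derivative-free (interval $[-14, 14]$, tolerance $10^{-8}$ by default, with an
explicit comparison against the $\sigma_g^2 = 0$ boundary — a boundary
estimate is returned flagged, not as an error). This is exact for a single
random effect. Standard errors come from the numerical Hessian of the
restricted likelihood in $(\sigma_g^2, \sigma_e^2)$; the heritability SE uses
the delta method. Phenotypic variance and heritability are
$\sigma_P^2 = \sigma_g^2 + \sigma_e^2$ and $h^2 = \sigma_g^2/\sigma_P^2$.

Held-out prediction masks test phenotypes and recovers test GEBVs through the
training–test covariance block of $G$; the test suite verifies this against
an independently hand-coded Henderson mixed-model-equation solve.

### BayesB

$$y = Xb + Mu + e$$

with a spike-and-slab prior on each marker effect: zero with probability
$\pi$ (default 0.95, fixed, not estimated), otherwise normal with a
locus-specific variance carrying a scaled-inverse-$\chi^2(\nu, S)$ prior.
The Gibbs sampler (C++, driven by R's RNG so chains are bit-reproducible
under a seed) updates: fixed effects from normal full conditionals; per SNP
the inclusion indicator from the marginal likelihood ratio with the effect
integrated out, then the effect from its normal full conditional and the
locus variance from its scaled-inverse-$\chi^2$ conditional; the residual
variance from its inverse-$\chi^2$ conditional. Genotype columns are centered
internally, and GEBV $= M_c\,\mathrm{E}[u]$.

Hyperpriors are not specified in the source study; we default to $\nu = 5$
and choose $S$ so the prior mean total marker variance corresponds to an
assumed $h^2$ of 0.5 spread over the non-null marker fraction (the common
convention of Bayesian-regression packages); both are exposed. Two chain
profiles exist: `fast` (5&nbsp;000 iterations / 500 burn-in; tests, smoke runs)
and `paper` (100&nbsp;000 / 3&nbsp;000; study-faithful).

Two deliberate design points:

* **$\nu = \infty$ freezes every locus variance at $S$**, which together with
  $\pi = 0$ makes the sampler an exact Bayesian ridge (RR-BLUP). Strict
  BayesB with $\pi = 0$ is BayesA, whose heavier-tailed prior is *not*
  exactly GBLUP; the ridge limit is what makes the GBLUP-equivalence oracle
  exact, and the equivalence test (GEBV correlation > 0.99 at matched
  variance) uses it.
* The study reports a single additive variance for BayesB without defining
  its estimator; we report $\widehat{\sigma}_g^2 = \mathrm{Var}(M_c\,\mathrm{E}[u])$
  across individuals and additionally expose the posterior mean of the
  per-iteration genetic variance (`sigma_g2_mcmc`) for diagnostics. The two
  differ by MCMC shrinkage; ours is documented, not asserted to be the
  study's.

### GWAS

The scan is a single-marker **EMMAX-style mixed linear model**: variance
components are estimated once under the null (covariates: intercept, batch,
and by default the first three principal components; kinship random effect),
and each marker receives a Wald test in the rotated, weighted least-squares
problem with the variance ratio held fixed. The original study used BLINK, a
published multi-locus algorithm we deliberately do not re-implement; the
EMMAX scan preserves the covariate structure, thresholds and outputs while
being implementable from first principles. Effects are reported per
minor-allele copy (at MAF exactly 0.5 the orientation is tie-broken by the
counted allele; p-values are invariant either way).

Thresholds: genome-wide Bonferroni $\alpha/m$ (for the study's
$m = 64\,788$: $7.72\times10^{-7}$, $-\log_{10} = 6.11$) and the
conventional suggestive $10^{-5}$. A p-value exactly at a threshold passes it
— the boundary goes untested in the source tables, so we fix the convention
and test it. Per-SNP variance explained uses the standard
$\mathrm{PVE} = 100\cdot 2p(1-p)\beta^2/\hat\sigma_P^2$; the study never
states its PVE formula, so printed PVE values are used only as worked-example
*inputs* (their classification counts and their 8.22% sum), never as numbers
this package claims to reproduce.

Candidate-gene annotation reports every gene overlapping a significant SNP or
within a configurable window (default 50 kb), else the nearest gene with its
distance. The toy GFF3 annotation carries gene spans only, so SNPs inside a
gene are labeled `genic` rather than intron/exon — a documented limitation.

### Population structure

Principal components come from the eigendecomposition of the GRM (scores are
eigenvectors scaled by the square root of their eigenvalue). Whether the
original analysis derived PCs from the GRM or from a separate genotype
standardization differs only by scaling; we document GRM-based as canonical.
Each leading eigenvalue is tested against the Tracy–Widom (GOE) null using
the moment-matching estimate of the effective marker number from the spread
of the remaining eigenvalues; TW p-values are log-linearly interpolated from
embedded published significance points. The pipeline passes the first three
PCs to the GWAS regardless, matching the source covariate structure.

## The synthetic world

The generator states, rather than tunes, its world:

* **Founders**: 400 broodstock; per-SNP frequencies uniform in
  [0.05, 0.5]; within-chromosome LD from a latent Gaussian AR(1)
  (haplotype-copying analogue) with `ld_rho = 0.9`, thresholded so marginal
  frequencies are exact and `ld_rho = 0` gives independent sites. The study
  reports no LD information; this model was chosen for O(m) cost and a
  tunable r² decay.
* **Mating**: random pairs of distinct parents, one gamete each with exactly
  one crossover per chromosome at a uniform position — the simplest model
  consistent with linkage. Full- and half-sib families arise naturally.
* **Trait**: a sparse architecture of many minor-effect QTLs; effects drawn
  double-exponential (a few loci reach the ~1% PVE scale) and rescaled so
  the realized additive variance is 0.9 — the variance scale of the study's
  Table-3 components. Residual variance is then set from the realized
  Var(g) so the variance ratio equals the target h² (0.40 by default)
  exactly in parameters; batch effects (4 batches, SD 0.5 h) are assigned
  round-robin; intercept 3.2 h. Phenotypes are clamped to [0, 6] h —
  right-censoring at the assay ceiling (survivors at 6 h, ~5–8% of animals,
  matching the study's 8.75% final attachment rate) and a floor at 0 since
  negative durations are unphysical. How the real analysis scored
  still-attached animals is unstated; we adopt the ceiling convention and
  flag it.
* **Missingness**: i.i.d. masking at 0.8%.

What the generator does **not** emulate: coalescent-grade LD structure,
genotyping-error patterns, selection or non-random mating, sex and maternal
effects, and the real (unpublished) genome and annotation. A green test
therefore establishes that the *methods* behave correctly in a population
with the study's design parameters — not that the study's exact real-data
numbers are recovered, which is impossible without the undeposited
genotypes. The study's headline real-data accuracies (0.40/0.55, top-5K
0.61/0.72) are consequently not acceptance targets; its printed worked
examples and qualitative panel results are.

## Cross-validation and SNP panels

Five-fold cross-validation, ten repeats; folds are balanced uniform
partitions, deterministic under a seed. Accuracy is the Pearson correlation
between observed phenotypes and GEBVs in the held-out fold (raw phenotypes,
as in the source; a batch-adjusted variant exists but is off by default).
Bias is the regression coefficient of phenotype on GEBV, computed per repeat
on pooled out-of-fold predictions — the source is ambiguous between per-fold
and pooled; pooled is stabler at fold size ~224.

Panels: `top_gwas` (smallest p-values, ties broken by chromosome then
position), `random` (uniform without replacement), `all`. The source does
not say whether its top-SNP ranking was re-run inside each training fold;
ranking on the whole data leaks test phenotypes into panel selection.
The default is `fold_safe` (re-rank within each training fold);
`whole_data` is provided to mimic the common practice and the test suite
demonstrates the inflation it causes on null data (accuracy ≈ 0.36 where
fold-safe gives ≈ 0).

## Numerical choices and degenerate inputs

* GRM requires ≥ 2 SNPs and errors on all-monomorphic input (zero
  denominator); individual monomorphic SNPs contribute nothing and are kept.
* A configurable diagonal ridge (default $10^{-6}$) is applied by the
  mixed-model fitters, not by the GRM constructor, so the GRM itself stays
  exactly VanRaden (the brute-force oracle equality is to $10^{-12}$).
* QC filter order is fixed: individuals → SNP call rate → MAF, with MAF
  recomputed after removals; all inequalities strict. The order is unstated
  in the source; this one is documented and idempotent.
* Naive imputation (mean `2p` or Hardy–Weinberg draw) replaces BEAGLE;
  at 0.8% missingness the difference is statistically immaterial, and
  haplotype-aware imputation is out of scope.
* Monomorphic SNPs in the scan get β = 0, p = 1, and a flag.
* A zero-variance GEBV vector in a CV fold (boundary REML fit on a panel
  with no signal) leaves that fold's accuracy undefined (NA, skipped with
  `na.rm` in aggregates) rather than failing the grid.
* Seed derivation: every pipeline stage hashes the global seed with the
  stage name, so adding a stage never perturbs earlier stages' randomness.

## Calibration-test design

The null-calibration acceptance test permutes a phenotype and requires the
scan's p-values to pass a Kolmogorov–Smirnov uniformity check. KS assumes
independent observations; in a family-structured population, background LD
makes single-marker statistics mutually correlated even when each is
perfectly calibrated marginally, and the KS test then over-rejects. The
calibration panel is therefore drawn without family structure (i.i.d.
Hardy–Weinberg dosages) — the canonical design for testing a scan's
calibration in isolation. Robustness to family structure is covered
separately by the null-heritability recovery test and the leakage
demonstration.

## Known limitations

* BLINK, BEAGLE and EIGENSOFT internals are intentionally out of scope;
  their roles are filled by EMMAX-style MLM, naive imputation, and our own
  Tracy–Widom PCA.
* The BayesB heritability estimator is a documented package choice (see
  above), so its value is comparable across runs of this package but not
  guaranteed to equal other software's definition.
* Tracy–Widom p-values are interpolated from a coarse published grid and are
  meant for significance flagging at conventional levels, not for precise
  tail probabilities.
* The per-locus variance prior makes BayesB results sensitive to `S` on very
  small datasets; the default `S` heuristic assumes the phenotype variance
  is a sensible scale for the genetic variance.
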