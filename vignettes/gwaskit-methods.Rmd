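---
title: "Models and methods behind gwaskit"
author: "gwaskit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gwaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gwaskit is a complete engine for genome-wide association studies (GWAS):
it converts the common genotype formats into a file-backed store, models
population structure and relatedness through a genomic relationship
matrix (GRM), estimates variance components by four routes, and scans
markers with three association models sharing one algebraic kernel.
This vignette explains the statistical models, the numerical choices,
and what the validation suite does and does not demonstrate.

## The file-backed genotype store

The dosage matrix (m markers by n samples, additive 0/1/2 coding or
fractional dosages in [0,2]) is written once to a flat binary file —
one byte per hard call with 255 as the missing sentinel, or eight bytes
per fractional dosage — alongside a JSON header and a tab-delimited
marker map. Every downstream operation reads marker rows in bounded
blocks through seeks, so peak memory for a scan is O(block x n) no
matter how large m grows, and forked scan workers share the immutable
file instead of copying the matrix. `peakBlockRows()` exposes an
instrumented counter so this contract is testable rather than
aspirational.

Missing genotypes are mean-imputed per marker on the fly for the GRM
and the scans (`onMissing = "fail"` hard-fails instead). Imputation
proper — e.g. with Beagle — is deliberately out of scope: the package
expects externally imputed or hard-called data. Half-missing VCF calls
such as `./1` are treated as fully missing; multiallelic VCF records
are skipped with a logged count rather than split.

## Relationship matrix and principal components

The GRM follows VanRaden's centered cross-product construction:
markers are centered by twice the allele frequency (computed on the
analyzed subset after imputation) and

$$G = \frac{Z^\top Z}{2\sum_j p_j(1-p_j)},$$

summed over polymorphic markers; monomorphic markers contribute to
neither numerator nor denominator. Some tools scale by
$\sum_j p_j(1-p_j)$ without the factor 2; the `denominator` argument
(`"vanraden2"`, the default, vs `"unscaled_pq"`) preserves both
conventions — the choice rescales $G$ by a constant, which cancels in
heritability and association statistics.

The full symmetric eigendecomposition of $G$ is computed once per
analysis and reused everywhere:

* **PC scores**: column $j$ is $U_j\sqrt{\lambda_j}$. These match the
  left singular vectors of the centered genotype matrix (the direct
  SVD route) because $G$ is, up to scaling, the Gram matrix of that
  matrix. Computing them from the n-by-n GRM is the cheapest of the
  equivalent routes whenever m exceeds n, and the GRM is needed anyway.
  Eigenvector signs are fixed so the largest-magnitude loading is
  positive, making results reproducible across LAPACK builds.
* **REML** and the **MLM scan** consume the same object (below).

`eigenCount()` counts decompositions; the pipeline asserts the count is
exactly one per run. Eigenvalues are clipped at −1e−8: anything more
negative indicates a malformed input matrix and raises an error instead
of being silently truncated.

## Variance components

All likelihood-based estimators maximize the same restricted likelihood
of $y = X\beta + g + e$, $\mathrm{Var}(g) = \sigma_g^2 K$,
$\mathrm{Var}(e) = \sigma_e^2 I$, parameterized by heritability
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ with the total variance
profiled out analytically. In the eigenbasis of $K$ the covariance is
diagonal with entries $h^2\lambda_i + (1-h^2)$, so each objective
evaluation is O(np) after a one-time rotation and no n-by-n inverse is
ever formed. REML (not ML) is used throughout: it is the field
standard for variance components and what the mixed-model scan's
population-parameters-previously-determined (P3D) step expects.

* **Brent** (default): derivative-free 1-D maximization over
  $h^2 \in [10^{-6}, 1-10^{-6}]$ with absolute tolerance 1e−6 on
  heritability itself — convergence is judged on the parameter of
  scientific interest, not on each variance separately.
* **EMMAX-style grid**: 100 log-spaced points of
  $\delta = \sigma_e^2/\sigma_g^2$ in $[10^{-5}, 10^5]$, then Brent
  refinement inside the best bracket. Same objective, robust to
  multimodality; the suite asserts the two routes agree to 1e−3.
* **Low-rank spectral route**: the same objective evaluated through the
  nonzero singular structure of the scaled marker matrix plus the
  identity complement. When m &lt; n this is a thin SVD of the m-by-n
  matrix; otherwise the identical components come from the n-by-n Gram
  matrix. Used directly, and reused by FarmCPU for its pseudo-QTN
  kinships (rank at most the pseudo-QTN count, so each fit is cheap).
* **Haseman-Elston regression**: residualize on covariates,
  standardize, regress pairwise phenotype products on the
  corresponding $G_{ij}$ (upper triangle only, diagonal excluded,
  intercept included); the slope estimates $h^2$, clipped to [0,1].
  Moment-based, no eigendecomposition, noticeably noisier — the suite
  holds it to a wider (0.15 vs 0.1) recovery band.

When $K$ is proportional to the identity the profile likelihood is flat
in $h^2$; the estimators return $h^2 = 0$ with an explanatory flag
rather than an arbitrary interior point, and the MLM then reduces
exactly to the GLM.

## The blockwise scan kernel

For a covariate block $w$ (intercept, PCs, user covariates, FarmCPU
pseudo-QTNs) and one tested marker $x$, every scan needs
$([w,x]^\top [w,x])^{-1}$. Writing the Schur complement
$s = x^\top x - x^\top w (w^\top w)^{-1} w^\top x$, the four blocks of
the inverse follow from $(w^\top w)^{-1}$ and $1/s$, so the covariate
inverse is computed once per scan instead of once per marker. A marker
collinear with the covariates ($s \le 10^{-12}$, which includes all
monomorphic markers) is flagged degenerate and reported as missing.

The GLM reports the marker coefficient, its standard error
$\sqrt{\hat\sigma_e^2/s}$ with $\hat\sigma_e^2 = RSS/(n-k-1)$, and a
two-sided t p-value on $n-k-1$ degrees of freedom (the reference
distribution is a package choice; at these sample sizes t vs normal is
immaterial). Perfect fits report the smallest positive normal double
with a flag — never an exact zero p-value. The MLM under P3D rotates
$y$, $w$ and each marker by $U^\top$, whitens by
$1/\sqrt{h^2\lambda_i + (1-h^2)}$ and runs the identical kernel:
weighted least squares in the rotated basis is exactly GLS under the
fixed variance components. Markers are processed in contiguous blocks;
forked workers write into disjoint row ranges of a preallocated table,
so results are bitwise identical for any worker count.

## FarmCPU

FarmCPU alternates a fixed-effect model (FEM) and a random-effect model
(REM). The FEM is the GLM kernel with the current pseudo-QTN dosages
appended as covariates — a pseudo-QTN is removed from the block while
it is itself the tested marker. The REM selects pseudo-QTNs: markers
passing a Bonferroni-informed entry threshold (previous FEM
p &lt; 0.01/m) are binned at each candidate bin size
(0.5, 5, 50 Mb), the best marker per bin is kept (ties: smaller p,
then lower position), and the (bin size, count) combination — counts
10, 20, ..., 100, capped at n/10 — that maximizes the restricted
likelihood of a kinship built from those markers alone is chosen. The
loop stops when the set repeats or after `maxLoop` (default 10)
iterations, and the final FEM statistics are reported. All of these
defaults are exposed as arguments, since the literature varies on the
exact grids.

## Simulated truth

The simulator is first-class, tested code, not a fixture: ancestral
frequencies uniform on [0.05, 0.5]; subpopulation drift via
Balding-Nichols Beta sampling at divergence F; cryptic relatedness via
full-sib family blocks with Mendelian transmission from simulated
parents; phenotypes as a sum of QTN effects (standard normal, or
equal-variance-share with random sign) plus noise that is decorrelated
from the genetic values in-sample and then scaled so the realized
heritability equals the target exactly. Marker maps spread markers over
10 chromosomes at about 1 marker/kb. What it does **not** emulate:
linkage disequilibrium between markers, minor allele frequency spectra
from real demography, genotyping error, and case-control traits.
Passing tests therefore validate the estimators' algebra and their
behavior under structure and relatedness, not robustness to LD or
ascertainment artifacts of real panels.

Validation problem sizes were chosen to exercise the regimes that
matter while staying comfortable on a laptop: oracle comparisons at
n = 40–200 where dense inverses are exact and cheap; recovery,
calibration and power studies at n = 1000 samples and m = 10,000
markers with 10–20 replicates; the streaming-memory check on an
m = 50,000 store.

## Numerical and design notes

* Degenerate inputs: all-monomorphic marker sets error (the GRM
  denominator would be zero); all-missing markers impute to zero and
  flag as monomorphic; rank-deficient covariate matrices error rather
  than silently dropping columns.
* The genomic inflation factor is the median observed $\chi^2_1$
  quantile over 0.4549; at least 100 p-values are required.
* Manhattan plots place chromosomes on a cumulative axis with a gap of
  1% of genome length; the default threshold line is Bonferroni
  0.05/m. Circular layouts normalize each track's $-\log_{10}p$ to its
  own radial band. Every plot function returns (and writes) its
  coordinate table — the tests assert coordinates, never pixels.
* Q-Q plots use expected quantiles $-\log_{10}((i-0.5)/N)$ and a 95%
  band from the beta distribution of uniform order statistics.
* Known limitations: no binary-trait (logistic) models, no multi-trait
  models, no dominance/epistasis terms, no LD-aware pseudo-QTN
  handling beyond binning, no quality-control filters — inputs are
  expected to be pre-filtered.
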