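---
title: "Methods: standardizing yield trials with a weather-driven potential yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardizing yield trials with a weather-driven potential yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ypcgm)
```

## The problem and the model

Yield trials accumulate by the tens of thousands across breeding stations,
but a cultivar's recorded yield mixes its genetics with the quality of each
trial environment, and different cultivars are rarely tested side by side.
`ypcgm` makes those records comparable by scoring every environment with a
*theoretical potential yield* Yp — what an idealized crop could have
produced there given only the daily temperature and solar radiation — and
regressing each cultivar's observed yields on Yp:

$$Y_{obs}(i,j) = \alpha_i\,(Y_p(i,j) - SPY) + \beta_i + \varepsilon_{ij}$$

The slope $\alpha_i$ (yield-plasticity) measures responsiveness to
environmental quality; $\beta_i$ (yield-ability) is the expected yield at
the standardized potential yield $SPY$. Reading the regression at a fixed
$SPY$ rather than at $Y_p = 0$ matters: the raw intercept $b_i$ is an
extrapolation far outside the data and mixes slope and level, while
$\beta_i = \alpha_i\,SPY + b_i$ is evaluated inside the observed range and
behaves as a genuine genotypic trait (exact identity, enforced to 1e-12 in
the tests). The default $SPY$ of 8 t/ha corresponds to a good but commonly
reached environment for irrigated temperate rice.

The key assumptions are (i) yields respond approximately linearly to Yp
over the observed range; (ii) deviations from the line are exchangeable
noise across environments (management was comparably good everywhere); and
(iii) Yp needs to *rank and scale* environments correctly, not predict
yields absolutely — any monotone miscalibration of the crop model is
absorbed into the per-cultivar regression.

## The crop growth model

Yp for one environment is a daily accounting from transplanting to
maturity:

* **Phenology.** The developmental index (DVI) is 0 at transplanting, 1 at
  heading, 2 at maturity. Each day advances DVI by its effective
  temperature (mean temperature above `t_base_dev` = 10 °C) divided by the
  phase total, so the observed heading and maturity dates pin the endpoints
  exactly and no cultivar-specific thermal parameters or daylength model
  are needed. A phase with zero cumulative effective temperature is
  reported as undevelopable rather than silently producing NaNs.
* **Growth.** Daily biomass gain is `srad × interception(DVI) × rue_base ×
  temperature_factor(tmean)`. Interception rises along a logistic in DVI
  from `f0` = 0.05 at transplanting to at least 95 % of `f_max` = 0.95 at
  `dvi_closure` = 0.7, then declines linearly after heading at
  `senescence_rate` = 0.5 per DVI unit (leaf senescence as assimilate is
  redirected to grain). The temperature factor is a trapezoid: 0 at or
  below 10 °C, 1 between 20 and 30 °C, 0 at or above 42 °C.
* **Cold sterility.** Cooling degree-days (CDD) accumulate the shortfall of
  the daily mean below `t_base_cold` = 20 °C over the cold-sensitive
  window, taken as DVI in [0.75, 1.0] (booting to heading — the stage at
  which pollen development fails under cold). Spikelet fertility declines
  as a logistic in CDD, centered at `cdd50` = 40 °C·d with steepness 0.15
  per °C·d and normalized so fertility(0) = 1.
* **Yield.** `Yp = biomass × harvest_index × fertility / (1 − 0.14)`,
  i.e. grain dry mass re-expressed at the 14 % moisture convention of
  yield reporting (`rue_base` = 1.6 g DM/MJ, `harvest_index` = 0.45).

The functional forms (logistic canopy, trapezoid temperature response,
logistic sterility) and all constants are deliberate package defaults,
chosen to be standard textbook shapes for rice with sensible magnitudes;
they are all exposed in `cgm_params()` so users can recalibrate. The
analyses downstream depend on the structural properties the test suite
enforces — DVI endpoint exactness, monotonicity in radiation, linearity in
RUE and harvest index, fertility nonincreasing in CDD, bit-identical
determinism — not on the specific constants. Heat and drought stress,
CO₂ fertilization, soil fertility and irrigation-water temperature are
deliberately excluded; daily mean temperature is used rather than min/max.

## Cleaning and fitting

Records with negative or non-finite yields are logged and dropped as
invalid. Per cultivar, records whose yield lies more than 4.0 standard
deviations (sample SD about the mean) from the cultivar's *median* yield
are removed — the median centre makes the rule robust to the very outliers
it hunts, while the SD scale keeps it interpretable. Cultivars with fewer
than 20 remaining trials are excluded entirely; the bound is inclusive
(exactly 20 is kept), since 20 environments is where the leave-one-out
analysis below shows the regression stabilizing. Every exclusion is logged
with its rule.

Fits are ordinary least squares per cultivar. Robustness is checked by
leave-one-out cross-validation: `r2_pred` (1 − prediction SS / total SS,
reported as computed, possibly negative) is compared with `r2_fit`; their
gap shrinks towards zero as environments accumulate, which is the
package's operational definition of "does not overfit". RMSE comparisons
against alternative single predictors (season cumulative temperature,
cumulative radiation, panicle traits) use
`100 × (RMSE_x − RMSE_Yp)/RMSE_x`.

## Scenarios and genetic gain

`run_scenarios()` simulates hypothetical cultivars with fixed ability
(default 8 t/ha) and plasticities spanning 0–0.6 (six evenly spaced values,
CV1–CV6; the intermediate values are a package choice within the stated
range) across a set of environments, aggregated by calendar decade
(1980–1989 = "1980s"). The zero-plasticity scenario is constant at the
fixed ability by construction — a useful analytic anchor the acceptance
suite checks exactly. Genetic gain is the OLS slope of a coefficient on
cultivar release year, reported in kg/ha/year (slope × 1000) with a
two-sided t-test; relative plasticity gain is the alpha slope as a percent
of the group mean.

## Quantitative genetics

**Relationship matrices.** `G = XX'/m` from column-standardized dosages
(population variance, so `mean(diag(G)) = 1` exactly); missing dosages are
mean-imputed per SNP before standardization, and SNPs with minor allele
frequency below 0.05 are removed first. The pedigree numerator matrix A
uses the tabular recursion with unknown parents contributing zero, after a
topological sort that reports any cycle. The genome-by-pedigree
interaction kernel is the Hadamard product G∘A.

**Multi-trait BLUP.** The model is `y = mu + sum_k u_k + e` over cultivars
with traits (alpha, beta) stacked, `u_k ~ N(0, Sigma_k ⊗ K_k)` and
`e ~ N(0, R ⊗ I)`; the four model forms use K ∈ {G}, {A}, {G, A},
{G, A, G∘A}. The reference fit is a Gibbs sampler: inverse-Wishart updates
(identity scale, traits + 2 degrees of freedom — minimally informative at
the unit trait scale the generators use) for every covariance, a flat
prior on the means, and joint updates of each random term. With a single
kernel and complete phenotypes the term update is done in the
eigenbasis of K, where the per-cultivar conditionals decouple into 2×2
problems — this is what makes 10×10-fold cross-validation affordable.
Multi-kernel models use the general Kronecker conditional with a Cholesky
solve. Kernel inverses are eigen-floored (relative 1e-8) because dense SNP
panels and deep pedigrees give numerically singular matrices. Default
sampler length is 20,000 iterations with 5,000 burn-in; the tests and the
acceptance script use shorter, seeded chains (hundreds to a few thousand
iterations) and correspondingly reduced panels (200–300 cultivars,
800–5,000 SNPs), sizes at which the checked properties are already stable.
A fast EM-based REML point-estimate backend is available for the
single-kernel models and agrees with the Gibbs posterior means in the test
suite.

Held-out cultivars are predicted by the conditional mean
`K[test,train] K[train,train]^{-1} u_train` — identical to including them
as missing data, for point prediction, but cheaper. Heritability is
`σ²G/(σ²G+σ²E)` from the diagonal elements of the fitted covariances.
Cross-validation folds are stratified on quantile bins of the first trait
so every fold spans the phenotype range, refit per fold, aggregated across
folds before computing r and RMSE, and repeated with fresh seeded fold
assignments.

**GWAS.** Association scans use the mixed model with fixed intercept and
four principal components of the standardized genotype matrix (the same X
that defines G), a polygenic term with kinship covariance, and per-SNP
Wald t-tests. Variance components are estimated once on the null model by
REML on the eigendecomposition of K (a 1-D profile optimization in the
variance ratio) and reused for every SNP; exact per-SNP REML is an opt-in
flag and agrees closely in the tests. The Bonferroni threshold is
`log10(m/q)`; at m = 91,800 and q = 0.05 this is 6.264 — note that a
threshold of 6.191 sometimes quoted for panels of this size corresponds to
m = 77,625 tests, a discrepancy the function documentation records rather
than hides. Haplotype comparisons group cultivars by their homozygous
dosage vector at chosen SNPs (heterozygous or missing calls excluded),
drop groups below 4 members, and test with Kruskal–Wallis followed by
all-pairs Steel–Dwass — pairwise midrank statistics (ties by midranks)
referred to the studentized-range distribution — with Shapiro–Wilk and
median-centered Levene checks reported as diagnostics, since the rank
tests are the appropriate choice precisely when those fail.

## Synthetic data: what it does and does not emulate

The generators are pure functions of configuration and seed.
`gen_weather()` produces contiguous daily series from annual sinusoids
(temperature peaking in early August, radiation in late June) plus
Gaussian noise and per-site offsets; an injectable cold snap exercises the
sterility pathway, which ordinary synthetic summers rarely trigger.
`gen_trials()` inverts the coefficient model exactly: yields are
`alpha(yp − SPY) + beta + ε` with residual SD 0.84 t/ha by default (the
typical per-cultivar regression RMSE in large rice panels), potential
yields drawn uniformly over [0.1, 9.8] t/ha — matching the mean (~5) and
range such panels report, and wide enough that the documented recovery
tolerances are attainable at 300 environments; a narrower design would
leave beta, read at SPY = 8, weakly determined. Because the linear model
is applied outside its physical domain, occasional negative yields can be
drawn; they are left in place (the generative model is the specification)
and the cleaning step logs them as invalid. `gen_genotypes_pedigree()`
drops founder alleles through random-mating generations (SNPs unlinked)
and scales additive effects at shared causal SNPs to hit target
heritabilities and a chosen genetic correlation. Heritability-recovery
simulations use these pedigree-structured panels deliberately: with
unrelated individuals and thousands of SNPs the genomic relationships are
nearly the identity and h² is weakly identifiable at n = 300, whereas
family structure — which real cultivar panels have in abundance —
identifies it well.

What passing tests therefore show: the estimators recover the parameters
of their own generative models at realistic sizes, match independent
closed-form oracles exactly where those exist, and control error rates
under the null. What they do not show: robustness to spatial climate
gradients, linked markers and LD decay, shared management artifacts,
non-Gaussian yield errors, or selection-driven pedigree structure — none
of which the generators attempt to mimic.

## Numerical choices and limitations

Degenerate inputs fail loudly: constant-Yp designs, undevelopable phases,
all-SNPs-filtered panels, pedigree cycles (reported with the cycle path),
monomorphic SNPs in LD computations, and singular covariate matrices are
all errors with named causes. Non-PSD relationship matrices receive a
single 1e-8 diagonal jitter before failing. The LOOCV `r2_pred` is not
floored at zero. Scenario decade bins with no environments are omitted
with a warning. All stochastic components (generators, sampler, folds)
take explicit integer seeds and are bit-reproducible.

Known limitations: the crop model's constants are package defaults, not a
calibration to any particular dataset, so Yp values are meaningful
relatively rather than absolutely; the GWAS assumes the P3D approximation
(per-SNP exact REML is opt-in and slow); the multi-kernel Gibbs path is
an order of magnitude slower than the single-kernel eigen path; and the
pipeline models one trait pair (alpha, beta) — a joint model of all
individual trial records is out of scope.
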