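---
title: "Geographically weighted twin models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographically weighted twin models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Twin studies decompose the variance of a trait into additive genetic (A),
shared environmental (C) and non-shared environmental (E) components by
comparing the resemblance of monozygotic (MZ) and dizygotic (DZ) twin
pairs: A correlates 1 in MZ and 0.5 in DZ pairs, C correlates 1 in both,
E is uncorrelated. If the environment in some places draws out genetic
differences (gene-by-environment interaction) or amplifies environmental
ones, the *magnitudes* of A, C and E should vary from place to place.

`twinspace` estimates this geographic variation without measuring any
specific environment. A classical twin model is fitted by full-information
maximum likelihood (FIML) at many target locations; at target $x$ every
twin pair $i$ contributes its log-likelihood with weight

$$w_i(x) = \frac{1}{d(x, x_i)^p},$$

where $d$ is Euclidean distance in a projected planar coordinate system
and $p$ controls how quickly influence drops off. Systematic spatial
patterns in the per-location estimates are the signature of aetiology
varying with geography. Because the weights change smoothly with $x$, the
choice of target locations only decides where results are *reported*; no
pair's data depend on it.

Each pair's likelihood is a bivariate normal with the model-implied
covariance (univariate marginal when one twin's phenotype is missing — the
FIML contract, so incomplete pairs still inform the fit). The weighted
objective $\sum_i w_i(x)\,\ell_i(\theta)$ is maximized over path
coefficients $a, c, e$ (variances are their squares, hence non-negative by
construction) and mean-model coefficients.

## Parameters that matter

- **`p` (default 0.5, dimensionless).** The smoothing/localisation
  trade-off. `p = 0` gives uniform weights: every location reproduces the
  population fit exactly. Larger `p` localises estimates but raises their
  variance; the package's tests assert that the across-location spread of
  $\hat a^2$ is ordered `p = 0 < 0.5 < 2` on a fixed structured cohort.
  The default produces deliberate smoothing toward the population mean, so
  mapped ranges understate true local extremes.
- **`d_floor` (default 1e-6 map units).** The printed kernel diverges at
  `d = 0`; distances are floored so a pair exactly on a target gets a
  large finite weight. No authoritative value exists for this constant;
  anything far below typical inter-pair distances behaves identically.
- **Covariates.** Sex is included in the mean model by default (effect
  coded ±0.5); age (years) is optional. They absorb mean differences only;
  variance components refer to the covariate-adjusted trait.
- **`ci_method`.** `"information"` (default): observed-information,
  delta-method intervals on the variance scale, truncated at 0.
  `"profile"`: likelihood-ratio inversion per component, slower but
  boundary-respecting. The weighted objective is a *working* likelihood;
  weights are normalized to sum to the number of contributing pairs before
  fitting, which leaves point estimates unchanged (positive rescaling of
  the objective) but makes log-likelihoods and information matrices
  comparable across locations, and prevents arbitrary weight rescaling
  from shrinking intervals. The original analysis does not state its CI
  construction; both choices here are defaults, not reconstructions.
- **Effective sample size.** Reported per zygosity group as the Kish ESS
  $(\sum w)^2 / \sum w^2$ — again a stated choice; the source analysis
  reports ESS values but not a formula.

## Model variants

- **ADE.** Dominance replaces C (DZ dominance coefficient 1/4). C and D
  are not jointly identifiable from MZ/DZ pairs, so the package never fits
  both; A from an ACE fit should be read as a broad genetic component.
- **Quantitative sex limitation.** Separate $a, c, e$ magnitudes by sex;
  opposite-sex DZ pairs contribute cross-covariance
  $0.5\,a_m a_f + c_m c_f$ and are what identifies sex-specific C. The
  likelihood-ratio test against the equated model uses df = 3 with no
  boundary correction — the conventional, slightly conservative-to-liberal
  approximation, noted as approximate. In the equated (default) model,
  opposite-sex DZ pairs are ordinary DZ pairs.

## The synthetic cohort generator

Restricted registry data cannot ship with a package, so every pipeline
stage is exercised against simulated cohorts with *known* spatial
aetiology. The generator's defaults state a Nordic-registry-like world:
~8300 pairs, trait standardized to mean 0 / SD 1 at the population level,
sex effect carrying 2.6% of trait variance, optional age effect (0.3% for
a UK-like cohort), ~0.8% incomplete pairs, clustered settlement geography
on a unit square, MZ fraction 0.5 and the DZ half split evenly between
same- and opposite-sex pairs (registry composition varies; these are the
package's fixed choices). Aetiology fields are simple parametric surfaces
(homogeneous, west/east step, linear gradient) — the real spatial
autocorrelation structure of aetiology is unknown (it is what such studies
set out to discover), so a green test establishes that the machinery
recovers *stated* spatial structure at realistic scale and noise, not that
any particular country's map is correct. Phenotypes are Gaussian on the
analysis scale; `skew_transform()` optionally warps them toward the heavy
right skew of symptom-count instruments, with the caveat that the FIML
model assumes normality.

Null-calibration simulations for the sex-limitation test generate with an
interior shared environment ($c^2 = 0.2$) so the $\chi^2(3)$ reference is
not distorted by the $c = 0$ boundary; recovery experiments for C-absent
traits use $c^2 = 0$ and accept the known upward pile-up of $\hat c^2$
(and matching small downward bias of $\hat a^2$) that boundary truncation
produces.

## Numerical choices

- Optimizer: deterministic BFGS (`stats::optim`) from fixed moment-based
  start values — Falconer estimates from double-entered weighted twin
  correlations, clipped to [0.01, 0.99] and rescaled to the weighted total
  variance. Per-location fits start from the population-fit optimum, for
  speed and cross-location comparability. `reltol = 1e-12` so that a
  `p = 0` run agrees with the population fit to better than 1e-6.
- Degenerate inputs: a singular model-implied covariance (e.g. `e2 = 0`
  with both twins observed) is rejected inside the likelihood by a large
  finite penalty; fits driven to that boundary are flagged
  (`boundary_e2`), as are non-converged locations, which are excluded from
  map colour scaling but never dropped from result tables.
- Winsorized colouring: exactly `ceiling(q*n)` values per tail (ceiling
  guarantees non-empty extremes at small n; the source method states only
  "4%") are pinned to the scale ends; interior values are clamped to the
  cut values and mapped linearly around the mean of all mapped values, then
  discretized into `n_bins` (default 256 — unstated in the source, exposed
  as config) equal ranges. Assignment depends only on ranks and the two
  cuts, hence is order- and affine-invariant.
- Coordinates: weighting demands planar coordinates; lon/lat input must
  pass through `project_coordinates()` (local equirectangular, spherical
  radius 6371008.8 m — no PROJ library is assumed; error vs geodesic
  distance is < 1% over 100 km spans, negligible for inverse-distance
  weights). Passing geographic coordinates to the weighting is a hard
  error, not a warning.
- Reproducibility: every stochastic operation is a pure function of its
  seed (RNG state is saved and restored); CSV writers use a fixed
  9-significant-digit format so reading and re-writing a file the package
  wrote is byte-identical, and the CLI pipeline is byte-for-byte
  reproducible given a seed.

## Known limitations

- Estimates at each location borrow strength from the whole cohort; maps
  are smoothed fields, not independent local estimates, and neighbouring
  targets are strongly correlated.
- Information-based intervals are symmetric on the variance scale and can
  be poorly calibrated for components at or near 0 (use `"profile"` for
  boundary components).
- The LRT df = 3 sex-limitation reference ignores boundary mixtures.
- Ordinal/liability-threshold likelihoods, multivariate twin models,
  continuous moderator models and longitudinal extensions are out of
  scope.
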