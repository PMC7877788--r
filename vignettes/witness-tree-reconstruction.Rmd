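---
title: "Reconstructing settlement-era forest structure from witness trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing settlement-era forest structure from witness trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsforest)
```

This vignette is the package's account of its statistical methods: the
models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## From survey notes to point estimates

Public Land Survey witness-tree records give, at each survey corner,
the taxon, diameter (dbh), distance, and bearing of the nearest tree
in each of two (sometimes three or four) sectors around the corner.
Three conventions matter before any estimation:

* **Units.** Historical notes record dbh in inches and distances in
  links or chains; the internal representation is cm and m. The unit
  dialect must be declared in `cleaning_config()` — silent
  autodetection was rejected because a misdetected dialect would bias
  every downstream quantity by a constant factor.
* **Effective distance.** Surveyors measured to the tree face; the
  plotless estimator wants the distance to the tree center, so the
  recorded distance plus `dbh/200` (half the diameter, in m) is used.
* **Cleaning.** Rules live in a registry so that dataset-specific
  steps can be added; each removal is charged to a rule code in an
  exclusion ledger, and `kept + excluded = input` always. The two
  default rules are: drop corners with any missing diameter (a corner
  with one usable and one missing tree cannot give an unbiased biomass
  product, and dropping it treats one- and two-tree corners alike),
  and drop effective distances below 1 mm (ε = 0.001 m), which would
  otherwise explode the inverse-square density estimator.
  Treeless corners ("no tree" posts) are kept as zero-tree points:
  they are essential denominators for the occupancy model.

**Density.** The two-sector Morisita estimator
`λ̂ = f·10⁴·m(m−1)/(π Σ r²)` is used, with `m` the number of sectors
(2 at the standard corner; 3- and 4-tree corners are treated as 3 and
4 sectors). This is the standard sector form for corner data in the
plotless-density literature. One-tree corners carry no sector
contrast, so their density is identifiable only through an explicit
design correction; without a configured `f_design` they are excluded
with a reason rather than guessed at. Correction factors
(`f_design` for instruction-era design changes, `f_size` for
converting the raw no-threshold density to trees ≥ 20.32 cm) are
exogenous lookup tables keyed by zone × corner type × era, composed
multiplicatively; the tables shipped with the package are labelled
illustrative, since the real factors are dataset-specific inputs.

**Biomass and basal area** use the *raw* density deliberately: every
recorded tree enters, with no size threshold, because small trees
contribute little biomass and an unbiased product matters more than a
sharp threshold. Per-corner, each tree contributes `density/n` times
its allometric biomass `exp(b0 + b1·log dbh)` (kg → Mg/ha) or basal
area `π(dbh/200)²`, assigned to its taxon; per-taxon values therefore
sum to the corner total exactly, and a taxon's density at a corner is
`density · (trees of taxon)/(trees)`.

## Gridding

Cells are half-open intervals so assignment is a partition; empty
cells stay in the grid as prediction targets. Per cell and taxon the
aggregates are `N`, `n_p`, `Ȳ_p` (mean over occupied points), and the
raw cell mean over *all* points, which satisfies
`cell mean = (n_p/N)·Ȳ_p` to machine precision by construction. The
grid origin, cell size (8 km default), and projection tag are explicit
configuration: coordinates are taken as given in an equal-area
projection and no geodesy is performed, so any production grid can be
reproduced by supplying its definition.

## The two-stage zero-inflated model

Raw cell means are non-negative, continuous, and have a spike at zero.
Rather than a single zero-inflated density, the model factors the
field into **occupancy** — `n_p(s) ~ Binomial(N(s), θ_p(s))`, logit
link — and **potential** — `log Ȳ_p(s) ~ Normal(m_p(s), σ_p²/n_p(s))`
on occupied cells, the `1/n_p` scaling being the usual variance of an
average and the `n_p` weights carrying the same information into the
fit. The biological reading: local conditions can exclude a taxon
(occupancy) even where its stand-level biomass potential is high, and
the conditional biomass surface is much smoother than the occupancy
surface. The field estimate is `b_p(s) = θ_p(s)·exp(m_p(s))`, and
predictions exist for every cell, including cells with no data.

Both stages are penalized 2-D spline smooths fit with `mgcv::gam` (a
`bam` engine option exists for large grids). Design choices that were
open:

* **Basis.** Low-rank thin-plate regression splines (`bs = "tp"`),
  the truncated eigenbasis of the full thin-plate spline. A
  tensor-product P-spline basis was considered, but its per-margin
  construction cannot honor small maximum dimensions (the margins have
  a floor of four functions each), whereas the thin-plate basis
  respects any requested `k ≥ 4` exactly — which keeps the `k` cap,
  the contract the cross-validation loop tunes, honest across its
  whole range. The basis is deterministic given coordinates and `k`,
  its penalty nullspace contains constants, and it is swappable behind
  the `build_basis()` contract.
* **Smoothing selection.** GCV by default, REML as an option. At a
  fixed smoothing parameter the Gaussian stage equals the closed-form
  penalized weighted least-squares solution and the binomial stage
  solves the penalized IRLS fixed point; the test suite verifies both
  against direct linear algebra.
* **Weights scaled by 70.** Dividing all weights by ~70 (points in a
  fully surveyed cell) only reparameterizes the smoothing parameter,
  so point estimates are unchanged; the option exists (default off)
  and the reported σ² is re-expressed per occupied point either way.
* **Delta-method variance.** The formally better log-scale variance
  carries an extra factor of the mean; there is no clean way to give
  GAM software that structure, so the model keeps `σ²/n_p` and the
  delta-method form `Var(Ȳ)/E[Ȳ]²` is computed only as a diagnostic
  (`potential_variance_diagnostic()`).
* **Independence across taxa.** Taxa are fit separately; sums of
  taxon fits will not match the total fit (log-scale smoothing
  discounts extreme taxon cells more strongly), and this discrepancy
  is surfaced, never "fixed", because there is no way to constrain it
  coherently at the level of posterior draws.

**Uncertainty.** 250 draws of each stage's coefficients from the
approximate Bayesian posterior of the penalized fit
(`N(β̂, (information + penalty)⁻¹·scale)`), combined independently.
Two ad hoc stabilizations protect against numerical anomalies of the
logistic posterior in near-degenerate cells: taxon-specific occupancy
draws larger than five times the point estimate are set to the point
estimate (anomalies concentrate outside range boundaries where θ̂ is
tiny), and for the total fit, draws in cells whose point estimate
exceeds 0.999 are set to 1. The rule keys on the *point estimate*
exceeding 0.999, not the draw — the natural reading of the procedure,
since the anomaly is near-zero draws in cells that are certainly
occupied. Draws are reproducible bit-for-bit given a seed.

A known property worth stating plainly: smoothing on the log scale is
akin to a geometric mean, so back-transformed estimates are biased
downward relative to raw arithmetic means, and the test suite checks
the *sign* of this effect on heavy-tailed synthetic data. The log
scale is still the default because cross-validation (below) favors it
for both error and the coverage/sharpness tradeoff; an
original-scale variant is retained behind `scale = "original"` for
that comparison.

## Cross-validation protocol

Cells are split at random into 10 folds (plain random, not spatially
stratified); each fold is held out in turn and both stages are refit.
Two metrics:

* **Weighted truncated absolute error** of the point prediction
  against the held-out raw cell mean, weighted by the held-out cell's
  point count, both sides truncated at a cap (600 Mg/ha for biomass;
  caps for density and basal area are configurable package choices,
  since only the biomass cap is canonical) so a handful of extreme
  cells cannot dominate the comparison.
* **Prediction-interval coverage and sharpness.** Data-level
  predictive draws per held-out cell: `n_d ~ Binomial(N, θ_d)`, zero
  if `n_d = 0`, else `(n_d/N)·exp(m_d + e_d)` with
  `e_d ~ N(0, σ̂²/n_d)`. The binomial draw plus residual noise makes
  the interval a prediction of the *observable* raw value, so coverage
  can be judged against data. Intervals are the empirical 5th/95th
  percentiles of 250 draws (linear-interpolation quantiles; the
  quantile rule is a package choice), coverage is measured only on
  cells with ≥ 60 points, and sharpness is the median (and median
  log) interval length, since wide intervals buy coverage trivially.

The `k` grid for model selection is {100, 250, 500, …}; on the
synthetic data used here the error curve plateaus from `k = 100`
upward, which is the expected signature once the basis is rich enough
for the generating surface.

## What the generators emulate — and what they do not

`simulate_forest()` + `sample_corners()` produce the tree-level world
the Morisita estimator assumes: a homogeneous marked Poisson forest
(dbh left-truncated log-normal, default meanlog log 25 cm, sdlog 0.45,
truncation 10 cm; taxon marks i.i.d. from a fixed mixture), sampled by
the nearest-tree-per-semicircle corner protocol with exact geometry.
For a Poisson forest the squared semicircle nearest distance has mean
`2/(λπ)`, which the tests verify, and the pooled Morisita mean is
unbiased — though heavy-tailed, so pooled means over a few thousand
corners still move by several percent between seeds.
`simulate_cells()` is the exact sampling counterpart of the two-stage
likelihoods over smooth closed-form truth surfaces (logistic of
Gaussian bumps for θ*, affine in Gaussian bumps for m*, giving
conditional biomass of roughly 18–135 Mg/ha), with σ² = 0.25 and
N = 70 points per cell as the reference conditions.

What passing tests on these generators shows is that the estimator,
the model, and the uncertainty machinery are *internally correct and
calibrated under the assumed data-generating process*. Real PLS data
violate these assumptions in known ways the generators deliberately do
not emulate: surveyor species and azimuth preference, size-selection
bias beyond a sharp threshold, spatially clustered (non-Poisson)
stands, transcription error, and instruction-era heterogeneity beyond
a multiplicative factor. Calibration results here therefore do not
certify coverage on historical data — they certify the machinery that
the historical corrections plug into.

## Numerical choices and degenerate inputs

* Density at a corner requires all sector distances strictly positive
  (ε guard upstream); a zero or negative distance is an error, never a
  silent `Inf`.
* Occupancy fits with all `n_p = 0` are flagged degenerate
  (θ̂ ≈ 0 everywhere) rather than refused; saturated fits (`n_p = N`)
  push θ̂ to 1 through the link without overflow.
* A non-positive-definite posterior covariance (possible after heavy
  penalization) is repaired by eigenvalue clamping with a warning; a
  zero covariance short-circuits to point-mass draws.
* Empty grid cells carry `NA` aggregates and are imputed by the
  smooth; cells on grid boundaries follow the half-open convention so
  assignment is always a partition.
* Problem sizes used throughout the tests and scripts — 30×30 cells,
  70 points per cell, 250 draws, 2000-corner forests — are the
  reference study conditions and keep every check comfortably
  desk-scale.

## Limitations

The package does not transcribe or georeference survey notebooks,
estimate allometries from harvest data or propagate allometric
uncertainty, model surveyor bias, fit covariate-driven or multi-taxon
joint models, or constrain taxon sums to totals; raster (GeoTIFF or
NetCDF) export is out of scope and gridded products are written as
CSV. Range boundaries appear as smoothly decaying, strictly positive
fields rather than hard edges — an inherent property of spatial
smoothing with a log link.
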