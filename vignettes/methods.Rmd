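---
title: "Methods: human-nature coupling coordination at the grid scale"
author: "hncoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: human-nature coupling coordination at the grid scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hncoupling)
```

`hncoupling` implements a grid-scale workflow for analysing the relationship
between human activity intensity and ecosystem quality: index construction,
change classification, coupling-coordination measurement, driver screening
and latent-variable path modeling. This vignette documents the models, the
tunable parameters and their defaults, the numerical conventions, and the
design choices that were genuinely open, so that results produced with the
package can be interpreted and audited.

## Indices

Human pressure is summarised by a human footprint index (HFI), consumed as a
given layer and min-max rescaled to 0-100 for comparability. Ecosystem
condition is summarised by the ecosystem quality index

$$\mathrm{EQI} = 100 \times \frac{\mathrm{LAI} + \mathrm{GPP} + \mathrm{FVC}}{3},$$

the equally weighted mean of leaf area index, gross primary productivity and
fractional vegetation cover, each min-max normalised to $[0,1]$ beforehand.
FVC is derived from the enhanced vegetation index by the linear mixture
rescale $\mathrm{FVC} = (\mathrm{EVI}-\mathrm{EVI}_{soil}) /
(\mathrm{EVI}_{veg}-\mathrm{EVI}_{soil})$, clamped to $[0,1]$; the bare-soil
and full-vegetation references default to the 5th and 95th percentiles of
the unmasked EVI cells. Percentiles use the linear-interpolation definition
(R's type 7) — a fixed, testable convention where several exist.

Two normalisation domains are offered for multi-epoch stacks. The default,
`pooled`, computes one min-max over all epochs so that index levels remain
comparable across years (class legends and level maps then share one scale);
`per-epoch` is available where within-year contrast matters. Display
classification uses Fisher-Jenks natural breaks — the exact
dynamic-programming optimum of the within-class sum of squares, not the
iterative heuristic — computed on the pooled values so class ranges are
constant across maps. A value equal to a break joins the lower class. For
large grids the break search runs on a deterministic thinning of the sorted
pool (default cap 2000 values), which preserves the quantile structure the
optimal partition depends on.

Operations that combine several grids mask the union of the input masks:
no value is ever fabricated for a cell missing in any input, and stacks
force a common mask across epochs so only cells observed in every year are
analysed.

## Four-quadrant change classification

For a period $t_0 \to t_1$ the per-cell changes $\Delta\mathrm{HFI}$ and
$\Delta\mathrm{EQI}$ place each cell in one of four quadrants:
coordination $(+,+)$, good-for-nature $(-,+)$, degradation $(-,-)$ and
conflict $(+,-)$. Changes smaller in magnitude than a fraction (default
10%) of the standard deviation of the respective *change* raster — not of
the index levels — are treated as no-change. Three conventions are fixed
and exposed as configuration:

* the significance reference is the SD of the change raster for the period;
* a change exactly equal to the threshold counts as significant;
* a cell must change significantly on **both** axes to receive a quadrant
  (`rule = "or"`: insignificance on either axis makes the cell
  insignificant). The `"and"` alternative, where only cells insignificant
  on both axes are excluded, is provided because the two-axis convention is
  genuinely ambiguous in the field literature; the default demands a signed
  direction on both axes before asserting a quadrant.

If a change raster has zero SD, every nonzero change is significant — a
documented consequence of the rule, not an error.

## Coupling coordination degree

With both indices min-max rescaled to $[0,1]$, the package computes

$$C = \frac{2\sqrt{\mathrm{HFI}\times\mathrm{EQI}}}{\mathrm{HFI}+\mathrm{EQI}},
\qquad T = a\,\mathrm{HFI} + b\,\mathrm{EQI}, \qquad
\mathrm{CCD} = \sqrt{C \times T},$$

with $a = b = 0.5$ by default (the two subsystems treated as equally
important). This is the canonical coupling-coordination form: $C = 1$
exactly when the two subsystem levels are equal and positive, and CCD is a
meaningful $[0,1]$ coordination scale with the analytic identity
$\mathrm{CCD}(x,x) = \sqrt{x}$. A `literal` variant without the radicals
($C$ as the harmonic mean, $\mathrm{CCD} = C \times T$) is provided for
sensitivity analysis. The $0/0$ case (both inputs zero) is defined as
$C = 0$: no coupling without activity or quality.

CCD is classified into five levels — severely disordered $[0,0.2)$, nearly
disordered $[0.2,0.4)$, primarily coordinated $[0.4,0.6)$, moderately
coordinated $[0.6,0.8)$ and highly coordinated $[0.8,1]$. Published level
tables typically print closed bounds on both ends, leaving boundary values
ambiguous; the package resolves this as half-open intervals with the top
interval closed, so classification is deterministic.

## Driver screening

Candidate drivers (by default the eleven layers PRE, TEM, ET, ELE, SLO, NL,
PD, GDP, NPP, FVC, kNDVI) are screened per region as the **intersection**
of two filters.

*Collinearity.* $\mathrm{VIF}_j = 1/(1-R^2_j)$, with $R^2_j$ from the OLS
regression of driver $j$ on the other drivers, computed as the diagonal of
the inverse correlation matrix. The default is one-shot exclusion of every
driver with VIF above 6, matching the usual phrasing of the rule; greedy
iterative removal (drop the worst, recompute) is available as an option.
Exact linear dependence yields `Inf`, flagged rather than thrown.

*Importance.* A regression forest (default 500 trees, via `ranger`, behind
a pluggable regressor contract) predicts CCD from the drivers; each driver
is scored by %IncMSE — out-of-bag permutation importance expressed as a
percentage of the out-of-bag MSE. Because an importance score has no
intrinsic null scale, significance is calibrated by a response-permutation
null: the response is permuted (default 100 times), the forest is refit and
the importance recomputed each time, and driver $j$'s p-value is
$(1 + \#\{\text{null} \ge \text{observed}\})/(B+1)$. Drivers with
$p < 0.05$ pass. This test is assumption-free and exactly exchangeable
under a null response, so its false-positive rate is calibrated by
construction (with $B = 100$ the achievable rejection rate below
$\alpha = 0.05$ is $5/101 \approx 4.95\%$). The number of permutations and
$\alpha$ are configuration because no standard choice exists for
forest-importance significance.

Screening operates on a per-cell driver table; by default all unmasked
cells of a region are used, with an optional seeded subsample cap for large
grids.

## PLS path modeling

Driving mechanisms are estimated by partial least squares path modeling
(PLS-PM), written from scratch in the package. The measurement model links
each latent variable to a reflective block of indicators
($x = \lambda \xi + \varepsilon$); the structural model is a recursive
(acyclic) system of directed paths among latents
($\eta = A\eta + r\xi + \zeta$). The default structural graph has five
latents in causal order — terrain, human activity, climate, vegetation,
CCD — with terrain acting on human activity, vegetation and CCD; human
activity on climate, vegetation and CCD; climate on vegetation and CCD;
and vegetation on CCD.

The estimator is the standard iterative algorithm: indicators are
standardized; outer weights start equal within block; latent scores are
standardized weighted block sums; inner proxies are built from adjacent
latent scores; and Mode A updates each weight vector as the covariance of
its block with the inner proxy, until the largest absolute weight change
falls below `tol` (default `1e-6`, `max_iter` 300 — both recorded in the
fit object, with a warning and `converged = FALSE` on failure). The inner
scheme defaults to `path` (predecessors weighted by regression,
successors by correlation), the common choice for directed structural
models; `centroid` and `factorial` are selectable. Loadings are
indicator-latent correlations; structural coefficients are OLS of each
endogenous score on its predecessors' scores; communality is the squared
loading.

Two indeterminacies are fixed deterministically. Latent score sign is
oriented so each block's summed loading is non-negative (the dominant-
indicator convention). Rows with missing indicator values are dropped
listwise before fitting, since no imputation procedure is assumed.

Goodness of fit is $\mathrm{GOF} = \sqrt{\overline{\mathrm{communality}}
\times \overline{R^2}}$ over indicators and endogenous latents, labelled
weak / medium / strong at 0.10 / 0.25 / 0.36 (boundaries closed upwards).
Single-indicator blocks have communality 1 and are included in the mean by
default; an exclusion switch is provided since reporting practice varies.

Effects are decomposed by explicit path tracing: the direct effect is the
edge coefficient, the indirect effect is the sum over all directed paths of
length $\ge 2$ of the products of edge coefficients, and total = direct +
indirect. Because the coefficient matrix is strictly lower-triangular
(nilpotent), the totals equal $\sum_{k\ge1} A^k = (I-A)^{-1} - I$; the two
computations are verified against each other in the test suite to 1e-10.

Inference is by nonparametric bootstrap over observations (default
$B = 999$): each resample is refit in full, sign-aligned to the base fit
per block (outer-weight inner product), and per-path standard errors are
the SDs of the bootstrap distribution. Two-sided p-values use the normal
approximation $z = \hat r / \mathrm{SE}$ — matching the convention of
star-coded path diagrams (\*\*\* $p<0.001$, \*\* $p<0.01$, \* $p<0.05$) —
and percentile intervals are reported alongside. Failed resamples (e.g. a
constant indicator after resampling) are dropped and counted; more than
10% failures aborts the inference. At $n = 300$ with $B = 199$ the
measured type-I error for a zero path is about 6-7%, the usual mild
anti-conservatism of the bootstrap-normal approximation at moderate $n$.

## Synthetic data and what it does (not) show

Every stage is exercised end-to-end on synthetic inputs with known ground
truth, generated by the package itself.

*Raster pairs.* `generate_coupled_stacks()` plants rectangular blocks, one
quadrant class each, with linear per-epoch trends plus iid Gaussian cell
noise and a common nodata mask. The default scene emulates an urbanising
region over three epochs (2000/2010/2020): HFI rising from about 35.7 to
46.1 on the 0-100 scale while EQI declines from about 50.4 to 47.2, with
block deviations (amplitudes 20 HFI and 10 EQI units around the mean
trends) large enough that all four quadrant classes occur with the correct
change signs. Defaults `noise_sd = 1` and `nodata_fraction = 0.02`
represent modest sensor noise and sparse missingness. Spatial structure is
block-wise only: the methods under test are strictly per-cell, so
geostatistical field simulation would add realism without adding test
power; consequently, passing tests demonstrate correctness of the per-cell
computations and the orchestration, not robustness to spatially
autocorrelated noise.

*Latent tables.* `generate_sem_table()` draws latents recursively along a
strictly lower-triangular path matrix and builds indicators as loading x
latent + noise. By default both noise scales are auto-calibrated so every
latent and indicator has unit population variance, which makes the planted
coefficients *themselves* the standardized truth the estimator should
recover; explicit noise SDs are honoured with the implied standardized
truth computed analytically from the covariance recursion. Recovery
simulations draw structural coefficients uniformly from $[-0.6, 0.6]$; a
draw implying more than 85% explained variance for some latent is scaled
down to keep the unit-variance construction feasible. Mean absolute
recovery error at $n = 5000$ with loadings 0.85-0.95 is about 0.03,
reflecting the well-known mild attenuation of composite-based path
estimates at finite reliability.

*Full bundles.* `generate_analysis_bundle()` ties the two together for
pipeline tests: driver rasters are drawn from the latent model
*conditionally on the realised CCD raster*, stratified by quadrant region
(the CCD values are rank-transformed to normal scores within each region,
and the upstream latents are drawn from their exact conditional Gaussian
distribution). Stratifying by region is deliberate: regions are defined by
selection on change behaviour, which is correlated with the CCD level, and
unconditional generation would make the within-region joint distribution —
the thing region-stratified path models estimate — deviate from the
planted model through selection effects. Within every region the planted
standardized model holds exactly, so the pipeline's per-region fits have
an exact target.

## Problem sizes used by the checks

The shipped test-suite and acceptance script sizes are the package's
choices for precise-but-quick verification: 80 x 80 grids (about 6,300
cells; four regions of roughly 1,500 cells) for end-to-end runs; $n =
5000$ and 50 replicate seeds for path recovery; 500 replicates at $B =
199$, $n = 300$ for bootstrap calibration; and 500 replicates of the
screening null at 100 permutations each. Null-calibration rates are
estimated from 500 rather than 200 replicates so the Monte-Carlo standard
error (about 0.9 points at a 5% rate) is small relative to the +-3-point
acceptance band.

## Known limitations

* PLS-PM is composite-based: path estimates attenuate as indicator
  reliability falls; no disattenuation (consistent-PLS) correction is
  applied.
* Mode A (reflective) blocks only; no formative blocks, higher-order
  constructs, or multi-group invariance testing.
* The raster container handles single-band, north-up, square-cell grids
  and performs no reprojection or resampling; inputs must be pre-aligned.
* Forest importance inherits the known behaviour of permutation importance
  under strongly correlated predictors: redundant drivers share, and can
  individually lose, importance. The screening intersection is therefore
  conservative by design.
* The significance rule's change-SD reference makes quadrant significance
  relative to the analysed scene; comparing maps across scenes with very
  different change variance requires care.
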