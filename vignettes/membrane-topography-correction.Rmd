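---
title: "Correcting membrane-topography artefacts in SMLM cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting membrane-topography artefacts in SMLM cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(memtopo)
```

## The problem

Single-molecule localization microscopy (SMLM) reduces a fluorescence
acquisition to a table of molecular coordinates, and the question asked of
such tables is almost always: *are these molecules clustered?* Three popular
answers — the pair correlation function g(r), nearest-neighbour (NN)
distances, and visual inspection of rendered images — all share a blind
spot when the molecules live in the plasma membrane. The membrane is not
flat: ruffles, folds, microvilli and collapsed filopodia mean that the 2D
pixel under the objective can contain one membrane sheet or several, at any
inclination. A molecule distributed *uniformly in the membrane* is then not
uniform in the 2D projection; it is enriched wherever more membrane is
present, and every cluster statistic duly reports clustering where there is
none. We call these **topography-instigated clusters**.

memtopo implements a dual-channel correction: record the protein of
interest together with a membrane marker (a lipophilic probe such as DiI
that samples membrane amount, not protein biology), render both channels to
images, smooth, normalize to a common mean, and subtract the marker image
from the protein image. Membrane-amount enrichment is common to both
channels and cancels; genuine protein clusters are not, and survive. The
difference image has zero mean by construction, so genuine clusters reveal
themselves as a *positively skewed* intensity distribution, quantified with
the type-3 sample skewness

$$b_1 = \frac{m_3}{m_2^{3/2}}\left(\frac{n-1}{n}\right)^{3/2},$$

with $m_k$ the central sample moments (divisor $n$). Replicate simulations
are compared with a Welch two-sided two-sample t-test.

## The statistics being corrected

**Pair correlation.** For each origin localization we count neighbours in
annular bands $(r, r+dr]$ and normalize by band area, number of origins,
and the overall target density $\lambda$:

$$g(r) = \frac{\sum_i \sum_{j \ne i} \delta\!\left(r < d_{ij} \le r+dr\right)}
              {\pi\left((r+dr)^2 - r^2\right)\, n\, \lambda}.$$

CSR (complete spatial randomness) gives $g \equiv 1$; clustering gives
$g > 1$ at short range. Only origins at least a guard width (default
$r_{max}$, 100 px for simulated data) from the border are used, but *all*
localizations count as neighbours and $\lambda$ uses the full region, so no
edge correction is required.

**PC-PALM.** Fluorophores blink: one molecule appears many times with
localization-precision scatter, inflating $g(r)$ at short range even for
unclustered molecules. The PC-PALM decomposition fitted by `pcpalm_fit()`
is

$$g(r) = \underbrace{\frac{1}{4\pi\sigma_{psf}^2\rho}
           e^{-r^2/4\sigma_{psf}^2}}_{\text{repeat appearances}}
         + \underbrace{A\,e^{-r/\xi} + 1}_{\text{protein organisation}},$$

with $\sigma_{psf}$ fixed from the mean localization uncertainty rather
than co-fitted (short curves cannot separate it from $\rho$), and
clustering flagged only when the fitted $A$ exceeds twice its standard
error. The fit uses Levenberg–Marquardt on the residuals directly
(`minpack.lm::nls.lm`) with $A \ge 0$, because at the CSR limit $A \to 0$
the correlation length $\xi$ becomes unidentifiable and the Jacobian
singular — a failure mode, not an error.

**Nearest neighbours.** `nearest_neighbour()` offers the exact continuous
Euclidean NN and a `distance_map` variant (exact Euclidean distance
transform of the rasterized target set, sampled at origin pixels) that
mirrors how pixel-grid dimer simulations are analysed in practice.
Summaries use linear-interpolation (type-7) quantiles.

## What the generators emulate

Three seeded generator families reproduce the study conditions that
validate the method:

* **Partition-ratio datasets** (`generate_cluster_layout()`,
  `sample_partitioned()`): 52 disks of radius 32 px in a 2048 × 2048 px
  field (3.99% coverage, strictly non-touching, fully inside the image),
  with a fixed localization budget split so that the in-cluster/out-cluster
  density ratio equals R. Points are added sequentially per pool, so the
  R′ < R dataset is a prefix subset of the R dataset under the same seed —
  nested ratios share localizations, exactly as sequential addition
  produces them. The total budget is a free parameter (default 500,000 for
  2048²; the skewness sweep in the tests uses 125,000 at 1024², the same
  density); the *magnitude* of b₁ depends on this budget, its
  monotone growth with R does not.
* **Topography-weighted membranes** (`build_membrane_map()`,
  `sample_topography()`): per-pixel membrane amount M = L·S, where L ≥ 1
  counts stacked membrane sheets (folds, collapsed filopodia) and
  S = √(1 + |∇h|²) is the slope factor of a Gaussian height field
  (ruffles). Markers sample with weight M; proteins with weight M·E, where
  E ≥ 1 is an optional genuine-enrichment field. This is a deliberately
  minimal model — enough membrane-per-pixel variation to instigate false
  clusters, with analytic gradients so tests can check S exactly.
* **Dimer fields** (`simulate_dimers()`, `thin_detections()`): 4048 black
  molecules at distinct pixels of a 600 × 600 image, each with a red
  partner uniform in its 8-neighbourhood; red detection is thinned to model
  the unknown detection efficiency of SMLM. Black molecules are analysed in
  the central 512 × 512 window (~2900 of them) from a distance map of the
  reds. Under thinning the mean black→red NN distance rises while the
  median stays at the pair scale as long as ≥ 50% of partners are detected.

What the generators do **not** emulate: blinking kinetics and photophysics
(repeat appearances enter only through the PC-PALM test fixtures), 3D
membrane geometry, localization drift, and antibody linkage error. Passing
tests therefore show the *statistics* behave as designed, not that any
particular cell dataset is artefact-free.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| smoothing sigma | 20 px (simulation study), 8 px (cell-style ROIs), 24 px (topography demos) | sets the spatial scale of the comparison; conclusions are stable across 4–20 px |
| guard (skewness) | 40 px | excludes filter edge effects from the intensity histogram |
| guard (PCF/NN origins) | 100 px = r_max | removes border bias without edge correction |
| dr, r_max | 5, 100 (table units) | band resolution and range of g(r) |
| partition ratios | 1, 2, 3, 4, 6, 8 | 1 = no intentional clusters (the membrane-marker condition) |
| replicates | 8 per ratio | matches the replicate count used for the Welch comparisons |
| σ_psf | from mean uncertainty (8–14 nm typical) | fixed scale of the repeat-appearance term |

## Numerical choices

* **Rendering** is a per-pixel count histogram with half-open pixels
  ($x = k \cdot p$ belongs to pixel $k$), not Gaussian splatting; splatting
  is equivalent to extra smoothing, and a single explicit sigma keeps the
  pipeline interpretable. Coordinates are continuous, origin top-left.
* **Smoothing** appends a one-pixel zero frame before Gaussian filtering
  (EBImage `gblur`, replicate boundary outside the frame) and removes it
  afterwards; all published statistics also apply guards, so the boundary
  mode is immaterial to results.
* **Common mean is fixed at 1.0**, not the pair average: deterministic and
  scale-free, and it makes mean(difference) = 0 exact to floating point.
* **Band convention** for g(r) is $(r, r+dr]$ with ties on the upper edge
  staying in the band they close; with continuous coordinates the boundary
  has measure zero, and a fixed convention keeps the O(n²) oracle equality
  in the tests exact to the bit.
* **Background handling** defines background as the area without protein,
  after morphological closing of the protein occupancy image with a disc of
  radius equal to the smoothing sigma (so sparse empty pixels inside the
  cell do not count as background); foreground pixels that go negative
  after the subtraction are dropped from the mask.
* **Degenerate inputs**: constant intensity vectors make $b_1$ undefined
  and error (the workflow flags them instead when the two channels are the
  same table); `thin_detections()` forces the retained count to
  `round(d·n)` rather than Bernoulli thinning so sweeps are exactly
  comparable.
* **Significance onset** reporting uses the uncorrected Welch p per ratio,
  matching single-comparison practice, with a Holm-corrected column
  alongside for transparency.

## Design choices where the design was open

* *Strict tangency*: "neither overlap nor touch" is enforced as center
  distance strictly greater than 2r.
* *Red molecules may share pixels* with other pairs' molecules; only black
  placement is constrained to distinct pixels. A black molecule on the
  image border draws its partner among its valid in-image neighbours; the
  analysed central window keeps this from ever influencing results.
* *Seeding*: every generator stage derives a child stream from the root
  seed, so marker/protein channels and nested-ratio datasets are
  independent yet individually reproducible. In- and out-pool samplers
  consume the RNG stream in fixed-size units so that prefix subsets are
  exact.
* *CSR calibration tolerance*: the per-band variance of ĝ under CSR
  exceeds the Poisson pair-count term because the guard-interior density
  fluctuates relative to the global λ; the calibration test uses
  $\mathrm{Var}(\hat g) \approx 1/(n\lambda a) + (A/A_{guard} - 1)/N$ as a
  floor on the replicate-estimated standard error.

## Problem sizes used by the test suite

The suite exercises the full pipeline at 512²–1024² fields with 30,000 to
150,000 localizations (the skewness-vs-ratio sweep runs 6 ratios × 8
replicates at 1024² with 125,000 localizations each), brute-force oracle
comparisons at n ≤ 500, and 20-replicate stochastic checks for the dimer
and PC-PALM properties. These sizes give the same densities as the
2048×2048 reference configuration while keeping a full run of the suite in
the minutes range.

## A worked example

```{r example, eval = FALSE}
map <- build_membrane_map(512, 512, list(
  list(type = "fold", x0 = 80, x1 = 130, y0 = 60, y1 = 400, layers = 3),
  list(type = "patch", cx = 360, cy = 300, radius = 16, enrichment = 6)))
marker  <- sample_topography(map, 150000, "marker",  seed = 1)
protein <- sample_topography(map, 150000, "protein", seed = 2)

res <- run_correction(protein, marker, sigma = 8, guard = 40)
res$skewness          # positive b1: the enrichment patch is genuine
autoplot(res$difference)
```

## Known limitations

* Strictly 2D: the topography model projects membrane amount into the
  plane; no 3D reconstruction is attempted.
* The correction needs a membrane marker channel acquired under the same
  conditions; chromatic registration is assumed done upstream.
* The b₁ magnitude depends on localization budget, smoothing sigma and
  field size; comparisons are meaningful within a pipeline run with fixed
  parameters (the sweep functions enforce this), not across differently
  parameterised runs.
* PC-PALM's exponential cluster term is a convenient single-scale model;
  multi-scale organisation will load on the nearest scale rather than be
  resolved.
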