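---
title: "Quantification methods for tissue-engineered micrometastasis assays"
author: "tecquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for tissue-engineered micrometastasis assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecquant)
```

# Scope

`tecquant` quantifies the four read-outs of a tissue-engineered
micrometastasis study built on decellularized organ scaffolds (AOSS) seeded
with invasive cancer cells (TECs, tissue-engineered constructs):

1. **Histomorphometry** — how cancer cells colonize the parenchymal and
   stromal compartments of a stained scaffold section: relative
   cellularity, convex-hull circularity morphotypes (epithelioid vs
   mesenchymal-like), invasion depth below the scaffold surface.
2. **Vasculometry** — how grafts change the chick chorioallantoic membrane
   (CAM) vascular network: ridge-detection skeletonization of
   stereomicrographs and branch length density per region of interest
   (ROI), averaged per egg and compared between groups.
3. **Growth dynamics** — logistic modelling of MTT viability time courses
   in 2D monolayers versus 3D constructs.
4. **Dose-response pharmacodynamics** — conversion of absorbances to dead
   fractions with error propagation, weighted Hill fitting on the
   log10-dose axis, and EC50/IC50 extraction.

Because raw micrographs and plate-reader tables of such a study are
typically not deposited, every stage is validated against a ground-truthed
synthetic-data generator that is itself part of the package (and tested).

# Models

## Logistic growth

Viability-proportional population size follows

$$N(t) = \frac{C_0\,C_{max}}{C_0 + (C_{max} - C_0)\,e^{-d t}},$$

with $N(0) = C_0$, carrying capacity $C_{max}$ and growth rate $d$
(day^-1^). `fitLogistic()` fits all replicate points jointly (means on
request) by Levenberg–Marquardt least squares. Positivity of all three
parameters is enforced by log-parameterisation — a smooth unconstrained
objective rather than a bounded search. Initialisation uses the logit
linearisation $\log(N/(C_{max}^{(0)}-N)) \approx a + d t$ with
$C_{max}^{(0)} = 1.05\max N$, followed by a small ladder of heuristic
restarts; the best converged deviance wins. A constant series makes $d$
unidentifiable: the fit short-circuits to $d = 0$, flags itself degenerate
and reports NA standard errors rather than pretending precision.

## Hill dose-response

Percent dead cells against dose, with dose and EC50 both on the
log~10~ µg/mL axis:

$$E(\mathrm{dose}) = \frac{E_{max}}{1 + 10^{\,(EC_{50} -
\mathrm{dose})\,h}}.$$

`deadFraction()` converts absorbances by $E = (1 - A/A_0)\cdot 100\%$ with
the uncertainty propagated as $\sigma_E = (100/A_0)\,\sigma_A$; values
above control (negative $E$) are reported unclipped with a flag.
`fitHill()` performs weighted least squares with the inverse error
$1/\sigma_E$ as the weight. Design choices, each exposed as a parameter:

* **Control anchor.** The zero-dose control cannot be log-transformed; it
  is anchored at a pseudo-dose two decades below the smallest nonzero dose
  with a ×10 weight multiplier, reflecting that the data are normalised to
  the control. The anchor pins $E = 0$ at a finite dose where the true
  sigmoid is small but nonzero, so it trades a small bias (fractions of a
  percent for common slopes, larger for very shallow $h$) for robustness
  of the intercept. Parameter-recovery tests therefore fit the nonzero-dose
  curve when they ask for exactness, and separately check that the
  anchored fit stays close.
* **Weight capping.** Weights are clipped at their 95th percentile so a
  single near-zero-σ point cannot dominate; all-zero σ falls back to unit
  weights with a warning.
* **Constraint mode.** The default fit constrains $0 < E_{max} \le 100$
  and $h > 0$ for robustness; a fully unconstrained mode is selectable.

`ic50()` inverts the fitted curve at 50% death in closed form,
$\mathrm{dose} = EC_{50} - \log_{10}(E_{max}/50 - 1)/h$, defined only for
$E_{max} > 50$; an $E_{max}$ at or below 50%, or a crossing beyond the
tested dose range, reports "not reached" instead of extrapolating.
`resistanceReport()` assembles linear-scale EC50 ratios (3D over 2D) per
formulation plus per-dose Mann–Whitney comparisons.

## Histomorphometry

The section pipeline mirrors standard stain-separation morphometry:

1. **Pre-blur**: per-channel Gaussian smoothing with physical scale
   σ = 0.65 µm (converted to pixels via the image's µm/px), reflective
   borders.
2. **Colour deconvolution**: optical density $OD = -\log_{10}(I/I_0)$
   unmixed through the inverse of a 3×3 stain matrix into cell, matrix and
   residual channels. The default stain vectors are the standard H&E
   optical-density convention (hematoxylin, eosin, orthogonal residual);
   they are configurable because real stain batches differ. Negative
   concentrations are clipped with the clipped mass reported, and the
   remix residual is part of the result object.
3. **Segmentation**: Otsu threshold on the cell channel (fixed-value
   override available), connected components, optional distance-transform
   watershed splitting of touching cells, minimum object area 20 µm².
4. **Shape**: circularity $4\pi A/P^2$ of the convex hull of the region's
   boundary pixel centres. The hull polygon is dilated by half a pixel
   (Minkowski sum with a radius-1/2 disk: $A' = A + P/2 + \pi/4$,
   $P' = P + \pi$) so that small digital shapes measure their pixel
   footprint rather than the shrunken centre lattice; this keeps a digital
   square at $\pi/4$ and a 10:1 rectangle at its closed form within a few
   percent. Values are clipped at 1 on report.
5. **Morphotype**: epithelioid if circularity ≥ cutoff (default 0.7, ties
   epithelioid), mesenchymal-like otherwise. The cutoff can also be taken
   from an Otsu split of the measured circularity histogram when the
   population is bimodal.
6. **Invasion depth**: Euclidean distance transform of the section mask at
   the cell centroid, minus one pixel so a centroid on the surface scores
   zero; the invasion front is a percentile (default 95th) of the depth
   distribution, robust to single outliers.
7. **Compartments**: a cell takes the compartment label under its
   centroid; cells with less than 80% of their pixels in one compartment
   are "mixed". Coordinates are 1-based row/col with pixel centres on the
   integer lattice (the R convention); all reported geometry is in µm.

## Vasculometry

CAM vessels have their strongest contrast in the green channel; the
pipeline is green-plane extraction, percentile histogram stretching, then
Steger-style line detection: convolution with first and second derivatives
of a Gaussian, principal-curvature direction from the local Hessian, a
sub-pixel line-point test ($|t| \le 1/2$ pixel along the line normal),
hysteresis linking between a lower and upper threshold on the
scale-normalised response $\sigma^2 \lambda_{max}$, thinning to an
8-connected unit-width skeleton, and spur pruning below 5 px. Dark-line
polarity implements the "local minima" reading of brightfield vessels; a
bright-line mode inverts the image.

* **Scale.** For a line of full width $w$, the second-derivative response
  across the profile is single-peaked only for
  $\sigma \ge w/(2\sqrt{3})$; the default ties σ to the expected vessel
  width by that relation. In rendered/anti-aliased imagery the effective
  width is about one pixel wider than nominal, so σ slightly above the
  bound behaves better than σ at the bound.
* **Thresholds.** The hysteresis defaults (0.08/0.02 on the normalised
  response) were calibrated on synthetic vessel images of contrast ~0.65
  after stretching; both are exposed.
* **Graph.** Skeleton pixels are linked by reduced 8-adjacency — a
  diagonal link is dropped when its two pixels share an axial skeleton
  neighbour — which resolves the staircase ambiguities thinning leaves
  behind. Nodes are 8-connected clusters of pixels with reduced degree ≠ 2
  (endpoints, junctions); edges are the chains between them.
* **Length metric.** Edge length is the Euclidean arc length of the
  moving-average-smoothed pixel chain (window 5 px) plus half a pixel per
  free end. Raw 8-connected step sums (1 per axial, √2 per diagonal step)
  systematically overestimate oblique digitized curves by 8–14% because
  thinning jitter alternates step directions; chain smoothing removes that
  bias while measuring straight axial and diagonal lines exactly, so the
  closed-form density of a straight line and rotation invariance both
  hold.
* **Junction counting.** Junction nodes closer than 3 px merge into one:
  a physical bifurcation has the spatial extent of the vessel width and
  thinning can split it into adjacent degree-3 pixels.

`branchLengthDensity()` restricts the skeleton to a rectangular or
polygonal ROI and divides the in-ROI length (µm) by the ROI area (µm²);
`eggSummary()` averages ROI densities per egg and pools junction counts as
total junctions over total area. Group comparisons use the two-sample
Kolmogorov–Smirnov test on pooled ROI densities (exact p below n·m =
10,000 without ties) and the two-sided Mann–Whitney U test on per-egg
means (exact p for both sizes below 50 without ties); both levels are
emitted because assays report both.

# The synthetic-data generators

Each generator returns the rendered artifact together with the analytic
truth used to render it, under a single RNG seed per spec (fixed seed →
byte-identical output).

* **Histology** (`synthHistology`): a two-compartment section (vertical
  split, parenchymal left / stromal right, optional background margin)
  with non-touching elliptical cells rendered through the Beer–Lambert
  model in the cell-stain colour over a smoothly textured matrix stain.
  Ellipse axis ratios are lognormal around per-compartment targets
  (defaults 1.1 round vs 4 elongated, emulating the epithelioid /
  mesenchymal-like dichotomy); the truth carries each ellipse's analytic
  hull circularity (the hull of an ellipse is the ellipse; perimeter via
  the complete elliptic integral). Non-touching placement uses an
  ellipse support-function test; an overcrowded compartment raises an
  error naming it. An overlap mode exists to stress segmentation
  splitting.
* **Vessels** (`synthVessels`): a random branching tree of smooth
  polylines grown from border roots, rendered as dark constant-width
  anti-aliased strokes (distance-transform tube) on a bright background,
  darkest in the green channel. Truth = polylines, analytic arc length,
  branch-event count. The default density (2 roots, 4% branch probability
  per step, ≤ 16 branches per 256 px field) keeps strokes from
  overlapping: overlapping strokes merge in the image and carry less
  rendered length than the summed polyline truth, which would break the
  truth-consistency contract. Trees escaping the canvas are clipped with
  a warning and the truth recomputed on the clipped polylines. Explicit
  polylines can be supplied; their truth junction count is the number of
  pairwise crossings.
* **Curves** (`synthViability`, `synthDoseResponse`): replicate values
  drawn from the logistic / Hill laws plus i.i.d. Gaussian noise; the
  default grids are the assay regimes (viability on days 1, 7, 14, 21,
  28; doses 0, 0.1–10 µg/mL with the zero-dose control, at which E = 0 is
  generated).

**What the generators do not emulate** — and hence what green tests do
not prove about real data: chromatic stain variability and uneven
illumination, nucleus/cytoplasm substructure, touching and overlapping
cells as the default regime, vessel width variation and diameter-dependent
contrast, out-of-focus blur, and non-Gaussian plate-reader noise. The
generators exercise the algorithms' geometry and statistics, not the full
messiness of microscopy.

# Problem sizes and numerical tolerances

The shipped tests run the full pipeline at sizes chosen to exercise every
code path while keeping the suite quick: 256–420 px sections with 60–100
cells, 20 seeded 256 px vessel trees for length recovery, 100 Monte-Carlo
fits for noise-bias checks. Optimizer tolerances are 1e-10 on the
least-squares objective; exact statistical enumeration oracles cover
sample sizes up to 5 per group (126 splits). Determinism is asserted by
byte-identical regeneration and by manifest checksums of re-run stages.

# Known limitations

* Ridge detection reports the centerline network only; vessel diameters,
  meshes and isolated-element statistics of full angiogenesis suites are
  out of scope.
* Junction recovery on trees with many stroke crossings counts real image
  crossings that a branching-event truth does not, so junction validation
  uses crossing-free constructions.
* The control-anchored Hill fit trades a small, slope-dependent bias for
  intercept robustness (see above); the anchor position and weight are
  parameters.
* Compartment "mixed" calls use region pixels rather than the hull
  interior; for convex cells these coincide almost everywhere.
* No stain normalisation across batches; the stain matrix is an input.
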