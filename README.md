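# tecquant

Quantification toolkit for tissue-engineered micrometastasis assays:
histology morphometry of cancer-cell colonization on decellularized organ
scaffolds, vascular-network quantification of the chick chorioallantoic
membrane (CAM) angiogenesis assay, logistic cell-growth modelling, and
weighted Hill dose–response pharmacodynamics. Every stage ships with a
ground-truthed synthetic-data generator, so the full pipeline is testable
without external data.

Audience: groups running 3D tumor-construct (TEC) studies — scaffold
recolonization histology, CAM grafting, MTT viability and drug-response
plates — who want the image and curve quantification reproducible in code
rather than spread across ImageJ macros and spreadsheets.

## The models at the core

**Logistic growth** of viability-proportional population size
*N*(*t*) = *C*₀*C*ₘₐₓ / (*C*₀ + (*C*ₘₐₓ − *C*₀)e^(−*dt*)), fitted by
Levenberg–Marquardt least squares with positivity via
log-parameterisation (`fitLogistic`).

**Hill dose–response** on the log₁₀-dose axis,
*E*(dose) = *E*ₘₐₓ / (1 + 10^((EC₅₀ − dose)·*h*)), fitted by weighted
least squares with inverse-error weights, a high-weight zero-dose control
anchor, and closed-form IC₅₀ inversion
dose = EC₅₀ − log₁₀(*E*ₘₐₓ/50 − 1)/*h*, reported as "not reached" when the
plateau stays at or below 50% (`fitHill`, `ic50`, `resistanceReport`).

**Histomorphometry**: Gaussian pre-blur (σ = 0.65 µm), H&E colour
deconvolution in optical-density space, Otsu + watershed segmentation,
convex-hull circularity 4π·A/P², epithelioid vs mesenchymal-like
morphotyping, distance-transform invasion depth, compartment-resolved
summaries (`analyzeHistology`).

**Vasculometry**: green channel, histogram stretching, Steger-style ridge
detection (Gaussian-derivative Hessian, sub-pixel line-point test,
hysteresis linking), skeleton graph with junctions and segments, branch
length density = skeleton length / ROI area, per-egg averaging, ECDF /
Kolmogorov–Smirnov / Mann–Whitney group comparisons (`detectRidges`,
`branchLengthDensity`, `eggSummary`, `ksTwoSample`, `mannWhitney`).

## Worked example

Growth rates of a fast 2D-like and a slow 3D-like synthetic culture:

```r
library(tecquant)

s2 <- synthViability(0.1, 1.0, 0.63, noiseSd = 0.02, seed = 42)
s3 <- synthViability(0.04, 0.35, 0.28, noiseSd = 0.008, seed = 43)
f2 <- fitLogistic(s2$series)
f3 <- fitLogistic(s3$series)
f2
#> LogisticFit: C0 = 0.09926  Cmax = 0.992  d = 0.6876 1/day
#>   RSS = 0.01376
f3
#> LogisticFit: C0 = 0.03527  Cmax = 0.3472  d = 0.2997 1/day
#>   RSS = 0.001523
compareGrowth(f2, f3)$dRatio
#> [1] 2.29401
```

The fitted growth rates recover the generating 0.63 and 0.28 day⁻¹ within
the noise, and their ratio (~2.3) quantifies how much slower the 3D-like
culture grows.

A noisy dose–response table and its Hill fit:

```r
tab <- synthDoseResponse(90, log10(0.35), 1.5, noiseSd = 2, seed = 44)$table
fitHill(tab)
#> HillFit: Emax = 88.97 %  EC50 = 0.3414 ug/mL  h = 1.571
#>   IC50: 0.4001 ug/mL
```

A synthetic CAM field, its skeleton and a ROI density:

```r
v  <- synthVessels(vesselSpec(seed = 21))
sk <- detectRidges(stretchContrast(greenChannel(v$image)),
                   ridgeParams(), pixelSizeUm = 2)
sk
#> VesselSkeleton: 1195 skeleton px, 104 segments, 30 junctions
#>   total length: 2287.17 um
v$truth$totalLengthUm
#> [1] 2292
branchLengthDensity(sk, rectRoi(65, 65, 128, 128))$densityUmPerUm2
#> [1] 0.02308044
```

The recovered skeleton length (2287 µm) sits within 0.3% of the analytic
truth (2292 µm); the ROI density is in µm of vessel per µm² of membrane.

Histomorphometry of a synthetic two-compartment section:

```r
h   <- synthHistology(histologySpec(seed = 7))
res <- analyzeHistology(h$image, pixelSizeUm = 1,
                        h$sectionMask, h$compartmentMask)
res$summary$relativeCellularityPct   # area % occupied by cells
#> [1] 11.06424
100 * h$truth$cellAreaFraction       # analytic truth
#> [1] 11.78097
```

Per-compartment morphotype fractions and invasion depths are in
`res$summary$perCompartment`; per-cell records (circularity, morphotype,
compartment, depth in µm) are in `res$cells`.

A thin shell wrapper for the synthetic and fitting stages is installed at
`inst/scripts/tecquant` (`tecquant synth_dose --out dir --seed 5 ...`);
each run writes its resolved `config.json`, a `manifest.json` with MD5
checksums, and a structured `run.log`.

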