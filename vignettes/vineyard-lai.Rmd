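---
title: "Estimating vineyard LAI from below-canopy images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vineyard LAI from below-canopy images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinelai)
```

## The estimation problem

Leaf area index (LAI, one-sided leaf area per unit ground area) is the
central canopy descriptor in viticulture, but vineyards are a hostile case
for the usual indirect optical methods: the canopy is a discontinuous wall
of leaves trained along rows, with bare inter-row soil, a woody cordon, and
strong leaf clumping. `vinelai` implements an indirect estimation chain
built around one physical idea: at a view zenith angle of 57.5° the leaf
projection function G(θ) is close to 0.5 for *any* leaf angle distribution,
so the extinction coefficient of a turbid-medium transmittance model is
nearly canopy-independent and the inversion needs no per-site calibration.

The chain is:

1. **Segmentation** — a below-canopy RGB photograph taken at 57.5° is
   converted to Hue–Saturation–Brightness and split into sky and
   vegetation pixels, fully unsupervised.
2. **Gap fraction** — the sky share of the frame is the directional gap
   fraction P0.
3. **Inversion** — the Warren–Wilson transmittance law
   P0 = exp(−k·LAI), with k = G(θ)/cos(θ) = 0.5/cos(57.5°) ≈ 0.9306,
   gives the per-image plant LAI: LAI = −ln(P0)/k.
4. **Protocol aggregation** — four replicates per vine (two row sides ×
   two offsets of 20 and 40 cm from the pole) are averaged into the vine
   estimate; vines are averaged per sampling area.
5. **Scale conversion** — the plant-scale LAI (referred to the ground band
   the instrument sees) is converted to vineyard LAI (referred to the
   ground allotted to one vine) through the row geometry.

Companion modules compute the destructive reference LAI, the standard
agronomic agreement statistics, and the NDVI-map calibration used for
"smart scouting".

## Segmentation: the unsupervised sky rule

The original mobile implementation's chromatic segmentation rule is not
published, so the rule here is the package's own design, chosen for
determinism and for behaving correctly on the scene classes the protocol
produces:

* **Stage a.** An Otsu threshold on the brightness channel marks bright
  pixels as sky candidates. In an upward shot the sky is backlit and
  bright; foliage seen against it is dark.
* **Stage b.** Candidates that are simultaneously saturated
  (S > `sat_max` = 0.5) and green-hued (hue in 60–180°) are reassigned to
  vegetation. This guards against bright sunlit leaves, which can exceed
  the brightness threshold but are chromatically green, unlike sky.

Otsu's method always returns *some* threshold, including on frames that
contain only sky or only foliage, where it would split a single population
in half. The rule therefore trusts the automatic threshold only when
Otsu's separability statistic — the between-class share of the total
brightness variance — reaches `separability_min` = 0.8. A genuine
two-tone frame scores ≥ 0.9 on this statistic; a single jittered
population tops out near 0.75 (the value attained by a uniform
distribution split at its midpoint, and the reason 0.8 sits just above
it). Below the cutoff the rule falls back to a fixed brightness cut of
0.75, which classifies pure-sky frames (brightness near 0.95) and closed
canopy frames (brightness near 0.33) correctly and deterministically.

Classification is hard (no sub-pixel mixing): the gap fraction is defined
as a binary pixel count ratio. No denoising is applied by default so that
the default pipeline is bit-reproducible; a 3×3 median pre-filter on
brightness (`median_filter = TRUE`) is available for heavily compressed
JPEG input.

## Saturation

A frame with no detected sky yields P0 = 0, outside the domain of the
logarithm. Physically such a frame only establishes that P0 is below the
frame's resolution, so `clamp_saturated()` raises any gap fraction below
half a pixel's worth — 1/(2·n_total) — to that floor and flags the record.
The resulting estimate is a finite lower-bound-style value; dense canopies
are therefore *underestimated* rather than rejected, which is the known
behaviour of all transmittance-based methods near canopy closure.

## Geometry and the two reference areas

Scale conversions are driven by `protocol_geometry()`: device-to-row
distance D (protocol 0.4 m), row spacing R, vine spacing V, and the
instrument's reference band width, defaulting to 2·D = 0.8 m (the device
looks into the row from both sides). Then

* vineyard LAI: LAIv = LAIp · reference_width / R,
* plant leaf area: LA = LAIp · reference_width · V (m²).

Two named presets are shipped. `"field"` is the acquisition protocol
above. `"unit_reference"` keeps the site spacing (R = 2.4 m, V = 1.0 m)
but sets the reference width to 1.0 m, i.e. a per-plant reference area of
exactly 1 m². The published worked conversions between the two scales
(vineyard LAI 2.84 ↔ plant LAI 6.8, and 1.41 ↔ 3.4) are consistent with
the 1 m² per-plant reference area, not with the 0.8 m protocol band
(which would give 2.84 ↔ 8.52). Rather than silently reinterpreting the
protocol, both parameterisations are first-class and the discrepancy is
left visible; the conversions themselves are implemented literally with
the geometry as a parameter.

Aggregation choices: inversion happens *per image*, then replicates are
averaged — not the other way around (averaging P0 first would bias the
concave log transform). Missing replicates are averaged over with a
warning, never imputed.

## Destructive reference and vigor index

The reference vineyard LAI comes from whole-vine defoliation: total leaf
fresh weight W (g) times the specific leaf area, referred to the ground
area per vine, LAIv = W·SLA/(R·V). SLA is computed from the pooled weight
of 40 leaf discs of 0.01 m² each (the discs are weighed jointly, so the
pooled ratio — not a mean of per-disc ratios — is the faithful estimator).
The theoretical leaf number TL = shoots per plant × mean leaves per shoot
is the quick non-destructive vigor descriptor used as a cross-check.

## Agreement statistics

`agreement_metrics()` reports the four standard agronomic
model-evaluation metrics — RRMSE (%, optimum 0), MAE (series units,
optimum 0), modelling efficiency EF (≤ 1, optimum 1), and the coefficient
of residual mass CRM (optimum 0; positive = the method underestimates the
reference) — plus the squared Pearson correlation and the OLS regression
of estimate on reference with a free intercept. R² is the squared
correlation (the regression line is reported but not used for R²), and
significance is a two-sided t-test on the correlation flagged at
α = 0.001. No multiple-testing correction is applied across method pairs.
Outlier handling is by explicit index only (`exclude_outlier()`), never by
automatic detection: the field practice it mirrors is setting aside a
known anomalous sampling area, such as an unpruned high-vigor vine row.

## NDVI maps and smart scouting

`classify_ndvi()` partitions an NDVI raster into k vigor classes (5 by
default). The zoning method of the original GIS workflow is unspecified,
so the default here is equal-interval breaks — the common default of
raster reclassification tools and fully deterministic — with quantile and
1-D k-means (natural-breaks style, deterministically initialised at
quantile centers) as options. `fit_calibration()` fits laiv = a·ndvi + b
by OLS to the in-situ calibration points (one ground estimate per class in
the scouting workflow; point NDVI is used rather than class-mean NDVI),
and `reclassify_to_lai()` applies the line cell-wise, flooring negative
predictions at zero and preserving no-data cells. Raster I/O is the
plain-text ESRI ASCII grid, written with 15 significant digits so grids
round trip bit-faithfully.

## The synthetic scene generator

Because no field imagery is distributed, validation rests on a generator
whose ground truth is exact. `render_canopy()` draws a **Boolean model**:
opaque leaf disks of radius r placed by a homogeneous Poisson process with
center intensity λ = k·LAI_true/(π·r²) per pixel², over a sky background.
For this process the probability that a pixel center stays uncovered is
exactly exp(−λ·π·r²) = exp(−k·LAI_true) — the same exponential law the
inversion assumes — so segmenting a render and inverting the measured gap
fraction must return LAI_true up to sampling noise. Disk centers are
drawn on a window extended r pixels beyond the image so coverage is
edge-effect-free. Pixels are colored from sky and leaf HSB palettes
(sky ≈ H 210°, S 0.15, B 0.95; leaf ≈ H 120°, S 0.75, B 0.33) with
per-pixel uniform jitter; `jitter = FALSE` renders exact two-tone frames
used to test pixel-exact segmentation. All randomness flows from one
explicit seed and the session RNG state is left untouched.

The **clumped variant** replaces the Poisson process with a Matérn
cluster process (disk centers scattered within `cluster_radius_px` of
Poisson parent points, `cluster_size` disks per cluster on average) at
the same expected disk count. By Jensen's inequality the expected gap
fraction of the clustered canopy exceeds exp(−k·LAI_true), so inversion
*underestimates* the truth — reproducing the direction of the saturation
and clumping bias reported for dense row canopies, where leaves are
bunched into walls rather than randomly dispersed.

What the generator does **not** emulate: sun-angle-dependent illumination
and sunlit/shaded leaf contrast, the woody cordon, mixed boundary pixels,
lens distortion, and JPEG compression artifacts. Passing the recovery
tests therefore demonstrates the correctness of the segmentation–
inversion–aggregation chain under its own assumptions, not field accuracy
on real imagery.

```{r recovery, eval = FALSE}
# end-to-end recovery at one operating point
img <- render_canopy(1.0, seed = 42)            # 512 x 512, LAI_true = 1
estimate_image(img)
#>    n_sky n_total        p0 saturated      lai
#> 1 101220  262144 0.3861237     FALSE 1.022586
```

## Numerical and testing choices

* The inversion round trip LAI → P0 → LAI is exact to 1e−12 over
  LAI ∈ [0, 6]; the scale conversions round trip to 1e−12.
* Gap-fraction sampling noise for a w×h render is assessed with a
  binomial-style standard deviation using w·h/(π·r²) independent
  disk-sized patches as the effective sample size; recovery tests use
  20 renders of 512×512 at each of LAI_true ∈ {0.25, 0.5, 1, 2} (a size
  chosen to keep each render's sampling error near 1% while the whole
  recovery study stays a desk-scale computation).
* Agreement metrics are verified against an independent loop-based
  recomputation on 100 random series at 1e−10.
* Ties in classification breaks: cells are assigned by half-open
  intervals with the last interval closed (`findInterval`,
  `rightmost.closed = TRUE`), so the maximum cell always belongs to the
  top class.
* Quantile classification refuses non-increasing breaks (heavily tied
  data) rather than silently merging classes.

## Known limitations

* The segmentation rule is behaviourally similar to, but cannot be
  asserted equivalent with, the unpublished mobile implementation.
* No correction is applied for the 15 cm below-canopy mounting height,
  row orientation, or the cordon's contribution.
* The NDVI calibration is a per-campaign empirical line; it does not
  transfer across dates, sensors or sites.
* GeoTIFF with georeferencing metadata is not read; the plain-text ESRI
  ASCII grid is the supported raster interchange format.
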