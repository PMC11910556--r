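---
title: "Detecting floating Sargassum rafts from surface reflectance"
author: "SargassumRafts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting floating Sargassum rafts from surface reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SargassumRafts)
```

## The problem

Pelagic *Sargassum* (S. natans, S. fluitans) drifts on the surface of the
tropical Atlantic and Caribbean in dense aggregations ("rafts") that
eventually strand on beaches, with serious ecological and economic
consequences. Monitoring systems for the Mexican Caribbean detect these
rafts in Sentinel-2 L2A surface-reflectance imagery at 20 m resolution,
vectorize them into attributed polygons, and publish per-scene statistics.
This package implements that processing chain as a reusable, fully
testable library: spectral detection, cloud masking, denoising,
vectorization with the standard attribute table, sandy-beach delineation,
scene summaries and attribute queries, plus a seeded synthetic-scene
generator with exact ground truth so every stage can be verified without
satellite downloads.

## The detection rule

Floating vegetation has a red edge: reflectance rises sharply from the
red (b04, 665 nm) into the near infrared (b08 at 842 nm, b8A at 865 nm).
Open water does the opposite — red exceeds NIR — and clouds, land and
sand are bright across all of these bands. The calibrated rule detects a
pixel as Sargassum when

$$ (b8A < 0.07)\ \wedge\ (b04 < 0.1)\ \wedge\ (b11 < 0.05)\ \wedge\
   (b04 < b8A)\ \wedge\ (b04 < b08) $$

on the 0–1 surface-reflectance scale. The three absolute thresholds
reject bright targets (clouds, land, breaking waves); the two relative
conditions demand the red-edge contrast that separates floating
vegetation from water. All inequalities are strict: a pixel sitting
exactly on a threshold is not detected. Integer digital numbers in input
rasters are divided by a configurable quantification value (default
10 000, the L2A convention) before the rule is applied — the thresholds
only make sense on the reflectance scale.

```{r}
syn <- plantRafts(makeScene(c(64, 64), waterPreset(0), seed = 1),
                  raftSpec(c(32, 32), "ellipse", 10), raftPreset(0))
sum(maskValues(eq1Mask(syn@scene)))   # the 10 planted pixels
```

## The Floating Algae Index

For Landsat-style scenes the package also computes the Floating Algae
Index, the NIR reflectance minus a linear baseline interpolated between
the red and SWIR bands:

$$ FAI = R_{nir} - R_{red} - (R_{swir} - R_{red})\,
   \frac{\lambda_{nir}-\lambda_{red}}{\lambda_{swir}-\lambda_{red}} $$

with band centers (655, 865, 1609) nm for Landsat-8 OLI and
(665, 865, 1610) nm for the Sentinel-2 b04/b8A/b11 mapping. A flat
spectrum gives FAI = 0; positive values mark the vegetation red edge. No
default detection cutoff is applied to FAI — the layer is reported as
raw values (`faiThreshold` in `DetectionParams` can impose one), since
observed FAI magnitudes vary strongly with water reflectance and no
universal cutoff is defensible.

## Cleaning stages and their order

The pipeline applies a fixed stage order:

`eq1 → scl → entropy → minsize → vectorize → attributes → summary`

recorded in each mask's `stages` provenance and in the run's audit
sidecar. The order is a package decision: cloud masking first removes
whole regions cheaply; entropy filtering then inspects texture only
where detections survive; size filtering last, so it counts pixels that
survived every other test. Every stage is monotone — it can only remove
detections — so the final mask is always a subset of the spectral rule's
output, and no stage can ever set a nodata pixel.

**SCL masking.** Sen2Cor's Scene Classification Layer provides the cloud
mask. Detections are removed in codes {0 nodata, 1 saturated, 3 cloud
shadow, 8 cloud medium probability, 9 cloud high probability, 10 thin
cirrus} by default. The excluded set is configurable; the choice is
conservative because cloud edges are the dominant false-positive source.

**Entropy filter.** The b8A band is quantized into Q = 32 equal-width
levels and the Shannon entropy (bits) of the level histogram in a 5×5
window is computed per pixel; detections where H > 3 bits are removed.
Calm water and coherent rafts are spectrally uniform, while glint and
broken cloud edges are texture-rich. The quantization interval is the
*fixed* nominal reflectance range [0, 1], giving a level width of about
0.03 — deliberately above the radiometric noise of L2A products over
dark water (≈ 0.002–0.005). A scene-relative (min–max) quantization is
also available (`localEntropy(range = NULL)`) but is not the default:
on a low-dynamic-range open-water scene it would make the level width
smaller than the sensor noise, so the window histogram would measure
pure noise and read uniform water — and every raft — as high-entropy
texture. Windows are truncated at the scene border and nodata pixels do
not contribute to any histogram.

**Minimum size.** Connected components (8-connectivity by default,
matching the visual contiguity of diagonal raft filaments) smaller than
2 pixels are dropped: at 20 m a single-pixel detection (0.0004 km²) is
indistinguishable from speckle. The threshold is inclusive — a
component of exactly the minimum size survives.

## Vectorization and the attribute table

Component boundaries are traced exactly along pixel edges, with no
smoothing or simplification, so that polygon area is conserved exactly
(Σ area = pixel count × pixel area) and rasterizing the polygons back
onto the grid reproduces the mask bit for bit — both properties are
tested for 4- and 8-connectivity. Holes are preserved. Under
8-connectivity, rings pinch through checkerboard-ambiguous corners (the
same convention GDAL's polygonizer uses), so a ring may touch itself at
isolated vertices; shoelace areas and even-odd rasterization are exact
regardless.

Each raft record carries the portal attribute schema: a unique id (1..n
in row-major order of each component's first pixel), acquisition date,
MGRS tile, pixel count, area in km², distance to the coastline in km
with its color-scale bin (default edges 0–1, 1–5, 5–10, >10 km), the
location class, and an `edge_touching` flag for rafts cut by the scene
boundary (the package does not merge rafts across tiles). Distance is
nearest-edge — the minimum Euclidean distance in the projected plane
between the polygon and any coastline polyline, exactly 0 on
intersection; a centroid-based distance would misstate large elongated
rafts. Location classification has precedence beach > other seaweed >
ocean; because detection masks and the beach/benthic masks share one
grid, polygon–mask intersection is evaluated on the component's pixel
set, which is exact for areal overlap (contact along a shared boundary
line only does not count as intersection).

GeoJSON output follows RFC 7946: coordinates are reprojected from the
processing CRS (UTM/WGS84) to geographic WGS84, since the standard
forbids alternative reference systems; the projected CRS travels as a
`crs_projected` foreign member so reading restores projected
coordinates. The transverse Mercator conversion is implemented with a
fourth-order series in the third flattening (sub-millimeter accuracy
over a UTM zone) and is tested against an independent formulation and
against numerical integration of the meridian arc.

## Sandy beaches and the shoreline

To distinguish beached Sargassum from coastal vegetation, the package
derives a persistent sandy-beach mask from a multi-epoch cover
classification (codes: water, vegetation, bare, nodata): a pixel is
beach iff it is *bare in every epoch* — never vegetated across dry and
rainy seasons — and its center lies within a buffer (default 100 m) of
the shoreline, which is traced along land/water pixel boundaries. The
epoch classifier is an input, not a commitment: a simple NDVI helper
(`coverFromNDVI`, bare below NDVI 0.2 by default) is provided, but any
external classification on the same grid can be supplied. In seasonal
mode the stack must contain at least one dry and one rainy epoch;
otherwise epochs are treated equally. The construction is anti-monotone
in epochs (adding an epoch never grows the mask) and monotone in the
buffer width, and both properties are tested.

## Statistics and queries

Per-scene summaries report the summed raft area, polygon count and
cloud percentage, defined as 100 × (pixels in codes 8, 9, 10) / (pixels
with code ≠ 0): nodata is excluded from the denominator so partially
covered granules are not misread as clear. The recent-pass table sorts
summaries newest first (ties break by tile id) and returns the last
n = 10 by default. Attribute queries support ≥, ≤ and = on area (= with
a 10⁻⁹ km² absolute tolerance, since exact float equality is
meaningless), inclusive UTC date ranges, and a location-class filter; an
empty filter is the identity and clauses compose by intersection.

## The synthetic-scene generator

`makeScene` draws each band i.i.d. Gaussian around a water spectrum,
truncated at 0; `plantRafts` overwrites elliptical or filament
footprints (exact pixel counts) with a raft spectrum; `addClouds` paints
opaque bright clouds, sets SCL code 9 and *clears the truth mask*
underneath — detection is defined on observed radiance, not latent
biomass, so an obscured raft is not recoverable ground truth. Default
spectra (water b04 = 0.03, b08 = 0.02, b8A = 0.015, b11 = 0.005; raft
b04 = 0.04, b08 = 0.09, b8A = 0.06, b11 = 0.03; cloud 0.3 in all bands)
sit strictly outside/inside every rule condition with at least 0.01
reflectance margin, so with zero noise the pipeline must recover planted
truth exactly, and small noise cannot flip the contract. The default
band noise of 0.002 approximates L2A radiometric scatter over dark
water; the regression guard runs at 0.005, twice that, and still
requires ≥ 0.95 recall for rafts of ≥ 4 pixels. Everything is a pure
function of (shape, specs, presets, seed): the generator seeds a local
RNG stream and restores the caller's state.

What the generator does *not* emulate — sun glint, mixed pixels at raft
edges, spatially correlated noise, cloud shadows with water-like
spectra, swell texture — bounds what passing tests show about real
scenes: they verify the algorithmic contracts (rule evaluation, masking
algebra, geometry exactness, determinism), not radiometric performance
on real imagery, which the original calibration addressed by
photointerpretation.

## Numerical and I/O choices

Problem sizes in the tests are chosen to keep the full suite around ten
seconds: oracle equivalence on 100 scenes of 64×64, end-to-end recovery
on 20 scenes of 256×256 per noise condition, 50-case geometry
round-trips. Grids are row-major with pixel (1,1)'s outer corner at the
transform origin; transforms are axis-aligned north-up (`c(x0, y0, dx,
dy)`), the dominant GeoTIFF case. Rasters travel as TIFF pixel data
plus an ESRI world file and a YAML sidecar carrying CRS, acquisition
metadata and the value encoding; because TIFF float storage here is
defined on [0, 1], continuous rasters use a fixed affine encoding
(reflectance: offset −0.1, gain 1.6; FAI: offset −2, gain 4) recorded
in the sidecar, with round-trip error below 10⁻⁶ reflectance. Masks are
8-bit with 1 = Sargassum, 0 = background, 255 = nodata, and nodata wins
over detection. Composites stretch each channel linearly between the
2nd and 98th percentile of valid pixels; a degenerate stretch renders
mid-gray. Scenes are processed on a single co-registered grid (the 20 m
grid for detection); nearest-neighbor resampling of 10 m bands is the
assumed pre-step, and reprojection across UTM zones is out of scope.

## Known limitations

* The detection thresholds are a regional calibration for the western
  Caribbean; other basins, sensors or atmospheric-correction chains
  need re-calibration.
* No sun-glint correction: heavy glint can defeat both the rule and the
  entropy filter.
* Cross-tile rafts are reported per tile with `edge_touching = TRUE`,
  never merged.
* The NDVI cover helper is a convenience, not a validated land-cover
  classifier; operational beach masks should come from a proper
  multi-temporal classification.
* Cloud percentage uses SCL codes alone; SCL itself misclassifies some
  bright rafts as cloud in rare cases, which the excluded-code set
  cannot recover.
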