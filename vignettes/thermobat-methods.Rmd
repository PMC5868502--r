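---
title: "Methods: thermal BAT quantification and PET cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal BAT quantification and PET cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermobat)
```

This vignette documents the models, conventions and numerical choices
behind `thermobat`, in the order the pipeline runs them: radiometric
conversion, ROI construction, time-series outcomes, registration, volume
projection, thermal-to-projection warping, overlap and cohort statistics,
and the synthetic phantom the whole chain is validated against.

## Radiometric model

Thermal cameras report raw sensor counts, not temperature. The package
uses the standard single-band Planck inversion

$$T(\mathrm{K}) = \frac{B}{\ln\!\left(R_1 / (R_2 (S_{obj} + O)) + F\right)},$$

where the object signal corrects the raw count for reflected ambient
radiation at the surface emissivity $\epsilon$:
$S_{obj} = (S_{raw} - (1-\epsilon) S_{refl})/\epsilon$, and $S_{refl}$ is
the signal a blackbody at the reflected apparent temperature would
produce. The five Planck constants and the emissivity travel with every
frame in a JSON sidecar; nothing is hard-coded. The conversion is strictly
increasing in the count, so pixel rankings are calibration-independent.
The inverse (`temperature_to_counts()`) is the exact algebraic inverse
followed by rounding to integer counts; the round-trip error is bounded by
half the local derivative $dT/dS$ (about 0.01 °C at skin temperatures with
the default constants).

**Assumptions and limitations.** Atmospheric transmission is not modelled:
at indoor imaging distances of a metre or two the air column attenuates
negligibly in the long-wave band. Camera non-uniformity and lens vignetting
are likewise out of scope; inputs are assumed flat-field corrected by the
acquisition software.

The frame format is a 16-bit single-channel PNG of raw counts plus the
sidecar. The PNG encoder is implemented in the package (base R's
`memCompress()` provides the zlib stream the format needs) because no
installed R package writes 16-bit PNG; decoding uses `png::readPNG`. The
representation is bit-exact, which the suite verifies by round-trip.

**Coordinates.** All pixel coordinates in the package and its CSV
interfaces are 1-based, `x` = column, `y` = row, origin at the top-left —
the native convention of R matrices and of R image packages. Windows in
time are half-open, `[start, end)`.

## ROI construction

Each supraclavicular ROI is bounded by three borders anchored at five
labelled apices (left/right superolateral, left/right acromioclavicular,
sternal): the medial border (sternal to superolateral apex) and inferior
border (acromioclavicular to sternal apex) are straight lines; the lateral
border follows the neck and is traced programmatically from the
skin/background temperature contrast.

The tracer scans each image row between the superolateral and
acromioclavicular apices and places the border at the maximum horizontal
temperature gradient within a band of ±30 px (configurable) around the
straight line joining the two apices. Two refinements matter in practice:

* the gradient is **signed** toward the body — positive (background to
  skin) at the left border, negative at the right — so that when both
  neck borders fall inside one band only the correct one is a candidate;
* gradient **ties** (a discrete step edge straddles two columns) resolve
  to the candidate nearest the straight-line prior, which keeps detection
  mirror-symmetric.

The first and last rows coincide with the apices by definition, so the
gradient is traced on interior rows only, and a row whose band spans less
than `min_contrast` (default 3 °C) raises an error naming the row rather
than silently placing a border in noise.

The closed polygon (superolateral → neck contour → acromioclavicular →
sternal → back) is rasterized by the even-odd rule on pixel centers with
boundary pixels included (`pracma::inpolygon`); self-intersecting polygons
and polygons whose area is below half a pixel are rejected. The reference
region is a circle of diameter 10 px whose center sits one diameter below
the sternal apex ("immediately below"; the offset is a parameter since no
exact distance is canonical); a pixel belongs to it when its center is
within the radius, ties included — 81 pixels at integer centers.

## Hotspot statistic and outcomes

Per frame, `T_SCR` is the median of the hottest 10% of ROI pixels:
`k = ceiling(0.1 N)` pixels are selected by a stable sort (ties at the
cutoff resolve in raster-scan order, row by row, left to right), and the
median of the selected values is returned (mean of the two middle values
for even `k`). The ceiling guarantees a nonempty selection for any
nonempty ROI, and `k = 1` reduces the statistic to the ROI maximum. The
reference-region statistic is the arithmetic mean by default (the median
is an option); with an 81-pixel homogeneous sternal patch the two differ
negligibly, and the mean has lower variance.

The relative series is hotspot minus reference **per frame, before
smoothing** — subtraction and smoothing commute for a linear filter, but
anchoring the subtraction per frame keeps the series well-defined if
frames are dropped. Smoothing is a centered period-5 moving average in
"valid" mode: the output is `n − 4` samples timestamped at the window
center, so no edge padding ever fabricates values.

Outcomes from the smoothed series, all half-open in time and anchored at
the stimulation onset:

* **base** — mean over `[onset, onset + 60 s)`;
* **peak (initial)** — maximum over `[onset, onset + 600 s)`, the first
  ten minutes of cooling;
* **peak (initial+final)** — maximum from onset to the end of the
  recording;
* **Δ₁₀T_SCR** — peak (initial) minus base, the primary outcome, reported
  for the right ROI relative to the sternal reference (both sides and
  both kinds are always computed);
* the mean of the last minute of the initial and final periods, which
  supports the "at 10 min" and "final minute" report rows.

The base window is anchored at onset (equal to the start of the initial
period in the generated studies); the peak is taken on the smoothed
series, since the outcomes are defined on "the resulting time series"
after smoothing.

## Frame registration and difference rendering

Sequential frames are registered to the baseline frame with a similarity
transform (translation, rotation, scale) about the image center,
estimated by multi-resolution (4×, 2×, 1× block-mean pyramids)
Nelder-Mead minimization of the mean-squared temperature difference over
validly-warped pixels, with a coarse translation sweep (±12 px) at the
coarsest level and one perturbed restart per level to avoid premature
simplex collapse. Resampling is bilinear; pixels sampling outside the
frame are excluded from the metric. The suite verifies recovery of known
transforms in the envelope |t| ≤ 10 px, |θ| ≤ 5°, s ∈ [0.95, 1.05] to
0.5 px / 0.5° / 0.01.

Difference videos render the change against baseline through a fixed
piecewise-linear colormap — white at 0, red at +range/2, yellow at +range,
blue at −range/2, black at −range, clamped beyond — with `range = 2 °C`
by default; frames are averaged in sliding windows of 3 before rendering,
after registration.

## Projection and LWM warping

Volumes are projected along the declared axis (default: third array axis)
by an exact maximum: `MIP(x, y) = max_z V(x, y, z)`, computed as an
iterated `pmax` over slices and verified against a triple-loop oracle.
Projection is performed on the native grid; no resampling to isotropic
voxels is applied first.

The thermal-to-projection mapping is a locally weighted mean transform:
at each control point a full bivariate degree-2 polynomial (terms 1, x,
y, x², xy, y²) per output coordinate is least-squares fitted to its 16
nearest control points (Euclidean distance in source coordinates, the
point itself included), and a point's mapped position is the average of
all covering local polynomials weighted by the smooth taper
$W(t) = 1 - 3t^2 + 2t^3$ of normalized distance $t = d_i/R_i$, where
$R_i$ is the distance to the most distant neighbour used. Key properties,
all under test:

* for control points drawn from any global polynomial of degree ≤ 2 the
  map reproduces it exactly (every local fit equals the global one) — the
  module's central oracle;
* $W$ is C¹, decreasing, $W(0)=1$, $W(1)=0$, so the blend is smooth and
  interpolating where neighbourhoods are exact-rank;
* rank-deficient neighbourhoods (collinear points) raise an error naming
  the control point; fewer than 6 pairs is an error (a quadric needs 6
  coefficients).

Points covered by no influence disk fall back to the nearest control
point's polynomial (selectable as an error instead); the count of such
fallbacks is attached to the result. The transform is not analytically
invertible, so the two directions are fitted independently from the same
pairs: forward (thermal → projection) for mapping points and the ROI
polygon, inverse for image and mask resampling (inverse mapping with
bilinear interpolation; nearest-neighbour for masks, which therefore stay
binary). Warped polygons are edge-densified until no mapped segment
exceeds 1 px so the curved outline rasterizes faithfully.

## Overlap and statistics

The spatial overlap of the warped thermal hotspot and the projection
hotspot is the shared pixel count divided by the projection-hotspot count,
as a percentage. The two hotspots are nominally the same size (same
fraction of the same ROI), but nearest-neighbour warping can change the
thermal mask's count by a few pixels; measuring the denominator in the
fixed frame keeps it exact, and a symmetric (mean-count) denominator is
available as an option.

SEM uses the n−1 sample standard deviation over √n. Correlations are
squared Pearson coefficients with two-sided p-values from the
t-distribution with n−2 degrees of freedom. Paired session comparisons
default to the paired two-sided t-test, with the Wilcoxon signed-rank
test as an option; no multiple-testing correction is applied, matching
the validation study design this pipeline reproduces. Report tables flag
statistics that need more observations than available as `NA` rather than
failing.

## The synthetic phantom

The generator emulates the validation study's conditions: frames at 5-s
intervals across an acclimatization period (60 s), a 600-s initial cooling
period and a final period (60 s); a torso/neck/head silhouette at skin
temperature 34 °C on a 22 °C background; one Gaussian warm blob per
supraclavicular fossa (σ = 6 px) whose amplitude follows
$A(t) = A_0 + \Delta T_{max}\,(1 - e^{-(t-onset)/\tau})$ after cooling
onset in the cold session and stays at the baseline $A_0$ in the vehicle
session; i.i.d. Gaussian sensor noise (σ = 0.05 °C); and a paired PET
volume whose uptake blobs sit where a known degree-2 warp maps the thermal
blob centers, with amplitude proportional to $\Delta T_{max}$ (lognormal
jitter controls the expected thermal/PET correlation). Frames are encoded
to integer counts and decoded back, so generated data carry the true
quantization of the frame format. All randomness derives from the spec
seed; identical specs generate identical data.

Default kinetics — $A_0 = 2$ °C, $\Delta T_{max} = 0.4$ °C (per-subject
SD 0.15 in cohorts), $\tau = 120$ s — were chosen once so that the
baseline relative elevation (~1.9 °C) and ten-minute rise (~0.3 °C) fall
in the physiologically reported range for supraclavicular skin over
active BAT; they are conditions of the phantom, not claims about any
individual study's kinetics. The saturating-exponential shape reproduces
the rapid early rise with a further rise under prolonged cooling. The
vehicle session shares all geometry with the cold session and differs
only in activation and uptake amplitude (1% of the cold amplitude, i.e.
essentially unactivated BAT under measurement noise), mirroring a
within-subject control design.

The analytic ground truth for recovery tests is computed from the
activation curve alone: $A(t)$ sampled at the frame times, smoothed with
the same period-5 moving average, reduced with the same windows. The
pipeline's recovered Δ₁₀T_SCR differs from this truth by a small
geometry factor — the hottest-10% median sits slightly off the blob peak,
and the two blobs overlap marginally — which the default geometry keeps
within about 2% of the effect size, far inside the ±0.05 °C recovery
tolerance the suite enforces.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: anatomical texture and vascular structures
(which make real neck contours harder than a clean thermal step),
subject motion (registration is validated on synthetic similarity
transforms, not physiological drift), PET count statistics and
reconstruction artifacts (volume noise is Gaussian, not Poisson through a
reconstruction), and manual control-point placement error beyond
isotropic Gaussian jitter. The phantom's cold-session overlaps (~90%) are
accordingly cleaner than the published human values (~30%); the pipeline
is validated on recovery of known truth and on the direction of the
cold/vehicle contrast, not on reproducing human effect sizes.

## Problem sizes

The suite and acceptance script run: thermal frames of 96×128 px, 144
frames per session; PET volumes of 96×128×16 voxels; 70 control points;
cohorts of 8 subjects × 2 sessions, 20 seeds in the acceptance test (5 in
the acceptance script). These sizes exercise every code path while
keeping a full run inside a few minutes on one core; every algorithm is
size-agnostic.

## Known limitations

* The Planck constants of a specific camera must be supplied by the user;
  the defaults are representative magnitudes for the synthetic phantom,
  not vendor values.
* Apex placement is manual by design (the method is semi-automated);
  automatic apex detection is out of scope.
* The regional kinetic uptake estimate (`mrgluc_bat`) is an external
  per-subject scalar input — kinetic modelling of dynamic PET is not
  reimplemented here.
* Deformable (non-similarity) motion correction and video encoding are
  out of scope; difference frames are written as numbered PNGs.
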