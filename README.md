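# thermobat

Quantifying supraclavicular brown adipose tissue (BAT) activity from
infrared thermography (IRT), with the tooling needed to cross-validate the
thermal readout against glucose-uptake projections from dynamic
¹⁸F-FDG PET/CT.

## Who this is for

BAT is the thermogenic fat depot that dissipates energy as heat; its
largest superficial adult depot sits in the supraclavicular fossae. The
reference method for measuring its activation — dynamic FDG PET/CT —
carries a substantial radiation dose, which rules out repeated measures,
children and large healthy cohorts. IRT measures the skin-surface
temperature over the depot noninvasively and in real time, but its readout
must be shown to track the PET one. This package implements that
validation pipeline end to end for researchers working with radiometric
thermal cameras and PET-derived uptake maps.

## What it computes

* **Radiometric conversion.** Raw 16-bit camera counts S are converted to
  temperature with the standard single-band Planck inversion
  T(K) = B / ln(R₁ / (R₂·(S_obj + O)) + F), with an emissivity/reflected
  -signal correction S_obj = (S_raw − (1−ε)·S_refl)/ε. Frames travel in an
  open format: 16-bit grayscale PNG plus a JSON calibration sidecar.
* **ROI construction.** The left/right supraclavicular regions of interest
  are built from five labelled apices; the lateral (neck) border is traced
  programmatically from the skin/background temperature gradient, the
  medial and inferior borders are straight lines between apices. A 10-px
  circle below the sternal apex serves as reference region.
* **T_SCR time series.** Per frame, T_SCR is the median of the hottest 10%
  of ROI pixels (the 95th percentile). After a period-5 moving average the
  outcomes are base T_SCR (mean of the first minute of stimulation), peak
  T_SCR (window maximum) and ΔT_SCR = peak − base, absolute and relative
  to the sternal reference, per side.
* **Projection comparison.** PET-derived volumes are collapsed to coronal
  maximum intensity projections, MIP(x,y) = max_z V(x,y,z). A locally
  weighted mean (LWM) transformation — a degree-2 polynomial fitted at
  each of ~70 control points to its 16 nearest neighbours, blended with a
  smooth distance taper — maps thermal coordinates onto the projection.
  The spatial overlap of the warped thermal hotspot and the projection
  hotspot is |A ∩ B| / |B| · 100%.
* **Cohort statistics.** Mean ± SEM, squared Pearson correlations with
  t-distribution p-values, and paired two-sided comparisons, assembled
  into per-cohort report tables.
* **Synthetic phantoms.** A generator producing thermal sequences, paired
  PET volumes, apices and control points with closed-form ground truth
  (activation curve, true warp, true edges), so every stage is testable
  without any acquisition hardware.

## Worked example

Generate one synthetic subject, run the thermal pipeline, and compare the
thermal hotspot with the projection hotspot:

```r
library(thermobat)

spec    <- phantom_spec(seed = 7)                 # study conditions
thermal <- generate_thermal_sequence(spec, session = "cold")
irt     <- analyze_thermal_session(thermal$frames, thermal$apices,
                                   thermal$periods, onset_s = spec$onset_s)
subset(irt$outcomes, kind == "relative" & side == "right",
       c(base, peak_initial, delta10, peak_combined))
#>      base peak_initial   delta10 peak_combined
#>  2.044192     2.369256 0.3250635      2.376869

pet   <- generate_pet_volume(spec, session = "cold")
pairs <- generate_control_points(spec)
cmp   <- compare_modalities(irt, mip(pet$mrgluc), pairs, side = "right")
sprintf("overlap: %.1f %%  MIP hotspot median: %.2f",
        cmp$overlap_pct, cmp$mip_hotspot_median)
#> "overlap: 87.0 %  MIP hotspot median: 8.53"
```

The right-side hotspot sits 2.04 °C above the sternal reference at the
start of cooling and rises by 0.33 °C over the first ten minutes — within
0.01 °C of the phantom's analytic truth (0.318 °C) — and 87% of the warped
thermal hotspot pixels coincide with the projection hotspot. The group
statistics of the published validation cohort are available as reference
data:

```r
ms <- mean_sem(subset(published_overlaps(), session == "cold")$overlap_pct)
sprintf("cold overlap: %.1f +/- %.1f %% (n = %d)", ms$mean, ms$sem, ms$n)
#> "cold overlap: 29.5 +/- 5.0 % (n = 8)"
```

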