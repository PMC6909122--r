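---
title: "Methods: independent dose verification for cup-based breast SRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: independent dose verification for cup-based breast SRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cup-based stereotactic breast radiosurgery delivers a prescription (typically
a single-fraction 8 Gy boost to the lumpectomy cavity) as several hundred
*control points*: table positions at which the beam assembly dwells for a few
seconds with a 15 or 25 mm collimator, the focal spot tracing out the target.
Patient-specific QA (PSQA) for such a device has three legs: an absolute
point-dose measurement, a relative film measurement, and an independent
point-dose calculation that can run before every treatment without a
measurement session. This package implements the computational stack for all
three legs, plus the synthetic data needed to validate the stack end to end
without vendor Monte-Carlo tables or clinical plans.

# Coordinate frame and geometry

The immobilization cup defines the stereotactic frame: `y` along the cup
axis, chest wall at `y = 0`, apex at `y = apex_y > 0`; `x, z` transverse;
`r = sqrt(x^2 + z^2)` is off-axis distance. The measurement jig addresses
points cylindrically as `(r, theta, y)` with `theta = atan2(z, x)` in
degrees. The cup wall is modelled as a hemi-ellipsoid of revolution — widest
at the chest wall (base diameters 93.7, 121.7 and 153.7 mm for the three
size classes), tapering to the apex. The depth class (`inner_index`, 1–10)
sets `apex_y = 40 + 5 * inner_index` mm plus a size-class offset (0/10/20 mm);
the default library covers 19 cups (small 1–6, medium 1–7, large 1–6),
mirroring the 19 inner cup sizes the device ships. These depth values are
package choices at realistic scale, not vendor data.

# The forward dose engine

The engine is the package's ground truth. Each control point `i` contributes

    dose(p) = rate(C_i, cup, y_i, r_i) * (t_i / 60) * OCR(dy / b_i, rho / b_i)

where `rate` is the isocenter dose rate (Gy/min) looked up from a
`(y, r)` table, `t_i` the dwell time (s), `dy = p_y - y_i` the axial offset,
`rho` the *transverse displacement* of `p` from the focal spot, and `OCR`
the off-center-ratio kernel looked up bilinearly from a `(delta_y, delta_r)`
table. Dose is the superposition over all control points; linearity and
additivity are exact.

`b_i = 1 + alpha * r_i / R` is the *distortion model*: off the cup axis the
real dose distribution is not a rigid copy of the central kernel, and the
simplest model reproducing that — error growing with off-axis distance,
hence with target size — is an isotropic kernel-width stretch proportional
to the control point's off-axis distance (`alpha = 0.15`, `R = 50` mm by
default; `alpha = 0` recovers a positionally invariant kernel exactly).

In-transit dose (sources unblocked while the table moves between control
points) is off by default, matching the instantaneous-move assumption of the
independent calculation; turning it on integrates the moving kernel along
straight inter-point segments by the trapezoid rule at ≤ 0.5 mm steps and a
configurable table speed. The transit model is a package invention — the
physical effect exists, but no published handling is available to copy.

Default grid spacing is 1 mm (0.001 cc voxels, the planning system's quoted
single-pixel volume); reference-point doses default to the mean of the
5×5×5 voxel block (0.125 cc), close to a small thimble chamber's 0.053 cc
sensitive volume and much closer than a single voxel.

# Synthetic kernels

OCR profiles are error-function-smoothed top-hats,

    OCR(d) = 0.5 * (erf((w/2 - d)/(s*sqrt(2))) + erf((w/2 + d)/(s*sqrt(2))))

applied separably along the axial and radial lattice directions and
renormalized so `OCR(0,0) = 1` exactly. The 15 mm collimator's width is
22.0 mm — the device's measured focal-spot FWHM. The 25 mm collimator's
width (35 mm default) and the penumbra sigmas (2.5 / 3.0 mm) are
configurable package defaults, not device data. Dose rates decay
exponentially with depth below the apex, `rate = R0 * exp(-mu * depth)` with
`mu = 0.005`/mm — a 6-MV-like effective attenuation — so the rate is lower
near the chest wall of a deep cup, qualitatively matching the stated
physics. Out-of-lattice OCR queries return 0 (beam fully blocked far
off-axis) rather than extrapolating; dose-rate queries outside the cup are
an error, since the focal spot cannot be parked there.

# The independent point-dose calculation

The first-order dose to a reference point is the kernel sum over control
points using the *central* beam's OCR:

    D_ref,no volume = sum_i  D_i(C_i, c_i, y_i, r_i, t_i) * OCR_i(C_i, y_i - y_ref, r_i - r_ref)

Note the radial argument: the off-axis *difference* `r_i - r_ref`, not the
true transverse displacement. The sum is therefore exact only when kernels
are positionally invariant and the geometry is effectively on-axis; with the
distorting engine the discrepancy grows with how far the control points
spread from the cup axis, i.e. with target volume. The volume-dependence
correction captures this as a linear factor

    Vf(v) = slope * v + intercept

in the target volume `v` (cc), determined empirically by regressing the
ratio of ground-truth (engine or measured) dose to the kernel sum on volume
(`calibrate_vf()`), and applied as a configurable convention in
`dose_ref()`.

**Why the convention is configurable.** The published coefficients for the
clinical device (slope 0.028 per cc, intercept 2.7, shipped as
`vf_preset()`) produce factors of roughly 2.7–7, which cannot literally
multiply a dose that is already within a few percent of truth. Since the
published account defines the factor operationally through the calibration
pathway, the package makes that pathway the default semantics
(`"multiplier"`, with Vf fitted as a truth/kernel-sum ratio near 1) and
offers `"percent_offset"` and `"divisor"` readings for completeness. The
preset ships with this caveat attached and is not the recommended default.

The linear form leaves a little lack of fit: in the synthetic world the
discrepancy grows like a fractional power of volume (the control-point
spread scales as `v^(1/3)`), so calibration residuals contain mild
curvature and held-out deviations occasionally reach ~3 residual SD. That
is a property of the linear model, retained deliberately because the
published correction is linear.

Comparison metrics use `100 * (calc - tps) / tps`, so an independent value
below the planning system reads negative — e.g. 0.987 Gy vs 1.000 Gy is
−1.3%.

# QA-plan generation and the low-gradient reference point

The measurement phantom accepts its chamber only at a fixed position, so
`make_qa_plan()` rigidly translates every control point by
`chamber - target centroid`, leaving dwell times and collimators untouched.
The clinical description is ambiguous about whether the GTV or the PTV
centroid is moved, so `centroid_of` is an explicit parameter (default GTV)
recorded in the QA metadata rather than a guess.

`find_low_gradient_point()` implements the chamber-point selection rule: a
voxel inside the target where the relative dose change over any 1 mm step
(central differences, all three axes) stays below 0.5%. The selection among
qualifying voxels is not specified clinically; the package takes the
largest dose, breaking ties by distance to the structure centroid, so the
choice is deterministic and reproducible.

The 1.6% density correction for water-vs-breast-tissue comparisons is
applied only through `apply_medium_correction()`, with the sign an explicit
argument recorded in the result — the direction depends on which side of
the comparison is being corrected, and the package refuses to guess.

# Gamma analysis and the film chain

`gamma_map()` is a global (Low-style) gamma: for each reference pixel the
minimum over nearby positions of the combined dose-difference /
distance-to-agreement metric, at 3%/1 mm by default. Implementation choices
not fixed by common usage are exposed in `gamma_params()`: the evaluated
plane is sampled at 0.1 mm steps, the spatial search stops at 3×DTA, and
reference pixels below 10% of the normalization dose are excluded from the
pass rate. Normalization follows the film workflow: the mean of an
operator-specified plateau region in the target (`"max"` and `"explicit"`
are available). The plateau region itself must satisfy a gradient check;
the end-to-end runner holds the film-plane region to 2%/mm rather than the
0.5%/mm point rule, because a transverse plane through a small stereotactic
field carries penumbra curvature that the 3-D point criterion never sees.

The film chain mirrors the physical procedure: a calibration curve fitted
to 12 points spanning 0.01–10 Gy (red-channel netOD), modelled as a
saturating Michaelis–Menten term plus a linear tail — any monotone form
meeting the inverse round-trip contract would do; four fiducial marks
registered by least-squares rigid Procrustes (no scaling, reflection
excluded); film response resampled into the plan frame and inverted through
the calibration curve. `synth_film()` closes the loop for validation:
known calibration, known noise, known misregistration, deterministic per
seed, so the pipeline's recovery can be asserted exactly.

Profile-area sensitivity uses the first-order identity that widening a
near-top-hat profile of width `w` by `delta` changes its area by
`100 * delta / w` percent — for the 22.0 mm profile, a 0.2 mm width error
(below what is experimentally measurable) already moves the area integral
by about 1%. For the smoothed top-hat this identity is exact, because the
symmetric erf penumbra integrates to the top-hat area.

`error_band_analysis()` formalizes the action-threshold argument: with an
agreement SD of 1.4% between the independent check and measurement, a
2.7-SD band is 3.8%, and under a normal model fewer than 1% of cases fall
outside it. `classify_qa_outcomes()` tabulates true pass/fail and
Type I (false fail) / Type II (false pass) decisions treating measurement
as truth.

# The synthetic cohort

`generate_synthetic_plan()` draws GTV volume, PTV volume, breast volume and
control-point count from scaled Beta distributions whose supports and means
match the 15-patient commissioning cohort (GTV 2.9–29.1 cc, mean 11.1;
PTV 21.7–153.9 cc, mean 66.9; breast 722–1994 cc, mean 1264; control points
361–813, mean 491). The cup follows from the breast volume; control points
are scattered uniformly in the PTV sphere around the target centroid and
clipped to the cup; dwell times are 0.3–2.5 s; the 25 mm collimator is used
with probability increasing in PTV volume.

Target centroids sit **on the cup axis by default**
(`max_centroid_offset_mm = 0`). This is a deliberate study-design choice:
the kernel-sum approximation is exact for an on-axis reference point and
degrades with centroid off-axis distance (~10%/mm in this synthetic world)
*independently of target size*, so off-axis placement confounds the
volume-driven distortion effect that the Vf calibration is meant to
capture. With axial targets the error is purely volume-driven and the
calibration premise (error magnitude monotone in volume) holds cleanly;
off-axis cohorts can be generated explicitly when that confound is the
object of study.

What the generator does **not** emulate: real cohorts correlate target
volume with location and cup size far more strongly; clinical targets sit
well off-axis (upper-outer quadrants); kernels differ per cup; measurement
noise is not Gaussian-multiplicative; film has scanner artefacts and
multichannel structure. Passing tests therefore demonstrate the *machinery*
— superposition, calibration transfer, registration recovery, gamma
behavior — not clinical accuracy of any particular device.

# Numerical choices and problem sizes

- Bilinear/trilinear interpolation throughout; node-exact by construction.
- OCR lattice ±40 mm at 0.5 mm (library) or 1 mm (tests); values < 1e-3 at
  the boundary so truncation to 0 outside is smooth in practice.
- Gamma evaluation at 0.1 mm fine steps with distance-sorted early exit.
- Calibration-curve inversion by `uniroot` at 1e-10 tolerance; the fit must
  round-trip its own model within 1% on the calibration points.
- Validation suites use 20 seeds (oracle equivalence), 30–50 plans
  (Vf calibration), 41–61-pixel planes (gamma/film) — sizes chosen so the
  whole suite runs in about two minutes while keeping Monte-Carlo noise
  well below the asserted tolerances.
- Degenerate inputs fail loudly: empty masks, non-monotone calibration
  responses, collinear marks, all-equal calibration volumes, focal spots
  outside the cup.

# Known limitations

- The engine abstracts the 25-source spiral delivery into kernels; no
  source-by-source ray tracing, scatter, heterogeneity, or mechanical-sag
  modelling.
- The distortion model is the simplest one producing the documented
  qualitative behavior; real distortion is anisotropic.
- Film handling is single-channel with a rigid registration; no scanner
  lateral corrections or multichannel dosimetry.
- 2-D gamma only; extending the comparison to 3-D is future work.
- No DICOM-RT or vendor file formats; the JSON/CSV formats documented here
  are the interchange surface.
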