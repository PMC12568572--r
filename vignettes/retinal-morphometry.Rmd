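---
title: "Retinal vascular morphometry on synthetic fundus photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vascular morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package measures

`retinavasc` quantifies the retinal vasculature and optic nerve head on
disc-centered 45° color fundus photographs. From a segmented vessel mask and
a fitted disc/cup geometry it derives nine per-eye parameters:

* **VDf** — box-counting fractal dimension of the binary vessel pattern
  (dimensionless, ~1.4–1.5 for a healthy posterior pole);
* **VC** — vascular caliber: mean vessel width along the centerline, in µm;
* **VT** — vascular tortuosity: arc length / chord length − 1 per segment,
  length-weighted over a region, conventionally reported ×10⁻³;
* **VD** — vascular density: the fraction of region pixels occupied by
  vessels;
* **VBA** — vascular branching angle: the angle between the two daughter
  branches at a bifurcation, from lines fitted near the branch point, in
  degrees;
* **AVR** — arteriole-to-venule ratio of the length-weighted mean calibers;
* disc area and cup area in mm², and their area ratio **C/D**.

Each parameter is evaluated globally and in peripapillary zones: four annuli
at 0.5-PD steps from the disc border (0.5–1.0 through 2.0–2.5 PD, where PD
is the equal-area disc diameter) and the four S/N/I/T quadrants of the
0.5–2.5 PD band, split along the 45° diagonals through the disc center.
Nasal/temporal assignment follows eye laterality (nasal is +x in OD images,
−x in OS images; top-left origin, x rightward, y downward, pixel centers at
integer coordinates).

The statistical layer reproduces a two-cohort observational comparison:
group descriptives (mean ± SD), independent-samples t and Pearson chi-square
tests for the covariates, and ANCOVA — `outcome ~ group + age + sex + axial
length`, group effect tested by extra sum of squares, adjusted means at the
grand covariate means — for every parameter and zone. Both eyes enter as
independent rows, matching the unit-of-analysis convention of the emulated
study design; a `subject_mean` switch averages eyes per subject for
sensitivity analysis. No multiple-testing correction is applied across
parameters or zones, again matching the emulated reporting convention.

# The synthetic study

No real fundus photographs ship with the package; every stage is validated
on synthetic scenes with exact ground truth.

## Vascular trees

Trees grow recursively from the optic disc border. At every bifurcation the
daughter calibers obey the Murray-type conservation
$c_p^e = c_1^e + c_2^e$ exactly (default exponent $e = 3$), implemented by
drawing a side-branch flow share $u \sim U(0.12, 0.28)$ and setting
$c_1 = c_p u^{1/e}$, $c_2 = c_p (1-u)^{1/e}$. The branching geometry is
arcade-like: the main branch (flow $1-u$) deviates little from the parent
axis while the side twig takes most of the turn; the total turn between the
two daughters is drawn from $N(63.6^\circ, 7.5^\circ)$ and recorded as the
truth angle. Child segment length scales with flow share
(`parent length × (0.55 + 0.55 × flow)`), and branching stops when a
daughter's width would fall below 2.6 px ≈ 26 µm — about the optical
resolution limit of fundus photography, which is also why thinner vessels
cannot be meaningfully rendered or measured here. This asymmetric growth was
chosen so that annulus vessel density and caliber *decrease monotonically*
outward from the disc, the hallmark peripapillary profile the emulated study
reports; a symmetric Murray tree cannot produce it (total width grows by
$2^{1-1/e}$ per generation while annulus area grows only linearly with
radius).

Centerlines are straight base paths plus a windowed sinusoidal perpendicular
perturbation `a · sin(2πs/λ + φ) · sin⁴(πs/L)` (defaults a = 3 px,
λ = 60 px). The sin⁴ window keeps both the displacement and its slope
negligible over the first ~15 px of each segment, so bifurcation positions
and daughter take-off directions are *exactly* the base geometry — the truth
angle is the same quantity the branch-angle fit estimates. The truth
tortuosity of every segment is computed by fine quadrature (4000-point
polyline) of the same perturbed path.

## Rendering

Vessels are rasterized as the exact set of pixel centers within the local
radius of the centerline (per-edge point-to-segment distance, radius
linearly interpolated); the ground-truth masks are that set, and image
shading never touches them. Veins are drawn over arteries at crossings, so
the artery/vein masks are disjoint and partition the vessel mask. The image
itself is a shaded scene — bright disc, brighter cup, darker vessels with
veins darker than arteries, smooth illumination gradient (radial vignette
plus lateral tilt), Gaussian pixel noise (SD 0.02 of the intensity range by
default) — inside a circular fundus aperture inscribed in a 1024×1024 frame
at 10 µm/px. The frame/pitch pair scales jointly, so physical truth is
size-invariant. The field of view, resolution, and calibration of the
emulated camera are not public; these defaults are explicit conventions, and
the pixel pitch is carried as metadata on every image.

## Cohorts

`generate_cohort()` draws per-subject covariates from group-specific
distributions that copy the published covariate imbalance of a
highland/lowland children comparison (age 8.66 ± 0.66 vs 8.08 ± 0.28 years;
male 43.8% vs 52.2%; axial length 22.76 ± 1.51 vs 23.27 ± 0.79 mm), and
per-eye truth parameters as baseline + highland offset + covariate effects +
subject- and eye-level noise. Defaults: caliber baseline 81.66 µm with a
−4 µm highland offset, −3 µm/mm of axial length and −1.5 µm for male sex
(both covariate effects in the direction the ophthalmic literature reports,
which makes the ANCOVA adjustment consequential because the groups differ in
those covariates); branching angle 63.6° − 1.5°; disc area
2.365 + 0.184 mm²; cup area 0.557 + 0.068 mm². The caliber residual SD is
11 µm per eye (3 µm subject-level + 10.58 µm eye-level). This default is set
by a power analysis rather than by copying the printed marginal SD
(~13 µm): the emulated covariate imbalance makes group membership strongly
collinear with age (variance-inflation factor ≈ 1.28 on the adjusted group
difference), and the design's stated operating point — ≥80% rejection of the
−4 µm offset at 100 subjects/group with both eyes as rows — is unreachable
at a 13 µm residual (power ≈ 0.75) but holds at 11 µm (power ≈ 0.85). The
resulting marginal caliber SD, including covariate-driven variance, is
11–12.5 µm. Eye-level variation dominating subject-level variation reflects
measurement-scale noise exceeding stable biological asymmetry.
Group effects are injected at the truth level, never at the image level, so
pipeline recovery can always be scored against known numbers.

## What the generator does *not* emulate

Photorealistic texture, media opacities, pathology (hemorrhages, drusen),
choroidal background, artery–vein crossing physiology (arteriovenous
nicking), capillary-scale vasculature, and inter-camera variability. Green
tests therefore demonstrate the *computational* correctness of the pipeline
on well-posed inputs, not clinical performance on real photographs; the
segmentation gate in particular is an analog of a reported recognition
floor, not a reproduction of it.

# The measurement pipeline and its numerical choices

**Preprocessing.** The fundus aperture is detected as the lit region; the
green channel (highest vessel contrast) is normalized by subtracting a
least-squares quadratic illumination surface fitted over the aperture.
Because the surface fit is a linear projection, preprocessing is idempotent
to machine precision — a property the test suite asserts.

**Segmentation.** A multiscale Hessian ridge (vesselness) filter — Gaussian
scales 1.5–9 px, scale-normalized eigenvalues, dark-ridge polarity — is
thresholded with hysteresis (weak ≥ 0.05, strong ≥ 0.25 of the normalized
response), gated on the normalized intensity being dark (< −0.01; the
vesselness ring is slightly wider than the vessel), cleaned of components
under 60 px, and boundary-regularized by a 3 px morphological
opening–closing so centerline tracing does not inherit threshold roughness. Thresholds were set by maximizing Youden's index on
the default synthetic scene and live in `default_config()`, not in code.
The segmenter sits behind `segment_vessels()` so a learned model can replace
it without touching anything downstream; this classical stand-in exists
because the emulated system's network and weights are proprietary.

**Disc and cup.** The disc is the dominant bright blob; ellipse from second
moments (for a filled ellipse the semi-axes are twice the principal SDs).
The cup is the brighter core of the disc blob, shrunk if necessary to
maintain containment.

**Skeleton and graph.** Zhang–Suen thinning with 5-px spur pruning;
junctions classified by the Rutovitz crossing number (raw neighbor counts
misfire on staircase bends) and merged within 2 px; segments traced by
walking; per-point radius = 3×3 local maximum of the Euclidean distance
transform at the centerline minus 0.25 px. The −0.25 px term is an
instrument calibration: the distance-transform ridge of a continuous band at
random sub-pixel offset overshoots the half-width by ~0.25 px on average
(the traced skeleton also wanders a pixel off the medial axis, hence the
local maximum). Stamping the measured radii back (`stamp_graph()`) recovers
≥95% of the mask pixels on synthetic scenes.

**Tortuosity on raster centerlines.** The digitization staircase inflates a
polyline's arc length by an order of magnitude more than the true signal at
VT ≈ 10⁻². Moving-average smoothing trades that inflation for signal
attenuation (~10% at useful windows), so the default estimator instead
applies a sharp spectral low-pass — resample to 1 px in arc length, even
extension, FFT, zero everything below the cut-off wavelength
min(20 px, L/2), calibrated once against generator truth on a dedicated
scene set — and computes arc/chord on the filtered curve. The sharp
cut-off passes the resolvable wiggle (λ = 60 px by default) unattenuated.
Below roughly half a segment's length no wiggle is resolvable at all, hence
the L/2 rule. On clean (non-raster) polylines the exported
`measure_tortuosity()` defaults to the exact ratio, which is what the
analytic oracles (straight line, semicircle = π/2 − 1, sinusoid vs
quadrature) exercise.

**Branch angles.** At a degree-3 node a line is fitted to each branch's
centerline points in an annular window from (local junction radius + 1) px
to +10 px further out — points inside the junction blob are excluded because
the medial skeleton bends between the daughters there and carries no
direction information. The daughters are the pair of fitted directions with
the smallest mutual angle (at a vascular bifurcation the parent opposes both
daughters); if the remaining branch fails to oppose both, the node is a
merged cluster or crossing and returns `NA`. Crossings (degree ≥ 4) are
excluded outright, as are bifurcations farther than 2 PD from the disc
center when disc geometry is supplied. Zone aggregates are unweighted means
over qualifying bifurcations. VBA is measured on arteries and veins alike.

**Aggregation conventions.** Caliber and AVR aggregate over interior
centerline points (points within 2 px of a node are excluded), which weights
segments by their arc length; tortuosity aggregates per segment with
arc-length weights, attributing each segment's value to zones in proportion
to the length inside each zone. C/D is the area ratio (with Table-style
means, the ratio of mean areas and the mean of per-eye ratios differ
slightly; the package reports per-eye ratios). Densities are reported as
fractions in [0, 1] — the emulated report labels ~0.07 values "%", an
ambiguity documented rather than imitated. The ×10⁻³ convention for VT is
treated as a display scale only.

**Box counting.** Dyadic box sizes 2, 4, … up to a quarter of the image
side, grid anchored at the origin (deterministic; multi-offset averaging is
deliberately off), least-squares slope of log N(s) vs log s; errors are
raised when fewer than three scales are usable or fewer than two boxes are
occupied at the largest scale.

# Validation design

* **Segmentation gate.** On the default scene (seed 0) pixel sensitivity
  ≥ 0.85 and specificity ≥ 0.96 inside the fundus aperture — the recognition
  floors the emulated system reports, transplanted to the synthetic analog.
* **Truth recovery (20 scenes, 1024 px).** Caliber is scored per segment
  (pooled MAE ≤ 0.5 px). Branching angle and tortuosity are scored as the
  error of the pooled eye-level aggregate — the statistic the cohort
  comparison actually consumes — over cleanly recovered structures: angle
  within 3°, tortuosity within 5%. Truth bifurcations whose daughters are
  thinner than ~2.5 px half-width are excluded from the angle match: below
  that, the two diverging daughters rasterize into a single wedge-shaped
  blob and the take-off angle is physically absent from the image. Per-match
  statistics are also reported (`validate_against_truth()`,
  `recovery_batch()`); per-bifurcation raster noise is of order 10° and
  averages out of the eye-level mean.
* **Zone geometry.** Annuli pairwise disjoint and quadrants an exact pixel
  partition of the 0.5–2.5 PD band (boundary pixels resolved by half-open
  radial and angular intervals); annulus density and caliber non-increasing
  outward on default scenes.
* **Statistics.** ANCOVA coefficients equal the explicitly solved normal
  equations to 1e-8; with no covariates the group F collapses to the pooled
  t²; the null rejection rate at α = 0.05 lies in [0.01, 0.12] over 100
  generator replicates; power ≥ 80% at the default −4 µm offset with 100
  subjects per group.
* **Determinism.** Identical config + seed gives byte-identical metrics CSV.

Problem sizes in the test suite (full scenes at 1024 px for gate and
recovery, 512 px for structural tests, 320 px for end-to-end pipeline runs,
100 generator replicates for the power properties) were chosen so the whole
suite exercises every stage at full fidelity where accuracy is asserted and
reduced scale where only structure is asserted.

# Known limitations

* The segmenter is classical; no claim is made about parity with a trained
  network on real photographs, and DRIVE/STARE-style benchmarking is out of
  scope.
* Artery–vein crossings become degree-4 nodes; their incident segments are
  excluded from branch-angle metrics, and no crossing disambiguation is
  attempted.
* Sub-pixel centerline estimation is limited to the calibrated radius
  correction; vessels below ~3 px width are neither generated nor reliably
  measurable.
* Intra-subject (two-eye) correlation is acknowledged but not modeled in the
  default eye-level analysis, mirroring the emulated study; the
  `subject_mean` switch exists for sensitivity analysis.
* Table-style covariate summaries of the emulated study contain internal
  inconsistencies (eye vs child counts); the generator parameterizes clean
  distributions instead of reproducing those cells.
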