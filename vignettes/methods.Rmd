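---
title: "Topographic structure–function mapping in AMD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic structure–function mapping in AMD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In age-related macular degeneration (AMD), structural damage visible on OCT —
drusen and pigment-epithelial detachments (PED), sub- and intraretinal fluid
(SRF/IRF), neovascularization (NV), fibrosis, atrophy — coexists with a loss
of visual function that is only partly explained by visual acuity.
Microperimetry (MP) measures light-sensitivity thresholds (dB) at protocolized
retinal loci under fundus tracking, so function can in principle be read out
*at* a lesion rather than averaged over the macula. The obstacle is
geometric: lesions are graded on OCT B-scans overlaid on an infrared (IR)
fundus image, while sensitivity points live on the microperimeter's color
fundus photograph (MP-CFP). `amdtopo` implements the full chain that joins the
two: enface lesion-mask construction from per-B-scan annotations, vessel-based
registration of the IR frame into the MP-CFP frame, pointwise assignment of
stimuli to lesion / peri-lesional / structurally-normal zones, zonal mean
retinal sensitivity (MRS), and the group-level statistics — plus a seeded
synthetic cohort generator that provides ground truth for every stage.

# Coordinate frames and raster conventions

All enface rasters share one convention (`enface_frame`): row-major, origin
top-left, 0-based pixel indices; physical coordinates are (x right, y down) in
mm relative to the fovea, measured at pixel centers. The default working scale
is 10 µm/px, so the 6 × 6 mm macular field is a 600 × 600 raster; the scale is
configurable everywhere. Degrees of visual angle convert to retinal distance
at a fixed 0.3 mm/deg. A schematic-eye constant (≈0.288 mm/deg) would be
marginally more accurate for an emmetropic eye, but the peri-lesional zone is
*defined* as a 0.3 mm band (1°), so using one constant everywhere keeps the
zone geometry and the grid geometry mutually consistent.

Pixel membership is always decided by pixel-center inclusion with no
anti-aliasing. This is deliberate: every area, overlap fraction and zone
partition then has an exact counting oracle, and the test suite holds the
implementation to *identity* with naive double-loop pixel counting rather
than to a tolerance.

# From B-scan annotations to enface lesion masks

Lesion boundaries are graded per B-scan as horizontal intervals (25 scans,
~240 µm apart, over the 6 mm field; the spacing is configurable and is *not*
assumed to equal field/(n−1)). Projecting these sparse rows to a filled
enface mask requires an interpolation rule, which we fix explicitly:

* every annotated interval is stamped over the half-spacing band around its
  scan row (so terminal scans extend half a spacing outward), and
* every pair of intervals on *consecutive* annotated scans whose x-ranges
  overlap is additionally connected by linear interpolation of its endpoints
  between the two scan rows.

A lesion absent on an intermediate scan therefore terminates an
interpolation run, so genuinely discontinuous lesions stay discontinuous.
We chose the band-plus-paired-tracks form over index-matched interval
interpolation because the latter is not monotone: adding one interval can
re-pair interval indices and silently *remove* mask pixels. Under our rule
adding an annotation only ever adds bands and adds tracks, which gives the
monotonicity property the test suite enforces, while reproducing the same
closed-form areas on simple cases (two identical intervals on adjacent scans
yield an exact rectangle of height two scan-spacings).

NV is delineated as an enface polygon on OCTA and rasterized even-odd by
pixel-center inclusion; self-intersecting polygons are rejected.

Zones are then: per-type lesion masks (overlapping types are allowed and kept
independently); their union (total lesion); the peri-lesional band =
Euclidean dilation of the union by 0.3 mm minus the union (computed by exact
distance transform, so it is disjoint from the lesion by construction); and
structurally-normal retina = the analysis region minus lesion minus
peri-lesional band. The analysis region defaults to the 5° (1.5 mm) disc
matching the MP grid extent. The three zones tile the analysis region
*exactly* in pixels. Composite zones (early/acute = SRF, IRF, drusen/PED, NV;
late/chronic = fibrosis, atrophy) are unions of member masks built before any
point assignment.

# Vessel extraction and registration

The IR and MP-CFP frames are aligned through the retinal vasculature, the
only structure reliably visible in both. Neither the vessel filter nor the
similarity metric is canonical, so we fix both and expose them in
configuration:

* **Filter**: multi-scale Hessian-ridge (Frangi-type tubularness) response
  for dark vessels, γ-normalized and maximized over scales (default 1.5,
  2.5, 4 px), thresholded at the 98th intensity percentile of the response,
  then cleaned by dropping connected components under 30 px. CFP images are
  reduced to the green channel first (highest vessel contrast). A constant or
  structureless image yields an empty mask flagged "not prominent".
* **Search**: coarse-to-fine maximization of the Dice overlap of the
  transformed moving mask against the fixed mask over a similarity transform
  (translation, rotation, scale about the frame center). At the ×4 pyramid
  level translation is searched exhaustively via FFT cross-correlation;
  rotation (±10° in 1° steps) and scale (0.95–1.05 in 0.01 steps) are swept
  in stages (rotation at unit scale, then scale at the best rotation, then a
  local joint grid) rather than as a full grid — the staging keeps the
  exhaustive translation search tractable and, on arcade-shaped vessel
  trees, loses nothing detectable. Refinement continues at ×2 (rotation step
  0.25°, scale step 0.005) and ×1 (rotation to 0.1°, scale to 0.0025,
  integer translations). Overlap is scored on 1-px-dilated masks to absorb
  centerline quantization. The search is fully deterministic.

On the default generator the search recovers seeded transforms to well under
a pixel, 0.1° and 0.25% scale; the acceptance property requires a 95th
percentile translation error ≤ 2 px over 50 seeded pairs spanning ±30 px,
±10°, scale 0.95–1.05.

**Quality gate.** Eyes whose vasculature cannot be matched are excluded, as
in the study flow this package mirrors (12 of 240 eyes). Our gate is a Dice
threshold at convergence, default **0.65**. The threshold is a stand-in for
the original tool's unquantified failure criterion and was chosen, before
any acceptance measurement, to separate the generator's score populations:
true rendered pairs score ≈0.85–0.95 while independent trees — which still
share arcade anatomy, as real retinas do — reach ≈0.2–0.5 under the
exhaustive search, so a gate at 0.3 would pass essentially every null pair.
With the default render noise (0.1), true pairs pass and null pairs fail
each at ≥95%; at five-fold noise the vessels are buried and most pairs fail
the gate, which is the intended degradation behaviour.

# Sensitivity grid, point assignment and zonal MRS

The MP protocol is a 68-stimulus grid over the central 10° of the macula.
The exact device layout is not public, so the default is concentric rings at
1°, 3°, 5° with 12, 24, 32 points — 4-fold symmetric, deterministic, and
replaceable via configuration; the tests enforce only the published totals
and extent. Each stimulus is a Goldmann III disc, taken as 0.43°
(0.129 mm) diameter — the standard perimetric constant, configurable.

A point belongs to a zone iff the fraction of its disc footprint overlapped
by the zone mask (carried into the MP-CFP frame by the estimated transform)
is at least **10%**, by exact pixel counting. A point may belong to several
zones; each zone summary row is computed independently, so a point
straddling lesion and peri-lesional retina contributes to both. Points whose
disc leaves the frame are recorded as unassessable and excluded from all
zones. Zonal MRS is the arithmetic mean of assigned point sensitivities;
zones with no assigned points yield a missing MRS and are dropped from
cohort averages.

"Not seen" stimuli are recorded with a flag and averaged at the device floor
(0 dB). Excluding them instead would bias lesional means upward most exactly
where function is worst; the choice is logged in the run metadata.

Fixation metrics are stand-ins for device outputs whose definitions are not
public: fixation area is the 95% bivariate contour ellipse area
(2·(−ln 0.05)·π·σₓ·σᵧ·√(1−ρ²)); stability requires ≥75% of samples within 1°
of the modal fixation position (Fujii-style); distance is the norm of the
sample centroid.

# Statistics

Group comparisons use the pooled-variance unpaired t-test for continuous
measures and Fisher's exact test for categorical ones. Pooled (rather than
Welch) variance is a deliberate, documented choice: computed from the
published summary statistics of the fellow-eye comparison (n = 22,
25.7 ± 3.0 vs n = 66, 27.8 ± 4.3 dB) it reproduces the reported p = 0.04,
where Welch gives ≈0.01. The t-test is computable directly from (n, mean,
sd) summaries; the raw-sample form reduces to it exactly, and is checked
against a permutation oracle.

The structure–function association is modelled by two-level mixed-effects
logistic regression: eyes (level 1) nested in subjects (level 2) via a
per-subject random intercept, fitted by Laplace-approximate ML
(`lme4::glmer`). The published analysis leaves the outcome/predictor wiring
ambiguous; we fix the outcome as the binary point-in-zone indicator (zone
points vs control-eye points) with point sensitivity (dB) as predictor —
which yields per-dB odds ratios of the magnitude reported (0.66–0.81) —
and adjust for the level-2 covariates age and sex in the multivariable
form. Odds ratios are exp(β) with Wald 95% CIs (profile CIs are slower and
change nothing at these sample sizes); non-convergence and separation are
flagged on the fit object, never silently worked around. No
multiple-testing correction is applied, matching the reference analysis.
`forest_table()` assembles the per-zone unadjusted and adjusted ORs in the
conventional reporting order and draws the forest plot.

# The synthetic cohort generator

No patient data are distributed, so validation runs end-to-end on a seeded
generator whose defaults *are* the study conditions:

* **Group sizes**: 66 control eyes (33 subjects), 30 early/intermediate and
  110 advanced AMD eyes plus 22 lesion-free fellow eyes (87 AMD subjects);
  the packaged enrollment ledger reproduces the reference flow (136
  participants − 16 missing = 120; 240 eyes − 12 registration failures =
  228). The 12 excluded eyes are exactly the fellow eyes of the unilateral
  subjects beyond the 22 analyzed, which makes the subject/eye bookkeeping
  internally consistent.
* **Zone sensitivities** (dB, mean/SD): fibrosis 5.5/5.4, atrophy 6.2/7.0,
  IRF 7.7/7.2, SRF 12.9/7.7, NV 13.2/8.7, drusen/PED 17.7/8.0,
  peri-lesional 20.2/7.6, structurally normal 22.2/7.0, controls 27.8/4.3,
  fellow eyes 25.7/3.0. These are treated as *observed* (post-censoring)
  moments: draws are clipped to the 0–34 dB device range, and the latent
  normal mean of each zone is solved (closed-form clipped-normal mean +
  root finding) so the clipped draws reproduce the configured mean. Without
  this the floor would bias low-sensitivity zones upward by ≈0.4 dB.
* **Variance decomposition**: the split between subject-level, eye-level
  and point-level variation is not identifiable from published tables; we
  default to 15% subject + 25% eye + 60% point noise. The subject share is
  what makes two eyes of one subject correlated, which the two-level model
  then detects.
* **Lesion geometry**: smoothed random stars (radially perturbed ellipses,
  renormalized to the target area) centered near the fovea, with per-type
  mean areas matching the reported zone summaries (e.g. fibrosis 5.3 mm²,
  drusen/PED 12.4 mm²) and log-normal area scatter. Advanced eyes sample
  lesion types at the published per-type frequencies; early/intermediate
  eyes carry drusen/PED; controls and fellow eyes are lesion-free. Blobs
  are sliced at the OCT scan rows into interval annotations (NV becomes an
  enface polygon), and the recorded ground-truth lesion extent is the
  *projection of those annotations* — i.e. the truth is what an ideal
  pipeline with a perfect registration would reconstruct, so recovery
  errors isolate the stages actually under test (registration, assignment,
  averaging) rather than the irreducible scan-sampling loss, which is
  tested separately as a round-trip Dice ≥ 0.95 property.
* **Imaging**: a per-seed branching vessel tree (two arcades from a
  disc-like origin at the nasal edge, 2–4 branch generations) rendered as
  an IR-style grayscale image and a CFP-style RGB image posed by a true
  similarity transform drawn from ±20 px, ±5°, scale 0.97–1.03, with
  modality-specific contrast, illumination gradients and additive noise
  (SD 0.1).
* **Per-point sensitivity**: zone mean (by ground-truth 10%-rule
  assignment, lesion types taking priority by largest overlap, then
  peri-lesional, then structurally normal) + subject effect + eye effect +
  point noise, clipped to the device range, rounded to 0.1 dB.

All randomness flows from a single seed; runs are bit-identical for a fixed
seed. What the generator does *not* emulate: photorealistic fundus texture,
media opacity, axial-length magnification differences, hemorrhage, fixation
losses correlated with disease, or test–retest variability beyond the point
noise term. Passing the recovery suites therefore demonstrates that the
pipeline is correct and unbiased *under its own geometric and statistical
assumptions*, not that it is robust to every feature of clinical images.

# Problem sizes and numerical choices

The validation experiments use sizes chosen to estimate each quantity with
useful precision while remaining desk-scale: 50 eyes per lesion-recovery
experiment (standard error of the zonal mean ≈ sd/√50), 66 control eyes for
the control-mean check, 50 seeded pairs for transform recovery, 50
replicates for mixed-model bias, 100 subjects × 60 points per replicate.
Registration grids and steps are as listed above; tie-breaks in all searches
go to the first-visited grid point, making every search deterministic.
Degenerate inputs are handled explicitly: empty lesion sets give empty
peri-lesional bands (not errors), empty discs make the intersection
fraction an error, constant images raise the low-prominence flag, empty
table margins give Fisher p = 1 with a warning, and fewer than two fixation
samples give a missing fixation area.

# Known limitations

* The enface projection discards axial (layer) information by design.
* The interpolation rule, grid layout, stimulus diameter, fixation metric
  definitions, logistic-model wiring and quality-gate threshold are
  declared package choices standing in for unpublished details of the
  original instrumentation; each is configurable and documented where it
  departs from a published constant.
* The registration model is similarity-only (no deformation, no
  mutual-information metric); eyes whose vasculature defeats it are
  excluded rather than force-fitted, mirroring the reference workflow.
* Mean areas and frequencies parameterize the generator per lesion *type*;
  co-occurrence structure between types is sampled independently, which is
  simpler than clinical reality.
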