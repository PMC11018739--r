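# amdtopo

Topographic structure–function mapping of AMD lesions with microperimetry.

In age-related macular degeneration (AMD), structural lesions graded on OCT —
drusen / pigment-epithelial detachment (PED), subretinal and intraretinal
fluid (SRF, IRF), neovascularization (NV), fibrosis, atrophy — sit in a
different coordinate frame from the retinal-sensitivity points (RSP, in dB)
that microperimetry (MP) measures on its own color fundus photograph
(MP-CFP). `amdtopo` is for retinal imaging researchers who want to read
function out *at* the lesion. It implements the full pipeline:

1. **Lesion marking** — project per-B-scan boundary annotations (25 scans,
   ~240 µm apart, 6 × 6 mm field) to enface lesion masks; NV polygons from
   enface OCTA are rasterized even-odd. Zones are derived per eye: total
   lesion area, the peri-lesional band (Euclidean dilation by 0.3 mm = 1° of
   visual angle, minus the lesion), and structurally-normal retina (the 5°
   analysis region minus both).
2. **Vessel registration** — multi-scale Hessian-ridge vessel masks from the
   IR fundus image and the MP-CFP, aligned by deterministic coarse-to-fine
   template matching (FFT-exhaustive translation; gridded, locally refined
   rotation and scale) maximizing Dice overlap, with a quality gate that
   excludes eyes whose vasculature cannot be matched.
3. **Overlay** — the 68-stimulus grid over the central 10°; a point is
   assigned to a zone iff ≥ 10% of its Goldmann III disc footprint
   intersects the zone mask; zonal mean retinal sensitivity (MRS, dB) is the
   mean over assigned points. Fixation area (95% BCEA), stability and
   distance from the fovea are computed from fixation tracks.
4. **Statistics** — pooled-variance unpaired t-tests and Fisher exact tests
   for group tables, and two-level mixed-effects logistic regression (eyes
   nested in subjects, per-subject random intercept) whose coefficients
   exponentiate to per-dB odds ratios, with forest-plot output.
5. **Synthetic cohorts** — a seeded generator (vessel trees, rendered IR /
   MP-CFP image pairs under a known similarity transform, lesion blobs
   sliced into B-scan annotations, zone-structured sensitivities, fixation
   tracks, and the enrollment ledger: 136 participants − 16 missing → 120;
   240 eyes − 12 registration failures → 228) so every stage can be
   validated against ground truth.

The central quantity is the zonal MRS: for zone $Z$ with assigned points
$\{s_i\}$, $\mathrm{MRS}(Z) = \tfrac1n \sum_i s_i$, a point being assigned
when $|D_i \cap Z| / |D_i| \ge 0.10$ for its disc footprint $D_i$ (exact
pixel counting). The association model is
$\mathrm{logit}\,P(\text{point} \in Z) = \beta_0 + \beta_1 s + \beta_2
\mathrm{age} + \beta_3 \mathrm{sex} + u_{\text{subject}}$, reported as
$\mathrm{OR} = e^{\beta_1}$ per dB.

## Worked example

```r
library(amdtopo)

cfg <- generator_config(seed = 5, n_per_group = c(control = 4L,
  early_intermediate = 1L, advanced = 3L, fellow = 1L))
cohort <- simulate_cohort(cfg)
res <- run_pipeline(cohort, run_config(seed = 5))
res$zone_table[, c("zone", "n_eyes_with_points", "mrs_db")]
```

```
                 zone n_eyes_with_points   mrs_db
1            fibrosis                  1 10.26735
2          drusen_ped                  2 15.42729
3                  nv                  3 11.35084
4         early_acute                  4 13.52741
5        late_chronic                  1 10.26735
6        total_lesion                  4 13.52741
7        perilesional                  4 18.37679
8 structurally_normal                  2 20.19167
```

Each row is one zone pooled over the simulated AMD eyes that contributed
assigned points: `mrs_db` is the across-eye mean of per-eye zonal MRS. Even
in this deliberately tiny nine-eye cohort the expected gradient appears —
lesional retina (fibrosis ≈ 10 dB here, from a single eye; drusen/PED
≈ 15 dB) is depressed relative to the peri-lesional band (≈ 18 dB) and
structurally-normal retina (≈ 20 dB), which in turn sit below healthy
controls (generator mean 27.8 dB); per-zone means at these sample sizes
carry eye-level random effects of several dB. `res$exclusions` lists eyes
that failed the vessel-matching gate, and `write_results(res, dir)` emits
the group-comparison, fellow-eye, zone and odds-ratio tables as CSV plus a
forest plot and a JSON run log.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/amdtopo.R run-all --seed 8 --n-control 4 --n-early 1 \
    --n-advanced 3 --n-fellow 1 --out results_dir
```

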