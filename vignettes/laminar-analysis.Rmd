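---
title: "Layer-specific BOLD analysis with layerglm: models, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-specific BOLD analysis with layerglm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerglm)
```

# The problem

Standard fMRI treats a cortical region as a single unit. At submillimetre
resolution the three depth compartments of grey matter (deep, middle,
superficial) can be resolved, and because feedforward and feedback circuits
terminate in different layers, a laminar activity profile constrains which
circuits produced a signal. Two obstacles stand between a 0.8-mm voxel grid
and a laminar profile:

1. **Partial volume.** Almost every voxel mixes signal from several
   compartments (white matter, up to three grey-matter layers, CSF).
2. **Geometry.** The layers follow the folded cortical sheet, so "depth" must
   be defined with respect to the white-matter and pial surfaces, and the
   surfaces must be accurately registered to the functional volume.

`layerglm` implements the full chain — equivolume layering, boundary-based
registration (global and recursive), orientation-preference ROI selection,
spatial-GLM unmixing, temporal-GLM response estimation, and repeated-measures
group inference — together with a synthetic cortical phantom and forward BOLD
simulator, so that every stage can be verified against known ground truth
without any scanner data.

# Equivolume layering

Each boundary is represented as a signed distance function (SDF): zero on the
surface, negative towards white matter, positive towards CSF
(`compute_sdf()`). Cortical layers keep their *volume* fractions through
folds: on the outer bank of a gyrus the superficial layer stretches and
thins, in a sulcal fundus it thickens. `equivolume_surfaces()` therefore
places the two intermediate surfaces so that the three grey-matter layers
have locally equal volume, not equal thickness.

The local volume element between parallel offsets of the white-matter
surface is modelled as
$A(t) = (1 + \kappa_1 t)(1 + \kappa_2 t)$,
with $\kappa_1,\kappa_2$ the principal curvatures of the WM surface. The
cumulative volume to depth $t$ is then a cubic,
$V(t) = t + \tfrac{1}{2}(\kappa_1{+}\kappa_2)t^2 +
\tfrac{1}{3}\kappa_1\kappa_2 t^3$,
and the boundary for volume fraction $g$ (measured from the WM side) solves
$V(t) = g\,V(T)$ with $T$ the local thickness — a vectorised Newton
iteration. On a plane this reduces to equidistant thirds; on a cylinder it
reproduces the equal-area radius $r_g = \sqrt{g\,r_p^2 + (1-g)\,r_w^2}$ and
on a sphere the equal-volume radius $r_g = (g\,r_p^3 + (1-g)\,r_w^3)^{1/3}$
exactly — these closed forms are the package's test oracles.

**Numerics.** Curvature invariants are estimated from the WM distance field
with fourth-order central differences (Richardson-extrapolated mixed terms)
after padding by linear extrapolation, which keeps affine fields exactly
curvature-free up to the grid border; the level-set curvature at offset $d$
is referred back to the surface via $\kappa_0 = \kappa/(1 - \kappa d)$,
clamped near the focal set. One pass of box smoothing stabilises
mesh-derived fields. Per-voxel volume fractions
(`layer_volume_distribution()`) classify `subdivision^3` regular sub-voxel
points (default 4, i.e. 64 points — a balance between the 0.8-mm grid and
phantom accuracy) by the interpolated signs of the four boundary fields; rows
sum to one exactly. Voxels without grey-matter volume are retained in the
matrix — their WM/CSF regressors absorb non-laminar signal — but are not
eligible for ROI membership.

On the 0.8-mm annulus phantom the implied boundary radii agree with the
closed forms to better than 1% and total ribbon volume is conserved to
better than 1%; the equal-volume property of the three layers holds to 1%
once the grid resolves the curvature (tested at 0.5 mm — at 0.8 mm trilinear
interpolation of the curved fields biases the outermost layer by about 1%).

# Boundary-based registration

`bbr_cost()` scores a surface-to-volume alignment by sampling the volume
1 mm inside and outside the white-matter boundary along vertex normals:
$\mathrm{cost} = 1 - \overline{\tanh(s\,Q)}$ with $Q$ the percent contrast
$200\,(O-I)/(|O|+|I|)$ and slope $s = 0.5$ per percent. The cost is
invariant to global intensity scaling. `fit_bbr()` minimises it over a
7-degree-of-freedom affine — rotation, translation, and scaling along the
phase-encoding axis (the direction distortions compress or stretch) — using
a coarse translation scan, Nelder-Mead, and a pattern-search polish with
absolute steps down to 2e-4. A capture-range box (20 degrees, 5 voxels, 10%
scale around the start) prevents drift along cost-flat directions such as
in-plane translation of a flat boundary patch.

`recursive_bbr()` corrects local distortions: after the global fit, the mesh
is recursively bisected into equal-vertex halves by planes normal to the
cardinal axes — the cut axis cycling through a permutation of x, y, z, each
cut orthogonal to the previous ones — and each partition is re-registered
with its own 7-DOF fit (tighter capture range: 5 degrees, 2.5 voxels, since
partition corrections are residual). Partitions that would split below 50
vertices are left intact. The procedure runs once per axis-order
permutation (all six by default) and the final per-vertex displacement is
the component-wise median over the runs, which rejects a single aberrant
ordering.

**What the phantom tests show and their limits.** On a noise-free tilted-slab
phantom whose two halves are displaced by opposite one-voxel shifts, the
recovered per-half displacement is accurate to well under 0.1 voxel, and the
absolute boundary contrast never decreases relative to the global fit. Two
caveats are inherent rather than implementation artefacts: (i) vertices
within roughly one final-partition width of a displacement *discontinuity*
sit in partitions whose image samples mix both displacement regimes, so
their individual estimates are intermediate — the per-region displacement is
the meaningful estimand for piecewise-constant distortion; (ii) on a
uniform-interior phantom the cost is flat against transforms that move
samples deeper into homogeneous tissue, so the 7th (scale) degree of freedom
is only identifiable when the intensity profile peaks at the boundary — the
scale-recovery test therefore uses a thick-ribbon shell with a smooth
(erf-profile) boundary, emulating the acquisition point-spread function.
Real EPI, with textured tissue, constrains these directions better than the
phantom does.

# ROI selection and voxel weighting

`localizer_glm()` fits, per voxel, HRF-convolved boxcars for the 45- and
135-degree localizer blocks and forms two T maps: both orientations against
baseline (activation) and 45 versus 135 (preference). `select_rois()`
restricts to a mask (the phantom ribbon in synthetic mode; an anatomical V1
label on real data) and to activation T > 2.3, then takes the 500 most
positive and 500 most negative preference-T voxels, each ROI drawing only
from voxels tuned towards its orientation; ties break by voxel index so
selection is deterministic. `weight_timecourses()` z-scores each voxel's
time course within each run (per-run rather than across runs, protecting
against inter-run offsets) and multiplies by the absolute preference T,
weighting the panel towards reliably tuned voxels; `mode = "raw"` bypasses
both steps and is the amplitude-preserving control.

`balance_layers()` implements the laminar-balance control: while a one-way
ANOVA on the per-voxel grey-matter layer fractions (observations: the three
fractions per voxel; factor: layer) is significant at p <= 0.1, the member
voxel with the largest fraction in the most over-represented layer is
removed. The unit of observation for this ANOVA is a design choice — the
per-voxel layer fractions make the procedure deterministic and directly
testable.

# Extraction and response estimation

For each functional volume the spatial GLM `Y = XB + e` regresses the ROI's
voxel values (`Y`) on the voxel-by-compartment volume fractions (`X`),
yielding one time course per compartment (`spatial_glm()`, QR-based — the
adjacent-layer columns are correlated, so QR is numerically safer than the
normal equations it is algebraically equal to; a warning fires when
cond(X) > 1e3). All five compartments are kept as regressors so WM and CSF
absorb non-laminar signal; only the three grey-matter courses propagate. The
control estimator `interpolation_extract()` computes `X'Y/N` — depth
interpolation — which by construction leaks signal between neighbouring
layers where the GLM does not; the phantom leakage comparison quantifies
exactly this.

`build_design()` constructs the temporal model per task: four regressors of
interest (present/omitted x 45/135), stick functions at the *expected*
first-grating onset (cue onset + 750 ms SOA — for omission trials too, since
the expectation pertains to the grating time) convolved with the canonical
double-gamma HRF (delays 6 s and 16 s, unit dispersions, undershoot ratio
1/6, 32-s kernel, unit peak); motion nuisance as the six parameters, their
backward differences, and squared differences; and a run-wise discrete
cosine high-pass (cutoff 128 s) applied identically to design and data.
One GLM is fitted per task over that task's concatenated runs. Percent
signal change uses per-compartment baselines unmixed from the pre-stimulus
(lead-in) volumes: a whole-run mean would be contaminated by the task
regressor mean and would break the exact noiseless round trip.

`orientation_specific_response()` subtracts each ROI's non-preferred from
preferred response per layer, stimulus type and task, then averages the two
ROIs. Swapping which orientation counts as preferred negates the output;
relabelling conditions and ROI identities together leaves it invariant.

# Group inference

`rm_anova()` computes the fully within-subject ANOVA through `aov()` error
strata (each effect tested against its own subject-by-effect interaction;
for 18 subjects a 2 x 3 interaction has df 2 and 34). No sphericity
correction is applied by default, matching the uncorrected df convention of
the target analysis; Greenhouse-Geisser is available via `gg = TRUE`. No
multiplicity correction is applied to per-layer tests — raw p-values are
reported. `paired_t()` wraps the two-sided paired t test with explicit
degenerate-case handling, `within_subject_sem()` implements
subject-centred error bars with the small-sample bias factor
$\sqrt{C/(C-1)}$, and `tsnr()` is mean over SD across time.

# The synthetic data model

`make_cortical_phantom()` builds slab, folded-sheet, annulus or shell
ribbons; the default pipeline phantom is a flat slab tilted 10 degrees
against the voxel grid. The tilt matters: an axis-aligned slab produces only
four distinct grey-matter voxel fraction patterns, making the five-column
laminar design matrix structurally rank-4 (unmixing unidentified), while any
oblique orientation — the generic case in real data — restores full rank.
Orientation preference alternates in two-voxel columns so both ROIs sample
all layers.

`simulate_bold()` is the forward model the analysis inverts: voxel signal =
volume fractions x compartment baselines (GM brighter than WM, 455-461 vs
427 raw units, out-of-brain 430) plus the grey-matter layers' HRF-convolved
condition responses in percent signal change, times a per-layer gain that
can emulate the superficial draining-vein amplitude bias (default 1).
Thermal noise defaults to a temporal SNR of 12.5, the post-realignment
in-brain value of the target acquisition; head motion is simulated as a
translation random walk that is *recorded* in the motion table but not
applied unless requested, since volume realignment is an input to — not part
of — this pipeline. Because the simulator and the analysis share the layer
volume matrix and the HRF code path, the noiseless raw-mode pipeline
recovers the injected amplitudes to machine precision; that round trip is
the package's strongest integration test.

The default condition amplitudes encode the effect structure under study:
an orientation-specific (preferred minus non-preferred) response of 0.14%
in all layers for presented gratings, and an omission response confined to
the deep layer (0.15% when orientation is task-relevant, 0.05% otherwise).

The session generator (`simulate_design()`) reproduces the target protocol:
4 runs x 2 blocks x 64 trials (512 trials, 256 per task, tasks alternating
by run), 75% cue validity with the remaining 25% omissions balanced exactly
within blocks, cue-colour contingency flipped halfway through the session,
750-ms cue-to-grating SOA, and inter-trial intervals jittered on
2.15-5.15 s. The jitter is a truncated exponential whose mean sits at one
third of the range above the lower bound — only the bounds are protocol
constants, the shape is this package's choice of a realistic rapid
event-related jitter. The staircase (`simulate_staircase_observer()`) is a
weighted up-down rule (descend by one step after a correct response, ascend
by three steps after an error), whose equilibrium is the 75%-correct point
of the observer's psychometric function; the protocol fixes only the target
accuracy, not the staircase family, and the weighted up-down rule is the
standard choice with that equilibrium. Thresholds adapt per task and the
design generator can consume traces from both tasks, mirroring the protocol
where each task's thresholds also set the other task's stimulus differences.

## What the group-level generator emulates

`simulate_effects_table()` draws per-subject laminar amplitude estimates:
truth + a per-subject offset (between-subject variability, SD 0.05% by
default) + independent per-cell estimation noise. The estimation noise is
calibrated so that each subject's task-averaged deep-layer omission estimate
has a single-subject t of about 3 (SE = amplitude/3) — the reliability
regime the pipeline targets for individual subjects. Under these conditions
the stimulus-type x layer interaction of the 3-way repeated-measures ANOVA
is detected in essentially every 18-subject dataset, while omission tests in
the middle and superficial layers stay at their nominal 5% size. Group-level
acceptance simulations operate on these per-subject estimates rather than on
1,800 full 4D simulations; the single-subject BOLD chain is validated
separately by the noiseless round trip and the per-stage oracles.

## What the phantom does not capture

No draining-vein deconvolution (the per-layer gain models a bias, not the
vascular transfer function), no k-space or distortion physics beyond
piecewise translations, no physiological noise structure (thermal noise is
white), no retinotopy, and no real segmentation errors — the surfaces are
exact. Passing phantom tests therefore demonstrates the correctness of the
estimators and their calibration, not robustness to every artefact of real
7T data.

# Problem sizes used by the test suite

Unit tests run on reduced geometries (16-24 voxels per axis, 8-16 trials
per block, ROIs of 40-200 voxels); the acceptance suite runs the session
structure at its protocol size (512 trials, 500 voxels per ROI, 16 localizer
blocks), 100 group datasets of 18 subjects, 4,000 null calibration
simulations, and the recursive registration at 6 iterations x 6 orderings
on a 24-voxel slab. These sizes were chosen so the full suite completes in
minutes while every guarantee is still exercised at its stated tolerance.

# A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg)
print(res)
round(res$effects[, , "orientation"], 3)   # layer x stimulus amplitudes

# group-level inference on simulated per-subject estimates
tab <- simulate_effects_table(n_subjects = 18, seed = 1)
rm_anova(tab, "amplitude", c("stimulus", "layer", "task"))
```
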