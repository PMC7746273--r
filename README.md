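# layerglm

Layer-specific (laminar) fMRI analysis in R: equivolume cortical layering,
partial-volume unmixing by a spatial GLM, boundary-based registration with a
recursive local variant, orientation-preference ROI selection, temporal GLM
response estimation, and repeated-measures group inference — plus a synthetic
cortical phantom and forward BOLD simulator with known laminar ground truth,
so every stage is verifiable without scanner data.

## Who this is for

Researchers analysing submillimetre BOLD data who need depth-resolved
(deep / middle / superficial grey matter) response estimates, and anyone who
wants a fully simulated test bed for laminar analysis methods: the package
generates cortical geometry, experimental designs, psychophysical staircase
behaviour, and 4D BOLD runs whose laminar truth is known, then recovers that
truth with the same estimators one would apply to real data.

## The core model

Cortical layers preserve their **volume** fractions through gyral and sulcal
folds. Given signed distance functions for the white-matter and pial
boundaries, the two intermediate surfaces are placed so the three layers have
locally equal volume, using the principal curvatures of the WM surface
(exact on planes, cylinders and spheres). Each voxel's volume is then
distributed over five compartments (WM | deep | middle | superficial | CSF),
giving an n-voxel x 5 matrix **X** of volume fractions. For every functional
volume, the voxel values **Y** of an ROI satisfy

    Y = X B + e

and ordinary least squares unmixes **B**, one time course per compartment —
the partial-volume problem solved as a spatial regression. The control
estimator `B = X'Y / N` (depth interpolation) is also provided; it leaks
signal between neighbouring layers where the GLM does not. Layer time
courses then enter a temporal GLM (canonical double-gamma HRF at the
expected stimulus onsets, motion nuisance, 128-s cosine high-pass), the
non-preferred orientation response is subtracted from the preferred one per
ROI, and group effects are tested with fully within-subject ANOVAs
(e.g. stimulus-type x layer with df 2, 34 for 18 subjects) and paired t
tests, with within-subject SEM error bars.

## A worked example

Simulate a complete noiseless session on a tilted-slab phantom and recover
the injected laminar amplitudes exactly:

```r
library(layerglm)
cfg <- pipeline_config(run_noise_sd = 0, localizer_noise_sd = 1e-3,
                       weighting = "raw", motion_step_sd_mm = 0, seed = 1)
res <- run_pipeline(cfg)
round(res$effects[, , "orientation"], 4)
#>              stimulus
#> layer         present omitted
#>   deep           0.14    0.15
#>   middle         0.14    0.00
#>   superficial    0.14    0.00
max(abs(res$effects - res$truth_specific))
#> [1] 4.82e-15
```

The printed matrix is the orientation-specific (preferred minus
non-preferred) BOLD amplitude in percent signal change, per layer, for
presented versus expected-but-omitted gratings during the orientation task:
presented gratings drive all layers (0.14%), while the omission response is
confined to the deep layer (0.15%) — exactly the generating truth, recovered
through layering, spatial-GLM unmixing, temporal GLM and subtraction.

Group-level inference on simulated 18-subject estimate tables:

```r
tab <- simulate_effects_table(n_subjects = 18, seed = 1)
rm_anova(tab, "amplitude", c("stimulus", "layer", "task"))
#>                 effect     F df_num df_den        p
#> 1             stimulus 311.2      1     17 2.31e-12
#> 2                layer  47.6      2     34 1.40e-10
#> 4       stimulus:layer  57.6      2     34 1.21e-11
#> ...
```

At realistic noise (the default reproduces a temporal SNR of 12.5) a single
subject's laminar estimates are noisy by design; the group statistics above
are where the effect structure becomes reliable.

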