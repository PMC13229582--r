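# statevel

Multi-voxel brain-state transition dynamics and their association with
self-reported psychological resilience, for resting-state fMRI
researchers who want a reproducible, testable implementation of
state-velocity analyses — plus a synthetic-cohort generator with known
ground truth so every stage can be validated without access to
restricted neuroimaging data.

## The model

The multi-voxel activity pattern of a network (e.g. the default mode
network, DMN) at timepoint *t* is a state vector *s<sub>t</sub>*. After
z-normalising the voxels × time matrix to SD units, states are embedded
in *k* ∈ {2, 3, 4} dimensions by non-metric multidimensional scaling
(Kruskal stress-1, dimension chosen by a stress threshold), and the
transition velocity between consecutive states is

> V<sub>s<sub>t</sub>→s<sub>t+1</sub></sub> = √ Σ<sub>k</sub> (d<sub>t+1</sub>(k) − d<sub>t</sub>(k))²   [SD per TR]

with per-subject summary μV = (1/(n−1)) Σ V. Region-mean variability is
summarised on the across-ROI mean z-series z̄<sub>t</sub> by

> rMSSD = √ (1/(n−1)) Σ (z̄<sub>t+1</sub> − z̄<sub>t</sub>)²

and by the ordinary (order-free) standard deviation. Resilience is
scored from the CD-RISC (0–100), BRS (1–5) and RSA (29–203, five
subscales) and summarised by correlation-matrix PCA (PC1 = general
resilience; PC2 contrasts BRS against RSA, i.e. perceived self-recovery
amid low external support) plus the intra/inter composite
½(PS + FSS) − ⅓(FC + SC + SR). Metrics and measures are related by
Pearson grids with Benjamini–Hochberg FDR per family and partial
correlations for confound control (mean framewise displacement, ROI
size). Signal conditioning (dummy discard, confound regression, linear
detrend, 0.009–0.08 Hz zero-phase bandpass, ROI masking) and the
>3.4375 mm / >3° motion-exclusion rule are included for raw data.

See `vignettes/state-dynamics-methods.Rmd` for the full model account,
parameter defaults, and design decisions.

## Worked example

Simulate a cohort at the design scale (336 subjects, 240 timepoints at
TR = 2 s, planted velocity ↔ self-recovery correlation −0.3), run the
pipeline, and correlate dynamics metrics with the resilience
components:

```r
library(statevel)

spec <- cohort_spec(n_subjects = 336, n_voxels = 96, n_timepoints = 240,
                    effect_r = -0.3, seed = 7)
cfg <- pipeline_config(spec = spec, condition = FALSE, k_candidates = 3,
                       restarts = 1, maxit = 50, covariates = "fd_mean",
                       seed = 8)
run <- run_pipeline(cfg, "demo_run")   # ~45 s

print(run$pca_main)
#> <scale_pca> 3 measures, n = 336
#>               PC1    PC2    PC3
#> cdrisc      0.915 -0.277 -0.294
#> brs         0.831  0.556 -0.020
#> rsa         0.924 -0.226  0.310
#> % variance 79.300 14.600  6.100

run$table$pc2_oriented <- orient_component(run$pca_main, 2,
                                           positive = "brs", negative = "rsa")
pearson_grid(run$table, metrics = c("mu_v", "rmssd", "sd"),
             measures = c("pc1", "pc2_oriented"), family = "demo")
#> <association_table> family 'demo', 6 tests, n = 336
#>  metric      measure      r  df   p_raw   p_fdr
#>    mu_v          pc1 -0.177 334 0.00114 0.00508
#>   rmssd          pc1 -0.153 334 0.00495 0.00876
#>      sd          pc1 -0.150 334 0.00584 0.00876
#>    mu_v pc2_oriented -0.171 334 0.00169 0.00508
#>   rmssd pc2_oriented  0.015 334 0.78000 0.78000
#>      sd pc2_oriented  0.022 334 0.69000 0.78000
```

Reading the output: PC1 loads all three scales positively (a general
resilience factor, ~79% of variance) while PC2 contrasts BRS (+0.56)
against RSA (−0.23). Subjects with smaller multi-voxel state transitions
(lower μV) report more self-recovery-type resilience (μV–PC2 r = −0.17,
p(FDR) < 0.01), recovering the planted −0.3 effect after attenuation
through item noise and component estimation; the region-mean
variability metrics (rMSSD, SD) instead track the general factor and
are flat against PC2 — the dissociation the two metric families are
designed to capture. Covariate-adjusted correlations (`run$adjusted`)
confirm the μV effects are not carried by head motion. Note
`condition = FALSE`: the generator emits already-conditioned matrices;
the conditioning stage is for raw data, whose slow drifts and confounds
it is contract-tested to remove.

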