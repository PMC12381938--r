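# latentcourse

Individual-level disease-progression prediction for 3D brain images with
a covariate-conditioned latent diffusion model.

## The problem

Neurodegenerative diseases change the brain regionally and at
subject-specific rates. Given a subject's scan at age *A* — plus simple
covariates: sex, cognitive status (CN / MCI / AD), and the volumes *v*
of five progression-related regions (hippocampus, cortex, amygdala,
white matter, lateral ventricles) as % of total brain volume — the
package predicts the scan at a later age *B* and quantifies how
uncertain that prediction is.

## The model

The pipeline combines five components:

* an autoencoder (ℰ, 𝒟) mapping images to compact latent grids
  *z* = ℰ(*x*);
* a denoiser ε<sub>θ</sub>(z<sub>t</sub>, t, c) trained with the
  diffusion noise-prediction objective under a scaled-linear β schedule
  (T = 1000, β ∈ [0.0015, 0.0205]), conditioned on the covariates
  c = ⟨s, v⟩;
* a control network ε<sub>θ,φ</sub>(z<sub>t</sub>, t, c, z(A)) — a
  trainable copy of the denoiser's encoder attached through
  zero-initialized connectors — that pins generation to the subject's
  baseline anatomy z(A) and starting age;
* an auxiliary disease-course model forecasting the region volumes
  v̂(B): a linear change model for single-visit inputs, or a logistic
  course model with subject time shift τ and acceleration e<sup>ξ</sup>
  for visit histories;
* latent average stabilization (LAS): inference is repeated *m* times
  from independent noise z<sub>T</sub> ~ N(0, I) with deterministic
  25-step DDIM; the prediction is the decoded mean latent
  x̂(B) = 𝒟(μ(B)), μ(B) = (1/m) Σ ẑ<sub>i</sub>(B). The per-element
  spread σ(B) gives a scalar global uncertainty u(B) = mean(σ(B)), and
  the voxel-wise variance of the decoded samples around 𝒟(μ(B)) gives
  an uncertainty map U(B).

Real training cohorts for such models are access-restricted, so the
package ships a synthetic longitudinal phantom generator (nested
ellipsoidal regions with diagnosis-dependent logistic volume
trajectories, ground-truth label maps and covariate tables) and runs the
whole pipeline end-to-end on phantoms at desk scale. The full-scale
configuration (122×146×122 images, 3×16×20×16 latents, m = 64) is
pinned by `paper_config()` as a configuration contract.

## Worked example

```r
library(latentcourse)

# simulate a small longitudinal cohort and inspect it
cohort <- simulate_cohort(n_subjects = 10, visits_per_subject = 3, seed = 42)
print(cohort)
#> phantom cohort: 10 subjects, 30 visits, grid 32x40x32
#> diagnoses: AD=5 CN=4 MCI=1

head(cohort$table[, c("subject_id", "age", "diagnosis",
                      "vol_hippocampus", "vol_ventricle")], 3)
#>   subject_id      age diagnosis vol_hippocampus vol_ventricle
#> 1      S0001 76.75564        AD       0.3294202      4.288452
#> 2      S0001 78.65914        AD       0.3114518      4.456157
#> 3      S0001 81.46325        AD       0.3054624      4.617873
```

Within one subject the hippocampus analog shrinks and the ventricle
analog grows, faster for AD than CN — the progression signal the
downstream models learn.

The full experiment — train codec, denoiser and control network on 60
subjects, fit the auxiliary model, predict 5-year follow-ups for 30
held-out subjects with m = 8, and evaluate — is one call (a few minutes
on one CPU):

```r
report <- run_pipeline(desk_config(seed = 1), verbose = TRUE)
print(report)
#> end-to-end evaluation (60 train / 30 test subjects)
#>   codec round-trip SSIM: 0.965
#>   follow-up prediction:  MSE 0.004256, SSIM 0.902
#>   requested vs measured ventricle: Spearman 0.850 (p = 2.77e-09)
#>   ventricle MAE: prediction 0.331 vs copy-forward 0.408
#>   uncertainty vs distance: pooled Spearman -0.224
#>   fast-progressor overlap (S = 10): 0.30
```

Reading the report: the autoencoder reconstructs held-out phantoms at
SSIM ≈ 0.96; the ventricle volumes measured in generated images track
the requested target volumes (rank correlation ≈ 0.85); the volumetric
error of the prediction is compared against the copy-forward baseline
(predicting no change); the uncertainty columns summarize how the LAS
spread relates to prediction distance; and the fast-progressor overlap
is the fraction of the truly fastest hippocampal atrophiers recovered by
ranking predicted atrophy (random selection would give S/n ≈ 0.33).

Single-subject prediction:

```r
models <- report$models
row <- report$cohorts$test$table[1, ]
x_A <- report$cohorts$test$images[[1]]
pred <- las_predict(x_A, row, B = row$age + 5, models, m = 8, seed = 7)
print(pred)
#> prediction at age 80.8 (m = 8): global uncertainty u = 0.009533
#> forecast volumes (% of brain): hippocampus=0.396 ventricle=3.75 cortex=17.8 white_matter=77.8 amygdala=0.218
```

`pred$image` is the decoded prediction, `pred$U` the voxel-wise
uncertainty map; `save_image()` writes either as NIfTI.

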