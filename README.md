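# photorecon

Brain banks routinely photograph coronal slices of dissected brains before
the tissue is archived or sent to histology. Those 2D photographs implicitly
contain a 3D image of the specimen — if the slices can be calibrated,
segmented and put back into register with each other and with a reference of
the intact brain. `photorecon` is an R package that does exactly that, for
neuropathologists and imaging scientists who want quantitative volumetry out
of routine dissection photography:

* **Calibration** — fiducial-marker detection (keypoint matching against
  user templates) and planar calibration from 2, 3 or 4 landmarks:
  isotropic scale, affine, or full perspective correction; rectification
  onto a regular mm grid.
* **Segmentation & grouping** — threshold + morphology tissue masks,
  8-connected components, and a declarative assignment of components to
  anatomical slices.
* **3D reconstruction** — joint estimation of per-slice planar transforms
  Φₙ, an anterior–posterior scale s, and the reference pose Ψ, by
  L-BFGS maximization (with full analytic gradients) of

  F = α·D(M, R∘Ψ) + β·mean NCC(Sₙ, Sₙ₊₁) + γ·mean D(Mₙ, Mₙ₊₁) − ν·mean |log det Lₙ|

  where D is soft Dice, NCC a masked normalized cross-correlation, and the
  last term penalizes per-slice scaling/shear. The reference is a binary
  mask rasterized from a surface scan (affine slices, free s, rigid Ψ) or
  a probabilistic atlas (rigid slices, s ≡ 1, affine Ψ).
* **Simulation** — multi-label hemisphere phantoms, digital slicing with
  per-slice affine distortion, illumination fields and thickness jitter,
  ground-truth poses, and a mean-voxel-displacement error metric; plus the
  domain-randomized label-conditioned generator of synthetic training
  images (GMM rendering, bias fields, intensity augmentation, anisotropic
  slicing and resampling).
* **Evaluation statistics** — 2D Dice, label volumes, age/sex GLM
  residualization, AUROC + Wilcoxon rank-sum group comparison (exact
  permutation p for small samples, ties included), Pearson correlations
  and Steiger tests for dependent correlations.

## Worked example

Reconstruct a digitally sliced phantom against its own surface mask:

```r
library(photorecon)

ph  <- make_phantom(phantom_spec(dims = c(48, 48, 64), seed = 3))
sim <- digitally_slice(ph$intensity, ph$mask,
                       slicing_config(spacing = 4, max_translation = 5,
                                      max_rotation = 10, seed = 7),
                       voxel_size = 1)
ref <- reference_volume(ph$mask, 1, "surface_mask")
fit <- reconstruct(sim$stack, ref, mode = "surface")
glance(fit)
#> # A tibble: 1 x 6
#>   mode    n_slices objective     s iterations converged
#>   <chr>      <int>     <dbl> <dbl>      <int> <lgl>
#> 1 surface       15     0.945 0.982         10 FALSE
reconstruction_error(fit, sim)
#> [1] 0.2937695
```

The 15 photographed slices — each perturbed by up to 5 mm translation,
10° rotation, mild scale/shear and an illumination field during simulated
dissection — are registered back to within about 0.3 mm mean voxel
displacement (the phantom's voxels are 1 mm). The `converged` flag reports
the strict objective-plateau criterion; the driver stopped here at its
iteration cap with the objective still creeping in the sixth decimal
place. `tidy(fit)` lists the
per-slice transforms, `autoplot(fit)` shows the monotone objective trace,
and `write_reconstruction(fit, "recon.nii.gz")` exports NIfTI volumes.

A thin command-line front end (`inst/cli/photorecon`) wraps the same
functions for shell pipelines (`calibrate`, `segment`, `reconstruct`,
`simulate`).

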