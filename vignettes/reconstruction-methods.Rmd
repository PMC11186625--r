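---
title: "From dissection photographs to 3D volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dissection photographs to 3D volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(photorecon)
```

## The problem

Brain banks photograph coronal slices of dissected specimens on a board
before the tissue goes to histology. Those photographs are, in effect, a
discarded 3D imaging modality: if the slices can be put back into register
with each other and with an external reference of the intact specimen, the
result is a calibrated 3D volume amenable to morphometry. `photorecon`
implements that pipeline: planar calibration of the photographs,
segmentation and grouping of the photographed slices, joint slice-to-volume
registration, a simulation framework for quantifying reconstruction error,
and the group-statistics toolbox used in ex vivo volumetry studies.

## Photograph calibration

Each photograph carries fiducials with known physical geometry. Three
calibration modes are supported, forced by the number of landmarks:

* **4 points** (corners of a rectangle of known width and height, in mm): a
  full projective homography, fitted by the normalized direct linear
  transform. This corrects perspective exactly and fixes the pixel size.
* **3 points** (two ruler arms of known length meeting at a corner): an
  exact affine transform mapping the arms onto orthogonal mm axes. Residual
  perspective is accepted; this is an approximate correction.
* **2 points** (one known distance): isotropic scaling only. No perspective
  correction — adequate when the camera is nearly fronto-parallel.

Fiducials are localized by matching user-supplied marker templates:
difference-of-Gaussian keypoints, a dominant gradient orientation per
keypoint (36-bin histogram with parabolic peak interpolation), 8×8
orientation-normalized patch descriptors, and a Lowe ratio test (0.75) with
an absolute descriptor-distance cap. The marker centre is mapped through a
similarity transform fitted to the matches with iterative outlier trimming;
a marker with fewer than 4 surviving matches is reported as not found.
Colour is reduced to luminance (0.299, 0.587, 0.114) before any geometry.

Tissue is segmented by thresholding (Otsu by default) followed by
morphological opening and closing with a 1 mm disk and removal of
components below 20 mm². Because real photographs need occasional manual
edits, externally edited masks can be substituted anywhere a `tissue_mask`
is accepted. Components are grouped into anatomical slices by a declarative
JSON specification rather than an interactive tool, which keeps the
pipeline scriptable and testable; a slice may own several components (a
detached temporal pole, for instance), and their in-photo positions are
never altered at this stage.

## The registration model

Given $N$ calibrated slice images $S_n$ with masks $M_n$, nominal thickness
$t$, and a reference volume $R$ (a rasterized surface scan of the specimen,
or a probabilistic atlas), the reconstruction estimates per-slice planar
transforms $\Phi_n$, an anterior–posterior scale $s$, and a reference pose
$\Psi$ by maximizing

$$F = \alpha\, D\!\big(M[\,\cdot\,;\{\Phi_n\},s],\, R\circ\Psi\big)
    + \frac{\beta}{N-1}\sum_n C(S_n, S_{n+1})
    + \frac{\gamma}{N-1}\sum_n D(M_n, M_{n+1})
    - \frac{\nu}{N}\sum_n f(\Phi_n),$$

where $D$ is the soft Dice coefficient, $C$ a normalized cross-correlation,
and $f(\Phi_n) = |\log\det L_n|$ penalizes scaling and shear in the linear
part $L_n$ of each planar transform (zero for any rigid motion). Weights
default to $\alpha=.95,\ \beta=\gamma=.025,\ \nu=\gamma/100$ with a surface
reference, and $\alpha=.8,\ \beta=\gamma=\nu=.1$ with an atlas, where the
reference deserves less trust and the slices more regularization.

Two search spaces are used. With a **surface scan** (same specimen, shape
is trustworthy): affine $\Phi_n$, free $s>0$, rigid $\Psi$. With a
**probabilistic atlas** (population average): rigid $\Phi_n$ (which makes
the regularizer identically zero), $s$ fixed to exactly 1, and a full 3D
affine $\Psi$.

All terms are evaluated on the common voxel grid of the assembled stack
(in-plane padded to 1.2× the largest slice bounding box so tissue cannot
drift off-grid); the reference is pulled onto that grid through $\Psi$ by
interpolation. The NCC support is the soft union
$M_n + M_{n+1} - M_n M_{n+1}$ of consecutive masks, so background never
dominates the similarity.

### The overlap term and the anterior–posterior scale

Two refinements of the $\alpha$ term matter in practice, both active during
optimization:

1. **Mass-consistent denominator.** The Dice denominator uses the
   reference's *total* volume under the current pose (in mm³), not just the
   part sampled by the stack grid. Otherwise the optimizer can contract the
   stack — in-plane or along the slicing axis — so that unexplained
   reference tissue simply disappears from view; with the invariant total
   mass in the denominator, hiding reference volume costs objective value.
2. **Slab integration.** Each slab is $s\,t$ mm thick, so the reference is
   averaged over the slab (3-point midpoint rule along the slicing axis)
   rather than sampled only at the centre plane. A stretched stack then
   dilutes its slab averages where they overrun the reference, which is
   what makes $s$ identifiable: with centre-plane sampling alone the
   objective is nearly flat in $s$ for small stacks and drifts by 10–15%.

`objective()` itself reports the plain centre-plane form (the direct
reading of the formula above), which attains exactly
$\alpha + \beta + \gamma$ on a self-consistent stack; `reconstruct()` uses
the slab-integrated form internally.

Even so, a residual scale bias of 1–2% remains on small stacks
(roughly 15 slices or fewer): the interior slabs of a smooth, convex object
constrain $s$ only weakly. The effect shrinks with slice count and with
shape irregularity, and is well inside the tolerance of the scale-recovery
checks, but it is the dominant error source for very coarse stacks (4–8
slices).

### Optimization

The objective is maximized by L-BFGS (`optim`'s implementation, history
size 10) on $-F$, with the **full analytic gradient**: bilinear slice
resampling, trilinear reference sampling, the weighted-NCC and soft-Dice
quotients, and the transform parameterizations are all differentiated in
closed form, and the gradient is verified against central finite
differences in the test suite (relative error below $10^{-4}$ on random
parameter points).

Parameterization keeps the search space well-behaved: planar affines are
(translation, rotation, two log-scales, shear), so the determinant stays
positive; $s = e^\sigma$ enforces positivity; the rigid reference pose uses
Euler angles and the atlas-mode affine uses free matrix entries.

Initialization follows the centre-of-gravity rule: each slice is translated
so its mask centroid sits at in-plane $(0,0)$, $s$ starts at 1, and $\Psi$
translates the reference centroid onto the stack centroid. No rotation,
scale or shear is introduced at this point.

The driver runs a 2-level coarse-to-fine pyramid (factor 2, block-mean
downsampling) by default, then rounds of up to 100 L-BFGS iterations;
convergence is declared when the objective changes by less than $10^{-6}$
across consecutive rounds (at most 5 rounds per level by default). The
trace of $F$ across rounds is monotone non-decreasing and is stored in the
result.

Two numerical details are worth recording. First, the trilinear
interpolant of a binary reference is only piecewise smooth; when the stack
and reference grids are commensurate (routine in simulations), the
centre-of-gravity start aligns *every* sample with a voxel corner, where
one-sided gradients stall the very first line search. The reference term
therefore uses a Hermite-smoothstep variant of trilinear interpolation —
same 8 neighbours, same values at voxel centres, but $C^1$ across voxel
boundaries. Second, soft Dice uses $\varepsilon = 10^{-6}$ in the
denominator only, so two empty masks give Dice 0 rather than 1.

## The simulation framework

`make_phantom()` builds multi-label hemisphere-like phantoms: a lobed
cortical shell (angular harmonics modulate the outer radius, emulating the
orientation information that gyri provide in real slices), white matter, a
ventricle, and four deep-gray structures, with a planar cut for the flat
medial face of a hemisphere. Intensities are per-label base values plus a
smooth random field. The lobes and the cut are not decoration: a smooth
ellipsoidal phantom leaves in-plane rotation and the anterior–posterior
scale nearly unidentifiable, which real anatomy does not.

`digitally_slice()` cuts a volume every $S$ voxels (thickness $S$ × voxel
size). Thickness jitter $j$ draws the $n$-th cut position uniformly from
$[n-j,\, n+j]$ in slice units. Every extracted slice receives an
independent random planar affine (defaults: ±5 mm translation, ±10°
rotation, ±0.1 log-scale and shear) and a multiplicative smooth
illumination field (low-resolution Gaussian noise upsampled by
interpolation, scaled to a maximum absolute log of 0.2). Slices whose mask
falls below 16 foreground pixels are dropped, as a photographed stack only
contains slices showing tissue. Ground-truth poses and cut positions are
recorded, and `reconstruction_error()` reports the mean displacement (mm)
over all foreground voxels between recovered and true positions, after an
optimal global rigid alignment removes the irrelevant common pose.

The experiment sizes used by the acceptance checks are a 48×48×64 phantom
at 1 mm for the recovery experiments (about 15 slices at spacing 4) and an
elongated 28×28×160 phantom for the spacing/jitter trend runs, whose
extent-to-thickness ratio at spacing 16 (about 9 slices) matches the
proportions of a real specimen sliced at that coarseness.

`simulate_training_pair()` implements the domain-randomized generative
process for segmentation training data: smooth 3D deformation plus an
abrupt per-coronal-slab in-plane jitter (emulating imperfect 3D
reconstruction), a Gaussian-mixture renderer conditioned on the labels with
per-label means and variances redrawn on every call (deliberately wider
than realistic appearance), digital slicing at a thickness drawn per
simulation with small per-slice variation, per-slice bias fields and
brightness/contrast/gamma transforms, and resampling back to the isotropic
grid. The target is the deformed label map on that same grid. Every
stochastic component is reproducible bitwise under a fixed seed.

What the phantoms do *not* emulate: real tissue texture and contrast
between anatomical boundaries, cracks and tears from handling, uneven
backgrounds, and camera noise. Passing recovery tests on phantoms therefore
demonstrates the correctness and conditioning of the machinery, not
photograph-level robustness; the preprocessing layer (calibration,
segmentation, grouping) is exercised separately on synthetic photographs
with pasted high-contrast markers.

## Evaluation statistics

The statistics module mirrors common practice in ex vivo volumetry:

* `dice2d()` — per-label 2D Dice on selected slices; a label absent from
  both rasters is undefined (`NA`) and excluded from aggregates.
* `residualize()` — ordinary least squares on `[1, age, sex]`, pooled over
  groups, replacing volumes by residuals.
* `auroc()` — the normalized Mann–Whitney U statistic (ties count 1/2),
  the non-parametric analogue of effect size.
* `ranksum_p()` — exact permutation p-value (mid-ranks under ties) when
  the smaller group has ≤ 8 observations and the combined sample ≤ 16;
  otherwise the tie-corrected normal approximation with continuity
  correction. The exact path exists because the standard implementation
  falls back to the approximation whenever ties are present.
* `steiger_test()` — comparison of two dependent correlations sharing one
  variable, via Fisher z-transforms with the pooled-correlation covariance
  term.
* `group_stats()` — the assembled pipeline: contralateral (left/right)
  averaging when both hemispheres are present, exclusion by default of the
  accumbens area and ventral diencephalon (regions whose segmentations are
  unreliable due to poor contrast), residualization, then per-region AUROC
  and rank-sum p. Raw p-values are reported by default; Bonferroni
  adjustment is available but off.

Open choices resolved here: mid-ranks are used for ties (rather than
dropping them), and the residualizing GLM is fitted on the pooled sample
rather than controls only.

## A worked example

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec(dims = c(48, 48, 64), seed = 3))
sim <- digitally_slice(ph$intensity, ph$mask,
                       slicing_config(spacing = 4, seed = 7), voxel_size = 1)
ref <- reference_volume(ph$mask, 1, "surface_mask")
fit <- reconstruct(sim$stack, ref, mode = "surface")
glance(fit)
reconstruction_error(fit, sim)
autoplot(fit)          # objective trace
plot_slab(fit)         # middle coronal slab
```

## Known limitations

* Per-slice transforms are affine; nonlinear within-slice deformation
  (tissue sagging, cracks) is out of scope.
* The anterior–posterior scale carries a small residual bias on very
  coarse stacks, as discussed above.
* Reconstruction quality depends on the reference: a probabilistic atlas
  yields plausible but not specimen-faithful shape, which is why atlas
  mode deliberately restricts its search space.
* The fiducial detector expects textured, high-contrast markers; it is a
  compact keypoint matcher, not a full-scale feature library, and marker
  appearance is a user input.
* Runtime is CPU-bound R; the experiment sizes above were chosen so the
  full simulation studies complete in minutes. Larger stacks benefit from
  the pyramid and the analytic gradient but scale linearly in voxels.
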