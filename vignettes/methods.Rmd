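---
title: "Fast atlas-based Bayesian segmentation: model, approximations and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast atlas-based Bayesian segmentation: model, approximations and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`histoseg` segments a brain scan $I$ with a high-granularity probabilistic
atlas $A$ under the classical generative model of Bayesian segmentation.
A deformation $\phi$ maps scan coordinates into the atlas; at voxel $j$ the
label $L_j$ follows the categorical distribution $A(\phi(x_j))$,
independently across voxels. Log-transformed intensities are Gaussian given
the label's tissue class, with a smooth additive bias field expanded in a
basis $\{\Psi_b\}$:

$$\tilde I_j \mid L_j = k \;\sim\; \mathcal N\!\Big(\mu_{c(k)} +
\textstyle\sum_b c_b \Psi_b(x_j),\; \sigma^2_{c(k)}\Big),$$

where $c(k)$ groups the hundreds of fine regions of interest (ROIs) into a
small number of tissue classes (16 by default) that share intensity
statistics. Classical inference alternates deformation, bias and Gaussian
updates around an expectation-maximization (EM) core, which is accurate but
slow. This package implements the fast approximation in which each
parameter group is visited **once**:

1. a coarse whole-brain segmentation (supplied by the user; in practice the
   output of a neural segmentation model at ~1 mm) yields a brain mask;
2. the bias field is estimated in a single M-step with responsibilities
   fixed to a blurred one-hot encoding of the coarse segmentation;
3. robust intensity statistics (median, 1.4826·MAD) per coarse structure
   feed heuristic linear "recipes" that give each tissue class a synthetic
   mean, from which a noise-free *synthetic anatomical volume* is rendered
   from the grouped atlas and matched to the scan's resolution;
4. a greedy multiscale diffeomorphic registration aligns the synthetic
   volume (plus protocol-grouped atlas label maps) with the scan, driven by
   local normalized cross-correlation (LNCC) and a soft-Dice label term;
5. EM over the grouped tissue classes runs once at the working resolution
   with the bias and deformation fixed, and the class posteriors are
   redistributed to the fine ROIs in proportion to the warped atlas.

# Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `bf_mode` | `dct` | — | bias basis family (`dct`, `polynomial`, `hybrid`) |
| bias order | 6 | per axis | 343 DCT basis functions |
| soft-seg blur | 0.5 | mm | one-hot blur for the bias M-step |
| `resolution` | 0.4 | mm | working grid of the final EM (ex vivo: `min(0.2, scan)`) |
| `skip` | 1 | voxels | stride subsampling of EM M-steps |
| `smoothing_steps_HRmask` | 3 | steps | box smoothing when upsampling the brain mask |
| `optimizer_lr` | 0.5 | voxels | registration step size (finest-grid voxels) |
| `smooth_grad_sigma` | 1.0 | voxels | Gaussian smoothing of the similarity gradient |
| `smooth_warp_sigma` | 0.25 | voxels | Gaussian smoothing of the composed warp |
| `cc_kernel_size` | 7 | voxels | LNCC window (radius 3) |
| `rel_weight_labeldiff` | 2.5 | — | weight of the soft-Dice term |
| pyramid start | 4 | mm | coarsest registration level, halving per level |

# Numerical and design choices

**Log transform.** $\tilde I = \log\max(I, \varepsilon)$ with
$\varepsilon = 10^{-6}$ times the robust maximum; nonpositive voxels leave
the mask. Densities are evaluated in log space with the log-sum-exp trick.

**Bias estimation grid.** The single M-step runs on a grid downsampled by
the integer factor $\max(1, \min(\lfloor 2\,\mathrm{mm}/v\rfloor,
\lfloor d_{\min}/64\rfloor))$, i.e. at about 2 mm for whole-brain scans
while always keeping at least 64 samples per axis so the 343-coefficient
normal equations remain well conditioned. The field is evaluated
analytically (separable tensor contraction) at any resolution afterwards.

**Robust (trimmed) bias M-step.** The fixed soft responsibilities
inevitably mislabel some boundary voxels; their residuals equal a full
class contrast (many standard deviations) and would otherwise leak anatomy
into the smooth field. Class moments and the precision-weighted
least-squares system therefore use per-class 3σ inlier voxels, with the
0.9735 truncation-consistency factor on variances. On phantoms this
reduces the residual field error by roughly a factor of four. The DC
component of the estimated field is removed at correction time (a scalar
chosen to preserve the masked median intensity): the overall gain is not
identifiable.

**Registration.** The warp is a dense displacement field on the fixed grid
composed with an affine pre-alignment obtained from probability-weighted
structure centroids. Per iteration: similarity forces are computed
analytically (exact adjoint of the box-window LNCC; per-label soft-Dice
derivative), multiplied by warped-image gradients, masked, smoothed
(`smooth_grad_sigma`), accumulated into a momentum field
($\beta_1 = 0.95$), scaled so the historical-maximum voxel displacement
maps to the (linearly decaying) learning rate expressed in finest-grid
voxels, composed with the running warp, and the result smoothed
(`smooth_warp_sigma`). Levels stop when the loss plateaus and always return
their best iterate. Three choices deserve emphasis, all diagnosed on pilot
phantoms:

* *Iteration budget as regularization.* The loss keeps improving past
  roughly 15–20 iterations per level while the recovered field gets
  *worse* — the intensity term starts matching noise texture. The default
  budget is therefore a deliberately modest 20 iterations per level.
* *Where the label term applies.* Soft Dice between operands of unequal
  sharpness is maximized away from alignment (a sharper moving map rewards
  warp-induced sharpening; a blurrier target rewards dilation into the
  blur skirt). Both operands are therefore one-hot at source — the atlas
  protocol maps are argmaxed — and the term is evaluated only at pyramid
  levels whose spacing does not exceed the label grid's, where both sides
  carry matched ~1-voxel interpolation transitions. Coarser levels run on
  LNCC alone. Only spatially compact protocol structures participate:
  mean Dice normalizes per label, so tiny scattered labels would reward
  pathological dilation.
* *Step normalization.* Voxel-wise Adam normalization steps a full
  learning rate even where the match is already good, turning flat regions
  into random walks; the global historical-max normalization keeps steps
  proportional to the gradient field and lets them fade near convergence.

**EM at the working resolution.** Warped class priors are renormalized
inside the brain mask; voxels with zero prior mass are excluded (counted in
a warning). Multi-component classes split their initial mean by ±0.5σ with
equal weights; variances are floored at $10^{-4}$ times the squared robust
intensity range. When the working grid is finer than the scan, the image is
upsampled by *nearest neighbour*: trilinear interpolation would shrink
within-tissue variance (noise averaging) and manufacture partial-volume
mixtures that the voxel-wise mixture model does not represent, biasing the
recovered standard deviations by tens of percent. Probability maps, being
smooth by nature, are always interpolated trilinearly.

**Sparse atlas handling.** Every ROI lives in a tight bounding box; warps
evaluate the deformation only inside a conservatively mapped box per ROI
and re-tighten afterwards, so memory scales with the ROIs' actual support
even for hundreds of regions at 0.4 mm.

**Tie-breaking.** Hard labels take the lowest label id on exact posterior
ties; nearest-survivor inpainting (after ROI removal) resolves equidistant
donors by lowest surviving label id.

# The phantom generator

`make_phantom_atlas()` + `sample_image()` + `corrupt_coarse_segmentation()`
generate a complete synthetic study: atlas, scan and coarse segmentation,
with every latent variable known. The default phantom is a 64³ volume at
1 mm — an in-vivo-like scan — whose anatomy mirrors the spatial statistics
that make real-brain segmentation well-posed:

* a gray-matter-like *fold texture* (thresholded smooth random field,
  features of ~4–6 voxels) interleaved everywhere with the white-like
  matrix, so no low-order bias basis can mimic tissue-class structure —
  with only a handful of large blobs the single M-step provably collapses,
  absorbing anatomy into the field, exactly as it would on an unrealistic
  phantom;
* the matrix split into ~10 compact Voronoi *cells*, the large (>500
  voxel) regions whose Dice is worth measuring;
* ~46 small spherical *nuclei* (radius 2) of darker/brighter classes.

Defaults (frozen once, before the acceptance suite existed): class means
110/170/80/230 intensity units, log-domain σ = 0.08, a zero-DC random
order-2 DCT bias field scaled to max |log-bias| 0.5 (strong shading of the
kind surface coils or ex vivo acquisitions produce; the DC is zero because
the overall gain is not identifiable), a deformation built from white
noise smoothed with σ = 8 voxels and scaled to a 6-voxel maximum (verified
diffeomorphic before sampling), and a coarse segmentation derived from the
true labels by a 3³ majority filter (a neural model produces smooth
boundaries, not the voxel-wise sampling speckle of the categorical model)
with 5% of boundary voxels flipped.

What the phantom does *not* emulate: partial-volume averaging (labels are
sampled per voxel, so boundaries are speckled rather than mixed), scanner
artifacts beyond smooth multiplicative bias, anatomical shape priors, and
multi-modal contrast. Passing the phantom suite therefore demonstrates the
*inference machinery* — bias recovery, registration, EM, redistribution —
under a faithfully generated model, not performance on real MRI.

# Problem sizes used in the validation suite

The end-to-end acceptance run uses the default 64³ phantom (~200 ROIs,
4 classes) and completes in a few minutes on one CPU; unit tests use 32³
phantoms with ~20 ROIs and small synthetic arrays (≤ 24³) whose expected
values come from brute-force oracles. The registration identity check, the
determinism check and the file-level pipeline test run at 32³ with a 1 mm
working resolution.

# Known limitations

* The deformation model is greedy and non-symmetric; no inverse field is
  produced, and no geodesic (velocity-integration) parameterization is
  available.
* The bias model assumes a single multiplicative field; slice-profile or
  wrap-around artifacts are out of scope.
* Recipes are linear in reference-structure medians; exotic contrasts may
  need user-supplied rules (`--yaml_path`).
* Hemisphere splitting relies on the coarse segmentation's labels; no
  template-space regression is performed.
* At working grids finer than the scan, volumes and posteriors inherit the
  nearest-neighbour upsampling's blocky boundaries (at sub-voxel scale).
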