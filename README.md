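# histoseg

Fast atlas-based Bayesian segmentation of brain MRI in R.

Segmenting a brain scan into hundreds of fine anatomical regions with a
high-granularity probabilistic atlas is classically posed as maximum a
posteriori inference in a generative model: a deformed atlas supplies a
categorical prior over labels at every voxel, and log-intensities follow a
Gaussian mixture per tissue class with a smooth multiplicative bias field,

    I~_j | L_j = k  ~  N( mu_c(k) + sum_b c_b Psi_b(x_j),  sigma^2_c(k) ),

where `c(k)` groups fine regions of interest (ROIs) into a small number of
tissue classes sharing intensity statistics. Exact inference alternates
registration, bias and Gaussian-mixture updates for hours to days.
`histoseg` implements the fast approximation in which each parameter group
is visited once:

1. **Bias field** — a single M-step of generalized EM with responsibilities
   fixed to a blurred one-hot encoding of a coarse (~1 mm) whole-brain
   segmentation; 3D DCT basis of order 6 (343 functions), robustly trimmed
   precision-weighted least squares.
2. **Contrast synthesis** — robust statistics (median, 1.4826·MAD) per
   coarse structure feed linear recipes that give every tissue class a
   synthetic mean; a noise-free *synthetic anatomical volume* is rendered
   from the grouped atlas and matched to the scan's resolution.
3. **Registration** — greedy, non-symmetric multiscale diffeomorphic
   registration of the synthetic volume to the scan, maximizing local
   normalized cross-correlation plus 2.5× a soft-Dice term over
   protocol-grouped atlas labels.
4. **Segmentation** — EM over the grouped tissue classes at the working
   resolution (0.4 mm by default), then redistribution of class posteriors
   to the fine ROIs in proportion to the warped atlas, hard labels and a
   soft volume table.

The package is exercised end to end on self-generated phantoms drawn from
the full generative model (known bias, deformation, labels and intensity
parameters), so every stage's recovery is measured against ground truth.
It is written for researchers who want a transparent, dependency-light
implementation of this pipeline, including its atlas format (sparse
per-ROI bounding boxes), evaluation metrics (Dice, ICC(2,1), Spearman
volume–covariate correlations) and a command-line entry point.

## Worked example

Generate a phantom study and run the whole pipeline with default settings:

```r
library(histoseg)

bm <- phantom_benchmark(seed = 1)
round(bm$metrics, 4)
```

```
        em_worst_relative_drop posterior_conservation_max_err
                        0.0000                         0.0000
        class_mean_max_rel_err           class_sd_max_rel_err
                        0.0122                         0.0387
              bias_correlation     mean_endpoint_error_voxels
                        0.9963                         0.7345
    jacobian_positive_fraction           mean_dice_large_rois
                        1.0000                         0.9317
           min_dice_large_rois                   n_large_rois
                        0.8827                        11.0000
```

Reading these numbers: the EM objective never decreased; redistributing
class posteriors to fine ROIs conserved probability mass to machine
precision; the four tissue-class means were recovered within 1.2% and the
standard deviations within 3.9% of the generative truth; the estimated
bias field correlates 0.996 with the known field; the known smooth
deformation (up to 6 voxels) was recovered with a mean endpoint error of
0.73 voxels and an everywhere-positive Jacobian; and the eleven regions
larger than 500 voxels reached a mean Dice of 0.93 against the sampled
ground-truth labels.

File-based use mirrors the command line. A complete on-disk test case:

```r
write_phantom_fixture("fixture", seed = 1)
segment("fixture/scan.nii.gz", "fixture/coarse_seg.nii.gz",
        "fixture/atlas", "out", yaml_path = "fixture/config")
read.csv("out/volumes.csv")[1:3, ]
```

which writes `seg.nii.gz` (working grid), `seg_inputres.nii.gz`,
`volumes.csv` (soft ROI volumes in mm³) and a machine-readable
`manifest.json` with per-stage wall times. The equivalent shell call:

```sh
Rscript inst/scripts/mri-histoseg.R --i fixture/scan.nii.gz \
    --coarse_seg fixture/coarse_seg.nii.gz --atlas fixture/atlas \
    --o out --mode invivo --side left --yaml_path fixture/config
```

All flags (`--bf_mode`, `--skip`, `--resolution`,
`--smoothing_steps_HRmask`, `--skip_bf`, `--smooth_grad_sigma`,
`--smooth_warp_sigma`, `--optimizer_lr`, `--cc_kernel_size`,
`--rel_weight_labeldiff`, `--write_rgb`, `--write_bias_corrected`,
`--save_atlas_nonlinear_reg`, `--save_field`, `--save_jacobian`,
`--yaml_path`) keep their documented defaults; `--device`,
`--device_registration` and `--threads` are accepted as execution hints
whose contract is that results do not depend on them.

See `vignettes/methods.Rmd` for the model, the numerical choices and what
the phantom validation does and does not demonstrate.

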