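#' End-to-end phantom validation run
#'
#' Generates a phantom study (atlas, scan sampled from the generative model
#' under a known bias field and deformation, corrupted coarse
#' segmentation), runs the full segmentation pipeline with default
#' settings, and scores the recovery of every latent component against the
#' ground truth.
#'
#' @param seed integer seed driving the phantom.
#' @param grid_shape phantom grid (default 64^3).
#' @param n_rois,n_classes phantom anatomy (defaults 10 ROIs, 4 classes).
#' @param error_rate coarse-segmentation boundary corruption rate.
#' @param opts a [segment_options()].
#' @param verbose print stage progress.
#' @return list with `metrics` (named numerics), `result` (the
#'   [run_segmentation()] output) and `truth`.
#' @export
phantom_benchmark <- function(seed = 1L, grid_shape = c(64L, 64L, 64L),
                              n_rois = 200L, n_classes = 4L, error_rate = 0.05,
                              opts = segment_options(), verbose = FALSE) {
  ph <- make_phantom_atlas(seed, grid_shape, n_rois, n_classes)
  sam <- sample_image(ph, seed + 1L)
  coarse <- corrupt_coarse_segmentation(sam$truth, error_rate = error_rate,
                                        seed = seed + 2L)
  recipe <- phantom_recipe(ph)
  res <- run_segmentation(sam$image, coarse, ph$atlas, ph$grouping, recipe,
                          opts = opts, protocol_map = ph$roi_to_protocol,
                          verbose = verbose)
  truth <- sam$truth
  geom <- atlas_geometry(ph$atlas)

  # EM monotonicity: largest relative decrease of the mean log-likelihood
  tr <- res$em$loglik_trace
  drops <- if (length(tr) > 1) diff(tr) / pmax(abs(tr[-length(tr)]), 1e-12) else 0
  em_worst_drop <- min(c(drops, 0))

  # posterior mass conservation after redistribution
  cons <- 0
  for (cl in ph$grouping$classes) {
    ids <- as.character(ph$atlas$labels$id[ph$atlas$labels$class == cl])
    s <- sparse_sum(res$fine_posteriors[ids], res$working_geom$dim)[res$em$mask_idx]
    ci <- match(cl, colnames(res$em$resp))
    cons <- max(cons, max(abs(s - res$em$resp[, ci])))
  }

  # parameter recovery (single-component classes)
  true_mu <- vapply(truth$params$components, `[[`, numeric(1), "mu")
  true_sd <- vapply(truth$params$components, `[[`, numeric(1), "sigma")
  est <- res$em$params$components[names(true_mu)]
  est_mu <- vapply(est, function(cp) sum(cp$w * cp$mu), numeric(1))
  est_sd <- vapply(est, function(cp)
    sqrt(sum(cp$w * (cp$sigma^2 + cp$mu^2)) - sum(cp$w * cp$mu)^2), numeric(1))
  mean_err <- max(abs(est_mu - true_mu) / abs(true_mu))
  sd_err <- max(abs(est_sd - true_sd) / true_sd)

  # bias-field recovery, correlated over the brain mask
  mask_idx <- which(sam$image$mask)
  bias_corr <- NA_real_
  if (!is.null(res$bias_fit)) {
    bt <- eval_bias_field(truth$bias)[mask_idx]
    be <- eval_bias_field(res$bias_fit$model, geom)[mask_idx]
    bias_corr <- cor(bt, be)
  }

  # deformation recovery: mean endpoint error of the full atlas-coordinate
  # mapping (affine + field), voxel units
  ch <- deformed_coords(res$registration$deformation, geom, geom)
  ct <- deformed_coords(truth$deformation, geom, geom)
  epe_all <- sqrt((ch$x - ct$x)^2 + (ch$y - ct$y)^2 + (ch$z - ct$z)^2)
  epe <- mean(epe_all[mask_idx])

  # Dice on large ROIs between the hard segmentation and the sampled truth
  hard_scan <- resample_nearest(res$hard_labels, res$working_geom, geom)
  sizes <- table(truth$labels[truth$labels > 0])
  big <- as.integer(names(sizes)[sizes > 500])
  dd <- dice_scores(hard_scan, truth$labels)
  dice_big <- dd$dice[dd$label %in% big]

  metrics <- c(
    em_worst_relative_drop = em_worst_drop,
    posterior_conservation_max_err = cons,
    class_mean_max_rel_err = mean_err,
    class_sd_max_rel_err = sd_err,
    bias_correlation = bias_corr,
    mean_endpoint_error_voxels = epe,
    jacobian_positive_fraction = res$registration$jacobian_positive,
    mean_dice_large_rois = mean(dice_big),
    min_dice_large_rois = min(dice_big),
    n_large_rois = length(dice_big)
  )
  list(metrics = metrics, result = res, truth = truth)
}
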