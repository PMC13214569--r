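#' Pipeline options
#'
#' Defaults mirror the tool's command-line defaults: DCT bias basis, no
#' EM subsampling, 0.4 mm output resolution, 3 mask smoothing steps, and
#' the standard registration settings.
#'
#' @param mode input type: `invivo`, `exvivo`, `cerebrum` or `hemi`.
#' @param side hemisphere (`left`/`right`); metadata only for phantoms.
#' @param bf_mode bias basis family: `dct`, `polynomial` or `hybrid`.
#' @param skip_bf skip bias-field correction.
#' @param skip integer stride for EM parameter estimation.
#' @param resolution working resolution of the output segmentation (mm);
#'   for `exvivo` mode the effective value is `min(0.2, scan resolution)`.
#' @param smoothing_steps_HRmask box-smoothing steps when upsampling the
#'   coarse brain mask.
#' @param smooth_grad_sigma,smooth_warp_sigma,optimizer_lr,cc_kernel_size,rel_weight_labeldiff
#'   registration settings (see [registration_config()]).
#' @param write_rgb,write_bias_corrected,save_atlas_nonlinear_reg,save_field,save_jacobian
#'   optional outputs.
#' @param seed integer recorded in the run manifest (the pipeline itself is
#'   deterministic).
#' @return a list of class `segment_options`.
#' @export
segment_options <- function(mode = "invivo", side = "left",
                            bf_mode = "dct", skip_bf = FALSE, skip = 1L,
                            resolution = 0.4, smoothing_steps_HRmask = 3L,
                            smooth_grad_sigma = 1.0, smooth_warp_sigma = 0.25,
                            optimizer_lr = 0.5, cc_kernel_size = 7L,
                            rel_weight_labeldiff = 2.5,
                            write_rgb = FALSE, write_bias_corrected = FALSE,
                            save_atlas_nonlinear_reg = FALSE, save_field = FALSE,
                            save_jacobian = FALSE, seed = 1L) {
  stopifnot(mode %in% c("invivo", "exvivo", "cerebrum", "hemi"),
            side %in% c("left", "right"))
  structure(as.list(environment()), class = "segment_options")
}

#' Upsample the coarse brain mask to a target grid
#'
#' Binary brain-vs-rest map (CSF and extracerebral structures excluded)
#' linearly interpolated to the target grid, smoothed `smoothing_steps`
#' times with a normalized 3x3x3 box kernel, and thresholded at 0.5.
#'
#' @param coarse a [coarse_segmentation()]; brain labels are those with
#'   `protocol$is_brain`, defaulting to every structure whose name is not
#'   background/CSF.
#' @param target_geom target grid geometry.
#' @param smoothing_steps nonnegative integer (default 3).
#' @return logical array on the target grid.
#' @export
preprocess_mask <- function(coarse, target_geom, smoothing_steps = 3L) {
  stopifnot(smoothing_steps >= 0L)
  if (inherits(target_geom, "image_volume")) target_geom <- grid_geometry(target_geom)
  p <- coarse$protocol
  brain_ids <- if ("is_brain" %in% names(p)) p$id[p$is_brain]
    else p$id[!tolower(p$name) %in% c("background", "cerebrospinal fluid", "csf")]
  bin <- array(as.numeric(coarse$labels %in% brain_ids), dim(coarse$labels))
  m <- resample_to_geometry(bin, coarse_geometry(coarse), target_geom)
  for (i in seq_len(smoothing_steps)) m <- box_filter(m, 3L)
  mask <- m > 0.5
  if (!any(mask)) stop("empty brain mask after preprocessing")
  mask
}

# Correspondence between atlas ROIs and coarse protocol labels for the
# registration Dice term: a ROI maps to the protocol structure whose name
# equals its tissue class. ROIs without a counterpart are left out.
protocol_map_from_names <- function(atlas, grouping, protocol) {
  cls <- vapply(as.character(atlas$labels$id),
                function(id) grouping$roi_to_class[[id]], character(1))
  pid <- protocol$id[match(cls, protocol$name)]
  stats::setNames(pid, atlas$labels$id)
}

# Group atlas ROI maps by their corresponding protocol label.
group_to_protocol <- function(atlas, protocol_map) {
  ids <- unique(protocol_map[!is.na(protocol_map)])
  maps <- lapply(ids, function(pid) {
    sel <- names(protocol_map)[!is.na(protocol_map) & protocol_map == pid]
    Reduce(`+`, lapply(as.integer(sel), function(l) atlas_dense_map(atlas, l)))
  })
  names(maps) <- as.character(ids)
  maps
}

# One-hot (argmax) version of the protocol-grouped maps, for the
# registration Dice term: both Dice operands are then binary at source and
# pass through identical anti-alias chains, so the term is maximized by
# alignment rather than by warp-induced sharpening of soft maps.
group_to_protocol_onehot <- function(atlas, protocol_map) {
  maps <- group_to_protocol(atlas, protocol_map)
  tot <- Reduce(`+`, maps)
  best <- array(0, dim(tot))
  arg <- array(0L, dim(tot))
  for (i in seq_along(maps)) {
    upd <- maps[[i]] > best
    arg[upd] <- i
    best[upd] <- maps[[i]][upd]
  }
  arg[tot <= 0.5] <- 0L
  out <- lapply(seq_along(maps), function(i) array(as.numeric(arg == i), dim(tot)))
  names(out) <- names(maps)
  out
}

#' Run the full fast-segmentation pipeline in memory
#'
#' Executes mask preprocessing, single-pass bias-field estimation, robust
#' intensity statistics and recipe-based contrast synthesis, affine
#' initialization, greedy multiscale diffeomorphic registration, EM over
#' grouped tissue classes at the working resolution, and redistribution of
#' class posteriors to fine ROIs.
#'
#' @param scan an `image_volume` of raw intensities.
#' @param coarse a [coarse_segmentation()].
#' @param atlas a [probabilistic_atlas()].
#' @param grouping a [label_grouping()] covering the atlas labels.
#' @param recipe an [intensity_recipe()] over protocol structure names.
#' @param opts a [segment_options()].
#' @param protocol_map optional named vector (ROI id -> protocol id)
#'   overriding the name-based correspondence used by the Dice term.
#' @param verbose print stage progress.
#' @return list with the per-stage products: `mask`, `bias_fit`,
#'   `corrected`, `stats`, `class_means`, `synthetic`, `affine_init`,
#'   `registration`, `em`, `fine_posteriors`, `hard_labels`, `volumes`,
#'   `working_geom`, `timings`, `opts`.
#' @export
run_segmentation <- function(scan, coarse, atlas, grouping, recipe,
                             opts = segment_options(), protocol_map = NULL,
                             verbose = FALSE) {
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(nm, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", nm, conditionMessage(e)), call. = FALSE))
    t_all[[nm]] <<- tic() - t0
    if (verbose) message(sprintf("stage %-14s %.1fs", nm, t_all[[nm]]))
    out
  }
  geom <- grid_geometry(scan)
  ageom <- atlas_geometry(atlas)
  if (opts$mode == "cerebrum") {
    drop <- atlas$labels$id[grepl("cerebell|brainstem", atlas$labels$class)]
    if (length(drop) && length(drop) < nrow(atlas$labels))
      atlas <- remove_and_inpaint(atlas, drop)
  }
  if (is.null(protocol_map))
    protocol_map <- protocol_map_from_names(atlas, grouping, coarse$protocol)

  mask <- stage("mask", preprocess_mask(coarse, geom, opts$smoothing_steps_HRmask))
  scan <- image_volume(scan$voxels, affine = scan$affine,
                       mask = mask & scan$voxels > 0)

  bias_fit <- NULL
  corrected <- scan
  if (!opts$skip_bf) {
    bias_fit <- stage("bias", {
      f <- max(1L, min(floor(2 / min(geom$voxel_size)), floor(min(geom$dim) / 64)))
      est_geom <- downsample_geometry(geom, f)
      lt <- log_transform(scan)
      lvf <- fill_from_mask(lt$voxels, lt$mask, iters = 8L)
      lv <- if (f > 1)
        resample_to_geometry(smooth_gaussian(lvf, rep(f / 2.355, 3)), geom, est_geom)
      else lvf
      mk <- resample_to_geometry(array(as.numeric(lt$mask), geom$dim), geom, est_geom) >= 0.5
      clab <- resample_nearest(coarse$labels, coarse_geometry(coarse), est_geom)
      p <- coarse$protocol
      bias_cls <- if ("bias_class" %in% names(p)) p$bias_class else p$name
      bias_names <- unique(bias_cls)
      grouped <- array(0L, est_geom$dim)
      for (i in seq_len(nrow(p)))
        grouped[clab == p$id[i]] <- match(bias_cls[i], bias_names)
      soft <- soft_segmentation(grouped, bias_names, sigma_mm = 0.5,
                                voxel_size = est_geom$voxel_size)
      basis <- build_basis(geom, opts$bf_mode, 6L)
      fit_bias_single_mstep(lv, soft, basis, mask = mk, est_geom = est_geom)
    })
    corrected <- stage("correct", correct_image(scan, bias_fit$model))
  }

  clab_hr <- resample_nearest(coarse$labels, coarse_geometry(coarse), geom)
  stats <- stage("stats", robust_stats(corrected$voxels, clab_hr, coarse$protocol,
                                       mask = corrected$mask))
  log_stats <- robust_stats(log(pmax(corrected$voxels, 1e-12)), clab_hr,
                            coarse$protocol, mask = corrected$mask)
  class_means <- stage("recipe", class_means_from_recipe(stats, recipe, grouping))

  synth <- stage("synthesis", {
    cm <- group_probabilities(atlas, grouping)
    v <- synthesize_volume(cm, class_means, ageom)
    match_resolution(v, geom$voxel_size)
  })

  aff <- stage("affine", {
    amaps <- group_to_protocol(atlas, protocol_map)
    affine_initialize(amaps, ageom, coarse$labels, coarse_geometry(coarse))
  })

  reg <- stage("registration", {
    amaps <- group_to_protocol_onehot(atlas, protocol_map)
    # Dice channels: the protocol's compact structures (protocol$dice),
    # defaulting to every structure
    dice_ids <- if ("dice" %in% names(coarse$protocol))
      coarse$protocol$id[coarse$protocol$dice] else coarse$protocol$id
    amaps <- amaps[names(amaps) %in% as.character(dice_ids)]
    dlab <- coarse$labels
    dlab[!(dlab %in% dice_ids)] <- 0L
    cfg <- registration_config(optimizer_lr = opts$optimizer_lr,
                               smooth_grad_sigma = opts$smooth_grad_sigma,
                               smooth_warp_sigma = opts$smooth_warp_sigma,
                               cc_kernel_size = opts$cc_kernel_size,
                               rel_weight_labeldiff = opts$rel_weight_labeldiff)
    run_multiscale_registration(corrected, synth, amaps, dlab,
                                coarse_geometry(coarse), pre_affine = aff$affine,
                                config = cfg, verbose = verbose)
  })

  wres <- if (opts$mode == "exvivo") min(0.2, min(geom$voxel_size)) else opts$resolution
  em <- stage("em", {
    wgeom <- regrid_geometry(geom, wres)
    if (all(wres <= geom$voxel_size + 1e-9)) {
      # upsampling to the working grid replicates voxel values (nearest
      # neighbour): trilinear interpolation would shrink within-tissue
      # variance and manufacture partial-volume mixtures that the
      # voxel-wise mixture model does not represent
      wv <- resample_nearest(corrected$voxels, geom, wgeom, fill = 0)
      wm <- resample_nearest(array(as.numeric(corrected$mask), geom$dim),
                             geom, wgeom, fill = 0) > 0.5
      wimg <- image_volume(array(as.numeric(wv), wgeom$dim), affine = wgeom$affine,
                           mask = wm)
    } else {
      wimg <- match_resolution(corrected, rep(wres, 3))
      if (!identical(wgeom$dim, grid_geometry(wimg)$dim)) wgeom <- grid_geometry(wimg)
    }
    lw <- log_transform(wimg)
    cmaps <- group_probabilities(atlas, grouping)
    priors <- resample_atlas(cmaps, reg$deformation, wgeom, ageom)
    tot <- Reduce(`+`, priors)
    wmask <- lw$mask & tot > 1e-4
    priors <- lapply(priors, function(m) ifelse(tot > 1e-4, m / pmax(tot, 1e-12), 0))
    init <- em_init_params(class_means, log_stats, recipe, grouping)
    fit <- fit_gmm_em(lw$voxels, priors, init, mask = wmask, skip = opts$skip)
    c(fit, list(geom = wgeom, mask = wmask, log_image = lw))
  })

  post <- stage("redistribute", {
    fine <- warp_atlas_sparse(atlas, reg$deformation, em$geom)
    redistribute_posteriors(em$resp, em$mask_idx, fine, grouping, em$geom$dim)
  })
  hard <- hard_segmentation(post, mask = em$mask)
  vols <- roi_volumes(post, em$geom$voxel_size, atlas$labels)

  list(mask = mask, bias_fit = bias_fit, corrected = corrected, stats = stats,
       class_means = class_means, synthetic = synth, affine_init = aff,
       registration = reg, em = em, fine_posteriors = post, hard_labels = hard,
       volumes = vols, working_geom = em$geom, timings = t_all, opts = opts)
}

# EM initialization: class means from the recipe (log domain), spreads from
# the reference structures' log-domain robust scales; multi-component
# classes split the mean by +/- 0.5 sd with equal weights.
em_init_params <- function(class_means, log_stats, recipe, grouping) {
  sds <- log_stats$sd[log_stats$usable]
  names(sds) <- log_stats$name[log_stats$usable]
  default_sd <- median(sds)
  comps <- lapply(grouping$classes, function(cl) {
    mu0 <- log(max(class_means[[cl]], 1e-12))
    r <- recipe$rules[[cl]]
    ok <- names(r) %in% names(sds)
    s0 <- if (any(ok)) sum(abs(r[ok]) * sds[names(r)[ok]]) / sum(abs(r[ok])) else default_sd
    s0 <- max(s0, 1e-4)
    m <- grouping$components_per_class[[cl]]
    if (m == 1L) list(w = 1, mu = mu0, sigma = s0)
    else {
      off <- seq(-0.5, 0.5, length.out = m) * s0
      list(w = rep(1 / m, m), mu = mu0 + off, sigma = rep(s0, m))
    }
  })
  names(comps) <- grouping$classes
  gaussian_params(comps)
}

#' Segment a scan from files
#'
#' File-level wrapper around [run_segmentation()]: reads the scan, coarse
#' segmentation, atlas directory and YAML configuration, runs the pipeline
#' and writes the outputs (hard segmentation at working and input
#' resolution, soft ROI volumes CSV, optional bias-corrected scan, RGB
#' posterior composite, registered atlas label map, deformation field and
#' log10 Jacobian) together with a machine-readable run manifest.
#'
#' @param scan_path input image (NIfTI).
#' @param coarse_path coarse segmentation (NIfTI, labels per protocol CSV).
#' @param atlas_path atlas directory (see [save_atlas()]).
#' @param out_dir output directory.
#' @param yaml_path directory with the grouping/components/recipe YAML
#'   files (defaults to the package's bundled configuration).
#' @param protocol data.frame describing the coarse labels, or path to a
#'   CSV with columns `id,name` (optional `bias_class`, `is_brain`,
#'   `dice`); defaults to `<dirname(coarse_path)>/protocol.csv`. If a
#'   `protocol_map.csv` (columns `label_id,protocol_id`) sits next to it,
#'   it supplies the atlas-ROI to protocol-structure correspondence;
#'   otherwise ROIs map to the protocol structure named after their
#'   tissue class.
#' @param opts a [segment_options()].
#' @param verbose print stage progress.
#' @return the [run_segmentation()] result, invisibly.
#' @export
segment <- function(scan_path, coarse_path, atlas_path, out_dir,
                    yaml_path = NULL, protocol = NULL,
                    opts = segment_options(), verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  scan <- read_volume(scan_path)
  cvol <- read_volume(coarse_path)
  if (is.null(protocol))
    protocol <- file.path(dirname(coarse_path), "protocol.csv")
  protocol_map <- NULL
  if (is.character(protocol)) {
    pm_path <- file.path(dirname(protocol), "protocol_map.csv")
    if (file.exists(pm_path)) {
      pm <- read.csv(pm_path)
      protocol_map <- stats::setNames(as.integer(pm$protocol_id), pm$label_id)
    }
    protocol <- read.csv(protocol, stringsAsFactors = FALSE)
  }
  coarse <- coarse_segmentation(array(as.integer(round(cvol$voxels)), dim(cvol$voxels)),
                                cvol$affine, protocol)
  atlas <- load_atlas(atlas_path)
  if (is.null(yaml_path))
    yaml_path <- system.file("extdata", "config", package = "histoseg")
  grouping <- read_grouping(yaml_path)
  recipe <- read_recipe(yaml_path)
  res <- run_segmentation(scan, coarse, atlas, grouping, recipe, opts,
                          protocol_map = protocol_map, verbose = verbose)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wg <- res$working_geom
  write_volume(image_volume(array(as.numeric(res$hard_labels), wg$dim),
                            affine = wg$affine),
               file.path(out_dir, "seg.nii.gz"), datatype = "int16")
  hard_in <- resample_nearest(res$hard_labels, wg, grid_geometry(scan))
  write_volume(image_volume(array(as.numeric(hard_in), dim(scan$voxels)),
                            affine = scan$affine),
               file.path(out_dir, "seg_inputres.nii.gz"), datatype = "int16")
  write.csv(res$volumes, file.path(out_dir, "volumes.csv"), row.names = FALSE)
  if (opts$write_bias_corrected && !is.null(res$bias_fit))
    write_volume(res$corrected, file.path(out_dir, "bias_corrected.nii.gz"))
  if (opts$write_rgb) {
    for (ch in 1:3) {
      out <- array(0, wg$dim)
      for (w in res$fine_posteriors) {
        rr <- atlas$labels[match(w$label_id, atlas$labels$id), c("R", "G", "B")]
        out <- box_add(out, w, w$values * as.numeric(rr[[ch]]))
      }
      write_volume(image_volume(out, affine = wg$affine),
                   file.path(out_dir, sprintf("posteriors_rgb_%d.nii.gz", ch)))
    }
  }
  if (opts$save_field) {
    u <- res$registration$deformation$disp
    for (i in 1:3)
      write_volume(image_volume(u[, , , i], affine = grid_geometry(scan)$affine),
                   file.path(out_dir, sprintf("field_%s.nii.gz", c("x", "y", "z")[i])))
  }
  if (opts$save_jacobian)
    write_volume(jacobian_map(res$registration$deformation, log10 = TRUE),
                 file.path(out_dir, "jacobian_log10.nii.gz"))
  if (opts$save_atlas_nonlinear_reg) {
    warped <- warp_atlas_sparse(atlas, res$registration$deformation, wg)
    hardat <- hard_segmentation(warped)
    write_volume(image_volume(array(as.numeric(hardat), wg$dim), affine = wg$affine),
                 file.path(out_dir, "atlas_nonlinear_reg.nii.gz"), datatype = "int16")
  }
  manifest <- list(
    version = as.character(utils::packageVersion("histoseg")),
    seed = res$opts$seed,
    options = res$opts[setdiff(names(res$opts), NULL)],
    stage_seconds = res$timings,
    total_seconds = proc.time()[["elapsed"]] - t0,
    inputs = list(scan = scan_path, coarse = coarse_path, atlas = atlas_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
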