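#' Generate a phantom probabilistic atlas
#'
#' Builds a brain-like phantom atlas inside an ellipsoidal "brain" with
#' three kinds of anatomy, mirroring the spatial statistics that make
#' atlas-based segmentation of real brains well-posed:
#'
#' * a fine, wavy "fold" texture (a thresholded smooth random field) of a
#'   gray-matter-like tissue class, interleaved everywhere with the
#'   white-matter-like matrix — tissue contrast at a spatial scale finer
#'   than any low-order bias-field basis can represent;
#' * the matrix partitioned into a few compact Voronoi "cells" (the large
#'   regions whose segmentation accuracy is worth measuring);
#' * many small spherical "nuclei" of darker/brighter classes.
#'
#' Fold pieces and nuclei are individual ROIs as well, so the atlas has
#' hundreds of sparse, locally-supported regions. Probability maps are
#' sharp (roughly one-voxel partial-volume transitions after a light
#' Gaussian smoothing), softmax-style normalized with an implicit
#' background margin at the brain edge. The result also carries a coarse
#' "protocol": one structure per matrix cell plus one per remaining tissue
#' class, the analogue of the whole-brain structures a neural
#' coarse-segmentation model provides (used for bias estimation, intensity
#' recipes and registration guidance). Regeneration from the same seed is
#' bit-identical.
#'
#' @param seed integer RNG seed.
#' @param grid_shape length-3 grid (default 64^3, minimum 32 per axis).
#' @param n_rois approximate total number of ROIs (default 200; the exact
#'   count adapts to seed geometry).
#' @param n_classes number of tissue classes (>= 2; default 4: gray-like
#'   folds, white-like matrix, then nucleus classes).
#' @param voxel_size isotropic spacing in mm (default 1, an in-vivo-like
#'   scan resolution).
#' @return list with `atlas` (a [probabilistic_atlas()]), `grouping`
#'   (a [label_grouping()]), `protocol` (data.frame `id`, `name`, `class`,
#'   `bias_class`, `is_brain`) and `roi_to_protocol` (named vector,
#'   ROI label id -> protocol id).
#' @export
make_phantom_atlas <- function(seed, grid_shape = c(64L, 64L, 64L),
                               n_rois = 200L, n_classes = 4L, voxel_size = 1.0) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  stopifnot(all(grid_shape >= 32L), n_classes >= 1L, n_rois >= n_classes)
  if (n_rois == 1L) return(single_roi_phantom(seed, grid_shape, voxel_size))
  n_cell <- max(2L, min(10L, round(0.05 * n_rois)))
  n_nuc_want <- if (n_classes > 2L) max(n_classes - 2L, round(0.23 * n_rois)) else 0L
  n_fold <- max(2L, n_rois - n_cell - n_nuc_want)
  with_seed(seed, {
    d <- grid_shape
    g <- grid_coords(d)
    ctr <- (d - 1) / 2
    semi <- c(0.42, 0.38, 0.34) * d
    e <- sqrt(((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
                ((g$z - ctr[3]) / semi[3])^2)
    brain <- e <= 1
    # gyral fold texture: thresholded smooth random field
    fld <- smooth_gaussian(array(rnorm(prod(d)), d), rep(1.8, 3))
    thr <- quantile(fld[brain], 1 - 0.32, names = FALSE)
    folds <- brain & fld > thr
    matrixm <- brain & !folds
    seed_in <- function(n, spread) {
      s <- matrix(0, n, 3)
      got <- 0L
      while (got < n) {
        p <- runif(3) * 2 - 1
        if (sum(p^2) <= 1) { got <- got + 1L; s[got, ] <- ctr + spread * p * semi }
      }
      s
    }
    r_ball <- 2.0
    nseeds <- matrix(0, n_nuc_want, 3)
    got <- 0L; tries <- 0L
    while (got < n_nuc_want && tries < 2e5) {
      tries <- tries + 1L
      p <- runif(3) * 2 - 1
      if (sum(p^2) > 1) next
      s <- ctr + 0.72 * p * semi
      i <- pmin(pmax(round(s) + 1, 1), d)
      if (!matrixm[i[1], i[2], i[3]]) next
      if (got > 0 && min(sqrt(rowSums(sweep(nseeds[seq_len(got), , drop = FALSE], 2, s)^2))) <
            2 * r_ball + 3) next
      got <- got + 1L
      nseeds[got, ] <- s
    }
    n_nuc <- got
    cseeds <- seed_in(n_cell, 0.8)
    sseeds <- seed_in(n_fold, 0.9)
    vor_id <- function(S) {
      best <- array(Inf, d); id <- array(1L, d)
      for (k in seq_len(nrow(S))) {
        dk <- array((g$x - S[k, 1])^2 + (g$y - S[k, 2])^2 + (g$z - S[k, 3])^2, d)
        upd <- dk < best
        id[upd] <- k
        best[upd] <- dk[upd]
      }
      id
    }
    cellid <- vor_id(cseeds)
    foldid <- vor_id(sseeds)
    # nuclei: sharp sigmoid balls, carved out of the underlying tissue
    nuc_sum <- array(0, d)
    nuc_rois <- list()
    for (k in seq_len(n_nuc)) {
      lo <- pmax(floor(nseeds[k, ] - r_ball - 3), 0)
      hi <- pmin(ceiling(nseeds[k, ] + r_ball + 3) + 1, d)
      idx <- lapply(1:3, function(ax) (lo[ax] + 1):hi[ax])
      gx <- idx[[1]] - 1; gy <- idx[[2]] - 1; gz <- idx[[3]] - 1
      dk <- sqrt(outer(outer((gx - nseeds[k, 1])^2, (gy - nseeds[k, 2])^2, `+`),
                       (gz - nseeds[k, 3])^2, `+`))
      p <- stats::plogis((r_ball - dk) / 0.12)
      nuc_rois[[k]] <- list(lo = as.integer(lo), hi = as.integer(hi), values = p)
      nuc_sum[idx[[1]], idx[[2]], idx[[3]]] <-
        nuc_sum[idx[[1]], idx[[2]], idx[[3]]] + p
    }
    rem <- pmax(1 - nuc_sum, 0)
    maps <- list()
    cls <- integer(0)
    kind <- character(0)
    for (k in seq_len(n_fold)) {
      m <- array(as.numeric(folds) * (foldid == k), d) * rem
      if (sum(m) < 5) next
      maps[[length(maps) + 1L]] <- m; cls <- c(cls, 1L); kind <- c(kind, "fold")
    }
    for (k in seq_len(n_cell)) {
      m <- array(as.numeric(matrixm) * (cellid == k), d) * rem
      maps[[length(maps) + 1L]] <- m
      cls <- c(cls, if (n_classes >= 2L) 2L else 1L)
      kind <- c(kind, "cell")
    }
    if (n_nuc > 0) {
      nuc_cls <- 2L + rep_len(seq_len(max(n_classes - 2L, 1L)), n_nuc)[sample(n_nuc)]
      for (k in seq_len(n_nuc)) {
        m <- array(0, d)
        r <- nuc_rois[[k]]
        m[(r$lo[1] + 1):r$hi[1], (r$lo[2] + 1):r$hi[2], (r$lo[3] + 1):r$hi[3]] <- r$values
        m <- m * as.numeric(brain)
        maps[[length(maps) + 1L]] <- m; cls <- c(cls, nuc_cls[k]); kind <- c(kind, "nucleus")
      }
    }
    maps <- lapply(maps, function(m) {
      m <- smooth_gaussian(m, rep(0.3, 3))
      m[m < 1e-4] <- 0
      m
    })
    tot <- Reduce(`+`, maps)
    over <- tot > 1
    if (any(over)) {
      sc <- ifelse(over, 1 / tot, 1)
      maps <- lapply(maps, function(m) m * sc)
    }
    n <- length(maps)
    class_names <- sprintf("class_%02d", seq_len(n_classes))
    labels <- data.frame(id = seq_len(n),
                         name = sprintf("%s_%03d", kind, seq_len(n)),
                         R = sample(0:255, n, replace = TRUE),
                         G = sample(0:255, n, replace = TRUE),
                         B = sample(0:255, n, replace = TRUE),
                         class = class_names[cls])
    rois <- lapply(seq_len(n), function(k)
      list(label_id = k, lo = c(0L, 0L, 0L), hi = d, values = maps[[k]]))
    A <- diag(c(rep(voxel_size, 3), 1))
    A[1:3, 4] <- -ctr * voxel_size
    atlas <- probabilistic_atlas(d, A, voxel_size, labels, rois)
    grouping <- label_grouping(class_names,
                               stats::setNames(as.list(labels$class), labels$id))
    # coarse protocol: one structure per matrix cell, one per other class
    cell_ids <- which(kind == "cell")
    proto_names <- c(class_names[1],
                     sprintf("cell_%02d", seq_along(cell_ids)),
                     if (n_classes > 2L) class_names[3:n_classes])
    proto_class <- c(class_names[1],
                     rep(class_names[min(2L, n_classes)], length(cell_ids)),
                     if (n_classes > 2L) class_names[3:n_classes])
    # only the compact whole structures guide the registration Dice term;
    # the dispersed fold texture and scattered micro-nuclei are matched by
    # the intensity term instead
    protocol <- data.frame(id = seq_along(proto_names), name = proto_names,
                           class = proto_class, bias_class = proto_class,
                           is_brain = TRUE,
                           dice = grepl("^cell_", proto_names))
    roi_to_protocol <- integer(n)
    roi_to_protocol[kind == "fold"] <- 1L
    roi_to_protocol[cell_ids] <- 1L + seq_along(cell_ids)
    if (n_classes > 2L)
      roi_to_protocol[kind == "nucleus"] <-
        1L + length(cell_ids) + (cls[kind == "nucleus"] - 2L)
    names(roi_to_protocol) <- labels$id
    list(atlas = atlas, grouping = grouping, protocol = protocol,
         roi_to_protocol = roi_to_protocol)
  })
}

#' Sample a phantom image from the generative model
#'
#' Draws a scan from the full forward model: the atlas is deformed by a
#' known smooth displacement (white-noise vector fields smoothed with
#' sigma = 8 voxels and scaled to a requested maximum), per-voxel labels
#' are sampled from the deformed categorical prior, log-intensities from
#' the labels' class Gaussians, a known zero-DC smooth bias field is added
#' in the log domain, and the result exponentiated. The generated
#' deformation is verified to be diffeomorphic before sampling.
#'
#' @param phantom output of [make_phantom_atlas()].
#' @param seed integer RNG seed.
#' @param class_means per-class mean intensities (default: 110 for the
#'   gray-like fold class, 170 for the white-like matrix, then 80/230/...
#'   for nucleus classes).
#' @param sigma_log per-class log-intensity standard deviation (default 0.08).
#' @param bias_order per-axis DCT order of the true bias (default 2).
#' @param bias_amplitude maximum absolute log-bias inside the brain
#'   (default 0.5, a strong shading typical of ex vivo or surface-coil
#'   acquisitions; 0 disables the bias).
#' @param max_disp maximum displacement in voxels (default 6; 0 disables).
#' @return list with `image` (an `image_volume`, mask = sampled foreground)
#'   and `truth` (the phantom plus true parameters, bias model, deformation,
#'   label volume, seed).
#' @export
sample_image <- function(phantom, seed, class_means = NULL, sigma_log = 0.08,
                         bias_order = 2L, bias_amplitude = 0.5, max_disp = 6) {
  atlas <- phantom$atlas
  grouping <- phantom$grouping
  geom <- atlas_geometry(atlas)
  nc <- length(grouping$classes)
  if (is.null(class_means))
    class_means <- c(110, 170, 80, 230, 60, 250, 100, 210)[seq_len(nc)]
  params <- gaussian_params(stats::setNames(lapply(seq_len(nc), function(ci)
    list(w = 1, mu = log(class_means[ci]), sigma = sigma_log)), grouping$classes))
  with_seed(seed, {
    d <- geom$dim
    u <- array(0, c(d, 3L))
    if (max_disp > 0) {
      for (i in 1:3) u[, , , i] <- smooth_gaussian(array(rnorm(prod(d)), d), rep(8, 3))
      nrm <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      u <- u * (max_disp / max(nrm))
    }
    def <- deformation(diag(4), u, geom)
    jac <- jacobian_map(def)
    if (min(jac$voxels) <= 0)
      stop("requested deformation is not diffeomorphic (nonpositive Jacobian)")
    warped <- warp_atlas_sparse(atlas, def, geom)
    # categorical label sampling (0 = background), sparse accumulation
    r <- array(runif(prod(d)), d)
    lab <- array(0L, d)
    cum <- array(0, d)
    for (w in warped) {
      sl <- box_slice(w)
      cumb <- box_get(cum, w) + w$values
      hit <- box_get(lab, w) == 0L & box_get(r, w) < cumb
      labb <- box_get(lab, w)
      labb[hit] <- w$label_id
      lab[sl$i1, sl$i2, sl$i3] <- labb
      cum[sl$i1, sl$i2, sl$i3] <- cumb
    }
    basis <- build_basis(geom, "dct", bias_order)
    coef <- rnorm(basis$n_basis)
    coef[1] <- 0   # frequency (0,0,0): the overall gain is not identifiable
    if (bias_amplitude > 0) {
      bias_model <- bias_field_model(basis, coef)
      b <- eval_bias_field(bias_model)
      sc <- bias_amplitude / max(abs(b[lab > 0]))
      bias_model <- bias_field_model(basis, coef * sc)
      b <- b * sc
    } else {
      bias_model <- bias_field_model(basis, coef * 0)
      b <- array(0, d)
    }
    cls_of <- integer(nrow(atlas$labels))
    cls_of[atlas$labels$id] <- match(atlas$labels$class, grouping$classes)
    logi <- array(0, d)
    fg <- lab > 0L
    ci <- cls_of[lab[fg]]
    mu <- vapply(params$components, `[[`, numeric(1), "mu")
    logi[fg] <- mu[ci] + rnorm(sum(fg), 0, sigma_log) + b[fg]
    img <- array(0, d)
    img[fg] <- exp(logi[fg])
    image <- image_volume(img, affine = geom$affine, mask = fg)
    list(image = image,
         truth = c(phantom,
                   list(params = params, bias = bias_model, deformation = def,
                        labels = lab, seed = seed)))
  })
}

#' Degrade the true labels into a coarse segmentation
#'
#' Projects the true fine labels to the phantom's coarse protocol, smooths
#' the projection with a 3x3x3 majority filter (a neural
#' coarse-segmentation model produces smooth boundaries, not the
#' voxel-wise sampling speckle of the generative model), downsamples to
#' roughly the requested coarse resolution, and flips boundary voxels to a
#' random differing 6-neighbour label at the given rate. Deterministic per
#' seed.
#'
#' @param truth the `truth` element of [sample_image()].
#' @param error_rate fraction of boundary voxels to corrupt (in `[0, 0.3]`).
#' @param seed integer RNG seed.
#' @param target_mm nominal coarse resolution (default 1 mm).
#' @return a [coarse_segmentation()] following the phantom protocol.
#' @export
corrupt_coarse_segmentation <- function(truth, error_rate = 0.05, seed = 1L,
                                        target_mm = 1.0) {
  stopifnot(error_rate >= 0, error_rate <= 0.3)
  atlas <- truth$atlas
  geom <- atlas_geometry(atlas)
  r2p <- integer(max(atlas$labels$id))
  r2p[as.integer(names(truth$roi_to_protocol))] <- truth$roi_to_protocol
  proto <- array(0L, geom$dim)
  fg <- truth$labels > 0L
  proto[fg] <- r2p[truth$labels[fg]]
  proto <- majority_filter(proto, n_labels = nrow(truth$protocol))
  f <- max(1L, round(target_mm / min(geom$voxel_size)))
  cg <- if (f > 1) downsample_geometry(geom, f) else geom
  lab <- if (f > 1) resample_nearest(proto, geom, cg) else proto
  with_seed(seed, {
    if (error_rate > 0) {
      d <- dim(lab)
      differs <- array(FALSE, d)
      nb <- list()
      shift <- function(a, ax, by) {
        idx <- rep(list(quote(expr = )), 3L)
        n <- dim(a)[ax]
        sel <- if (by > 0) c(seq_len(n)[-1], n) else c(1L, seq_len(n)[-n])
        idx[[ax]] <- sel
        do.call(`[`, c(list(a), idx))
      }
      for (ax in 1:3) for (by in c(-1L, 1L)) {
        s <- shift(lab, ax, by)
        nb[[length(nb) + 1L]] <- s
        differs <- differs | (s != lab)
      }
      boundary <- which(differs & lab > 0L)
      flip <- boundary[runif(length(boundary)) < error_rate]
      if (length(flip)) {
        pick <- sample.int(6L, length(flip), replace = TRUE)
        for (i in seq_along(flip)) {
          cand <- vapply(nb, function(s) s[flip[i]], integer(1))
          cand <- cand[cand != lab[flip[i]]]
          lab[flip[i]] <- cand[1L + (pick[i] - 1L) %% length(cand)]
        }
      }
    }
    coarse_segmentation(lab, cg$affine, truth$protocol)
  })
}

#' Write a complete phantom test fixture to disk
#'
#' Emits an atlas directory, the sampled scan and coarse segmentation as
#' NIfTI, the protocol CSV, the grouping/components/recipe YAML files and
#' a JSON record of the ground truth (seed, class parameters, bias
#' coefficients).
#'
#' @param dir output directory.
#' @param seed integer RNG seed driving the whole fixture.
#' @param ... passed to [make_phantom_atlas()].
#' @return `dir`, invisibly.
#' @export
write_phantom_fixture <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- make_phantom_atlas(seed, ...)
  sam <- sample_image(ph, seed + 1L)
  coarse <- corrupt_coarse_segmentation(sam$truth, seed = seed + 2L)
  save_atlas(ph$atlas, file.path(dir, "atlas"))
  write_volume(sam$image, file.path(dir, "scan.nii.gz"))
  write_volume(image_volume(array(as.numeric(coarse$labels), dim(coarse$labels)),
                            affine = coarse$affine),
               file.path(dir, "coarse_seg.nii.gz"), datatype = "int16")
  write.csv(ph$protocol, file.path(dir, "protocol.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(label_id = as.integer(names(ph$roi_to_protocol)),
                       protocol_id = as.integer(ph$roi_to_protocol)),
            file.path(dir, "protocol_map.csv"), row.names = FALSE, quote = FALSE)
  ycfg <- file.path(dir, "config")
  write_grouping(ph$grouping, ycfg)
  write_recipe(phantom_recipe(ph), ycfg)
  mu <- vapply(sam$truth$params$components, `[[`, numeric(1), "mu")
  jsonlite::write_json(
    list(seed = seed, class_log_means = as.numeric(mu),
         sigma_log = as.numeric(vapply(sam$truth$params$components, `[[`,
                                       numeric(1), "sigma")),
         bias_coefficients = sam$truth$bias$coefficients,
         max_displacement = max(sqrt(rowSums(matrix(sam$truth$deformation$disp,
                                                    ncol = 3)^2)))),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

# Degenerate single-ROI phantom: one region covering the whole (smoothed)
# brain indicator.
single_roi_phantom <- function(seed, grid_shape, voxel_size) {
  with_seed(seed, {
    d <- grid_shape
    g <- grid_coords(d)
    ctr <- (d - 1) / 2
    semi <- c(0.42, 0.38, 0.34) * d
    e <- sqrt(((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
                ((g$z - ctr[3]) / semi[3])^2)
    m <- smooth_gaussian(array(as.numeric(e <= 1), d), rep(1.5, 3))
    m <- pmin(m, 1); m[m < 1e-4] <- 0
    labels <- data.frame(id = 1L, name = "brain", R = 128L, G = 128L, B = 128L,
                         class = "class_01")
    atlas <- probabilistic_atlas(d, {
      A <- diag(c(rep(voxel_size, 3), 1)); A[1:3, 4] <- -ctr * voxel_size; A
    }, voxel_size, labels,
    list(list(label_id = 1L, lo = c(0L, 0L, 0L), hi = d, values = m)))
    grouping <- label_grouping("class_01", list(`1` = "class_01"))
    protocol <- data.frame(id = 1L, name = "class_01", class = "class_01",
                           bias_class = "class_01", is_brain = TRUE, dice = TRUE)
    list(atlas = atlas, grouping = grouping, protocol = protocol,
         roi_to_protocol = stats::setNames(1L, "1"))
  })
}

# 3x3x3 majority (mode) filter over labels 0..n_labels; ties go to the
# lowest label.
majority_filter <- function(lab, n_labels) {
  counts <- lapply(0:n_labels, function(l)
    box_filter(array(as.numeric(lab == l), dim(lab)), 3L, normalize = FALSE))
  best <- counts[[1]]
  out <- array(0L, dim(lab))
  for (l in seq_len(n_labels)) {
    upd <- counts[[l + 1]] > best
    out[upd] <- l
    best[upd] <- counts[[l + 1]][upd]
  }
  out
}

# Recipe for a phantom: each tissue class averages the medians of the
# protocol structures belonging to it.
phantom_recipe <- function(phantom) {
  grouping <- phantom$grouping
  protocol <- phantom$protocol
  rules <- lapply(grouping$classes, function(cl) {
    nm <- protocol$name[protocol$class == cl]
    if (length(nm) == 0L) nm <- protocol$name[1L]
    stats::setNames(rep(1 / length(nm), length(nm)), nm)
  })
  intensity_recipe(stats::setNames(rules, grouping$classes))
}
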