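#' Probabilistic atlas with sparse per-ROI storage
#'
#' The atlas stores, for every region of interest (ROI), a dense probability
#' sub-array inside a tight bounding box on a common grid. Background is
#' implicit: at each voxel the ROI probabilities sum to at most one and the
#' residual is background. Probabilities are held at float32 precision, the
#' on-disk storage precision, so save/load round-trips are bit-exact.
#'
#' @param grid_shape length-3 integer grid shape.
#' @param affine 4x4 voxel-to-world matrix (RAS, mm).
#' @param resolution nominal isotropic resolution in mm.
#' @param labels data.frame with columns `id,name,R,G,B,class`.
#' @param rois list of `list(label_id, lo, hi, values)` with `lo`/`hi`
#'   0-based half-open box bounds and `values` the probability sub-array.
#' @return an object of class `probabilistic_atlas`.
#' @export
probabilistic_atlas <- function(grid_shape, affine, resolution, labels, rois) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, nrow(labels) == length(rois))
  need <- c("id", "name", "R", "G", "B", "class")
  if (!all(need %in% names(labels))) stop("label table must have columns id,name,R,G,B,class")
  if (anyDuplicated(labels$id)) stop("label ids must be unique")
  if (any(labels$id < 1)) stop("label ids must be >= 1")
  rois <- lapply(rois, function(r) {
    v <- r$values
    if (min(v) < -1e-7 || max(v) > 1 + 1e-6)
      stop("probabilities outside [0, 1]")
    v[] <- pmin(pmax(as_float32(v), 0), 1)
    tighten_roi(list(label_id = as.integer(r$label_id),
                     lo = as.integer(r$lo), hi = as.integer(r$hi),
                     values = v), grid_shape)
  })
  ids <- vapply(rois, `[[`, integer(1), "label_id")
  if (!setequal(ids, labels$id)) stop("ROI list and label table disagree")
  rois <- rois[order(ids)]
  labels <- labels[order(labels$id), , drop = FALSE]
  rownames(labels) <- NULL
  atl <- structure(list(grid_shape = grid_shape, affine = as.matrix(affine),
                        resolution = resolution, labels = labels, rois = rois),
                   class = "probabilistic_atlas")
  s <- atlas_foreground(atl)
  if (max(s) > 1 + 1e-6) stop("per-voxel ROI probabilities sum above 1")
  atl
}

# Shrink a box to the nonzero extent of its values (empty ROI keeps a
# degenerate 1-voxel box at the origin of its old box).
tighten_roi <- function(r, grid_shape) {
  v <- r$values
  stopifnot(all(dim(v) == r$hi - r$lo), all(r$lo >= 0), all(r$hi <= grid_shape))
  nz <- which(v != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    r$hi <- r$lo + 1L
    r$values <- array(0, c(1L, 1L, 1L))
    return(r)
  }
  lo1 <- apply(nz, 2, min) - 1L
  hi1 <- apply(nz, 2, max)
  r$values <- v[(lo1[1] + 1):hi1[1], (lo1[2] + 1):hi1[2], (lo1[3] + 1):hi1[3], drop = FALSE]
  dim(r$values) <- hi1 - lo1
  r$lo <- r$lo + as.integer(lo1)
  r$hi <- r$lo + as.integer(hi1 - lo1)
  r
}

#' @export
print.probabilistic_atlas <- function(x, ...) {
  cat(sprintf("<probabilistic_atlas> %d ROIs on %s grid @ %.3g mm\n",
              nrow(x$labels), paste(x$grid_shape, collapse = "x"), x$resolution))
  invisible(x)
}

atlas_geometry <- function(atlas) {
  list(dim = atlas$grid_shape, affine = atlas$affine,
       voxel_size = sqrt(colSums(atlas$affine[1:3, 1:3]^2)))
}

# Dense full-grid probability map of one ROI.
atlas_dense_map <- function(atlas, label_id) {
  out <- array(0, atlas$grid_shape)
  r <- atlas$rois[[match(label_id, atlas$labels$id)]]
  if (any(r$values != 0)) out <- box_add(out, r, r$values)
  out
}

# Per-voxel sum of all ROI probabilities (foreground probability).
atlas_foreground <- function(atlas) {
  out <- array(0, atlas$grid_shape)
  for (r in atlas$rois) {
    if (all(r$values == 0)) next
    out <- box_add(out, r, r$values)
  }
  out
}

#' Save a probabilistic atlas to a directory
#'
#' Writes `labels.csv` (`id,name,R,G,B,class`), `atlas.json` (grid shape,
#' affine, resolution) and, per ROI, a gzip-compressed NIfTI probability
#' sub-volume `roi_<id>.nii.gz` with a JSON sidecar `roi_<id>.json` holding
#' the 0-based half-open bounding box.
#'
#' @param atlas a `probabilistic_atlas`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_atlas <- function(atlas, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(atlas$labels, file.path(path, "labels.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(grid_shape = atlas$grid_shape,
         affine = as.numeric(atlas$affine),  # column-major flat 16-vector
         resolution = atlas$resolution),
    file.path(path, "atlas.json"), digits = NA)
  for (r in atlas$rois) {
    stem <- sprintf("roi_%04d", r$label_id)
    write_volume(image_volume(r$values, affine = diag(4)),
                 file.path(path, paste0(stem, ".nii.gz")))
    jsonlite::write_json(list(label_id = r$label_id, lo = r$lo, hi = r$hi),
                         file.path(path, paste0(stem, ".json")), digits = NA)
  }
  invisible(path)
}

#' Load a probabilistic atlas from a directory
#'
#' Inverse of [save_atlas()]. Bounding boxes are re-tightened to the minimal
#' nonzero extent on load; probabilities are validated to lie in `[0, 1]`
#' and to sum to at most one per voxel.
#'
#' @param path atlas directory.
#' @return a `probabilistic_atlas`.
#' @export
load_atlas <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "atlas.json"), simplifyVector = TRUE)
  labels <- read.csv(file.path(path, "labels.csv"), stringsAsFactors = FALSE)
  rois <- lapply(labels$id, function(id) {
    stem <- file.path(path, sprintf("roi_%04d", id))
    sidecar <- paste0(stem, ".json")
    if (!file.exists(sidecar)) stop(sprintf("missing box sidecar for ROI %d", id))
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vol <- RNifti::readNifti(paste0(stem, ".nii.gz"))
    v <- array(as.numeric(vol), dim(vol)[1:3])
    if (min(v) < 0 || max(v) > 1) stop(sprintf("ROI %d probabilities outside [0, 1]", id))
    list(label_id = side$label_id, lo = as.integer(side$lo),
         hi = as.integer(side$hi), values = v)
  })
  probabilistic_atlas(as.integer(meta$grid_shape), matrix(unlist(meta$affine), 4, 4),
                      meta$resolution, labels, rois)
}

#' Remove ROIs and inpaint their probability mass
#'
#' Deletes the given labels. At every voxel where removed ROIs carried mass,
#' that mass is reassigned to the surviving ROI that is the modal (argmax)
#' label of the nearest voxel (Euclidean distance on the atlas grid) whose
#' modal label survives; distance ties go to the lowest surviving label id.
#' Per-voxel total probability mass is conserved.
#'
#' @param atlas a `probabilistic_atlas`.
#' @param removed integer vector of label ids to remove.
#' @return a `probabilistic_atlas` without the removed ROIs.
#' @export
remove_and_inpaint <- function(atlas, removed) {
  removed <- as.integer(removed)
  if (!all(removed %in% atlas$labels$id)) stop("removed ids not all present in atlas")
  survivors <- setdiff(atlas$labels$id, removed)
  if (length(survivors) == 0L) stop("cannot remove every ROI")

  # modal label per voxel (0 where no ROI has mass)
  best <- array(0, atlas$grid_shape)
  mode_lab <- array(0L, atlas$grid_shape)
  for (id in atlas$labels$id) {
    m <- atlas_dense_map(atlas, id)
    upd <- m > best
    mode_lab[upd] <- id
    best[upd] <- m[upd]
  }
  removed_mass <- array(0, atlas$grid_shape)
  for (id in removed) removed_mass <- removed_mass + atlas_dense_map(atlas, id)

  donor <- array(NA_integer_, atlas$grid_shape)
  if (any(removed_mass > 0)) {
    bestd <- array(Inf, atlas$grid_shape)
    found <- FALSE
    for (id in sort(survivors)) {
      sites <- mode_lab == id
      if (!any(sites)) next
      found <- TRUE
      d2 <- array(edt3_cpp(as.logical(sites), atlas$grid_shape), atlas$grid_shape)
      upd <- d2 < bestd   # strict: earlier (lower) ids win ties
      donor[upd] <- id
      bestd[upd] <- d2[upd]
    }
    if (!found) stop("no surviving voxel with a surviving modal label")
  }

  keep <- atlas$labels$id %in% survivors
  labels <- atlas$labels[keep, , drop = FALSE]
  rois <- lapply(survivors, function(id) {
    m <- atlas_dense_map(atlas, id)
    sel <- removed_mass > 0 & donor == id
    if (any(sel)) m[sel] <- m[sel] + removed_mass[sel]
    list(label_id = id, lo = c(0L, 0L, 0L), hi = atlas$grid_shape, values = m)
  })
  probabilistic_atlas(atlas$grid_shape, atlas$affine, atlas$resolution, labels, rois)
}

#' Group ROI probabilities into tissue-class maps
#'
#' Sums the ROI probability maps of each tissue class, giving per-class
#' prior maps on the atlas grid.
#'
#' @param atlas a `probabilistic_atlas`.
#' @param grouping a [label_grouping()] covering every atlas label.
#' @return named list of dense 3D class probability maps.
#' @export
group_probabilities <- function(atlas, grouping) {
  miss <- setdiff(atlas$labels$id, as.integer(names(grouping$roi_to_class)))
  if (length(miss)) stop(sprintf("labels without a tissue class: %s", paste(miss, collapse = ", ")))
  maps <- lapply(grouping$classes, function(cl) array(0, atlas$grid_shape))
  names(maps) <- grouping$classes
  for (r in atlas$rois) {
    cl <- grouping$roi_to_class[[as.character(r$label_id)]]
    if (all(r$values == 0)) next
    maps[[cl]] <- box_add(maps[[cl]], r, r$values)
  }
  maps
}

#' Resample probability maps through a deformation
#'
#' Warps atlas probability maps onto a target grid by trilinear
#' interpolation at deformed coordinates. Samples outside the atlas get
#' probability zero. Per-voxel sums are renormalized only where they exceed
#' one, preserving partial-volume semantics at the brain edge.
#'
#' @param x a `probabilistic_atlas` or a named list of dense maps.
#' @param deformation a [deformation()] (or `NULL` for the identity map
#'   between the two grids' world frames).
#' @param target_geom target grid geometry (`list(dim, affine, voxel_size)`
#'   or an `image_volume`).
#' @param source_geom geometry of the maps when `x` is a plain list.
#' @return named list of probability maps on the target grid.
#' @export
resample_atlas <- function(x, deformation, target_geom, source_geom = NULL) {
  if (inherits(target_geom, "image_volume")) target_geom <- grid_geometry(target_geom)
  if (inherits(x, "probabilistic_atlas")) {
    source_geom <- atlas_geometry(x)
    maps <- lapply(x$labels$id, function(id) atlas_dense_map(x, id))
    names(maps) <- as.character(x$labels$id)
  } else {
    stopifnot(!is.null(source_geom))
    maps <- x
  }
  cc <- deformed_coords(deformation, target_geom, source_geom)
  out <- lapply(maps, function(m) {
    w <- interp_trilinear(m, cc$x, cc$y, cc$z, fill = 0)
    array(w, target_geom$dim)
  })
  s <- Reduce(`+`, out)
  over <- s > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / s, 1)
    out <- lapply(out, function(m) m * sc)
  }
  out
}

#' Warp every atlas ROI to a target grid, keeping sparse storage
#'
#' Deforms each ROI's probability sub-volume onto the target grid,
#' evaluating the deformation only inside a conservative bounding box per
#' ROI (the source box mapped through the affine chain, expanded by the
#' maximum displacement). Boxes are re-tightened to the warped nonzero
#' support, so memory stays proportional to the ROIs' actual extent.
#' Per-voxel sums above one are renormalized, as in [resample_atlas()].
#'
#' @param atlas a [probabilistic_atlas()].
#' @param deformation a [deformation()] or `NULL` (affine-only mapping).
#' @param target_geom target grid geometry.
#' @param margin extra voxels around each mapped box (default 2).
#' @return list of `list(label_id, lo, hi, values)` sparse warped maps with
#'   attribute `dim` (the target grid shape).
#' @export
warp_atlas_sparse <- function(atlas, deformation, target_geom, margin = 2L) {
  if (inherits(target_geom, "image_volume")) target_geom <- grid_geometry(target_geom)
  ageom <- atlas_geometry(atlas)
  if (is.null(deformation)) {
    L <- solve(solve(ageom$affine) %*% target_geom$affine)
    umax_t <- 0
  } else {
    fg <- deformation$geom
    Af <- solve(fg$affine) %*% target_geom$affine
    A2 <- solve(ageom$affine) %*% solve(deformation$pre_affine) %*% fg$affine
    L <- solve(A2 %*% Af)
    umax_t <- max(abs(deformation$disp)) * max(sqrt(colSums(solve(Af)[1:3, 1:3]^2)))
  }
  pad <- ceiling(umax_t) + margin
  out <- vector("list", length(atlas$rois))
  dsum <- array(0, target_geom$dim)
  # deformed source coordinates of the whole target grid, computed once
  cc_full <- deformed_coords(deformation, target_geom, ageom)
  cx <- array(cc_full$x, target_geom$dim)
  cy <- array(cc_full$y, target_geom$dim)
  cz <- array(cc_full$z, target_geom$dim)
  for (i in seq_along(atlas$rois)) {
    r <- atlas$rois[[i]]
    corners <- as.matrix(expand.grid(c(r$lo[1] - 0.5, r$hi[1] - 0.5),
                                     c(r$lo[2] - 0.5, r$hi[2] - 0.5),
                                     c(r$lo[3] - 0.5, r$hi[3] - 0.5)))
    tc <- t(L[1:3, ] %*% t(cbind(corners, 1)))
    lo <- pmax(floor(apply(tc, 2, min)) - pad, 0)
    hi <- pmin(ceiling(apply(tc, 2, max)) + pad + 1, target_geom$dim)
    if (any(hi <= lo)) {
      out[[i]] <- list(label_id = r$label_id, lo = c(0L, 0L, 0L),
                       hi = c(1L, 1L, 1L), values = array(0, c(1, 1, 1)))
      next
    }
    bw <- list(lo = as.integer(lo), hi = as.integer(hi))
    bx <- box_get(cx, bw); by <- box_get(cy, bw); bz <- box_get(cz, bw)
    vals <- interp_trilinear(atlas_box_pad(r), bx - r$lo[1] + 1, by - r$lo[2] + 1,
                             bz - r$lo[3] + 1, fill = 0)
    w <- tighten_roi(list(label_id = r$label_id, lo = bw$lo, hi = bw$hi,
                          values = array(vals, bw$hi - bw$lo)),
                     target_geom$dim)
    out[[i]] <- w
    if (any(w$values != 0)) dsum <- box_add(dsum, w, w$values)
  }
  if (max(dsum) > 1) {
    sc <- ifelse(dsum > 1, 1 / dsum, 1)
    out <- lapply(out, function(w) {
      w$values <- w$values * box_get(sc, w)
      w
    })
  }
  names(out) <- as.character(vapply(out, `[[`, integer(1), "label_id"))
  attr(out, "grid_dim") <- target_geom$dim
  out
}

# ROI sub-volume padded with one zero voxel on every face, so trilinear
# interpolation decays to zero at the true box edge instead of clamping.
atlas_box_pad <- function(r) {
  d <- dim(r$values)
  out <- array(0, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- r$values
  out
}

# 0-based source-grid voxel coordinates of every target-grid voxel under
# `deformation` (affine pre-alignment composed with the dense displacement).
deformed_coords <- function(deformation, target_geom, source_geom) {
  g <- grid_coords(target_geom$dim)
  if (is.null(deformation)) {
    A <- solve(source_geom$affine) %*% target_geom$affine
    return(apply_affine(A, g$x, g$y, g$z))
  }
  stopifnot(inherits(deformation, "deformation"))
  if (any(!is.finite(deformation$disp))) stop("non-finite deformation values")
  fg <- deformation$geom
  Af <- solve(fg$affine) %*% target_geom$affine
  fx <- apply_affine(Af, g$x, g$y, g$z)
  ux <- interp_trilinear(deformation$disp[, , , 1], fx$x, fx$y, fx$z, fill = 0)
  uy <- interp_trilinear(deformation$disp[, , , 2], fx$x, fx$y, fx$z, fill = 0)
  uz <- interp_trilinear(deformation$disp[, , , 3], fx$x, fx$y, fx$z, fill = 0)
  # fixed voxel -> fixed world -> (undo atlas->scan pre-affine) -> source voxel
  A2 <- solve(source_geom$affine) %*% solve(deformation$pre_affine) %*% fg$affine
  apply_affine(A2, fx$x + ux, fx$y + uy, fx$z + uz)
}
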