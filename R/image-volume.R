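#' Create an image volume
#'
#' A lightweight container for a 3D scalar image: a voxel array, a 4x4
#' voxel-to-world affine (RAS millimetres, 0-based voxel indices addressing
#' voxel centres) and an optional binary mask of valid voxels.
#'
#' @param voxels 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (RAS, mm). Defaults to
#'   `diag(c(voxel_size, 1))` when only `voxel_size` is given.
#' @param voxel_size length-3 spacing in mm; derived from `affine` if missing.
#' @param mask optional logical array of the same shape.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, affine = NULL, voxel_size = NULL, mask = NULL) {
  stopifnot(length(dim(voxels)) == 3L)
  if (is.null(affine)) {
    if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(voxel_size)) voxel_size <- colnorm
  if (any(voxel_size <= 0) || any(abs(voxel_size - colnorm) > 1e-6))
    stop("voxel_size must be positive and match the affine column norms")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim(voxels))
    stopifnot(all(dim(mask) == dim(voxels)))
  }
  structure(list(voxels = voxels, affine = affine,
                 voxel_size = as.numeric(voxel_size), mask = mask),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm, range [%.4g, %.4g]%s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$voxels), max(x$voxels),
              if (is.null(x$mask)) "" else sprintf(", %d masked-in", sum(x$mask))))
  invisible(x)
}

grid_geometry <- function(vol) {
  list(dim = dim(vol$voxels), affine = vol$affine, voxel_size = vol$voxel_size)
}

#' Read a NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file into an [image_volume()], reorienting the
#' array to RAS so that voxel axes align with world axes.
#'
#' @param path file path.
#' @return an `image_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS")) RNifti::orientation(img) <- "RAS"
  A <- structure(RNifti::xform(img), class = NULL)
  A <- matrix(as.numeric(A), 4, 4)
  vox <- array(as.numeric(img), dim(img)[1:3])
  image_volume(vox, affine = A)
}

#' Write a NIfTI volume
#'
#' @param vol an `image_volume` (or bare 3D array plus `affine`).
#' @param path output path (`.nii.gz`).
#' @param datatype NIfTI storage datatype (`"float"` or `"int16"` etc.).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  if (is.array(vol)) vol <- image_volume(vol)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Coordinates of every voxel of `target_geom` expressed in the 0-based voxel
# frame of `source_geom` (both axis-aligned or general affines).
voxel_map <- function(target_geom, source_geom) {
  g <- grid_coords(target_geom$dim)
  A <- solve(source_geom$affine) %*% target_geom$affine
  apply_affine(A, g$x, g$y, g$z)
}

# Resample a volume onto a target geometry through the two affines
# (trilinear; `fill` outside). Returns a bare array.
resample_to_geometry <- function(arr, source_geom, target_geom, fill = 0) {
  cc <- voxel_map(target_geom, source_geom)
  out <- interp_trilinear(arr, cc$x, cc$y, cc$z, fill = fill)
  array(out, target_geom$dim)
}

# Nearest-neighbour resampling for label volumes.
resample_nearest <- function(arr, source_geom, target_geom, fill = 0L) {
  cc <- voxel_map(target_geom, source_geom)
  d <- dim(arr)
  xi <- round(cc$x); yi <- round(cc$y); zi <- round(cc$z)
  ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
  out <- rep(fill, length(xi))
  idx <- 1 + xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok])
  out[ok] <- arr[idx]
  array(out, target_geom$dim)
}

# Geometry of a grid downsampled by integer per-axis factors, with the
# half-voxel origin shift that keeps voxel centres centred on the blocks.
downsample_geometry <- function(geom, factor) {
  factor <- rep_len(as.integer(factor), 3L)
  ndim <- pmax(1L, ceiling(geom$dim / factor))
  S <- diag(c(factor, 1))
  S[1:3, 4] <- (factor - 1) / 2
  A <- geom$affine %*% S
  list(dim = ndim, affine = A, voxel_size = geom$voxel_size * factor)
}

# Geometry covering the same world extent at a new isotropic spacing.
regrid_geometry <- function(geom, new_voxel_size) {
  new_voxel_size <- rep_len(new_voxel_size, 3L)
  ratio <- new_voxel_size / geom$voxel_size
  ndim <- pmax(1L, round(geom$dim / ratio))
  S <- diag(c(ratio, 1))
  S[1:3, 4] <- (ratio - 1) / 2
  A <- geom$affine %*% S
  list(dim = as.integer(ndim), affine = A, voxel_size = new_voxel_size)
}
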