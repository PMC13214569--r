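#' Robust per-structure intensity statistics
#'
#' For every labelled structure, computes the median intensity (robust mean)
#' and 1.4826 times the median absolute deviation (robust standard
#' deviation, consistent for a Gaussian). Structures with fewer than 10
#' voxels are flagged unusable; the standard deviation is floored at
#' `1e-4` of the robust intensity range.
#'
#' @param values 3D array of intensities.
#' @param labels 3D integer array of structure labels on the same grid.
#' @param protocol data.frame with columns `id`, `name` describing nonzero
#'   labels.
#' @param mask optional logical array restricting the voxels used.
#' @return data.frame with columns `id`, `name`, `n`, `median`, `sd`,
#'   `usable`.
#' @export
robust_stats <- function(values, labels, protocol, mask = NULL) {
  if (inherits(values, "image_volume")) {
    if (is.null(mask)) mask <- values$mask
    values <- values$voxels
  }
  stopifnot(identical(dim(values), dim(labels)))
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  floor_sd <- 1e-4 * robust_range(values[mask])
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    id <- protocol$id[i]
    x <- values[labels == id & mask]
    n <- length(x)
    if (n == 0L)
      return(data.frame(id = id, name = protocol$name[i], n = 0L,
                        median = NA_real_, sd = NA_real_, usable = FALSE))
    m <- median(x)
    s <- max(1.4826 * median(abs(x - m)), floor_sd)
    data.frame(id = id, name = protocol$name[i], n = n, median = m, sd = s,
               usable = n >= 10L)
  })
  do.call(rbind, rows)
}

#' Intensity recipe
#'
#' A recipe gives, for every tissue class of the grouping, a linear rule
#' over the robust statistics of reference structures that the coarse
#' segmentation protocol segments reliably. Weights may sum to more or
#' less than one to darken or brighten a class relative to its references.
#'
#' @param rules named list: class name -> named numeric vector of weights
#'   over reference structure names.
#' @return an object of class `intensity_recipe`.
#' @export
intensity_recipe <- function(rules) {
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (is.null(names(r)) || any(names(r) == ""))
      stop(sprintf("rule for class '%s' must name its reference structures", nm))
  }
  structure(list(rules = rules), class = "intensity_recipe")
}

#' Read an intensity recipe from YAML
#'
#' The file maps each tissue-class name to `structure: weight` pairs
#' (`recipe_intensities_cheating_image_fireants.yaml`).
#'
#' @param yaml_path directory containing the recipe file, or a file path.
#' @return an [intensity_recipe()].
#' @export
read_recipe <- function(yaml_path) {
  f <- if (dir.exists(yaml_path))
    file.path(yaml_path, "recipe_intensities_cheating_image_fireants.yaml")
  else yaml_path
  raw <- yaml::read_yaml(f)
  intensity_recipe(lapply(raw, function(r) unlist(r)))
}

#' Write an intensity recipe to YAML
#'
#' @param recipe an [intensity_recipe()].
#' @param yaml_path output directory.
#' @return the file path, invisibly.
#' @export
write_recipe <- function(recipe, yaml_path) {
  dir.create(yaml_path, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(yaml_path, "recipe_intensities_cheating_image_fireants.yaml")
  yaml::write_yaml(lapply(recipe$rules, as.list), f)
  invisible(f)
}

#' Derive synthetic class means from a recipe
#'
#' Applies each class's linear rule to the reference-structure medians. A
#' rule term referencing an unusable structure is dropped and the remaining
#' terms rescaled to the rule's original weight sum (with a warning); a rule
#' with no usable term falls back to the median over all usable structures.
#'
#' @param stats data.frame from [robust_stats()].
#' @param recipe an [intensity_recipe()].
#' @param grouping a [label_grouping()]; every class must have a rule.
#' @return named numeric vector of per-class synthetic means.
#' @export
class_means_from_recipe <- function(stats, recipe, grouping) {
  missing_rules <- setdiff(grouping$classes, names(recipe$rules))
  if (length(missing_rules))
    stop(sprintf("classes without a recipe rule: %s", paste(missing_rules, collapse = ", ")))
  med <- stats$median[stats$usable]
  names(med) <- stats$name[stats$usable]
  fallback <- median(med)
  out <- vapply(grouping$classes, function(cl) {
    r <- recipe$rules[[cl]]
    usable <- names(r) %in% names(med)
    if (!all(usable)) {
      warning(sprintf("rule for '%s': dropping unusable references %s", cl,
                      paste(names(r)[!usable], collapse = ", ")))
      if (!any(usable)) return(fallback)
      tot <- sum(r)
      r <- r[usable]
      r <- r * tot / sum(r)
    }
    sum(r * med[names(r)])
  }, numeric(1))
  out
}

#' Synthesize an anatomical volume from grouped class maps
#'
#' Renders the noise-free expectation image `sum_c p_c(x) mu_c` (background
#' mean fixed at zero, matching a masked scan) on the atlas grid.
#'
#' @param class_maps named list of class probability maps.
#' @param class_means named numeric vector of synthetic means.
#' @param geom grid geometry of the maps.
#' @return an `image_volume`.
#' @export
synthesize_volume <- function(class_maps, class_means, geom) {
  stopifnot(all(names(class_maps) %in% names(class_means)))
  out <- array(0, dim(class_maps[[1]]))
  for (nm in names(class_maps)) out <- out + class_maps[[nm]] * class_means[[nm]]
  image_volume(out, affine = geom$affine)
}

#' Match a volume to a target resolution
#'
#' Anti-aliased resampling: when downsampling, the image is first blurred
#' with a Gaussian whose per-axis FWHM equals the target spacing
#' (sigma = spacing / 2.355 in source voxel units), then trilinearly
#' resampled onto the target grid. Upsampling interpolates directly.
#'
#' @param vol an `image_volume`.
#' @param target_voxel_size length-3 (or scalar) target spacing in mm.
#' @return an `image_volume` on the new grid.
#' @export
match_resolution <- function(vol, target_voxel_size) {
  target_voxel_size <- rep_len(target_voxel_size, 3L)
  src <- grid_geometry(vol)
  if (max(abs(target_voxel_size - src$voxel_size)) < 1e-9) return(vol)
  ratio <- target_voxel_size / src$voxel_size
  sig <- ifelse(ratio > 1, ratio / 2.355, 0)
  v <- vol$voxels
  # keep background values from bleeding across the mask edge
  if (!is.null(vol$mask)) v <- fill_from_mask(v, vol$mask, iters = 8L)
  v <- if (any(sig > 0)) smooth_gaussian(v, sig) else v
  tg <- regrid_geometry(src, target_voxel_size)
  out <- resample_to_geometry(v, src, tg)
  m <- NULL
  if (!is.null(vol$mask))
    m <- resample_to_geometry(array(as.numeric(vol$mask), src$dim), src, tg) >= 0.5
  image_volume(out, affine = tg$affine, mask = m)
}
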