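#' Tissue-class grouping of atlas ROIs
#'
#' Bayesian segmentation groups fine ROIs into a small number of tissue
#' classes that share an intensity model; this object records that mapping
#' together with the number of Gaussian mixture components per class.
#'
#' @param classes ordered character vector of class names.
#' @param roi_to_class named list/vector mapping label id (as character) to
#'   class name.
#' @param components_per_class named integer vector (class name -> number of
#'   Gaussian components, >= 1). Defaults to one component per class.
#' @return an object of class `label_grouping`.
#' @export
label_grouping <- function(classes, roi_to_class, components_per_class = NULL) {
  classes <- as.character(classes)
  if (length(classes) == 0L) stop("class list must be non-empty")
  roi_to_class <- as.list(roi_to_class)
  if (anyDuplicated(names(roi_to_class))) stop("each label id may appear only once")
  bad <- setdiff(unique(unlist(roi_to_class)), classes)
  if (length(bad)) stop(sprintf("unknown classes in mapping: %s", paste(bad, collapse = ", ")))
  if (is.null(components_per_class)) components_per_class <- stats::setNames(rep(1L, length(classes)), classes)
  components_per_class <- components_per_class[classes]
  if (any(is.na(components_per_class)) || any(components_per_class < 1L))
    stop("every class needs a component count >= 1")
  structure(list(classes = classes, roi_to_class = roi_to_class,
                 components_per_class = as.integer(components_per_class) |>
                   stats::setNames(classes)),
            class = "label_grouping")
}

#' @export
print.label_grouping <- function(x, ...) {
  cat(sprintf("<label_grouping> %d classes over %d labels\n",
              length(x$classes), length(x$roi_to_class)))
  invisible(x)
}

#' Read a label grouping from YAML configuration files
#'
#' `combined_atlas_labels_fireants.yaml` maps each tissue-class name to the
#' list of atlas label ids it contains; `gmm_components_fireants.yaml` maps
#' each class name to its number of Gaussian components.
#'
#' @param yaml_path directory holding the two YAML files.
#' @return a [label_grouping()].
#' @export
read_grouping <- function(yaml_path) {
  lab <- yaml::read_yaml(file.path(yaml_path, "combined_atlas_labels_fireants.yaml"))
  cmp <- yaml::read_yaml(file.path(yaml_path, "gmm_components_fireants.yaml"))
  classes <- names(lab)
  roi_to_class <- list()
  for (cl in classes) {
    for (id in lab[[cl]]) roi_to_class[[as.character(id)]] <- cl
  }
  comps <- vapply(classes, function(cl) {
    if (is.null(cmp[[cl]])) 1L else as.integer(cmp[[cl]])
  }, integer(1))
  label_grouping(classes, roi_to_class, comps)
}

#' Write a label grouping to YAML configuration files
#'
#' @param grouping a [label_grouping()].
#' @param yaml_path output directory.
#' @return `yaml_path`, invisibly.
#' @export
write_grouping <- function(grouping, yaml_path) {
  dir.create(yaml_path, showWarnings = FALSE, recursive = TRUE)
  lab <- lapply(grouping$classes, function(cl) {
    ids <- as.integer(names(grouping$roi_to_class)[
      vapply(grouping$roi_to_class, identical, logical(1), cl)])
    sort(ids)
  })
  names(lab) <- grouping$classes
  yaml::write_yaml(lab, file.path(yaml_path, "combined_atlas_labels_fireants.yaml"))
  yaml::write_yaml(as.list(grouping$components_per_class),
                   file.path(yaml_path, "gmm_components_fireants.yaml"))
  invisible(yaml_path)
}

#' Coarse whole-brain segmentation
#'
#' A low-resolution (~1 mm) whole-brain labelling following a fixed
#' protocol; label 0 is background and every nonzero label present in the
#' volume must be described by the protocol table.
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param protocol data.frame with columns `id`, `name` (and optionally
#'   `bias_class` and logical `is_brain`).
#' @return an object of class `coarse_segmentation`.
#' @export
coarse_segmentation <- function(labels, affine, protocol) {
  labels <- array(as.integer(labels), dim(labels))
  present <- setdiff(unique(as.vector(labels)), 0L)
  miss <- setdiff(present, protocol$id)
  if (length(miss))
    stop(sprintf("labels missing from protocol: %s", paste(miss, collapse = ", ")))
  structure(list(labels = labels, affine = as.matrix(affine), protocol = protocol),
            class = "coarse_segmentation")
}

coarse_geometry <- function(coarse) {
  list(dim = dim(coarse$labels), affine = coarse$affine,
       voxel_size = sqrt(colSums(coarse$affine[1:3, 1:3]^2)))
}

#' @export
print.coarse_segmentation <- function(x, ...) {
  cat(sprintf("<coarse_segmentation> %s grid, %d protocol labels\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$protocol)))
  invisible(x)
}

#' Default tissue classes for intensity modelling
#'
#' The sixteen tissue classes used by default to group atlas ROIs that share
#' an intensity profile.
#'
#' @return character vector of 16 class names.
#' @export
default_tissue_classes <- function() {
  c("cerebral white matter", "cerebral gray matter",
    "cerebellar white matter", "cerebellar cortex",
    "caudate", "putamen", "pallidum",
    "lateral thalamus", "medial thalamus", "red nucleus",
    "compact brainstem white matter", "diffuse brainstem white matter",
    "hypothalamus", "mammillary bodies",
    "dentate nucleus of the cerebellum", "hippocampal white matter")
}

#' Default classes for bias-field estimation
#'
#' The eight coarse-segmentation classes used as fixed soft responsibilities
#' when fitting the bias field.
#'
#' @return character vector of 8 class names.
#' @export
default_bias_classes <- function() {
  c("cerebral gray matter", "cerebellar gray matter",
    "cerebral white matter", "cerebellar white matter",
    "brainstem", "cerebrospinal fluid", "thalamus", "pallidum")
}
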