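#' Fit the tissue-class GMM by expectation maximization
#'
#' With the bias field and atlas deformation fixed, alternates E-steps
#' (class/component responsibilities under the warped priors) and
#' closed-form M-steps (weights, means, variances). The M-step may
#' subsample voxels by an integer stride per axis (`skip`); the E-step
#' log-likelihood is tracked on the same subsample and is non-decreasing.
#' Stops when the relative change of the mean log-likelihood falls below
#' `tol` or after `max_iter` iterations, then runs a final E-step on the
#' full working grid.
#'
#' @param log_image 3D array of bias-corrected log intensities at working
#'   resolution.
#' @param priors named list of warped class probability maps (same grid).
#' @param init a [gaussian_params()] initialization (classes must match
#'   `priors`).
#' @param mask logical array of brain voxels.
#' @param bias optional 3D additive log-bias array (usually already
#'   corrected; default `NULL`).
#' @param skip integer >= 1 M-step subsampling stride per axis.
#' @param max_iter,tol stopping rule.
#' @return list with `params`, `resp` (full-grid responsibilities, matrix
#'   voxels x classes), `mask_idx`, `loglik_trace` (mean log-likelihood per
#'   iteration) and `frozen` (classes kept at their initialization).
#' @export
fit_gmm_em <- function(log_image, priors, init, mask = NULL, bias = NULL,
                       skip = 1L, max_iter = 100L, tol = 1e-5) {
  skip <- as.integer(skip)
  stopifnot(skip >= 1L)
  if (is.null(mask)) mask <- array(TRUE, dim(log_image))
  classes <- init$classes
  stopifnot(all(classes %in% names(priors)))
  mask_idx <- which(mask)
  pm <- Reduce(`+`, lapply(classes, function(cl) priors[[cl]]))[mask_idx]
  zero <- pm <= 0
  if (any(zero)) {
    warning(sprintf("%d masked voxels with zero prior mass excluded", sum(zero)))
    mask_idx <- mask_idx[!zero]
  }
  sub_idx <- mask_idx
  if (skip > 1L) {
    d <- dim(log_image)
    co <- arrayInd(mask_idx, d)
    keep <- (co[, 1] %% skip == 1L) & (co[, 2] %% skip == 1L) & (co[, 3] %% skip == 1L)
    sub_idx <- mask_idx[keep]
  }
  y <- log_image[sub_idx]
  if (!is.null(bias)) y <- y - bias[sub_idx]

  params <- init
  frozen <- character(0)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lt <- component_log_terms(y, priors, params, sub_idx)
    ll <- logsumexp_mat(lt$mat)
    mean_ll <- mean(ll)
    trace <- c(trace, mean_ll)
    post <- exp(lt$mat - ll)
    new_params <- params$components
    frozen <- character(0)
    var_floor <- 1e-4 * robust_range(y)^2
    for (ci in seq_along(classes)) {
      cols <- which(lt$class_of == ci)
      rc <- post[, cols, drop = FALSE]
      tot <- sum(rc)
      if (tot < 10) { frozen <- c(frozen, classes[ci]); next }
      w <- colSums(rc) / tot
      mu <- as.numeric(crossprod(rc, y)) / pmax(colSums(rc), 1e-12)
      s2 <- as.numeric(crossprod(rc, y^2)) / pmax(colSums(rc), 1e-12) - mu^2
      new_params[[classes[ci]]] <- list(w = w / sum(w), mu = mu,
                                        sigma = sqrt(pmax(s2, var_floor)))
    }
    params <- gaussian_params(new_params)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) <
        tol * max(abs(trace[it - 1L]), 1e-12)) break
  }
  if (length(frozen))
    warning(sprintf("classes frozen at initialization: %s", paste(frozen, collapse = ", ")))
  fin <- gmm_log_likelihood(log_image, bias, priors, params,
                            mask = mask)
  list(params = params, resp = fin$resp, mask_idx = fin$mask_idx,
       loglik_trace = trace, frozen = frozen)
}

#' Redistribute class posteriors to fine ROIs
#'
#' Splits each tissue class's posterior probability at every voxel across
#' its constituent ROIs in proportion to the warped fine atlas:
#' `p_jk = r_jc(k) * A_kj / sum_{k' in c} A_k'j` (zero where the class has
#' no atlas mass). Per voxel, the fine posteriors of a class sum to the
#' class responsibility.
#'
#' @param resp matrix (voxels x classes) of class responsibilities.
#' @param mask_idx linear indices of the voxels behind `resp` rows.
#' @param fine_maps warped ROI probability maps on the working grid: either
#'   a named list (by label id) of dense arrays, or the sparse output of
#'   [warp_atlas_sparse()].
#' @param grouping a [label_grouping()].
#' @param grid_dim working grid dimensions.
#' @return sparse posterior maps in the [warp_atlas_sparse()] layout (with
#'   attribute `dim`), named by label id.
#' @export
redistribute_posteriors <- function(resp, mask_idx, fine_maps, grouping, grid_dim) {
  fine_maps <- as_sparse_maps(fine_maps, grid_dim)
  # dense per-class responsibilities and atlas-class totals
  rc <- lapply(grouping$classes, function(cl) {
    m <- array(0, grid_dim)
    ci <- match(cl, colnames(resp))
    m[mask_idx] <- resp[, ci]
    m
  })
  names(rc) <- grouping$classes
  class_tot <- lapply(grouping$classes, function(cl) array(0, grid_dim))
  names(class_tot) <- grouping$classes
  for (w in fine_maps) {
    cl <- grouping$roi_to_class[[as.character(w$label_id)]]
    class_tot[[cl]] <- box_add(class_tot[[cl]], w, w$values)
  }
  out <- lapply(fine_maps, function(w) {
    cl <- grouping$roi_to_class[[as.character(w$label_id)]]
    tot <- box_get(class_tot[[cl]], w)
    frac <- ifelse(tot > 0, w$values / tot, 0)
    w$values <- box_get(rc[[cl]], w) * frac
    w
  })
  names(out) <- names(fine_maps)
  attr(out, "grid_dim") <- grid_dim
  out
}

# Accept dense named lists as well as sparse map lists.
as_sparse_maps <- function(maps, grid_dim) {
  if (!is.null(attr(maps, "grid_dim")) ||
      (length(maps) && is.list(maps[[1]]) && !is.null(maps[[1]]$lo)))
    return(maps)
  out <- lapply(names(maps), function(id)
    tighten_roi(list(label_id = as.integer(id), lo = c(0L, 0L, 0L),
                     hi = as.integer(grid_dim), values = maps[[id]]), grid_dim))
  names(out) <- names(maps)
  attr(out, "grid_dim") <- grid_dim
  out
}

box_slice <- function(w) {
  list(i1 = (w$lo[1] + 1):w$hi[1], i2 = (w$lo[2] + 1):w$hi[2],
       i3 = (w$lo[3] + 1):w$hi[3])
}

# Box extraction/insertion that never drops singleton dimensions.
box_get <- function(arr, w) {
  sl <- box_slice(w)
  out <- arr[sl$i1, sl$i2, sl$i3, drop = FALSE]
  dim(out) <- w$hi - w$lo
  out
}

box_add <- function(arr, w, values) {
  sl <- box_slice(w)
  cur <- arr[sl$i1, sl$i2, sl$i3, drop = FALSE]
  arr[sl$i1, sl$i2, sl$i3] <- cur + values
  arr
}

# Dense accumulation of sparse maps (sum over ROIs).
sparse_sum <- function(maps, grid_dim = attr(maps, "grid_dim")) {
  out <- array(0, grid_dim)
  for (w in maps) {
    if (all(w$values == 0)) next
    out <- box_add(out, w, w$values)
  }
  out
}

#' Hard segmentation from fine posteriors
#'
#' Per-voxel argmax over ROIs and background (background probability is one
#' minus the summed fine posteriors); ties break to the lowest label id;
#' voxels outside the mask get label 0.
#'
#' @param fine_post fine posterior maps: named list of dense arrays or the
#'   sparse layout of [redistribute_posteriors()].
#' @param mask logical array (or `NULL` for all voxels).
#' @param grid_dim grid shape (required for dense lists without names).
#' @return 3D integer label volume.
#' @export
hard_segmentation <- function(fine_post, mask = NULL, grid_dim = NULL) {
  if (is.null(grid_dim))
    grid_dim <- attr(fine_post, "grid_dim") %||% dim(fine_post[[1]])
  fine_post <- as_sparse_maps(fine_post, grid_dim)
  best <- 1 - sparse_sum(fine_post, grid_dim)   # background probability
  lab <- array(0L, grid_dim)
  ids <- sort(vapply(fine_post, `[[`, integer(1), "label_id"))
  for (id in ids) {
    w <- fine_post[[match(id, vapply(fine_post, `[[`, integer(1), "label_id"))]]
    if (all(w$values == 0)) next
    sl <- box_slice(w)
    bb <- box_get(best, w)
    ll <- box_get(lab, w)
    upd <- w$values > bb
    ll[upd] <- id
    bb[upd] <- w$values[upd]
    best[sl$i1, sl$i2, sl$i3] <- bb
    lab[sl$i1, sl$i2, sl$i3] <- ll
  }
  if (!is.null(mask)) lab[!mask] <- 0L
  lab
}

#' Soft ROI volumes
#'
#' Expected (probability-weighted) volume of every ROI in cubic
#' millimetres.
#'
#' @param fine_post fine posterior maps (dense named list or sparse layout).
#' @param voxel_size grid spacing (mm, length 3).
#' @param labels optional data.frame with `id`, `name` for annotation.
#' @return data.frame with `label_id`, `name`, `volume_mm3`, sorted by id.
#' @export
roi_volumes <- function(fine_post, voxel_size, labels = NULL) {
  voxvol <- prod(rep_len(voxel_size, 3L))
  sums <- vapply(fine_post, function(w)
    sum(if (is.list(w)) w$values else w), numeric(1))
  ids <- if (is.list(fine_post[[1]]) && !is.null(fine_post[[1]]$label_id))
    vapply(fine_post, `[[`, integer(1), "label_id")
  else as.integer(names(fine_post))
  ord <- order(ids)
  nm <- if (is.null(labels)) rep(NA_character_, length(ids))
        else labels$name[match(ids[ord], labels$id)]
  data.frame(label_id = ids[ord], name = nm,
             volume_mm3 = as.numeric(sums[ord] * voxvol))
}
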