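#' Build a bias-field basis
#'
#' Constructs a separable smooth basis over a reference grid for modelling
#' the (log-domain additive) bias field. Three families are supported:
#' `dct` uses separable products of orthonormal 1D DCT-II modes with
#' frequencies `0..order` per axis (`(order+1)^3` functions, lexicographic
#' frequency ordering); `polynomial` uses monomials `x^a y^b z^c` with
#' `a+b+c <= order` over grid coordinates scaled to `[-1, 1]`; `hybrid`
#' uses DCT modes in-plane (x, y) and polynomials through-plane (z), for
#' thick-slice acquisitions.
#'
#' @param geom reference grid geometry (`list(dim, affine, voxel_size)` or
#'   an `image_volume`).
#' @param kind one of `"dct"`, `"polynomial"`, `"hybrid"`.
#' @param order nonnegative integer per-axis order.
#' @return an object of class `bias_basis` with `n_basis` functions.
#' @export
build_basis <- function(geom, kind = c("dct", "polynomial", "hybrid"), order = 6L) {
  kind <- match.arg(kind)
  if (inherits(geom, "image_volume")) geom <- grid_geometry(geom)
  order <- as.integer(order)
  stopifnot(order >= 0L)
  k <- order + 1L
  if (kind == "dct") {
    active <- as.matrix(expand.grid(a = 1:k, b = 1:k, c = 1:k))
  } else if (kind == "polynomial") {
    g <- expand.grid(a = 1:k, b = 1:k, c = 1:k)
    active <- as.matrix(g[(g$a - 1) + (g$b - 1) + (g$c - 1) <= order, , drop = FALSE])
  } else {
    active <- as.matrix(expand.grid(a = 1:k, b = 1:k, c = 1:k))
  }
  # lexicographic in (a, b, c) with a fastest; reorder to frequency-major
  active <- active[order(active[, 1], active[, 2], active[, 3]), , drop = FALSE]
  structure(list(kind = kind, order = order, geom = geom, active = active,
                 n_basis = nrow(active)),
            class = "bias_basis")
}

# 1D basis functions of `basis` along `axis`, evaluated at continuous
# 0-based reference-grid voxel coordinates `v`; matrix length(v) x (order+1).
eval_basis_1d <- function(basis, axis, v) {
  n <- basis$geom$dim[axis]
  k <- basis$order + 1L
  kind <- if (basis$kind == "hybrid" && axis == 3L) "polynomial"
          else if (basis$kind == "hybrid") "dct" else basis$kind
  out <- matrix(0, length(v), k)
  if (kind == "dct") {
    for (f in 0:(k - 1L)) {
      scale <- sqrt((if (f == 0L) 1 else 2) / n)
      out[, f + 1L] <- scale * cos(pi * f * (v + 0.5) / n)
    }
  } else {
    t <- if (n > 1L) 2 * v / (n - 1) - 1 else rep(0, length(v))
    for (f in 0:(k - 1L)) out[, f + 1L] <- t^f
  }
  out
}

# Explicit design matrix (points x n_basis) at reference-grid coordinates.
bias_design_matrix <- function(basis, x, y, z) {
  Fx <- eval_basis_1d(basis, 1L, x)
  Fy <- eval_basis_1d(basis, 2L, y)
  Fz <- eval_basis_1d(basis, 3L, z)
  A <- basis$active
  out <- matrix(0, length(x), nrow(A))
  for (b in seq_len(nrow(A)))
    out[, b] <- Fx[, A[b, 1]] * Fy[, A[b, 2]] * Fz[, A[b, 3]]
  out
}

#' Bias-field model
#'
#' @param basis a [build_basis()] object.
#' @param coefficients numeric vector of length `basis$n_basis`.
#' @return an object of class `bias_field_model`.
#' @export
bias_field_model <- function(basis, coefficients) {
  stopifnot(inherits(basis, "bias_basis"),
            length(coefficients) == basis$n_basis,
            all(is.finite(coefficients)))
  structure(list(basis = basis, coefficients = as.numeric(coefficients)),
            class = "bias_field_model")
}

#' Evaluate a bias field on a grid
#'
#' Evaluates the log-domain bias field analytically on any axis-aligned
#' target grid (the basis is separable, so the evaluation is a tensor
#' contraction; no full design matrix is formed).
#'
#' @param model a [bias_field_model()].
#' @param target_geom target grid geometry (defaults to the basis grid).
#' @return 3D array of bias values.
#' @export
eval_bias_field <- function(model, target_geom = NULL) {
  basis <- model$basis
  if (is.null(target_geom)) target_geom <- basis$geom
  if (inherits(target_geom, "image_volume")) target_geom <- grid_geometry(target_geom)
  M <- solve(basis$geom$affine) %*% target_geom$affine
  offdiag <- M[1:3, 1:3]; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-6)
    stop("bias evaluation requires axis-aligned grids")
  k <- basis$order + 1L
  coef <- array(0, c(k, k, k))
  coef[basis$active] <- model$coefficients
  out <- coef
  for (ax in 1:3) {
    v <- (seq_len(target_geom$dim[ax]) - 1) * M[ax, ax] + M[ax, 4]
    out <- axis_apply(out, eval_basis_1d(basis, ax, v), ax)
  }
  out
}

#' Soft segmentation for bias estimation
#'
#' One-hot encodes a grouped label volume and blurs each class indicator
#' with an isotropic Gaussian kernel given in millimetres, yielding fixed
#' soft responsibilities for the single M-step bias fit.
#'
#' @param labels 3D integer array of grouped class labels (0 = background).
#' @param class_names character vector of class names indexed by label.
#' @param sigma_mm Gaussian kernel standard deviation in mm (default 0.5).
#' @param voxel_size grid spacing in mm (length 3).
#' @return named list of soft class maps (classes absent from the volume
#'   yield empty maps with a warning).
#' @export
soft_segmentation <- function(labels, class_names, sigma_mm = 0.5, voxel_size = c(1, 1, 1)) {
  stopifnot(sigma_mm >= 0)
  voxel_size <- rep_len(voxel_size, 3L)
  sig <- sigma_mm / voxel_size
  maps <- vector("list", length(class_names))
  names(maps) <- class_names
  for (ci in seq_along(class_names)) {
    onehot <- array(as.numeric(labels == ci), dim(labels))
    if (!any(onehot > 0))
      warning(sprintf("class '%s' absent from volume", class_names[ci]))
    maps[[ci]] <- if (sigma_mm > 0) smooth_gaussian(onehot, sig) else onehot
  }
  maps
}

#' Fit the bias field with a single fixed-responsibility M-step
#'
#' With soft class assignments held fixed, alternates closed-form updates
#' of (a) class means and variances as weighted moments of bias-corrected
#' log-intensities and (b) basis coefficients by precision-weighted least
#' squares, until the field change falls below `1e-4` of the robust
#' intensity range or 50 alternations. The fixed-responsibility lower bound
#' is tracked and returned; ridge regularization (`1e-8 * trace`) guards
#' the normal equations.
#'
#' @param log_image 3D array of log intensities on the estimation grid.
#' @param soft_maps named list of fixed soft class maps (same grid).
#' @param basis a [build_basis()]; the estimation grid must be axis-aligned
#'   with the basis reference grid.
#' @param mask logical array of voxels to use.
#' @param est_geom geometry of the estimation grid (defaults to the basis
#'   reference geometry).
#' @return list with `model` ([bias_field_model()]), `class_stats`
#'   (data.frame class/mean/sd), `lower_bound` trace and `n_alternations`.
#' @export
fit_bias_single_mstep <- function(log_image, soft_maps, basis, mask = NULL,
                                  est_geom = NULL) {
  if (is.null(est_geom)) est_geom <- basis$geom
  if (is.null(mask)) mask <- array(TRUE, dim(log_image))
  idx <- which(mask & is.finite(log_image))
  stopifnot(length(idx) > 0L)
  yy <- log_image[idx]
  R <- do.call(cbind, lapply(soft_maps, function(m) pmax(m[idx], 0)))
  colnames(R) <- names(soft_maps)
  keep <- rowSums(R) > 1e-8
  idx <- idx[keep]; yy <- yy[keep]; R <- R[keep, , drop = FALSE]

  M <- solve(basis$geom$affine) %*% est_geom$affine
  g <- grid_coords(dim(log_image))
  cc <- apply_affine(M, g$x[idx], g$y[idx], g$z[idx])
  Psi <- bias_design_matrix(basis, cc$x, cc$y, cc$z)

  empty <- colSums(R) < 10
  if (any(empty)) {
    warning(sprintf("dropping %d empty classes from bias fit", sum(empty)))
    R <- R[, !empty, drop = FALSE]
  }
  rr <- robust_range(yy)
  b <- rep(0, length(yy))
  coef <- rep(0, basis$n_basis)
  lb <- numeric(0)
  var_floor <- (1e-4 * rr)^2
  nC <- ncol(R)
  # class moments and the coefficient system are computed over per-class
  # inlier voxels (|residual| < 3 sigma_c): fixed soft assignments taken
  # from a coarse segmentation inevitably mislabel some boundary voxels,
  # whose residuals (one full class contrast) would otherwise leak anatomy
  # into the smooth field. The 0.9735 factor restores variance consistency
  # under 3-sigma truncation of a Gaussian.
  trim_c <- 0.97346
  Rt <- R
  for (it in seq_len(50L)) {
    resid <- yy - b
    Nc <- pmax(colSums(Rt), 1e-9)
    mu <- as.numeric(crossprod(Rt, resid)) / Nc
    s2 <- pmax((as.numeric(crossprod(Rt, resid^2)) / Nc - mu^2) / trim_c, var_floor)
    Rt <- R
    for (ci in seq_len(nC))
      Rt[abs(resid - mu[ci]) >= 3 * sqrt(s2[ci]), ci] <- 0
    # precision-weighted residual target for the coefficient update
    prec <- sweep(Rt, 2, 1 / s2, `*`)
    w <- rowSums(prec)
    ok <- w > 1e-12
    t_num <- as.numeric(prec %*% mu)
    target <- ifelse(ok, (yy * w - t_num) / pmax(w, 1e-12), 0)
    XtW <- t(Psi * w)
    G <- XtW %*% Psi
    G <- G + diag(1e-8 * sum(diag(G)) / nrow(G), nrow(G))
    coef_new <- solve(G, XtW %*% target)
    b_new <- as.numeric(Psi %*% coef_new)
    q <- sum(vapply(seq_len(nC), function(ci)
      sum(Rt[, ci] * dnorm(yy - b_new, mu[ci], sqrt(s2[ci]), log = TRUE)), numeric(1)))
    lb <- c(lb, q)
    delta <- max(abs(b_new - b))
    b <- b_new
    coef <- as.numeric(coef_new)
    if (delta < 1e-4 * rr) break
  }
  resid <- yy - b
  Nc <- pmax(colSums(Rt), 1e-9)
  mu <- as.numeric(crossprod(Rt, resid)) / Nc
  s2 <- pmax((as.numeric(crossprod(Rt, resid^2)) / Nc - mu^2) / trim_c, var_floor)
  list(model = bias_field_model(basis, coef),
       class_stats = data.frame(class = colnames(R) %||% names(soft_maps),
                                mean = mu, sd = sqrt(s2)),
       lower_bound = lb, n_alternations = it)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct an image for its bias field
#'
#' Subtracts the estimated log-domain bias from the log intensities and
#' exponentiates back. The field's DC component is removed (a scalar shift
#' chosen so the corrected image preserves the masked median intensity):
#' the overall gain is not identifiable from the model.
#'
#' @param image an `image_volume` of raw intensities.
#' @param model a [bias_field_model()].
#' @return bias-corrected `image_volume` (same mask and geometry).
#' @export
correct_image <- function(image, model) {
  lt <- log_transform(image)
  b <- eval_bias_field(model, grid_geometry(image))
  idx <- which(lt$mask)
  corrected <- lt$voxels - b
  shift <- median(lt$voxels[idx]) - median(corrected[idx])
  corrected <- corrected + shift
  out <- image$voxels
  out[idx] <- exp(corrected[idx])
  image_volume(out, affine = image$affine, mask = lt$mask)
}

#' Log-transform an image volume
#'
#' Computes `log(max(I, eps))` with `eps = 1e-6` times the robust maximum
#' intensity; voxels with nonpositive intensity are excluded from the mask.
#'
#' @param image an `image_volume`.
#' @return an `image_volume` of log intensities with an updated mask.
#' @export
log_transform <- function(image) {
  v <- image$voxels
  pos <- v > 0
  robust_max <- quantile(v[pos], 0.999, names = FALSE)
  eps <- 1e-6 * robust_max
  lv <- log(pmax(v, eps))
  mask <- if (is.null(image$mask)) pos else image$mask & pos
  image_volume(lv, affine = image$affine, mask = mask)
}
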