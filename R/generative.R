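#' Gaussian mixture parameters per tissue class
#'
#' Per class: component weights (sum one), means (log-intensity units) and
#' standard deviations (> 0).
#'
#' @param components named list, one entry per class, each
#'   `list(w, mu, sigma)` with equal-length numeric vectors.
#' @return an object of class `gaussian_params`.
#' @export
gaussian_params <- function(components) {
  for (nm in names(components)) {
    cp <- components[[nm]]
    stopifnot(length(cp$w) == length(cp$mu), length(cp$mu) == length(cp$sigma))
    if (any(cp$sigma <= 0)) stop(sprintf("class '%s': sigma must be > 0", nm))
    if (any(cp$w < 0) || abs(sum(cp$w) - 1) > 1e-9)
      stop(sprintf("class '%s': weights must be nonnegative and sum to 1", nm))
  }
  structure(list(classes = names(components), components = components),
            class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  for (nm in x$classes) {
    cp <- x$components[[nm]]
    cat(sprintf("%-28s mu=%s sigma=%s w=%s\n", nm,
                paste(signif(cp$mu, 4), collapse = "/"),
                paste(signif(cp$sigma, 4), collapse = "/"),
                paste(signif(cp$w, 3), collapse = "/")))
  }
  invisible(x)
}

# Stack per-(class, component) log densities for masked voxels.
# Returns list(mat = n_mask x n_comp matrix of
# log p_cj + log w_cm + log g(res_j; mu_cm, sigma_cm), class_of = class index
# per column).
component_log_terms <- function(res, priors, params, mask_idx) {
  cols <- list()
  class_of <- integer(0)
  for (ci in seq_along(params$classes)) {
    cl <- params$classes[ci]
    cp <- params$components[[cl]]
    lp <- log(pmax(priors[[cl]][mask_idx], 0))
    for (m in seq_along(cp$w)) {
      cols[[length(cols) + 1L]] <-
        lp + log(cp$w[m]) + dnorm(res, cp$mu[m], cp$sigma[m], log = TRUE)
      class_of <- c(class_of, ci)
    }
  }
  list(mat = do.call(cbind, cols), class_of = class_of)
}

#' GMM log-likelihood and class responsibilities
#'
#' Evaluates, per masked voxel, the log-likelihood of the bias-corrected
#' log-intensity under the prior-weighted Gaussian mixture, together with
#' the posterior tissue-class probabilities ("responsibilities"). Voxels
#' with zero prior mass across all classes are excluded (a warning reports
#' their count).
#'
#' @param log_image 3D array of log intensities (or an `image_volume`).
#' @param bias 3D array of the additive log-domain bias field (or `NULL`).
#' @param priors named list of class probability maps on the same grid.
#' @param params a [gaussian_params()] whose classes match `priors`.
#' @param mask logical array of voxels to evaluate (defaults to the volume's
#'   mask, else all voxels).
#' @return list with `loglik` (vector over used voxels), `resp` (matrix
#'   used-voxels x classes, rows summing to one), `mask_idx` (linear indices
#'   of used voxels) and `n_excluded`.
#' @export
gmm_log_likelihood <- function(log_image, bias, priors, params, mask = NULL) {
  if (inherits(log_image, "image_volume")) {
    if (is.null(mask)) mask <- log_image$mask
    log_image <- log_image$voxels
  }
  if (is.null(mask)) mask <- array(TRUE, dim(log_image))
  stopifnot(identical(dim(priors[[1]]), dim(log_image)))
  mask_idx <- which(mask)
  pm <- Reduce(`+`, lapply(params$classes, function(cl) priors[[cl]]))[mask_idx]
  zero <- pm <= 0
  if (any(zero)) {
    warning(sprintf("%d masked voxels with zero prior mass excluded", sum(zero)))
    mask_idx <- mask_idx[!zero]
  }
  res <- log_image[mask_idx]
  if (!is.null(bias)) res <- res - bias[mask_idx]
  lt <- component_log_terms(res, priors, params, mask_idx)
  ll <- logsumexp_mat(lt$mat)
  post <- exp(lt$mat - ll)
  nc <- length(params$classes)
  resp <- matrix(0, length(mask_idx), nc)
  for (ci in seq_len(nc))
    resp[, ci] <- rowSums(post[, lt$class_of == ci, drop = FALSE])
  colnames(resp) <- params$classes
  list(loglik = ll, resp = resp, mask_idx = mask_idx, n_excluded = sum(zero))
}

#' Membrane energy of a deformation field
#'
#' Sum over voxels and displacement components of the squared spatial
#' gradient (central finite differences, voxel units, replicate boundary).
#'
#' @param deformation a [deformation()] or a bare 4D displacement array
#'   (`dim x 3`, voxel units).
#' @return nonnegative scalar.
#' @export
membrane_energy <- function(deformation) {
  u <- if (inherits(deformation, "deformation")) deformation$disp else deformation
  stopifnot(length(dim(u)) == 4L, dim(u)[4] == 3L)
  e <- 0
  for (i in 1:3) {
    ui <- u[, , , i]
    for (ax in 1:3) e <- e + sum(central_diff(ui, ax)^2)
  }
  e
}

#' Evaluate the full segmentation objective
#'
#' Diagnostic evaluation of the model objective: the summed GMM
#' log-likelihood of the image under the warped class priors, minus
#' `lambda` times the membrane energy of the deformation.
#'
#' @inheritParams gmm_log_likelihood
#' @param deformation the deformation whose membrane energy regularizes the
#'   objective (may be `NULL` with `lambda = 0`).
#' @param lambda nonnegative regularization constant (default 0).
#' @return list with `data_term`, `regularizer`, `total`, `lambda`.
#' @export
evaluate_objective <- function(log_image, bias, priors, params, mask = NULL,
                               deformation = NULL, lambda = 0) {
  stopifnot(lambda >= 0)
  g <- gmm_log_likelihood(log_image, bias, priors, params, mask)
  data_term <- sum(g$loglik)
  reg <- if (lambda > 0) lambda * membrane_energy(deformation) else 0
  list(data_term = data_term, regularizer = reg,
       total = data_term - reg, lambda = lambda)
}
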