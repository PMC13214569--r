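#' Deformation: affine pre-alignment plus dense displacement
#'
#' Maps fixed-grid voxel coordinates to moving (atlas) coordinates via the
#' atlas-to-scan affine composed with `id + u`, where `u` is a dense
#' displacement field on the fixed grid in voxel units.
#'
#' @param pre_affine 4x4 affine taking atlas world coordinates to scan
#'   world coordinates.
#' @param disp 4D array (fixed grid dims x 3) of voxel displacements.
#' @param geom fixed-grid geometry.
#' @return an object of class `deformation`.
#' @export
deformation <- function(pre_affine, disp, geom) {
  stopifnot(length(dim(disp)) == 4L, dim(disp)[4] == 3L,
            all(dim(disp)[1:3] == geom$dim))
  if (any(!is.finite(disp))) stop("displacement must be finite everywhere")
  structure(list(pre_affine = as.matrix(pre_affine), disp = disp, geom = geom),
            class = "deformation")
}

identity_deformation <- function(geom, pre_affine = diag(4)) {
  deformation(pre_affine, array(0, c(geom$dim, 3L)), geom)
}

#' Registration configuration
#'
#' Defaults follow the tool's standard settings: Adam learning rate 0.5,
#' gradient smoothing sigma 1.0 voxels, warp smoothing sigma 0.25 voxels,
#' local correlation window 7 (radius 3), Dice term weight 2.5, pyramid
#' starting at ~4 mm per voxel and halving per level.
#'
#' @param optimizer_lr Adam step size (voxels).
#' @param smooth_grad_sigma Gaussian sigma (voxels) for gradient smoothing.
#' @param smooth_warp_sigma Gaussian sigma (voxels) for warp smoothing.
#' @param cc_kernel_size odd local-correlation window (>= 3).
#' @param rel_weight_labeldiff relative weight of the soft-Dice term.
#' @param pyramid_start_mm coarsest pyramid voxel size (mm).
#' @param pyramid_factor spacing factor between levels.
#' @param iterations_per_level iteration cap per pyramid level (default 20;
#'   a deliberately modest budget — beyond it the intensity term starts
#'   fitting noise texture, degrading the field while still improving the
#'   loss). Levels also stop early when the loss plateaus.
#' @return a list of class `registration_config`.
#' @export
registration_config <- function(optimizer_lr = 0.5, smooth_grad_sigma = 1.0,
                                smooth_warp_sigma = 0.25, cc_kernel_size = 7L,
                                rel_weight_labeldiff = 2.5,
                                pyramid_start_mm = 4.0, pyramid_factor = 2L,
                                iterations_per_level = 20L) {
  stopifnot(cc_kernel_size %% 2L == 1L, cc_kernel_size >= 3L,
            smooth_grad_sigma >= 0, smooth_warp_sigma >= 0, optimizer_lr > 0)
  structure(list(optimizer_lr = optimizer_lr,
                 smooth_grad_sigma = smooth_grad_sigma,
                 smooth_warp_sigma = smooth_warp_sigma,
                 cc_kernel_size = as.integer(cc_kernel_size),
                 rel_weight_labeldiff = rel_weight_labeldiff,
                 pyramid_start_mm = pyramid_start_mm,
                 pyramid_factor = as.integer(pyramid_factor),
                 iterations_per_level = as.integer(iterations_per_level)),
            class = "registration_config")
}

#' Affine initialization from matched structure centroids
#'
#' Least-squares affine mapping the probability-weighted centroids of atlas
#' structures (world coordinates) to the centroids of the corresponding
#' coarse-segmentation structures. With fewer than four non-degenerate
#' matches, or a rank-deficient system, falls back to a similarity
#' transform (weighted Procrustes).
#'
#' @param atlas_maps named list of atlas probability maps grouped to the
#'   coarse protocol (names = protocol label ids).
#' @param atlas_geom atlas grid geometry.
#' @param coarse_labels 3D integer array of coarse protocol labels.
#' @param coarse_geom its grid geometry.
#' @return list with `affine` (4x4, atlas world to scan world), `residual`
#'   (RMS centroid mismatch, mm) and `kind` (`"affine"` or `"similarity"`).
#' @export
affine_initialize <- function(atlas_maps, atlas_geom, coarse_labels, coarse_geom) {
  ids <- names(atlas_maps)
  X <- NULL; Y <- NULL; wts <- NULL
  for (id in ids) {
    m <- atlas_maps[[id]]
    tot <- sum(m)
    sel <- coarse_labels == as.integer(id)
    if (tot < 1e-6 || !any(sel)) next
    g <- grid_coords(dim(m))
    w <- as.vector(m) / tot
    ca <- c(sum(g$x * w), sum(g$y * w), sum(g$z * w))
    ca <- (atlas_geom$affine %*% c(ca, 1))[1:3]
    idxc <- which(sel, arr.ind = FALSE)
    gc <- grid_coords(dim(coarse_labels))
    cc <- c(mean(gc$x[idxc]), mean(gc$y[idxc]), mean(gc$z[idxc]))
    cc <- (coarse_geom$affine %*% c(cc, 1))[1:3]
    X <- rbind(X, ca); Y <- rbind(Y, cc); wts <- c(wts, tot)
  }
  if (is.null(X) || nrow(X) < 3L) stop("not enough matched structures for initialization")
  wts <- wts / sum(wts)
  fit_similarity <- function() {
    mx <- colSums(X * wts); my <- colSums(Y * wts)
    Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
    S <- t(Xc * wts) %*% Yc
    sv <- svd(S)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    s <- sum(diag(t(Yc) %*% (Xc * wts) %*% t(Rm))) / sum(wts * rowSums(Xc^2))
    A <- diag(4); A[1:3, 1:3] <- s * Rm; A[1:3, 4] <- my - s * Rm %*% mx
    list(A = A, kind = "similarity")
  }
  res <- if (nrow(X) >= 4L) {
    Xh <- cbind(X, 1)
    G <- t(Xh * wts) %*% Xh
    if (rcond(G) < 1e-10) fit_similarity()
    else {
      B <- solve(G, t(Xh * wts) %*% Y)   # 4 x 3
      A <- diag(4); A[1:3, ] <- t(B)
      list(A = A, kind = "affine")
    }
  } else fit_similarity()
  pred <- t(res$A[1:3, ] %*% t(cbind(X, 1)))
  rms <- sqrt(sum(wts * rowSums((pred - Y)^2)))
  list(affine = res$A, residual = rms, kind = res$kind)
}

# Local box-window statistics for LNCC. Returns means, variances (floored)
# and cross-covariance.
lncc_stats <- function(fixed, moving, w, floor_f, floor_m) {
  mf <- box_filter(fixed, w)
  mm <- box_filter(moving, w)
  vf <- pmax(box_filter(fixed^2, w) - mf^2, floor_f)
  vm <- pmax(box_filter(moving^2, w) - mm^2, floor_m)
  cv <- box_filter(fixed * moving, w) - mf * mm
  list(mf = mf, mm = mm, vf = vf, vm = vm, cv = cv)
}

#' Local normalized cross-correlation
#'
#' Mean over masked voxels of the squared local correlation coefficient,
#' computed with box-window local means and variances (window
#' `cc_kernel_size`); local variances are floored at `1e-6` times the
#' global variance. Invariant to locally affine intensity changes.
#'
#' @param fixed,moving 3D arrays (or `image_volume`s) on the same grid.
#' @param kernel_size odd window width (default 7, radius 3).
#' @param mask optional logical array (defaults to the fixed mask, else all).
#' @return scalar in `[0, 1]` (up to floor effects).
#' @export
lncc <- function(fixed, moving, kernel_size = 7L, mask = NULL) {
  if (inherits(fixed, "image_volume")) { if (is.null(mask)) mask <- fixed$mask; fixed <- fixed$voxels }
  if (inherits(moving, "image_volume")) moving <- moving$voxels
  if (is.null(mask)) mask <- array(TRUE, dim(fixed))
  st <- lncc_stats(fixed, moving, kernel_size,
                   1e-6 * max(var(as.vector(fixed)), .Machine$double.eps),
                   1e-6 * max(var(as.vector(moving)), .Machine$double.eps))
  r2 <- st$cv^2 / (st$vf * st$vm)
  mean(r2[mask])
}

# LNCC value and dS/dM (exact adjoint through the box windows).
lncc_force <- function(fixed, moving, w, mask) {
  floor_f <- 1e-6 * max(var(as.vector(fixed)), .Machine$double.eps)
  floor_m <- 1e-6 * max(var(as.vector(moving)), .Machine$double.eps)
  st <- lncc_stats(fixed, moving, w, floor_f, floor_m)
  r2 <- st$cv^2 / (st$vf * st$vm)
  n <- sum(mask)
  value <- sum(r2[mask]) / n
  msk <- array(as.numeric(mask), dim(fixed))
  counts <- box_filter(array(1, dim(fixed)), w, normalize = FALSE)
  a <- msk * 2 * st$cv / (st$vf * st$vm) / counts
  g <- msk * (-(st$cv^2) / (st$vf * st$vm^2)) / counts
  g[st$vm <= floor_m] <- 0
  force <- fixed * box_filter(a, w, normalize = FALSE) -
    box_filter(a * st$mf, w, normalize = FALSE) +
    2 * (moving * box_filter(g, w, normalize = FALSE) -
           box_filter(g * st$mm, w, normalize = FALSE))
  list(value = value, force = force / n)
}

#' Soft Dice over probabilistic label maps
#'
#' Mean over labels of `2 sum(pq) / (sum(p) + sum(q) + eps)`; labels with
#' zero mass in both maps are skipped.
#'
#' @param p_maps,q_maps named lists of probability maps on the same grid.
#' @param eps stabilizer (default 1e-6).
#' @return scalar in `[0, 1]`.
#' @export
soft_dice <- function(p_maps, q_maps, eps = 1e-6) {
  stopifnot(all(names(p_maps) == names(q_maps)))
  vals <- c()
  for (nm in names(p_maps)) {
    sp <- sum(p_maps[[nm]]); sq <- sum(q_maps[[nm]])
    if (sp == 0 && sq == 0) next
    vals <- c(vals, 2 * sum(p_maps[[nm]] * q_maps[[nm]]) / (sp + sq + eps))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# Soft Dice value and the per-label forces dD/dp_l.
soft_dice_force <- function(p_maps, q_maps, eps = 1e-6) {
  nms <- names(p_maps)
  used <- vapply(nms, function(nm) sum(p_maps[[nm]]) > 0 || sum(q_maps[[nm]]) > 0,
                 logical(1))
  L <- sum(used)
  forces <- vector("list", length(nms)); names(forces) <- nms
  vals <- numeric(0)
  for (nm in nms) {
    if (!used[[nm]]) { forces[[nm]] <- NULL; next }
    p <- p_maps[[nm]]; q <- q_maps[[nm]]
    den <- sum(p) + sum(q) + eps
    num <- 2 * sum(p * q)
    vals <- c(vals, num / den)
    forces[[nm]] <- (2 * q / den - num / den^2) / L
  }
  list(value = if (L) mean(vals) else NA_real_, forces = forces)
}

# Warp a level-grid channel by displacement u (voxel units, level grid).
warp_channel <- function(ch, u, coords) {
  array(interp_trilinear(ch, coords$x + u[, , , 1], coords$y + u[, , , 2],
                         coords$z + u[, , , 3], fill = 0), dim(ch))
}

#' Greedy multiscale diffeomorphic registration
#'
#' Registers the moving synthetic anatomical volume (plus protocol-grouped
#' atlas label maps) to the fixed scan by maximizing
#' `lncc + rel_weight_labeldiff * soft_dice` with respect to a dense
#' displacement field on the fixed grid. At each iteration the similarity
#' gradient is smoothed (`smooth_grad_sigma`), one Adam step is taken, the
#' incremental update is composed with the running warp, and the composed
#' field is smoothed (`smooth_warp_sigma`). Optimization proceeds coarse to
#' fine on a spacing-halving pyramid starting at ~`pyramid_start_mm`.
#'
#' @param fixed an `image_volume` (the scan; its mask defines the loss
#'   region, dilated by 3 voxels).
#' @param moving an `image_volume` (synthetic anatomical volume on the
#'   atlas grid).
#' @param moving_labels named list of atlas maps grouped to the coarse
#'   protocol (atlas grid; names = protocol ids).
#' @param fixed_labels 3D integer array of coarse protocol labels.
#' @param fixed_labels_geom geometry of `fixed_labels`.
#' @param pre_affine 4x4 atlas-to-scan world affine initialization.
#' @param config a [registration_config()].
#' @param verbose print per-level progress.
#' @return list with `deformation` (a [deformation()]), `loss_trace` (per
#'   level), and `jacobian_positive` (masked fraction with positive
#'   Jacobian determinant).
#' @export
run_multiscale_registration <- function(fixed, moving, moving_labels,
                                        fixed_labels, fixed_labels_geom,
                                        pre_affine = diag(4),
                                        config = registration_config(),
                                        verbose = FALSE) {
  fgeom <- grid_geometry(fixed)
  mgeom <- grid_geometry(moving)
  fl_geom <- fixed_labels_geom
  vmin <- min(fgeom$voxel_size)
  k_start <- max(0L, ceiling(log2(config$pyramid_start_mm / vmin)))
  label_ids <- names(moving_labels)
  q_onehot <- lapply(label_ids, function(id)
    array(as.numeric(fixed_labels == as.integer(id)), dim(fixed_labels)))
  names(q_onehot) <- label_ids
  mask_full <- if (is.null(fixed$mask)) array(TRUE, fgeom$dim) else fixed$mask

  u <- NULL
  prev_geom <- NULL
  loss_trace <- list()
  lr <- config$optimizer_lr
  for (k in seq(k_start, 0L)) {
    f <- config$pyramid_factor^k
    geom_l <- if (f > 1) downsample_geometry(fgeom, f) else fgeom
    sig <- if (f > 1) rep(f / 2.355, 3) else rep(0, 3)
    fx <- resample_to_geometry(
      if (f > 1) smooth_gaussian(fixed$voxels, sig) else fixed$voxels, fgeom, geom_l)
    mk <- resample_to_geometry(array(as.numeric(mask_full), fgeom$dim), fgeom, geom_l) >= 0.5
    mk_dil <- box_filter(array(as.numeric(mk), geom_l$dim), 7L, normalize = FALSE) > 0
    # moving channels pre-aligned to the level grid through the affine
    sig_m <- pmax(geom_l$voxel_size / mgeom$voxel_size / 2.355, 0)
    sig_m[sig_m <= 1 / 2.355] <- 0
    A_chain <- solve(mgeom$affine) %*% solve(pre_affine) %*% geom_l$affine
    gl <- grid_coords(geom_l$dim)
    ml_coords <- apply_affine(A_chain, gl$x, gl$y, gl$z)
    align <- function(ch, sg) {
      chs <- if (any(sg > 0)) smooth_gaussian(ch, sg) else ch
      array(interp_trilinear(chs, ml_coords$x, ml_coords$y, ml_coords$z, 0), geom_l$dim)
    }
    mv <- align(moving$voxels, sig_m)
    # The Dice term is used only at levels that sample the label maps
    # faithfully (level spacing not coarser than the label grid). At
    # coarser levels binary labels either alias (if resampled raw) or
    # acquire blur skirts whose soft-Dice optimum is a dilated, not an
    # aligned, map; those levels run on the intensity term alone. Both
    # Dice operands stay binary at source with matched ~1-voxel
    # interpolation transitions.
    use_dice <- all(geom_l$voxel_size <= fl_geom$voxel_size * 1.01)
    w_dice <- if (use_dice) config$rel_weight_labeldiff else 0
    mv_lab <- if (use_dice) lapply(moving_labels, align, sg = 0) else list()
    q_l <- if (use_dice) lapply(q_onehot, function(q)
      resample_to_geometry(q, fl_geom, geom_l)) else list()

    if (is.null(u)) {
      u <- array(0, c(geom_l$dim, 3L))
    } else {
      u_new <- array(0, c(geom_l$dim, 3L))
      for (i in 1:3) {
        ui <- resample_to_geometry(u[, , , i], prev_geom, geom_l)
        u_new[, , , i] <- ui * (prev_geom$voxel_size[i] / geom_l$voxel_size[i])
      }
      u <- u_new
    }
    coords <- grid_coords(geom_l$dim)
    coords <- list(x = array(coords$x, geom_l$dim), y = array(coords$y, geom_l$dim),
                   z = array(coords$z, geom_l$dim))
    n_it <- config$iterations_per_level
    madam <- array(0, c(geom_l$dim, 3L)); gref <- 0
    beta1 <- 0.95
    losses <- numeric(n_it)
    it <- 1L
    retried <- FALSE
    u_best <- u
    loss_best <- Inf
    while (it <= n_it) {
      wm <- warp_channel(mv, u, coords)
      wl <- lapply(mv_lab, warp_channel, u = u, coords = coords)
      lf <- lncc_force(fx, wm, config$cc_kernel_size, mk_dil)
      df <- if (use_dice) soft_dice_force(wl, q_l)
            else list(value = NA_real_, forces = list())
      loss <- -(lf$value + w_dice *
                  (if (is.na(df$value)) 0 else df$value))
      if (!is.finite(loss)) {
        if (!retried) { lr <- lr / 2; retried <- TRUE; next }
        stop(sprintf("non-finite registration loss at level %d iteration %d", k, it))
      }
      losses[it] <- loss
      if (loss < loss_best) { loss_best <- loss; u_best <- u }
      # stop the level once the loss plateaus (sliding-window criterion)
      if (it >= 12L) {
        recent <- mean(losses[(it - 3L):it])
        before <- mean(losses[(it - 7L):(it - 4L)])
        if (before - recent < 1e-4) { losses <- losses[seq_len(it)]; break }
      }
      g <- array(0, c(geom_l$dim, 3L))
      add_channel_grad <- function(g, W, force) {
        for (i in 1:3) g[, , , i] <- g[, , , i] + force * central_diff(W, i)
        g
      }
      g <- add_channel_grad(g, wm, lf$force)
      for (nm in names(df$forces)) {
        if (is.null(df$forces[[nm]])) next
        g <- add_channel_grad(g, wl[[nm]], w_dice * df$forces[[nm]])
      }
      mnum <- array(as.numeric(mk_dil), geom_l$dim)
      for (i in 1:3)
        g[, , , i] <- smooth_gaussian(g[, , , i] * mnum, rep(config$smooth_grad_sigma, 3))
      madam <- beta1 * madam + (1 - beta1) * g
      mh <- madam / (1 - beta1^it)
      # the momentum field is scaled so that the largest voxel displacement
      # seen so far maps to the (decaying) learning rate, the standard step
      # convention of greedy registration; as the gradient fades near
      # convergence the steps fade with it instead of wandering at full lr
      mnorm_max <- max(sqrt(mh[, , , 1]^2 + mh[, , , 2]^2 + mh[, , , 3]^2))
      gref <- max(gref, mnorm_max)
      # the learning rate is expressed in voxels of the input image, so
      # coarser levels take proportionally smaller (sub-voxel) steps
      lr_t <- (lr / f) * (0.02 + 0.98 * (n_it - it + 1) / n_it)
      step <- mh * (lr_t / (gref + 1e-12))
      # compose the (ascending) increment with the running warp
      u_old <- u
      for (i in 1:3) {
        comp <- interp_trilinear(u_old[, , , i],
                                 coords$x + step[, , , 1],
                                 coords$y + step[, , , 2],
                                 coords$z + step[, , , 3], fill = 0)
        u[, , , i] <- step[, , , i] + array(comp, geom_l$dim)
      }
      if (config$smooth_warp_sigma > 0)
        for (i in 1:3)
          u[, , , i] <- smooth_gaussian(u[, , , i], rep(config$smooth_warp_sigma, 3))
      it <- it + 1L
    }
    u <- u_best   # a level never ends worse than its best iterate
    loss_trace[[length(loss_trace) + 1L]] <- losses
    if (verbose)
      message(sprintf("level %d (factor %d): loss %.5f -> %.5f", k, f,
                      losses[1], loss_best))
    prev_geom <- geom_l
  }
  def <- deformation(pre_affine, u, fgeom)
  jac <- jacobian_map(def)
  jpos <- mean(jac$voxels[mask_full] > 0)
  list(deformation = def, loss_trace = loss_trace, jacobian_positive = jpos)
}

#' Jacobian determinant map of a deformation
#'
#' Determinant of the central-difference Jacobian of `id + u` per voxel.
#'
#' @param deformation a [deformation()].
#' @param log10 return `log10` of the determinant instead.
#' @return an `image_volume` on the fixed grid.
#' @export
jacobian_map <- function(deformation, log10 = FALSE) {
  u <- deformation$disp
  d <- dim(u)[1:3]
  J <- array(0, c(d, 3, 3))
  for (i in 1:3) for (ax in 1:3) {
    J[, , , i, ax] <- central_diff(u[, , , i], ax) + as.numeric(i == ax)
  }
  det <- J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
         J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
         J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
  if (log10) det <- log(det, base = 10)
  image_volume(det, affine = deformation$geom$affine)
}
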