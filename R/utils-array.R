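#' @useDynLib histoseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median qnorm quantile rnorm runif cor dnorm var sd
#' @importFrom utils read.csv write.csv
NULL

# Contract `arr` along `axis` with matrix M (m x dim(arr)[axis]); the axis
# length becomes m. Implemented as a BLAS matrix product.
axis_apply <- function(arr, M, axis) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, ncol(M) == d[axis])
  if (axis == 1L) {
    out <- M %*% matrix(arr, d[1L])
    dim(out) <- c(nrow(M), d[2L], d[3L])
    out
  } else if (axis == 2L) {
    a <- aperm(arr, c(2L, 1L, 3L))
    out <- M %*% matrix(a, d[2L])
    dim(out) <- c(nrow(M), d[1L], d[3L])
    aperm(out, c(2L, 1L, 3L))
  } else {
    out <- matrix(arr, d[1L] * d[2L]) %*% t(M)
    dim(out) <- c(d[1L], d[2L], nrow(M))
    out
  }
}

# n x n Gaussian smoothing matrix, kernel truncated at 4 sigma, rows
# renormalized at the boundary (mass-preserving for constant inputs).
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  idx <- seq_len(n)
  M <- outer(idx, idx, function(i, j) {
    d <- i - j
    ifelse(abs(d) <= r, exp(-0.5 * (d / sigma)^2), 0)
  })
  M / rowSums(M)
}

# n x n mean-filter matrix with window width w (odd), renormalized at the
# boundary so rows always average over the in-grid part of the window.
box_matrix <- function(n, w, normalize = TRUE) {
  r <- (w - 1L) %/% 2L
  idx <- seq_len(n)
  M <- outer(idx, idx, function(i, j) as.numeric(abs(i - j) <= r))
  if (normalize) M / rowSums(M) else M
}

smooth_gaussian <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma[ax] > 0) arr <- axis_apply(arr, gauss_matrix(d[ax], sigma[ax]), ax)
  }
  arr
}

box_filter <- function(arr, w, normalize = TRUE) {
  w <- rep_len(w, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (w[ax] > 1L) arr <- axis_apply(arr, box_matrix(d[ax], w[ax], normalize), ax)
  }
  arr
}

# Central-difference derivative along one axis, replicate boundary
# (one-sided half-step at the edges), voxel units.
central_diff <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n == 1L) return(array(0, d))
  ip <- c(2:n, n)
  im <- c(1L, 1:(n - 1L))
  D <- matrix(0, n, n)
  D[cbind(seq_len(n), ip)] <- D[cbind(seq_len(n), ip)] + 0.5
  D[cbind(seq_len(n), im)] <- D[cbind(seq_len(n), im)] - 0.5
  axis_apply(arr, D, axis)
}

# 0-based voxel coordinates of every grid point, x fastest (column-major).
grid_coords <- function(dim) {
  list(
    x = rep.int(seq_len(dim[1L]) - 1, dim[2L] * dim[3L]),
    y = rep.int(rep(seq_len(dim[2L]) - 1, each = dim[1L]), dim[3L]),
    z = rep(seq_len(dim[3L]) - 1, each = dim[1L] * dim[2L])
  )
}

# Trilinear interpolation of 3D array `vol` at fractional 0-based voxel
# coordinates; out-of-grid samples return `fill`.
interp_trilinear <- function(vol, x, y, z, fill = 0) {
  stopifnot(length(dim(vol)) == 3L)
  if (any(!is.finite(x) & !is.na(x))) stop("non-finite interpolation coordinates")
  out <- interp3_cpp(as.double(vol), as.integer(dim(vol)),
                     as.double(x), as.double(y), as.double(z), as.double(fill))
  out
}

# Apply a 4x4 affine to 0-based voxel coordinates given as three vectors.
apply_affine <- function(A, x, y, z) {
  list(
    x = A[1, 1] * x + A[1, 2] * y + A[1, 3] * z + A[1, 4],
    y = A[2, 1] * x + A[2, 2] * y + A[2, 3] * z + A[2, 4],
    z = A[3, 1] * x + A[3, 2] * y + A[3, 3] * z + A[3, 4]
  )
}

logsumexp_mat <- function(M) {
  # rows: observations, cols: mixture members
  mx <- do.call(pmax, c(as.data.frame(M), list(na.rm = FALSE)))
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(M - mx)))
}

# Round doubles to float32 precision (storage precision of probability maps).
as_float32 <- function(x) {
  readBin(writeBin(as.double(x), raw(), size = 4L), what = "double",
          size = 4L, n = length(x))
}

# Run `expr` with a private RNG stream seeded by `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Replace values outside `mask` by a local average of masked values,
# growing outward iteratively (normalized 3^3 box diffusion). Prevents
# background values from bleeding into the foreground under blurring or
# interpolation. Voxels still unreached after `iters` get the masked median.
fill_from_mask <- function(arr, mask, iters = 8L) {
  m <- array(as.numeric(mask), dim(arr))
  v <- arr * m
  for (i in seq_len(iters)) {
    if (all(m > 0)) break
    num <- box_filter(v, 3L)
    den <- box_filter(m, 3L)
    new <- den > 1e-6 & m == 0
    v[new] <- num[new] / den[new]
    m[new] <- 1
  }
  if (any(m == 0)) v[m == 0] <- median(arr[mask])
  v
}

robust_range <- function(x) {
  q <- quantile(x, c(0.001, 0.999), names = FALSE, na.rm = TRUE)
  max(q[2] - q[1], .Machine$double.eps)
}
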