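#' Per-label Dice scores between two segmentations
#'
#' `Dice_k = 2|A∩B| / (|A| + |B|)` per label, after optionally clustering
#' the labels of `seg_a` through a many-to-one mapping (applied to `seg_a`
#' only, before comparison). Labels absent from both volumes are excluded.
#'
#' @param seg_a,seg_b 3D integer label volumes on the same grid.
#' @param cluster_map optional named integer vector mapping `seg_a` labels
#'   to the label space of `seg_b`.
#' @return data.frame with `label`, `dice`, plus attributes `mean` and `sd`.
#' @export
dice_scores <- function(seg_a, seg_b, cluster_map = NULL) {
  if (!identical(dim(seg_a), dim(seg_b))) stop("segmentations are on different grids")
  a <- as.vector(seg_a)
  b <- as.vector(seg_b)
  if (!is.null(cluster_map)) {
    m <- a %in% as.integer(names(cluster_map))
    a[m] <- as.integer(cluster_map[as.character(a[m])])
  }
  labs <- sort(setdiff(union(unique(a), unique(b)), 0L))
  d <- vapply(labs, function(l) {
    na <- sum(a == l); nb <- sum(b == l)
    if (na + nb == 0L) return(NA_real_)
    2 * sum(a == l & b == l) / (na + nb)
  }, numeric(1))
  out <- data.frame(label = labs, dice = d)
  out <- out[!is.na(out$dice), , drop = FALSE]
  attr(out, "mean") <- mean(out$dice)
  attr(out, "sd") <- sd(out$dice)
  out
}

#' Test-retest intra-class correlation of ROI volumes
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1)) per ROI, computed from the subject-by-session mean squares.
#'
#' @param test,retest data.frames of volumes: one row per subject, one
#'   column per ROI (same column order), or matrices.
#' @return named numeric vector of ICC values in `[-1, 1]`.
#' @export
icc_volumes <- function(test, retest) {
  test <- as.matrix(test); retest <- as.matrix(retest)
  stopifnot(all(dim(test) == dim(retest)))
  n <- nrow(test)
  if (n < 5L) stop("need at least 5 paired subjects")
  k <- 2
  vapply(seq_len(ncol(test)), function(j) {
    Y <- cbind(test[, j], retest[, j])
    gm <- mean(Y)
    sm <- rowMeans(Y)   # subject means
    mm <- colMeans(Y)   # session means
    MSR <- k * sum((sm - gm)^2) / (n - 1)
    MSC <- n * sum((mm - gm)^2) / (k - 1)
    SSE <- sum((Y - outer(sm, rep(1, k)) - outer(rep(1, n), mm) + gm)^2)
    MSE <- SSE / ((n - 1) * (k - 1))
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  }, numeric(1)) |> stats::setNames(colnames(test))
}

#' Rank correlation of ROI volumes with a covariate
#'
#' Spearman correlation (average ranks for ties) of each ROI's volume with
#' a subject covariate such as age. ROIs with constant volumes yield `NA`.
#'
#' @param volumes matrix/data.frame, one row per subject, one column per ROI.
#' @param covariate numeric vector, one value per subject (>= 10 subjects).
#' @return named numeric vector of Spearman rho per ROI.
#' @export
volume_covariate_correlation <- function(volumes, covariate) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) < 10L) stop("need at least 10 subjects")
  stopifnot(length(covariate) == nrow(volumes))
  vapply(seq_len(ncol(volumes)), function(j) {
    v <- volumes[, j]
    if (sd(v) == 0) return(NA_real_)
    suppressWarnings(cor(v, covariate, method = "spearman"))
  }, numeric(1)) |> stats::setNames(colnames(volumes))
}
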