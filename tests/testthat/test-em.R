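test_that("EM fixed point and parameter recovery", {
  d <- c(12L, 12L, 12L)
  set.seed(14)
  # one-hot priors with data exactly at the initialization
  lab <- array(1L + (histoseg:::grid_coords(d)$x >= 6), d)
  pri <- list(a = array(as.numeric(lab == 1L), d),
              b = array(as.numeric(lab == 2L), d))
  y <- array(ifelse(lab == 1L, rnorm(prod(d), 4, 0.2), rnorm(prod(d), 5, 0.3)), d)
  init <- gaussian_params(list(
    a = list(w = 1, mu = mean(y[lab == 1L]), sigma = sd(y[lab == 1L])),
    b = list(w = 1, mu = mean(y[lab == 2L]), sigma = sd(y[lab == 2L]))))
  fit <- fit_gmm_em(y, pri, init, max_iter = 3L)
  expect_equal(fit$params$components$a$mu, init$components$a$mu, tolerance = 1e-5)
  expect_equal(fit$params$components$b$sigma, init$components$b$sigma,
               tolerance = 1e-3)

  # well-separated two-class mixture: parameters recovered from soft priors
  set.seed(15)
  pa <- histoseg:::smooth_gaussian(array(runif(prod(d)), d), rep(2, 3))
  pa <- (pa - min(pa)) / diff(range(pa))
  pa <- 0.05 + 0.9 * pa
  truth_lab <- array(runif(prod(d)) < pa, d)
  mu_t <- c(4, 5.2); sd_t <- c(0.15, 0.2)
  y2 <- array(ifelse(truth_lab, rnorm(prod(d), mu_t[1], sd_t[1]),
                     rnorm(prod(d), mu_t[2], sd_t[2])), d)
  pri2 <- list(a = array(pa, d), b = array(1 - pa, d))
  init2 <- gaussian_params(list(a = list(w = 1, mu = 4.2, sigma = 0.3),
                                b = list(w = 1, mu = 5.0, sigma = 0.3)))
  fit2 <- fit_gmm_em(y2, pri2, init2)
  expect_lt(abs(fit2$params$components$a$mu - mu_t[1]) / mu_t[1], 0.02)
  expect_lt(abs(fit2$params$components$b$mu - mu_t[2]) / mu_t[2], 0.02)
  expect_lt(abs(fit2$params$components$a$sigma - sd_t[1]) / sd_t[1], 0.05)

  # stride subsampling changes the estimates only marginally
  fit3 <- fit_gmm_em(y2, pri2, init2, skip = 2L)
  expect_lt(abs(fit3$params$components$a$mu - fit2$params$components$a$mu) /
              abs(fit2$params$components$a$mu), 0.01)
})

test_that("posterior redistribution follows atlas proportions and conserves mass", {
  d <- c(8L, 8L, 8L)
  grouping <- label_grouping(c("g", "w"),
                             list(`1` = "g", `2` = "g", `3` = "w"))
  # atlas proportions 0.75/0.25 for the two ROIs of class g
  f1 <- array(0.6, d); f2 <- array(0.2, d); f3 <- array(0.2, d)
  fine <- list(`1` = f1, `2` = f2, `3` = f3)
  mask_idx <- seq_len(prod(d))
  resp <- cbind(g = rep(0.8, prod(d)), w = rep(0.2, prod(d)))
  post <- redistribute_posteriors(resp, mask_idx, fine, grouping, d)
  expect_equal(post[["1"]]$values[1], 0.8 * 0.75)
  expect_equal(post[["2"]]$values[1], 0.8 * 0.25)
  # class with a single ROI: posterior equals the class responsibility
  expect_equal(post[["3"]]$values[1], 0.2)

  # conservation on a phantom, verified voxel by voxel
  ph <- small_phantom()
  maps <- lapply(ph$atlas$labels$id, function(id)
    histoseg:::atlas_dense_map(ph$atlas, id))
  names(maps) <- ph$atlas$labels$id
  dd <- ph$atlas$grid_shape
  tot <- Reduce(`+`, maps)
  midx <- which(tot > 0.5)
  set.seed(3)
  rr <- matrix(runif(length(midx) * 4), ncol = 4)
  rr <- rr / rowSums(rr)
  colnames(rr) <- ph$grouping$classes
  post2 <- redistribute_posteriors(rr, midx, maps, ph$grouping, dd)
  for (cl in ph$grouping$classes) {
    ids <- as.character(ph$atlas$labels$id[ph$atlas$labels$class == cl])
    s <- histoseg:::sparse_sum(post2[ids], dd)[midx]
    has_atlas <- Reduce(`+`, maps[ids])[midx] > 0
    expect_lt(max(abs(s - rr[, cl])[has_atlas]), 1e-6)
  }
})

test_that("hard segmentation takes the argmax with deterministic ties", {
  d <- c(6L, 6L, 6L)
  one <- list(`4` = array(1, d))
  expect_true(all(hard_segmentation(one) == 4L))

  # exact tie between labels 5 and 9 resolves to 5
  tie <- list(`9` = array(0.5, d), `5` = array(0.5, d))
  expect_true(all(hard_segmentation(tie) == 5L))

  # random posteriors match a brute-force argmax oracle
  set.seed(6)
  ps <- lapply(1:5, function(i) array(runif(prod(d)) / 5, d))
  names(ps) <- as.character(c(3, 7, 2, 9, 11))
  hs <- hard_segmentation(ps)
  stack <- sapply(ps, as.vector)
  bg <- 1 - rowSums(stack)
  oracle <- integer(prod(d))
  for (j in seq_len(prod(d))) {
    vals <- c(bg[j], stack[j, ])
    k <- which.max(vals)
    oracle[j] <- if (k == 1L) 0L else as.integer(names(ps)[k - 1L])
  }
  expect_identical(as.vector(hs), oracle)

  # masked-out voxels get the background label
  m <- array(TRUE, d); m[1, 1, 1] <- FALSE
  expect_equal(hard_segmentation(one, mask = m)[1, 1, 1], 0L)
})

test_that("soft volumes scale with probability and voxel size", {
  d <- c(20L, 10L, 5L)
  p <- array(0, d); p[seq_len(1000)] <- 1
  vols <- roi_volumes(list(`1` = p), voxel_size = rep(0.4, 3))
  expect_equal(vols$volume_mm3, 1000 * 0.4^3)   # 64 mm^3

  half <- roi_volumes(list(`1` = p / 2), voxel_size = rep(0.4, 3))
  expect_equal(half$volume_mm3, vols$volume_mm3 / 2)

  # soft volumes of sampled phantom ROIs track ground-truth voxel counts
  sam <- small_sample()
  ph <- small_phantom()
  maps <- lapply(ph$atlas$labels$id, function(id)
    histoseg:::atlas_dense_map(ph$atlas, id))
  names(maps) <- ph$atlas$labels$id
  counts <- table(factor(sam$truth$labels[sam$truth$labels > 0],
                         levels = ph$atlas$labels$id))
  vox <- prod(histoseg:::atlas_geometry(ph$atlas)$voxel_size)
  # expected (soft, deformed-atlas) volumes vs realized sampled counts
  warped <- warp_atlas_sparse(ph$atlas, sam$truth$deformation,
                              histoseg:::atlas_geometry(ph$atlas))
  vv <- roi_volumes(warped, histoseg:::atlas_geometry(ph$atlas)$voxel_size)
  big <- as.integer(names(counts))[counts > 500]
  for (id in big) {
    expect_lt(abs(vv$volume_mm3[vv$label_id == id] / vox - counts[[as.character(id)]]) /
                counts[[as.character(id)]], 0.1)
  }
})
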