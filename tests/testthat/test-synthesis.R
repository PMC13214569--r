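test_that("robust statistics are robust and equivariant", {
  d <- c(12L, 12L, 12L)
  lab <- array(0L, d)
  lab[2:6, 2:6, 2:6] <- 1L
  lab[8:11, 8:11, 8:11] <- 2L
  vals <- array(rnorm(prod(d), 50, 5), d)
  vals[lab == 1L] <- 7   # constant region
  proto <- data.frame(id = 1:2, name = c("flat", "noisy"))
  st <- robust_stats(vals, lab, proto)
  expect_equal(st$median[1], 7)
  expect_gt(st$sd[1], 0)          # floored, never zero
  expect_true(all(st$usable))

  # consistency for a Gaussian at n = 1e6: median ~ 0, scaled MAD ~ 1
  x <- with_seed_test(77, rnorm(1e6))
  m <- median(x)
  s <- 1.4826 * median(abs(x - m))
  expect_lt(abs(m), 0.01)
  expect_lt(abs(s - 1), 0.01)

  # 10% gross one-sided outliers at +100: the mean would shift by 10,
  # the median only to the 5/9 quantile of the clean sample (~0.1397,
  # closed form qnorm(0.5/0.9)), and the scaled MAD stays within ~13%
  xo <- x
  xo[seq_len(1e5)] <- xo[seq_len(1e5)] + 100
  mo <- median(xo)
  so <- 1.4826 * median(abs(xo - mo))
  expect_equal(mo - m, qnorm(0.5 / 0.9), tolerance = 0.05)
  expect_lt(abs(so / s - 1), 0.15)
  expect_gt(mean(xo) - mean(x), 9)

  # affine intensity equivariance: stats(aI + b) = (a m + b, |a| s)
  st1 <- robust_stats(vals, lab, proto)
  st2 <- robust_stats(-2.5 * vals + 7, lab, proto)
  expect_equal(st2$median, -2.5 * st1$median + 7, tolerance = 1e-9)
  expect_equal(st2$sd[2], 2.5 * st1$sd[2], tolerance = 1e-9)

  # structures under 10 voxels are flagged unusable
  lab[lab == 2L] <- 0L
  lab[1, 1, 1:3] <- 2L
  st3 <- robust_stats(vals, lab, proto)
  expect_false(st3$usable[2])
})

test_that("recipe rules combine reference medians linearly", {
  stats <- data.frame(id = 1:3, name = c("gray", "white", "dark"),
                      n = c(100, 100, 5), median = c(80, 120, 30),
                      sd = c(4, 5, 2), usable = c(TRUE, TRUE, FALSE))
  grouping <- label_grouping(c("g", "w", "mix"),
                             list(`1` = "g", `2` = "w", `3` = "mix"))
  rec <- intensity_recipe(list(g = c(gray = 1), w = c(white = 1),
                               mix = c(gray = 0.5, white = 0.5)))
  cm <- class_means_from_recipe(stats, rec, grouping)
  expect_equal(unname(cm), c(80, 120, 100))

  # unusable reference dropped, weights rescaled, with a warning
  rec2 <- intensity_recipe(list(g = c(gray = 1), w = c(white = 1),
                                mix = c(gray = 0.5, dark = 0.5)))
  expect_warning(cm2 <- class_means_from_recipe(stats, rec2, grouping), "unusable")
  expect_equal(unname(cm2["mix"]), 80)   # rescaled to full weight on gray

  expect_error(class_means_from_recipe(stats, intensity_recipe(list(g = c(gray = 1))),
                                       grouping), "without a recipe")
})

test_that("synthesize_volume renders the expectation image", {
  d <- c(10L, 10L, 10L)
  geom <- list(dim = d, affine = diag(4), voxel_size = c(1, 1, 1))
  one <- list(a = array(1, d))
  v1 <- synthesize_volume(one, c(a = 42), geom)
  expect_true(all(v1$voxels == 42))

  half <- list(a = array(0.5, d), b = array(0.5, d))
  v2 <- synthesize_volume(half, c(a = 100, b = 200), geom)
  expect_true(all(abs(v2$voxels - 150) < 1e-12))

  # dense dot-product oracle on phantom class maps
  ph <- small_phantom()
  maps <- group_probabilities(ph$atlas, ph$grouping)
  mu <- stats::setNames(c(110, 170, 80, 230), ph$grouping$classes)
  v3 <- synthesize_volume(maps, mu, histoseg:::atlas_geometry(ph$atlas))
  j <- sample(prod(dim(v3$voxels)), 20)
  oracle <- rowSums(sapply(seq_along(maps),
                           function(i) maps[[i]][j] * mu[[names(maps)[i]]]))
  expect_equal(v3$voxels[j], oracle, tolerance = 1e-12)
  # for non-overlapping class maps, the class-weighted mean intensity of
  # the rendered volume equals the recipe mean exactly
  oh <- list(a = array(0, d), b = array(0, d))
  oh$a[1:5, , ] <- 1; oh$b[6:10, , ] <- 1
  v4 <- synthesize_volume(oh, c(a = 90, b = 210), geom)
  expect_equal(sum(v4$voxels * oh$a) / sum(oh$a), 90, tolerance = 1e-6)
  expect_equal(sum(v4$voxels * oh$b) / sum(oh$b), 210, tolerance = 1e-6)
})

test_that("match_resolution anti-aliases on the way down", {
  d <- c(24L, 24L, 24L)
  img <- image_volume(array(100, d), voxel_size = c(1, 1, 1))
  same <- match_resolution(img, 1)
  expect_lt(max(abs(same$voxels - img$voxels)), 1e-6)

  down <- match_resolution(img, 2)
  expect_equal(dim(down$voxels), c(12L, 12L, 12L))
  expect_lt(max(abs(down$voxels - 100)), 1e-9)   # constants preserved

  # Nyquist-rate stripes lose most amplitude under 2x downsampling
  stripes <- array(rep(c(0, 200), length.out = prod(d)), d)
  simg <- image_volume(stripes, voxel_size = c(1, 1, 1))
  sd0 <- sd(simg$voxels)
  sdn <- sd(match_resolution(simg, 2)$voxels)
  expect_lt(sdn / sd0, 0.3)
})
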