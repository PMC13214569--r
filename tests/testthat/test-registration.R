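test_that("LNCC is maximal for intensity-affine copies, low for noise", {
  set.seed(2)
  d <- c(16L, 16L, 16L)
  img <- histoseg:::smooth_gaussian(array(rnorm(prod(d)), d), rep(1.5, 3))
  expect_equal(lncc(img, img), 1, tolerance = 1e-4)

  # global affine rescale a*I + b: exact invariance
  expect_equal(lncc(img, 2.3 * img + 5), 1, tolerance = 1e-3)
  # region-wise affine rescale: invariance everywhere except the few
  # windows straddling the region boundary
  scale <- array(1, d); scale[1:8, , ] <- 2.3
  offs <- array(0, d); offs[, 9:16, ] <- 5
  expect_gt(lncc(img, scale * img + offs), 0.6)

  noise <- array(rnorm(prod(d)), d)
  expect_lt(lncc(img, noise), 0.1)
})

test_that("soft Dice anchors: identity, disjoint, half overlap", {
  d <- c(12L, 12L, 12L)
  p <- array(0, d); p[3:8, 3:8, 3:8] <- 1
  expect_equal(soft_dice(list(a = p), list(a = p)), 1, tolerance = 1e-6)

  q <- array(0, d); q[9:12, 9:12, 9:12] <- 1
  expect_lt(soft_dice(list(a = p), list(a = q)), 1e-6)

  # equal cubes sharing half their extent along one axis
  p2 <- array(0, d); p2[1:6, 1:6, 1:6] <- 1
  q2 <- array(0, d); q2[4:9, 1:6, 1:6] <- 1
  expect_equal(soft_dice(list(a = p2), list(a = q2)), 0.5, tolerance = 1e-3)

  # labels empty on both sides are skipped
  expect_equal(soft_dice(list(a = p, z = array(0, d)),
                         list(a = p, z = array(0, d))), 1, tolerance = 1e-6)
})

test_that("Jacobian determinant map: identity, expansion, analytic", {
  d <- c(10L, 10L, 10L)
  geom <- list(dim = d, affine = diag(4), voxel_size = c(1, 1, 1))
  ident <- histoseg:::identity_deformation(geom)
  expect_true(all(abs(jacobian_map(ident)$voxels - 1) < 1e-12))
  expect_true(all(abs(jacobian_map(ident, log10 = TRUE)$voxels) < 1e-12))

  # u = 0.1 * x: interior determinant 1.1 along one axis
  def <- ident
  def$disp[, , , 1] <- array(rep(0.1 * (0:(d[1] - 1)), d[2] * d[3]), d)
  jm <- jacobian_map(def)$voxels
  expect_equal(jm[5, 5, 5], 1.1, tolerance = 1e-9)

  # isotropic expansion: det = 1.1^3 in the interior
  for (i in 1:3) {
    g <- histoseg:::grid_coords(d)
    def$disp[, , , i] <- array(0.1 * switch(i, g$x, g$y, g$z), d)
  }
  expect_equal(jacobian_map(def)$voxels[5, 5, 5], 1.1^3, tolerance = 1e-9)
})

test_that("warp smoothing never increases membrane energy", {
  set.seed(77)
  d <- c(12L, 12L, 12L)
  u <- array(rnorm(prod(d) * 3), c(d, 3L))
  e0 <- membrane_energy(u)
  us <- u
  for (i in 1:3) us[, , , i] <- histoseg:::smooth_gaussian(u[, , , i], rep(0.8, 3))
  expect_lt(membrane_energy(us), e0)
})

test_that("affine initialization recovers translations and scales", {
  ph <- small_phantom(seed = 11L, n_rois = 120L)
  geom <- histoseg:::atlas_geometry(ph$atlas)
  amaps <- histoseg:::group_to_protocol(ph$atlas, ph$roi_to_protocol)
  P <- sapply(amaps, as.vector)
  lab <- array(ifelse(rowSums(P) > 0.5,
                      as.integer(names(amaps))[max.col(P, ties.method = "first")], 0L),
               geom$dim)

  # already aligned: affine ~ identity
  a0 <- affine_initialize(amaps, geom, lab, geom)
  expect_lt(norm(a0$affine - diag(4), "F"), 0.05)

  # translated scan: translation recovered within 0.5 mm
  tgeom <- geom
  tgeom$affine[1:3, 4] <- tgeom$affine[1:3, 4] + c(5, -3, 2)
  a1 <- affine_initialize(amaps, geom, lab, tgeom)
  expect_lt(max(abs(a1$affine[1:3, 4] - c(5, -3, 2))), 0.5)
  expect_lt(norm(a1$affine[1:3, 1:3] - diag(3), "F"), 0.05)

  # isotropically scaled scan: scale recovered within 2%
  sgeom <- geom
  sgeom$affine[1:3, 1:3] <- 1.1 * sgeom$affine[1:3, 1:3]
  a2 <- affine_initialize(amaps, geom, lab, sgeom)
  sc <- det(a2$affine[1:3, 1:3])^(1 / 3)
  expect_lt(abs(sc - 1.1) / 1.1, 0.02)
})

test_that("registration of an image to itself stays near the identity", {
  ph <- small_phantom()
  geom <- histoseg:::atlas_geometry(ph$atlas)
  cmaps <- group_probabilities(ph$atlas, ph$grouping)
  mu <- stats::setNames(c(110, 170, 80, 230), ph$grouping$classes)
  synth <- synthesize_volume(cmaps, mu, geom)
  amaps <- histoseg:::group_to_protocol_onehot(ph$atlas, ph$roi_to_protocol)
  dice_ids <- ph$protocol$id[ph$protocol$dice]
  amaps <- amaps[names(amaps) %in% as.character(dice_ids)]
  P <- sapply(amaps, as.vector)
  lab <- array(ifelse(rowSums(P) > 0.5,
                      as.integer(names(amaps))[max.col(P, ties.method = "first")], 0L),
               geom$dim)
  fixed <- image_volume(synth$voxels, affine = geom$affine,
                        mask = Reduce(`+`, cmaps) > 0.5)
  cfg <- registration_config(iterations_per_level = 30L)
  reg <- run_multiscale_registration(fixed, synth, amaps, lab, geom,
                                     pre_affine = diag(4), config = cfg)
  u <- reg$deformation$disp
  expect_lt(mean(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)), 0.1)
  expect_gte(reg$jacobian_positive, 0.999)

  # determinism: identical inputs give bit-identical fields
  reg2 <- run_multiscale_registration(fixed, synth, amaps, lab, geom,
                                      pre_affine = diag(4), config = cfg)
  expect_lt(max(abs(reg2$deformation$disp - reg$deformation$disp)), 1e-5)
})
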