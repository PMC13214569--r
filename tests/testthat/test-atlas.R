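test_that("atlas save/load round-trips bit-exactly", {
  # single uniform ROI
  d <- c(32L, 32L, 32L)
  vals <- array(0.5, d)
  labels <- data.frame(id = 1L, name = "all", R = 10L, G = 20L, B = 30L,
                       class = "a")
  atl <- probabilistic_atlas(d, diag(4), 1, labels,
                             list(list(label_id = 1L, lo = c(0L, 0L, 0L),
                                       hi = d, values = vals)))
  td <- withr::local_tempdir()
  save_atlas(atl, td)
  back <- load_atlas(td)
  expect_identical(back$rois[[1]]$values, atl$rois[[1]]$values)
  expect_identical(back$labels$name, atl$labels$name)

  ph <- small_phantom()
  td2 <- withr::local_tempdir()
  save_atlas(ph$atlas, td2)
  back2 <- load_atlas(td2)
  expect_identical(lapply(back2$rois, `[[`, "values"),
                   lapply(ph$atlas$rois, `[[`, "values"))
  expect_identical(lapply(back2$rois, function(r) c(r$lo, r$hi)),
                   lapply(ph$atlas$rois, function(r) c(r$lo, r$hi)))
  expect_equal(back2$affine, ph$atlas$affine)
})

test_that("per-voxel ROI probabilities sum to at most one", {
  ph <- small_phantom()
  fg <- histoseg:::atlas_foreground(ph$atlas)
  expect_lte(max(fg), 1 + 1e-6)
  expect_gte(min(fg), 0)
})

test_that("padded boxes are re-tightened to the brute-force nonzero extent", {
  d <- c(16L, 16L, 16L)
  vals <- array(0, d)
  vals[5:9, 7:11, 3:6] <- 0.8
  labels <- data.frame(id = 3L, name = "blob", R = 0L, G = 0L, B = 0L, class = "a")
  atl <- probabilistic_atlas(d, diag(4), 1, labels,
                             list(list(label_id = 3L, lo = c(0L, 0L, 0L),
                                       hi = d, values = vals)))
  r <- atl$rois[[1]]
  nz <- which(vals != 0, arr.ind = TRUE)
  expect_equal(r$lo, as.integer(apply(nz, 2, min) - 1L))
  expect_equal(r$hi, as.integer(apply(nz, 2, max)))
  td <- withr::local_tempdir()
  save_atlas(atl, td)
  r2 <- load_atlas(td)$rois[[1]]
  expect_equal(r2$lo, r$lo)
  expect_equal(r2$hi, r$hi)
})

test_that("load_atlas rejects broken inputs", {
  ph <- small_phantom()
  td <- withr::local_tempdir()
  save_atlas(ph$atlas, td)
  file.remove(file.path(td, "roi_0001.json"))
  expect_error(load_atlas(td), "sidecar")
})

make_three_blob_atlas <- function() {
  d <- c(20L, 20L, 8L)
  mk <- function(xr) { v <- array(0, d); v[xr, 8:13, 3:6] <- 0.9; v }
  labels <- data.frame(id = 1:3, name = c("l", "m", "r"), R = 0L, G = 0L, B = 0L,
                       class = "a")
  probabilistic_atlas(d, diag(4), 1, labels, list(
    list(label_id = 1L, lo = c(0L, 0L, 0L), hi = d, values = mk(2:6)),
    list(label_id = 2L, lo = c(0L, 0L, 0L), hi = d, values = mk(9:12)),
    list(label_id = 3L, lo = c(0L, 0L, 0L), hi = d, values = mk(15:19))))
}

test_that("remove_and_inpaint reassigns mass to the nearest surviving ROI", {
  atl <- make_three_blob_atlas()

  # removing a zero-mass label changes only the label table
  d <- atl$grid_shape
  empty <- probabilistic_atlas(d, diag(4), 1,
    rbind(atl$labels, data.frame(id = 9L, name = "none", R = 0L, G = 0L, B = 0L,
                                 class = "a")),
    c(atl$rois, list(list(label_id = 9L, lo = c(0L, 0L, 0L), hi = d,
                          values = array(0, d)))))
  pruned <- remove_and_inpaint(empty, 9L)
  expect_equal(nrow(pruned$labels), 3L)
  expect_identical(lapply(pruned$rois, `[[`, "values"),
                   lapply(atl$rois, `[[`, "values"))

  # single survivor absorbs everything
  two <- remove_and_inpaint(atl, c(2L, 3L))
  tot_before <- histoseg:::atlas_foreground(atl)
  tot_after <- histoseg:::atlas_foreground(two)
  expect_lt(max(abs(tot_before - tot_after)), 1e-6)
  expect_equal(nrow(two$labels), 1L)

  # middle ROI removed: mass splits by brute-force nearest-survivor search
  res <- remove_and_inpaint(atl, 2L)
  mid <- histoseg:::atlas_dense_map(atl, 2L)
  # oracle: exhaustive nearest voxel whose modal label survives
  mode_lab <- array(0L, d); best <- array(0, d)
  for (id in 1:3) {
    m <- histoseg:::atlas_dense_map(atl, id)
    upd <- m > best; mode_lab[upd] <- id; best[upd] <- m[upd]
  }
  surv <- which(mode_lab %in% c(1L, 3L))
  co_surv <- arrayInd(surv, d)
  need <- which(mid > 0)
  co_need <- arrayInd(need, d)
  expected1 <- histoseg:::atlas_dense_map(atl, 1L)
  expected3 <- histoseg:::atlas_dense_map(atl, 3L)
  for (i in seq_along(need)) {
    d2 <- (co_surv[, 1] - co_need[i, 1])^2 + (co_surv[, 2] - co_need[i, 2])^2 +
      (co_surv[, 3] - co_need[i, 3])^2
    cand <- surv[d2 == min(d2)]
    donor <- min(mode_lab[cand])   # ties: lowest surviving label
    if (donor == 1L) expected1[need[i]] <- expected1[need[i]] + mid[need[i]]
    else expected3[need[i]] <- expected3[need[i]] + mid[need[i]]
  }
  got1 <- histoseg:::atlas_dense_map(res, 1L)
  got3 <- histoseg:::atlas_dense_map(res, 3L)
  expect_lt(max(abs(got1 - histoseg:::as_float32(expected1))), 1e-6)
  expect_lt(max(abs(got3 - histoseg:::as_float32(expected3))), 1e-6)

  expect_error(remove_and_inpaint(atl, 1:3), "every ROI")
})

test_that("group_probabilities sums ROI maps per class and conserves mass", {
  ph <- small_phantom()
  atl <- ph$atlas

  # one class holding every ROI equals the total foreground
  all_in_one <- label_grouping("only",
    stats::setNames(as.list(rep("only", nrow(atl$labels))), atl$labels$id))
  g1 <- group_probabilities(atl, all_in_one)
  expect_lt(max(abs(g1$only - histoseg:::atlas_foreground(atl))), 1e-6)

  # identity grouping reproduces the ROI maps
  ident <- label_grouping(as.character(atl$labels$id),
    stats::setNames(as.list(as.character(atl$labels$id)), atl$labels$id))
  g2 <- group_probabilities(atl, ident)
  expect_lt(max(abs(g2[["5"]] - histoseg:::atlas_dense_map(atl, 5L))), 1e-6)

  # class maps verified against dense summation
  g3 <- group_probabilities(atl, ph$grouping)
  for (cl in ph$grouping$classes) {
    ids <- atl$labels$id[atl$labels$class == cl]
    dense <- Reduce(`+`, lapply(ids, function(id) histoseg:::atlas_dense_map(atl, id)))
    expect_lt(max(abs(g3[[cl]] - dense)), 1e-6)
  }
  tot_classes <- sum(vapply(g3, sum, numeric(1)))
  expect_equal(tot_classes, sum(histoseg:::atlas_foreground(atl)),
               tolerance = 1e-5)

  bad <- label_grouping("a", list(`1` = "a"))
  expect_error(group_probabilities(atl, bad), "without a tissue class")
})

test_that("resample_atlas: identity, exact shifts, sum preservation", {
  ph <- small_phantom()
  atl <- ph$atlas
  geom <- histoseg:::atlas_geometry(atl)
  maps <- group_probabilities(atl, ph$grouping)

  ident <- histoseg:::identity_deformation(geom)
  out <- resample_atlas(maps, ident, geom, geom)
  expect_lt(max(abs(out[[1]] - maps[[1]])), 1e-6)

  # pure integer translation: maps shifted exactly
  def <- histoseg:::identity_deformation(geom)
  def$disp[, , , 1] <- 2   # sample source at x + 2
  out2 <- resample_atlas(maps, def, geom, geom)
  m <- maps[[2]]; d <- dim(m)
  shifted <- array(0, d)
  shifted[1:(d[1] - 2), , ] <- m[3:d[1], , ]
  expect_lt(max(abs(out2[[2]] - shifted)), 1e-6)

  # warped per-voxel sums stay at most 1
  def$disp[, , , 1] <- 1.7; def$disp[, , , 2] <- -0.9
  out3 <- resample_atlas(maps, def, geom, geom)
  s <- Reduce(`+`, out3)
  expect_lte(max(s), 1 + 1e-6)

  def$disp[1] <- NaN
  expect_error(resample_atlas(maps, def, geom, geom), "finite")
})

test_that("sparse warping agrees with dense resampling", {
  ph <- small_phantom()
  atl <- ph$atlas
  geom <- histoseg:::atlas_geometry(atl)
  def <- histoseg:::identity_deformation(geom)
  set.seed(11)
  for (i in 1:3)
    def$disp[, , , i] <- histoseg:::smooth_gaussian(array(rnorm(prod(geom$dim)),
                                                          geom$dim), rep(6, 3)) * 8
  sparse <- warp_atlas_sparse(atl, def, geom)
  dense <- resample_atlas(atl, def, geom)
  for (id in c("3", "11")) {
    w <- sparse[[id]]
    full <- array(0, geom$dim)
    full <- histoseg:::box_add(full, w, w$values)
    expect_lt(max(abs(full - dense[[id]])), 1e-6)
  }
})
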