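test_that("gmm_log_likelihood matches closed forms and normalizes", {
  d <- c(6L, 6L, 6L)
  # one class, flat prior, zero bias, standard normal at its mode
  pri <- list(a = array(1, d))
  par <- gaussian_params(list(a = list(w = 1, mu = 0, sigma = 1)))
  g <- gmm_log_likelihood(array(0, d), NULL, pri, par)
  expect_equal(g$loglik, rep(-0.5 * log(2 * pi), prod(d)))
  expect_equal(unname(g$resp[, 1]), rep(1, prod(d)))

  # two equally likely identical classes: responsibilities 0.5/0.5
  pri2 <- list(a = array(0.5, d), b = array(0.5, d))
  par2 <- gaussian_params(list(a = list(w = 1, mu = 2, sigma = 0.7),
                               b = list(w = 1, mu = 2, sigma = 0.7)))
  y <- with_seed_test(3, array(rnorm(prod(d), 2, 0.7), d))
  g2 <- gmm_log_likelihood(y, NULL, pri2, par2)
  expect_lt(max(abs(g2$resp - 0.5)), 1e-12)
})

test_that("responsibilities match a brute-force per-voxel oracle", {
  d <- c(5L, 4L, 3L)
  set.seed(42)
  pa <- array(runif(prod(d), 0.1, 0.6), d)
  pb <- array(runif(prod(d), 0.1, 0.35), d)
  pri <- list(a = pa, b = pb)
  par <- gaussian_params(list(
    a = list(w = c(0.3, 0.7), mu = c(1, 2), sigma = c(0.5, 1.2)),
    b = list(w = 1, mu = 3, sigma = 0.8)))
  y <- array(rnorm(prod(d), 2, 1), d)
  bias <- array(runif(prod(d), -0.2, 0.2), d)
  g <- gmm_log_likelihood(y, bias, pri, par)

  # oracle: direct density evaluation per voxel
  for (j in sample(prod(d), 12)) {
    r <- y[j] - bias[j]
    da <- pa[j] * (0.3 * dnorm(r, 1, 0.5) + 0.7 * dnorm(r, 2, 1.2))
    db <- pb[j] * dnorm(r, 3, 0.8)
    expect_equal(g$loglik[j], log(da + db), tolerance = 1e-10)
    expect_equal(unname(g$resp[j, "a"]), da / (da + db), tolerance = 1e-10)
  }
  expect_lt(max(abs(rowSums(g$resp) - 1)), 1e-6)

  # zero-prior voxels are excluded with a warning
  pa[1] <- 0; pb[1] <- 0
  expect_warning(g3 <- gmm_log_likelihood(y, bias, list(a = pa, b = pb), par),
                 "zero prior")
  expect_equal(g3$n_excluded, 1L)
})

test_that("membrane energy: identity, translation, analytic ramp", {
  d <- c(8L, 8L, 8L)
  geom <- list(dim = d, affine = diag(4), voxel_size = c(1, 1, 1))
  expect_equal(membrane_energy(histoseg:::identity_deformation(geom)), 0)

  u <- array(0, c(d, 3L))
  u[, , , 1] <- 3.2; u[, , , 2] <- -1.1   # uniform translation
  expect_equal(membrane_energy(u), 0)

  # linear ramp u_x = a*x: du/dx = a at interior, a/2 at replicate edges
  a <- 0.25
  u <- array(0, c(d, 3L))
  u[, , , 1] <- array(rep(a * (0:(d[1] - 1)), d[2] * d[3]), d)
  n <- prod(d)
  interior <- (d[1] - 2) * d[2] * d[3]
  edge <- 2 * d[2] * d[3]
  expect_equal(membrane_energy(u), interior * a^2 + edge * (a / 2)^2,
               tolerance = 1e-12)

  # brute-force oracle on a random smooth field
  set.seed(9)
  for (i in 1:3) u[, , , i] <- histoseg:::smooth_gaussian(array(rnorm(n), d), rep(2, 3))
  oracle <- 0
  for (i in 1:3) for (ax in 1:3) {
    ui <- u[, , , i]
    for (j in seq_len(n)) {
      co <- arrayInd(j, d)
      cp <- co; cp[ax] <- min(cp[ax] + 1L, d[ax])
      cm <- co; cm[ax] <- max(cm[ax] - 1L, 1L)
      oracle <- oracle + ((ui[cp[1], cp[2], cp[3]] - ui[cm[1], cm[2], cm[3]]) / 2)^2
    }
  }
  expect_equal(membrane_energy(u), oracle, tolerance = 1e-9)
})

test_that("evaluate_objective decomposes and is shift-equivariant", {
  d <- c(6L, 6L, 6L)
  set.seed(5)
  pri <- list(a = array(0.6, d), b = array(0.4, d))
  par <- gaussian_params(list(a = list(w = 1, mu = 4.2, sigma = 0.3),
                              b = list(w = 1, mu = 5.0, sigma = 0.4)))
  y <- array(rnorm(prod(d), 4.5, 0.5), d)
  geom <- list(dim = d, affine = diag(4), voxel_size = c(1, 1, 1))
  ident <- histoseg:::identity_deformation(geom)

  ob <- evaluate_objective(y, NULL, pri, par, deformation = ident, lambda = 0)
  g <- gmm_log_likelihood(y, NULL, pri, par)
  expect_equal(ob$total, sum(g$loglik))
  expect_equal(ob$regularizer, 0)

  ob2 <- evaluate_objective(y, NULL, pri, par, deformation = ident, lambda = 3)
  expect_equal(ob2$regularizer, 0)   # identity deformation

  # shift equivariance: same constant added to means and image
  c0 <- 1.37
  par_s <- gaussian_params(list(a = list(w = 1, mu = 4.2 + c0, sigma = 0.3),
                                b = list(w = 1, mu = 5.0 + c0, sigma = 0.4)))
  ob3 <- evaluate_objective(y + c0, NULL, pri, par_s, deformation = ident, lambda = 0)
  expect_equal(ob3$total, ob$total, tolerance = 1e-6)
})

test_that("EM iterations never decrease the objective", {
  d <- c(10L, 10L, 10L)
  set.seed(21)
  pa <- array(runif(prod(d), 0.2, 0.8), d)
  pri <- list(a = pa, b = 1 - pa)
  lab <- array(runif(prod(d)) < pa, d)
  y <- array(ifelse(lab, rnorm(prod(d), 4, 0.3), rnorm(prod(d), 5, 0.4)), d)
  init <- gaussian_params(list(a = list(w = 1, mu = 4.3, sigma = 0.5),
                               b = list(w = 1, mu = 4.7, sigma = 0.5)))
  fit <- fit_gmm_em(y, pri, init, max_iter = 20L, tol = 0)
  tr <- fit$loglik_trace
  expect_gte(length(tr), 10)
  drops <- diff(tr) / pmax(abs(tr[-length(tr)]), 1e-12)
  expect_gt(min(drops), -1e-8)
})
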