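test_that("full-sib relationship matrix has the stated closed form", {
  expect_equal(kinship_fullsib(3),
               matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3))
  expect_equal(kinship_fullsib(1), matrix(1, 1, 1))
  ev <- eigen(kinship_fullsib(10), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), sort(c(5.5, rep(0.5, 9))))
  expect_error(kinship_fullsib(0), "positive")
})

test_that("univariate REML recovers the simulated variance components", {
  ests <- t(vapply(1:40, function(r) {
    tr <- trial_config(n_blocks = 3, cuttings_per_plot = 5, n_traits = 1,
                       V_G = matrix(1), V_E = matrix(1), survival_rate = 1,
                       seed = 300 + r)
    ph <- simulate_rcbd_phenotypes(150, tr)
    X <- build_fixed_design(ph)$X
    f <- reml_univariate(ph$trait_1, X, ph$clone)
    c(f$sigma_g2, f$sigma_e2)
  }, numeric(2)))
  expect_equal(mean(ests[, 1]), 1, tolerance = 0.1)
  expect_equal(mean(ests[, 2]), 1, tolerance = 0.05)
})

test_that("sigma_g2 hits the zero boundary when there is no genetic signal", {
  tr <- trial_config(n_blocks = 2, cuttings_per_plot = 4, n_traits = 1,
                     V_G = matrix(0), V_E = matrix(1), survival_rate = 1,
                     seed = 55)
  ph <- simulate_rcbd_phenotypes(100, tr)
  f <- reml_univariate(ph$trait_1, build_fixed_design(ph)$X, ph$clone)
  expect_lt(f$h2, 0.05)
})

test_that("REML optimum is a local maximum of the restricted likelihood", {
  tr <- tiny_trial(t = 1, seed = 61)
  ph <- simulate_rcbd_phenotypes(80, tr)
  Y <- matrix(ph$trait_1)
  X <- build_fixed_design(ph)$X
  f <- reml_multivariate(Y, X, ph$clone, tol = 1e-12)
  sp <- leafgwas:::spectral_design(factor(ph$clone), kinship_fullsib(80))
  X1 <- leafgwas:::rotate1(sp, X)
  Y1 <- leafgwas:::rotate1(sp, Y)
  ll <- function(VG, VE) {
    leafgwas:::mv_em_step(VG, VE, X1, Y1,
                          crossprod(X) - crossprod(X1),
                          crossprod(X, Y) - crossprod(X1, Y1),
                          crossprod(Y) - crossprod(Y1),
                          sp$d, nrow(Y), 80, ncol(X), 1)$loglik
  }
  base <- ll(f$V_G, f$V_E)
  for (mult in c(0.9, 1.1)) {
    expect_lte(ll(f$V_G * mult, f$V_E), base + 1e-6)
    expect_lte(ll(f$V_G, f$V_E * mult), base + 1e-6)
  }
})

test_that("heritability follows its definition and rejects bad input", {
  expect_equal(heritability(1, 1), 0.5)
  expect_equal(heritability(0, 2), 0)
  expect_equal(heritability(3, 1), 0.75)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-1, 1), "non-negative")
})

test_that("multivariate REML at t = 1 equals the univariate fitter", {
  tr <- trial_config(n_blocks = 3, cuttings_per_plot = 4, n_traits = 1,
                     V_G = matrix(0.8), V_E = matrix(1.2), survival_rate = 1,
                     seed = 71)
  ph <- simulate_rcbd_phenotypes(120, tr)
  X <- build_fixed_design(ph)$X
  fu <- reml_univariate(ph$trait_1, X, ph$clone)
  fm <- reml_multivariate(matrix(ph$trait_1), X, ph$clone, tol = 1e-12,
                          maxit = 20000)
  expect_equal(as.numeric(fm$V_G), fu$sigma_g2, tolerance = 1e-6)
  expect_equal(as.numeric(fm$V_E), fu$sigma_e2, tolerance = 1e-6)
})

test_that("multivariate REML recovers t = 2 covariance components", {
  VG <- diag(c(1, 2)); VE <- diag(2)
  est_g <- array(0, c(2, 2, 25)); est_e <- est_g
  for (r in 1:25) {
    tr <- trial_config(n_blocks = 3, cuttings_per_plot = 5, n_traits = 2,
                       V_G = VG, V_E = VE, survival_rate = 1, seed = 500 + r)
    ph <- simulate_rcbd_phenotypes(150, tr)
    f <- reml_multivariate(as.matrix(ph[, c("trait_1", "trait_2")]),
                           build_fixed_design(ph)$X, ph$clone)
    est_g[, , r] <- f$V_G; est_e[, , r] <- f$V_E
  }
  mg <- apply(est_g, 1:2, mean); me <- apply(est_e, 1:2, mean)
  se_g <- apply(est_g, 1:2, sd) / sqrt(25)
  se_e <- apply(est_e, 1:2, sd) / sqrt(25)
  expect_true(all(abs(mg - VG) <= 3 * se_g + 1e-8))
  expect_true(all(abs(me - VE) <= 3 * se_e + 1e-8))
})

test_that("permuting trait order permutes the estimated components", {
  tr <- trial_config(n_blocks = 2, cuttings_per_plot = 3, n_traits = 3,
                     V_G = equicorr(3, 1, 0.4) + diag(c(0, .5, 1)),
                     V_E = equicorr(3, 1, 0.2), survival_rate = 1, seed = 81)
  ph <- simulate_rcbd_phenotypes(90, tr)
  X <- build_fixed_design(ph)$X
  Y <- as.matrix(ph[, trait_names(ph)])
  perm <- c(3, 1, 2)
  f1 <- reml_multivariate(Y, X, ph$clone, tol = 1e-11)
  f2 <- reml_multivariate(Y[, perm], X, ph$clone, tol = 1e-11)
  expect_equal(unname(f2$V_G), unname(f1$V_G[perm, perm]), tolerance = 1e-5)
  expect_equal(unname(f2$V_E), unname(f1$V_E[perm, perm]), tolerance = 1e-5)
})

test_that("EM increases the restricted likelihood monotonically", {
  tr <- tiny_trial(t = 2, seed = 91)
  ph <- simulate_rcbd_phenotypes(60, tr)
  Y <- as.matrix(ph[, trait_names(ph)])
  X <- build_fixed_design(ph)$X
  sp <- leafgwas:::spectral_design(factor(ph$clone), kinship_fullsib(60))
  X1 <- leafgwas:::rotate1(sp, X); Y1 <- leafgwas:::rotate1(sp, Y)
  Cxx0 <- crossprod(X) - crossprod(X1)
  Cxy0 <- crossprod(X, Y) - crossprod(X1, Y1)
  Cyy0 <- crossprod(Y) - crossprod(Y1)
  VG <- diag(2); VE <- diag(2)
  lls <- numeric(30)
  for (i in 1:30) {
    st <- leafgwas:::mv_em_step(VG, VE, X1, Y1, Cxx0, Cxy0, Cyy0, sp$d,
                                nrow(Y), 60, ncol(X), 2)
    lls[i] <- st$loglik
    VG <- st$V_G; VE <- st$V_E
  }
  expect_true(all(diff(lls) > -1e-8))
})
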