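test_that("fixed design has the expected column structure", {
  cr <- tiny_cross(n_clones = 60, m = 6, seed = 3)
  tr <- trial_config(n_blocks = 3, cuttings_per_plot = 2, n_traits = 1,
                     V_G = matrix(1), V_E = matrix(1), survival_rate = 1,
                     seed = 4)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  # 2-class SNP with 3 blocks: p = 1 + 2 + 1 = 4
  j <- which(cr$snps$type %in% c("aaxab", "abxaa"))[1]
  des <- build_fixed_design(ph, cr$geno[j, ])
  expect_equal(ncol(des$X), 4)
  expect_equal(length(des$geno_cols), 1)
  # monomorphic SNP: untestable
  mono <- setNames(rep("A/A", 60), colnames(cr$geno))
  expect_lt(build_fixed_design(ph, mono)$g, 2)
  # trees of missing-genotype clones are dropped
  cls <- cr$geno[j, ]
  cls[1:5] <- NA
  des2 <- build_fixed_design(ph, cls)
  expect_equal(length(des2$rows), sum(!ph$clone %in% colnames(cr$geno)[1:5]))
})

test_that("GLS with identity covariance reduces to OLS", {
  set.seed(5)
  n <- 12; Y <- matrix(rnorm(2 * n), n, 2)
  X <- cbind(1, rnorm(n))
  fit <- gls_fit(Y, X, diag(2 * n))
  ols <- qr.solve(X, Y)
  expect_equal(unname(fit$B_hat), unname(ols), tolerance = 1e-10)
  # intercept-only: trait means
  fit0 <- gls_fit(Y, matrix(1, n, 1), diag(2 * n))
  expect_equal(as.vector(fit0$B_hat), colMeans(Y))
})

test_that("GLS matches a direct dense solve of the vectorized equations", {
  set.seed(7)
  n <- 6; t <- 2; p <- 2
  Y <- matrix(rnorm(n * t), n, t)
  X <- cbind(1, rnorm(n))
  M <- matrix(rnorm((n * t)^2), n * t)
  V <- crossprod(M) / (n * t) + diag(n * t)
  fit <- gls_fit(Y, X, V)
  Xk <- kronecker(diag(t), X)
  Vi <- solve(V)
  b <- solve(t(Xk) %*% Vi %*% Xk, t(Xk) %*% Vi %*% as.vector(Y))
  expect_equal(as.vector(fit$B_hat), as.vector(b), tolerance = 1e-8)
  r <- as.vector(Y) - Xk %*% b
  expect_equal(fit$RSS, as.numeric(t(r) %*% Vi %*% r), tolerance = 1e-8)
})

test_that("univariate F equals the squared t statistic of one contrast", {
  set.seed(9)
  n <- 30
  X <- cbind(1, rbinom(n, 1, 0.5))
  y <- matrix(rnorm(n) + 0.5 * X[, 2])
  fit <- gls_fit(y, X, diag(n))
  ft <- f_test(fit, geno_cols = 2)
  tstat <- fit$B_hat[2, 1] / sqrt(fit$vcov[2, 2])
  expect_equal(ft$F, tstat^2, tolerance = 1e-10)
  expect_equal(ft$q, 1)
  expect_equal(ft$df2, n - 2)
})

test_that("degrees of freedom follow q = (g-1) t and df2 = t (n-p)", {
  cr <- tiny_cross(n_clones = 50, m = 6, seed = 13)
  tr <- trial_config(n_blocks = 3, cuttings_per_plot = 2, n_traits = 11,
                     survival_rate = 1, seed = 14)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  sc <- run_scan(ph, cr, m_independent = 6)
  two_class <- sc$g == 2
  expect_true(all(sc$q[two_class] == 11))
  expect_true(all(sc$df2 == 11 * (vapply(seq_len(nrow(sc)), function(i) {
    des <- build_fixed_design(ph, cr$geno[match(sc$snp_id[i], cr$snps$snp_id), ])
    length(des$rows) - ncol(des$X)
  }, numeric(1)))))
})

test_that("PVE follows 1 - RSS/RSS0 with clipping", {
  expect_equal(pve(1000, 1000), 0)
  expect_equal(pve(0, 1000), 1)
  expect_equal(pve(998, 1000), 0.002)
  expect_warning(out <- pve(1001, 1000), "clipped")
  expect_equal(out, 0)
  expect_error(pve(1, 0), "RSS0")
})

test_that("structured scan path equals the dense GLS oracle", {
  cr <- tiny_cross(n_clones = 25, m = 5, seed = 15)
  tr <- tiny_trial(t = 2, seed = 16)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  Y <- as.matrix(ph[, trait_names(ph)])
  clone <- factor(ph$clone)
  vc <- reml_multivariate(Y, build_fixed_design(ph)$X, clone)
  tw <- leafgwas:::mv_whiten(vc$V_G, vc$V_E)
  V <- leafgwas:::vec_covariance(vc$V_G, vc$V_E, clone)
  A <- kinship_fullsib(25)
  for (j in seq_len(5)) {
    des <- build_fixed_design(ph, cr$geno[j, ])
    if (des$g < 2) next
    X <- des$X; X0 <- X[, -des$geno_cols, drop = FALSE]
    st <- leafgwas:::snp_gls_test(Y, X, X0, clone, A, tw, des$geno_cols)
    fit <- gls_fit(Y, X, V)
    ft <- f_test(fit, geno_cols = des$geno_cols)
    fit0 <- gls_fit(Y, X0, V)
    expect_equal(st$F, ft$F, tolerance = 1e-8)
    expect_equal(st$p_value, ft$p_value, tolerance = 1e-8)
    expect_equal(st$pve, 1 - fit$RSS / fit0$RSS, tolerance = 1e-8)
  }
})

test_that("rescaling a trait leaves F and p unchanged (GLS invariance)", {
  cr <- tiny_cross(n_clones = 40, m = 4, seed = 17)
  tr <- tiny_trial(t = 3, seed = 18)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  sc1 <- run_scan(ph, cr, m_independent = 4)
  ph2 <- ph
  ph2$trait_2 <- ph2$trait_2 * 37
  sc2 <- run_scan(ph2, cr, m_independent = 4)
  # invariance holds up to the REML convergence tolerance of the re-fitted V
  expect_equal(sc1$F, sc2$F, tolerance = 1e-4)
  expect_equal(sc1$p_raw, sc2$p_raw, tolerance = 1e-4)
})
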