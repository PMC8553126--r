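test_that("inflation factor matches chi-square quantile arithmetic", {
  expect_equal(inflation_factor(rep(0.5, 10)), 1)
  expect_equal(inflation_factor(rep(0.05, 3)),
               qchisq(0.05, 1, lower.tail = FALSE) / qchisq(0.5, 1),
               tolerance = 1e-10)
  expect_equal(inflation_factor(rep(0.05, 3)), 8.44, tolerance = 1e-3)
  set.seed(2)
  expect_equal(inflation_factor(runif(10000)), 1, tolerance = 0.03)
  expect_error(inflation_factor(numeric(0)), "no p-values")
})

test_that("genomic control divides chi-squares, deflation passes through", {
  p <- c(0.05, 0.2, 0.9)
  expect_identical(genomic_control(p, 1), p)
  expect_identical(genomic_control(p, 0.8), p)
  adj <- genomic_control(0.05, 2)
  expect_equal(adj,
               pchisq(qchisq(0.05, 1, lower.tail = FALSE) / 2, 1,
                      lower.tail = FALSE))
  expect_equal(adj, 0.1658, tolerance = 1e-3)
  lam <- 1.7
  expect_true(all(genomic_control(p, lam) >= p))
})

test_that("Bonferroni threshold reproduces the worked numbers", {
  th <- bonferroni_threshold(10735, 0.05)
  expect_equal(signif(th$p_threshold, 3), 4.66e-6)
  expect_equal(round(th$neglog10, 2), 5.33)
  expect_equal(bonferroni_threshold(1, 0.05)$p_threshold, 0.05)
  expect_equal(bonferroni_threshold(20, 0.05)$p_threshold, 2.5e-3)
  expect_error(bonferroni_threshold(0), "positive")
})

test_that("region splitting follows the decrease-to-increase rule", {
  expect_equal(split_regions(c(6, 5, 4)), c(1, 1, 1))
  expect_equal(split_regions(c(6, 5, 7, 6)), c(1, 1, 2, 2))
  expect_equal(split_regions(rep(4, 5)), rep(1, 5))
  expect_equal(split_regions(7), 1)
  expect_equal(split_regions(c(1, 2, 3)), c(1, 1, 1))
  # ties extend the current direction
  expect_equal(split_regions(c(6, 5, 5, 7)), c(1, 1, 1, 2))
  expect_equal(split_regions(c(6, 5, 4, 6, 5, 7)), c(1, 1, 1, 2, 2, 3))
})

test_that("scan output is deterministic and regions cover significant SNPs", {
  cr <- tiny_cross(n_clones = 60, m = 8, seed = 21)
  eff <- qtl_shape_effects(sort(unique(cr$geno_true[4, ])), t = 3,
                           effect_size = 3)
  tr <- trial_config(n_blocks = 2, cuttings_per_plot = 3, n_traits = 3,
                     V_G = equicorr(3, 0.4, 0.5), V_E = equicorr(3, 0.6, 0.3),
                     survival_rate = 1,
                     qtl_spec = list(list(snp = 4, effects = eff)), seed = 22)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  sc1 <- run_scan(ph, cr, m_independent = 8, alpha = 0.5)
  sc2 <- run_scan(ph, cr, m_independent = 8, alpha = 0.5)
  expect_identical(as.data.frame(sc1), as.data.frame(sc2))
  expect_true(all(!is.na(sc1$region_id[sc1$significant])))
  expect_true(all(is.na(sc1$region_id[!sc1$significant])))
  # regions are contiguous in position
  sig <- sc1[sc1$significant & !is.na(sc1$region_id), ]
  if (nrow(sig) > 1) {
    sig <- sig[order(sig$chrom, sig$pos), ]
    expect_true(all(diff(sig$region_id[sig$chrom == sig$chrom[1]]) >= 0))
  }
})

test_that("a large pleiotropic QTL is the scan minimum", {
  cr <- tiny_cross(n_clones = 100, m = 12, seed = 25, chromosome_length = 4)
  qtl <- 6
  eff <- qtl_shape_effects(sort(unique(cr$geno_true[qtl, ])), t = 5,
                           effect_size = 2.5)
  tr <- trial_config(n_blocks = 3, cuttings_per_plot = 4, n_traits = 5,
                     V_G = equicorr(5, 0.45, 0.9), V_E = equicorr(5, 0.55, 0.8),
                     survival_rate = 1,
                     qtl_spec = list(list(snp = qtl, effects = eff)), seed = 26)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  sc <- run_scan(ph, cr, m_independent = 12)
  top <- sc$snp_id[which.min(sc$p_raw)]
  # the QTL or a tightly linked neighbour tops the scan
  top_pos <- cr$snps$pos[match(top, cr$snps$snp_id)]
  qtl_cm <- cr$snps$cm[qtl]
  top_cm <- cr$snps$cm[match(top, cr$snps$snp_id)]
  expect_lt(abs(top_cm - qtl_cm), 30)
})

test_that("threshold bookkeeping uses the pruned count, and p_gc ordering", {
  cr <- tiny_cross(n_clones = 50, m = 10, seed = 27)
  tr <- tiny_trial(t = 2, seed = 28)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  pr <- ld_prune(cr)
  sc <- run_scan(ph, cr, m_independent = pr$n_independent)
  expect_equal(attr(sc, "m_independent"), pr$n_independent)
  expect_equal(attr(sc, "threshold"), 0.05 / pr$n_independent)
  lam <- attr(sc, "lambda_gc")
  if (lam > 1) expect_true(all(sc$p_gc >= sc$p_raw))
  # QQ table reproduces lambda from the plotted values
  qq <- qq_table(sc, "raw")
  lam_re <- inflation_factor(10^(-qq$observed))
  expect_equal(lam_re, lam, tolerance = 1e-6)
})

test_that("tidy/glance/autoplot methods work on scans and fits", {
  cr <- tiny_cross(n_clones = 30, m = 5, seed = 33)
  tr <- tiny_trial(t = 2, seed = 34)
  ph <- simulate_rcbd_phenotypes(cr, tr)
  sc <- run_scan(ph, cr, m_independent = 5)
  expect_s3_class(tidy(sc), "tbl_df")
  g <- glance(sc)
  expect_equal(g$n_snps, nrow(sc))
  expect_s3_class(plot_manhattan(sc), "ggplot")
  expect_s3_class(plot_qq(sc), "ggplot")
  expect_s3_class(autoplot(sc), "ggplot")
  vc <- attr(sc, "vc")
  expect_s3_class(tidy(vc), "tbl_df")
  expect_true(glance(vc)$converged)
})
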