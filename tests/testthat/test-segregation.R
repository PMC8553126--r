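test_that("segregation types are classified from parental genotypes", {
  cases <- list(
    list(p1 = "A/A", p2 = "A/T", type = "aaxab", ratio = c(1, 1)),
    list(p1 = "A/A", p2 = "C/T", type = "aaxbc", ratio = c(1, 1)),
    list(p1 = "A/T", p2 = "A/A", type = "abxaa", ratio = c(1, 1)),
    list(p1 = "A/T", p2 = "C/C", type = "abxcc", ratio = c(1, 1)),
    list(p1 = "A/T", p2 = "A/T", type = "abxab", ratio = c(1, 2, 1)),
    list(p1 = "A/T", p2 = "A/C", type = "abxac", ratio = c(1, 1, 1, 1)),
    list(p1 = "A/T", p2 = "C/G", type = "abxcd", ratio = c(1, 1, 1, 1))
  )
  for (cs in cases) {
    cl <- classify_segregation(cs$p1, cs$p2)
    expect_equal(cl$type, cs$type)
    expect_equal(cl$ratio, as.integer(cs$ratio))
    expect_equal(length(cl$classes), length(cs$ratio))
  }
  expect_equal(classify_segregation("A/A", "A/A")$type, "unclassifiable")
  expect_equal(classify_segregation("A/A", "T/T")$type, "unclassifiable")
  expect_equal(classify_segregation(NA, "A/T")$type, "unclassifiable")
})

test_that("abxab offspring classes align with the 1:2:1 ratio", {
  cl <- classify_segregation("A/T", "A/T")
  expect_equal(cl$classes, c("A/A", "A/T", "T/T"))
})

test_that("chi-square test matches hand-worked examples", {
  t1 <- segregation_test(c(50, 50), c(1, 1))
  expect_equal(t1$chi2, 0)
  expect_equal(t1$p, 1)
  t2 <- segregation_test(c(40, 60), c(1, 1))
  expect_equal(t2$chi2, 4)
  expect_equal(t2$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t2$p, 0.0455, tolerance = 1e-3)
  t3 <- segregation_test(c(80, 20), c(1, 1))
  expect_equal(t3$chi2, 36)
  expect_lt(t3$p, 1e-8)
  expect_error(segregation_test(c(0, 0), c(1, 1)), "zero")
})

test_that("QC records apply the p, missingness and ratio rules", {
  cr <- tiny_cross(n_clones = 200, m = 30, seed = 17, missing_rate = 0.05)
  rec <- qc_segregation(cr)
  expect_equal(nrow(rec), 30)
  expect_true(all(rec$pass == (rec$p > 0.01 & rec$missing_fraction < 0.10 &
                                 rec$ratio %in% c("1:1", "1:2:1", "1:1:1:1")),
                  na.rm = TRUE))
  # boundary: p just below / above the cutoff
  expect_false(isTRUE(0.009 > 0.01))
  expect_true(0.011 > 0.01)
})

test_that("a heavily distorted SNP fails and a >10% missing SNP fails", {
  cr <- tiny_cross(n_clones = 100, m = 5, seed = 23)
  # distort SNP 1: overwrite offspring with one class
  cl <- classify_segregation(cr$snps$p1[1], cr$snps$p2[1])
  cr$geno[1, ] <- cl$classes[1]
  # SNP 2: 12% missing
  cr$geno[2, 1:12] <- NA
  rec <- qc_segregation(cr)
  expect_false(rec$pass[1])
  expect_false(rec$pass[2])
  expect_gte(rec$missing_fraction[2], 0.12)
})

test_that("filtering partitions kept SNPs by type (funnel identity)", {
  cr <- tiny_cross(n_clones = 300, m = 50, seed = 19, missing_rate = 0.02)
  rec <- qc_segregation(cr)
  flt <- filter_snps(rec, cr)
  smry <- attr(flt, "summary")
  expect_equal(sum(smry$n_pass), nrow(flt$snps))
  expect_equal(sum(smry$n_total), nrow(cr$snps))
  expect_true(all(flt$snps$snp_id %in% rec$snp_id[rec$pass]))
})

test_that("filter is monotone in its cutoffs", {
  cr <- tiny_cross(n_clones = 150, m = 60, seed = 29, missing_rate = 0.06)
  base <- qc_segregation(cr, min_p = 0.01, max_missing = 0.10)
  stricter_p <- qc_segregation(cr, min_p = 0.05, max_missing = 0.10)
  stricter_m <- qc_segregation(cr, min_p = 0.01, max_missing = 0.05)
  expect_lte(sum(stricter_p$pass), sum(base$pass))
  expect_lte(sum(stricter_m$pass), sum(base$pass))
  expect_true(all(stricter_p$snp_id[stricter_p$pass] %in%
                    base$snp_id[base$pass]))
})

test_that("false-removal rate of the Mendelian filter is about 1 percent", {
  # 2000 undistorted SNPs on many chromosomes; every SNP is truly Mendelian
  cr <- simulate_cross(cross_config(
    n_clones = 163, n_chromosomes = 20, snps_per_chromosome = 100,
    missing_rate = 0, seed = 37
  ))
  rec <- qc_segregation(cr)
  fr <- mean(rec$p <= 0.01)
  ci <- stats::binom.test(sum(rec$p <= 0.01), nrow(rec), p = 0.01)$conf.int
  expect_true(ci[1] <= 0.015 && fr < 0.03)
  expect_equal(fr, 0.01, tolerance = 0.7)
})
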