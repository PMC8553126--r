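#' Radius-pattern QTL effects for power studies
#'
#' Builds per-genotype-class effect vectors for a pleiotropic leaf-shape QTL
#' acting on the RD-k radius traits: a `sin(theta)` contrast across the radius
#' angles (tip radii up, base radii down) scaled to `effect_size` genetic
#' standard deviations between the two genotype classes. The pattern is
#' orthogonal to overall leaf size, i.e. a pure shape effect.
#'
#' @param classes Genotype class labels of the QTL (e.g. `c("a/a", "a/b")`).
#' @param t Number of radius traits (angles at the RD-k grid).
#' @param effect_size Between-class difference, in units of the per-trait
#'   genetic SD.
#' @param sd_trait Per-trait genetic SD used for scaling.
#' @return A `classes x t` effect matrix.
#' @export
qtl_shape_effects <- function(classes, t = 11L, effect_size = 0.3,
                              sd_trait = sqrt(0.45)) {
  theta <- -pi / 2 + (seq_len(t) - 1) * pi / (t - 1)
  pattern <- sin(theta) * effect_size * sd_trait
  half <- seq_along(classes) - (length(classes) + 1) / 2
  out <- outer(half, pattern)
  rownames(out) <- classes
  out
}

#' Power comparison: multivariate versus univariate scans at one QTL
#'
#' Simulates replicate trials with a single pleiotropic shape QTL and records,
#' at a common (Bonferroni-matched) significance level, whether the
#' multivariate F test of all traits rejects and whether each single-trait
#' test rejects. The multivariate test pools the per-radius effects and is
#' expected to reject at least as often as the best univariate trait.
#'
#' @param n_reps Number of replicate datasets.
#' @param n_clones Clones per dataset.
#' @param n_traits Radius traits t.
#' @param effect_size Between-class QTL effect in genetic SDs
#'   ([qtl_shape_effects()]).
#' @param alpha_star Per-test significance level (e.g. a Bonferroni threshold).
#' @param n_blocks,cuttings_per_plot,survival_rate Trial geometry.
#' @param seed Integer seed.
#' @return A tibble with one row per method (`mv` plus each trait): `method`,
#'   `rejections`, `n_reps`, `power`.
#' @export
power_ordering_sim <- function(n_reps = 200L, n_clones = 150L, n_traits = 11L,
                               effect_size = 0.3, alpha_star = 0.05 / 10735,
                               n_blocks = 3L, cuttings_per_plot = 6L,
                               survival_rate = 0.765, seed = 1L) {
  rej_mv <- 0L
  rej_uni <- integer(n_traits)
  A <- kinship_fullsib(n_clones)
  for (r in seq_len(n_reps)) {
    cfg <- cross_config(
      n_clones = n_clones, n_chromosomes = 1L, snps_per_chromosome = 1L,
      segregation_mix = c(aaxab = 1, aaxbc = 0, abxaa = 0, abxcc = 0,
                          abxab = 0),
      missing_rate = 0, seed = seed + 7L * r
    )
    cr <- simulate_cross(cfg)
    eff <- qtl_shape_effects(c("a/a", "a/b"), t = n_traits,
                             effect_size = effect_size)
    trial <- trial_config(
      n_blocks = n_blocks, cuttings_per_plot = cuttings_per_plot,
      n_traits = n_traits, survival_rate = survival_rate,
      qtl_spec = list(list(snp = 1L, effects = eff)),
      seed = seed + 7L * r + 3L
    )
    ph <- simulate_rcbd_phenotypes(cr, trial)
    Y <- as.matrix(ph[, trait_names(ph), drop = FALSE])
    clone <- factor(ph$clone)
    null_X <- build_fixed_design(ph)$X
    des <- build_fixed_design(ph, cr$geno[1, ])
    X <- des$X
    X0 <- X[, -des$geno_cols, drop = FALSE]

    vc <- reml_multivariate(Y, null_X, clone, A)
    tw <- mv_whiten(vc$V_G, vc$V_E)
    p_mv <- snp_gls_test(Y, X, X0, clone, A, tw, des$geno_cols)$p_value
    rej_mv <- rej_mv + (p_mv < alpha_star)

    for (l in seq_len(n_traits)) {
      fu <- reml_univariate(Y[, l], null_X, clone, A)
      twu <- mv_whiten(matrix(fu$sigma_g2, 1, 1), matrix(fu$sigma_e2, 1, 1))
      p_u <- snp_gls_test(Y[, l, drop = FALSE], X, X0, clone, A, twu,
                          des$geno_cols)$p_value
      rej_uni[l] <- rej_uni[l] + (p_u < alpha_star)
    }
  }
  tibble::tibble(
    method = c("mv", paste0("trait_", seq_len(n_traits))),
    rejections = c(rej_mv, rej_uni),
    n_reps = n_reps,
    power = c(rej_mv, rej_uni) / n_reps
  )
}
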