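#' Additive relationship matrix of a single full-sib family
#'
#' For clones from one full-sib family with unrelated, non-inbred parents the
#' kinship coefficient between any two clones is 0.25, so the additive
#' relationship matrix `A` (twice the kinship) has ones on the diagonal and
#' 0.5 everywhere else. Its eigenstructure is closed-form: eigenvalue
#' `0.5 + 0.5 c` on the all-ones vector and `0.5` with multiplicity `c - 1`.
#'
#' @param c Number of clones.
#' @return A `c x c` relationship matrix.
#' @export
kinship_fullsib <- function(c) {
  if (!is_count(c)) stop("`c` must be a positive integer", call. = FALSE)
  A <- matrix(0.5, c, c)
  diag(A) <- 1
  A
}

# Equicorrelated t x t covariance: variance * ((1 - rho) I + rho J).
equicorr <- function(t, variance, rho) {
  variance * ((1 - rho) * diag(t) + rho * matrix(1, t, t))
}

#' Configure a randomized complete block trial
#'
#' Defaults describe the study conditions of a clonally replicated poplar F1
#' trial: 3 blocks, 6 cuttings per clone per plot, about 76.5% of planted
#' trees surviving to measurement, and t = 11 standardized radius-like traits
#' with per-trait heritability ~0.45 and high genetic (0.95) and residual
#' (0.85) trait correlations, matching the strong inter-radius correlations of
#' real leaf outlines.
#'
#' @param n_blocks Number of blocks.
#' @param cuttings_per_plot Trees planted per clone within each block.
#' @param n_traits Number of traits t (used only to build default matrices).
#' @param block_effects `n_blocks x t` matrix of fixed block shifts (recycled
#'   from a vector of per-block scalars if needed).
#' @param qtl_spec List of QTLs, each `list(snp = <snp_id or index>, effects =
#'   <named class x t matrix or named vector of per-class scalars>)`; effects
#'   are added to every trait value of trees whose clone carries that class.
#' @param V_G,V_E `t x t` genetic and residual covariance matrices (symmetric
#'   positive semidefinite).
#' @param mu Length-t vector of trait means.
#' @param survival_rate Probability that a planted tree survives to
#'   measurement (trees are dropped independently).
#' @param seed Integer seed.
#' @return A `trial_config` list.
#' @export
trial_config <- function(n_blocks = 3L, cuttings_per_plot = 6L, n_traits = 11L,
                         block_effects = NULL, qtl_spec = list(),
                         V_G = equicorr(n_traits, 0.45, 0.95),
                         V_E = equicorr(n_traits, 0.55, 0.85),
                         mu = rep(0, n_traits), survival_rate = 0.765,
                         seed = 1L) {
  if (!is_count(n_blocks) || !is_count(cuttings_per_plot)) {
    stop("n_blocks and cuttings_per_plot must be positive integers", call. = FALSE)
  }
  V_G <- as.matrix(V_G); V_E <- as.matrix(V_E)
  t <- length(mu)
  if (!all(dim(V_G) == t) || !all(dim(V_E) == t)) {
    stop("V_G, V_E and mu disagree on the trait count", call. = FALSE)
  }
  for (nm in c("V_G", "V_E")) {
    M <- get(nm)
    if (max(abs(M - t(M))) > 1e-8 || min(eigen(M, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-8) {
      stop(nm, " must be symmetric positive semidefinite", call. = FALSE)
    }
  }
  if (is.null(block_effects)) {
    block_effects <- matrix(seq(-0.3, 0.3, length.out = n_blocks), n_blocks, t)
  } else if (is.vector(block_effects)) {
    block_effects <- matrix(block_effects, n_blocks, t)
  }
  block_effects <- as.matrix(block_effects)
  if (nrow(block_effects) != n_blocks || ncol(block_effects) != t) {
    stop("block_effects must be n_blocks x t", call. = FALSE)
  }
  if (survival_rate <= 0 || survival_rate > 1) {
    stop("survival_rate must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_blocks = as.integer(n_blocks),
         cuttings_per_plot = as.integer(cuttings_per_plot),
         n_traits = as.integer(t), block_effects = block_effects,
         qtl_spec = qtl_spec, V_G = V_G, V_E = V_E, mu = mu,
         survival_rate = survival_rate, seed = as.integer(seed)),
    class = "trial_config"
  )
}

#' Simulate RCBD phenotypes under the multivariate clone model
#'
#' Realizes tree-level multivariate phenotypes exactly under the model
#' \deqn{Y = XB + ZG + E,\qquad
#'       \mathrm{Vec}(G) \sim N(0, V_G \otimes A),\quad
#'       \mathrm{Vec}(E) \sim N(0, V_E \otimes I_n),}
#' where rows of `X` carry the mean, block, and (optional) QTL genotype-class
#' effects, `Z` maps trees to clones, and `A` is the clone relationship
#' matrix. Planted trees are then dropped independently with probability
#' `1 - survival_rate`, mimicking field attrition.
#'
#' QTL effects are looked up in the true (pre-masking) genotypes when `cross`
#' is an `f1_geno` object.
#'
#' @param cross An `f1_geno` from [simulate_cross()], or an integer clone
#'   count when no QTL effects are requested.
#' @param trial A [trial_config()].
#' @param kinship Clone relationship matrix `A` (default: full-sib,
#'   [kinship_fullsib()]).
#' @return A tibble with columns `tree_id`, `block`, `clone`, `plot`, and
#'   `trait_1 ... trait_t`. The realized clone effect matrix `G` and the QTL
#'   class assignments are attached as attributes `"G"` and `"qtl_classes"`
#'   for parameter-recovery checks.
#' @export
simulate_rcbd_phenotypes <- function(cross, trial = trial_config(),
                                     kinship = NULL) {
  stopifnot(inherits(trial, "trial_config"))
  if (inherits(cross, "f1_geno")) {
    clone_ids <- colnames(cross$geno)
  } else if (is_count(cross)) {
    clone_ids <- sprintf("C%03d", seq_len(cross))
    cross <- NULL
  } else {
    stop("`cross` must be an f1_geno object or a clone count", call. = FALSE)
  }
  c <- length(clone_ids)
  t <- trial$n_traits
  A <- kinship %||% kinship_fullsib(c)
  if (!all(dim(A) == c)) stop("kinship must be c x c", call. = FALSE)

  with_seed(trial$seed, {
    G <- psd_sqrt(A) %*% matrix(rnorm(c * t), c, t) %*% psd_sqrt(trial$V_G)
    rownames(G) <- clone_ids

    trees <- tidyr::expand_grid(
      block = seq_len(trial$n_blocks),
      clone = clone_ids,
      cutting = seq_len(trial$cuttings_per_plot)
    )
    n <- nrow(trees)
    ci <- match(trees$clone, clone_ids)

    Y <- matrix(trial$mu, n, t, byrow = TRUE) +
      trial$block_effects[trees$block, , drop = FALSE] +
      G[ci, , drop = FALSE] +
      matrix(rnorm(n * t), n, t) %*% psd_sqrt(trial$V_E)

    qtl_classes <- list()
    for (q in trial$qtl_spec) {
      if (is.null(cross)) {
        stop("qtl_spec requires genotypes; pass an f1_geno object", call. = FALSE)
      }
      j <- if (is.character(q$snp)) match(q$snp, cross$snps$snp_id) else q$snp
      if (is.na(j) || j < 1 || j > nrow(cross$snps)) {
        stop("qtl_spec refers to an unknown SNP", call. = FALSE)
      }
      cls <- cross$geno_true[j, ]
      eff <- q$effects
      if (is.vector(eff)) {
        eff <- matrix(rep(eff, t), nrow = length(eff),
                      dimnames = list(names(eff), NULL))
      }
      miss <- setdiff(unique(cls), rownames(eff))
      if (length(miss)) {
        stop("qtl effects missing for class(es): ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      Y <- Y + eff[cls[ci], , drop = FALSE]
      qtl_classes[[cross$snps$snp_id[j]]] <- cls
    }

    keep <- if (trial$survival_rate < 1) {
      runif(n) < trial$survival_rate
    } else rep(TRUE, n)

    out <- tibble::tibble(
      tree_id = sprintf("T%05d", seq_len(n)),
      block = trees$block,
      clone = trees$clone,
      plot = paste0("B", trees$block, "-", trees$clone)
    )
    colnames(Y) <- paste0("trait_", seq_len(t))
    out <- dplyr::bind_cols(out, tibble::as_tibble(Y))[keep, ]
    attr(out, "G") <- G
    attr(out, "qtl_classes") <- qtl_classes
    out
  })
}

#' Names of the trait columns of a phenotype table
#'
#' @param phenotypes A phenotype tibble.
#' @return Character vector of `trait_*` column names.
#' @export
trait_names <- function(phenotypes) {
  grep("^trait_", names(phenotypes), value = TRUE)
}
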