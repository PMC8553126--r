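#' Genomic inflation factor
#'
#' Median-based \eqn{\lambda_{GC}}: each p-value is converted to its 1-df
#' chi-square upper-tail quantile and the median is divided by the null median
#' of \eqn{\chi^2_1} (0.4549364).
#'
#' @param p Vector of p-values in (0, 1\].
#' @return `lambda_gc`.
#' @export
inflation_factor <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Genomic control adjustment
#'
#' When \eqn{\lambda_{GC} > 1}, each association chi-square is divided by
#' \eqn{\lambda_{GC}} and converted back to a p-value; deflation
#' (\eqn{\lambda_{GC} \le 1}) is left uncorrected and p-values pass through
#' unchanged.
#'
#' @param p Vector of p-values.
#' @param lambda_gc Inflation factor ([inflation_factor()]).
#' @return Adjusted p-values.
#' @export
genomic_control <- function(p, lambda_gc) {
  if (lambda_gc <= 0) stop("lambda_gc must be positive", call. = FALSE)
  if (lambda_gc <= 1) return(p)
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  pchisq(chi / lambda_gc, df = 1, lower.tail = FALSE)
}

#' Bonferroni threshold on the number of independent tests
#'
#' @param m_independent Count of independent markers and LD blocks
#'   (survivors of [ld_prune()]).
#' @param alpha Family-wise significance level.
#' @return A list with `p_threshold = alpha / m_independent` and its
#'   `neglog10` companion.
#' @export
bonferroni_threshold <- function(m_independent, alpha = 0.05) {
  if (!is_count(m_independent)) {
    stop("m_independent must be a positive integer", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  th <- alpha / m_independent
  list(p_threshold = th, neglog10 = -log10(th))
}

#' Split significant SNPs of one chromosome into regions
#'
#' Assigns region identifiers to position-sorted significant SNPs: a new
#' region starts at each SNP where the \eqn{-\log_{10}(p)} score sequence
#' switches from (strictly) decreasing to (strictly) increasing, i.e. at each
#' strict local minimum boundary. Ties extend the current direction, so a
#' constant sequence forms a single region.
#'
#' @param score Scores (\eqn{-\log_{10} p}) of the significant SNPs of one
#'   chromosome, in position order.
#' @return Integer region ids (1, 2, ...), one per SNP.
#' @export
split_regions <- function(score) {
  m <- length(score)
  if (m == 0) return(integer(0))
  id <- 1L
  ids <- integer(m)
  ids[1] <- 1L
  last_dir <- 0L
  for (k in seq_len(m)[-1]) {
    d <- sign(score[k] - score[k - 1])
    if (d > 0 && last_dir < 0) id <- id + 1L
    ids[k] <- id
    if (d != 0) last_dir <- d
  }
  ids
}

#' Genome scan with the (multivariate) linear mixed model
#'
#' Runs the association scan of one or more traits against every testable SNP.
#' Variance components are estimated once under the no-SNP null model
#' (REML; [reml_multivariate()] or [reml_univariate()]) and the fitted
#' covariance is reused for every SNP's GLS fit and F test (the fast default);
#' `exact = TRUE` re-estimates the components for each SNP's complete cases.
#' For each SNP, trees whose clone genotype is missing are dropped, the
#' fixed-effect design (mean, blocks, genotype classes) is rebuilt, the
#' multivariate F statistic with `q = (g - 1) t` numerator and `t (n - p)`
#' denominator degrees of freedom is computed, and the variance explained is
#' measured as `1 - RSS/RSS0` against the no-SNP fixed-effects fit under the
#' same covariance.
#'
#' The scan then computes the genomic inflation factor, applies genomic
#' control when inflated, thresholds at `alpha / m_independent`, and splits
#' significant SNPs into regions per chromosome ([split_regions()]).
#' Monomorphic SNPs (a single genotype class among retained trees) are
#' untestable and skipped.
#'
#' @param phenotypes Tree-level phenotype tibble (`tree_id`, `block`, `clone`,
#'   trait columns).
#' @param geno An `f1_geno` object (ideally QC-filtered; see [filter_snps()]).
#' @param traits Character vector of trait columns to analyse (default: all
#'   `trait_*` columns; length 1 gives the univariate LMM).
#' @param kinship Clone relationship matrix (default full-sib), or
#'   `"identity"`.
#' @param m_independent Count of independent tests for the Bonferroni
#'   threshold (from [ld_prune()]); defaults to the number of SNPs tested,
#'   with a message.
#' @param alpha Family-wise significance level.
#' @param exact Re-estimate variance components per SNP instead of reusing the
#'   null-model fit.
#' @param gc Apply genomic control to the significance calls when
#'   \eqn{\lambda_{GC} > 1}.
#' @return A `leaf_scan` tibble: one row per tested SNP with `snp_id`, `chrom`,
#'   `pos`, `g`, `q`, `df2`, `F`, `p_raw`, `p_gc`, `pve`, `significant`,
#'   `region_id`. Attributes: `lambda_gc`, `threshold`, `m_independent`,
#'   `alpha`, `traits`, `vc` (the null-model REML fit), `n_skipped`.
#' @export
run_scan <- function(phenotypes, geno, traits = NULL, kinship = NULL,
                     m_independent = NULL, alpha = 0.05, exact = FALSE,
                     gc = TRUE) {
  stopifnot(inherits(geno, "f1_geno"))
  traits <- traits %||% trait_names(phenotypes)
  if (length(traits) == 0) stop("no trait columns found", call. = FALSE)
  Y <- as.matrix(phenotypes[, traits, drop = FALSE])
  if (anyNA(Y)) stop("phenotypes contain missing trait values", call. = FALSE)
  t <- ncol(Y)
  clone <- factor(phenotypes$clone)
  c <- nlevels(clone)
  A <- kinship %||% kinship_fullsib(c)
  if (identical(A, "identity")) A <- diag(c)

  m <- nrow(geno$snps)
  if (is.null(m_independent)) {
    m_independent <- m
    message("m_independent not supplied; using the number of SNPs (", m, ")")
  }

  null_design <- build_fixed_design(phenotypes)
  vc <- if (t == 1) {
    fit <- reml_univariate(Y[, 1], null_design$X, clone, A)
    list(V_G = matrix(fit$sigma_g2, 1, 1), V_E = matrix(fit$sigma_e2, 1, 1),
         fit = fit)
  } else {
    fit <- reml_multivariate(Y, null_design$X, clone, A, tol = 1e-10)
    list(V_G = fit$V_G, V_E = fit$V_E, fit = fit)
  }
  tw <- mv_whiten(vc$V_G, vc$V_E)

  rows_out <- vector("list", m)
  n_skipped <- 0L
  for (j in seq_len(m)) {
    snp_classes <- geno$geno[j, ]
    des <- build_fixed_design(phenotypes, snp_classes)
    if (des$g < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows <- des$rows
    cl_s <- droplevels(clone[rows])
    A_s <- A[match(levels(cl_s), levels(clone)),
             match(levels(cl_s), levels(clone)), drop = FALSE]
    X <- des$X
    X0 <- X[, -des$geno_cols, drop = FALSE]
    tw_j <- tw
    if (exact) {
      fit_j <- if (t == 1) {
        f <- reml_univariate(Y[rows, 1], X, cl_s, A_s)
        list(V_G = matrix(f$sigma_g2, 1, 1), V_E = matrix(f$sigma_e2, 1, 1))
      } else {
        f <- reml_multivariate(Y[rows, , drop = FALSE], X, cl_s, A_s)
        list(V_G = f$V_G, V_E = f$V_E)
      }
      tw_j <- mv_whiten(fit_j$V_G, fit_j$V_E)
    }
    res <- snp_gls_test(Y[rows, , drop = FALSE], X, X0, cl_s, A_s, tw_j,
                        des$geno_cols)
    rows_out[[j]] <- tibble::tibble(
      snp_id = geno$snps$snp_id[j], chrom = geno$snps$chrom[j],
      pos = geno$snps$pos[j], g = res$g, q = res$q, df2 = res$df2,
      F = res$F, p_raw = res$p_value, pve = res$pve
    )
  }
  out <- dplyr::bind_rows(rows_out)
  if (nrow(out) == 0) {
    warning("no testable SNPs")
    return(structure(out, class = c("leaf_scan", class(out)),
                     lambda_gc = NA_real_, threshold = NA_real_,
                     m_independent = m_independent, alpha = alpha,
                     traits = traits, vc = vc$fit, n_skipped = n_skipped))
  }

  lambda_gc <- inflation_factor(out$p_raw)
  out$p_gc <- genomic_control(out$p_raw, lambda_gc)
  thr <- bonferroni_threshold(m_independent, alpha)
  p_used <- if (gc && lambda_gc > 1) out$p_gc else out$p_raw
  out$significant <- p_used < thr$p_threshold

  out$region_id <- NA_integer_
  for (ch in unique(out$chrom[out$significant])) {
    sel <- which(out$significant & out$chrom == ch)
    sel <- sel[order(out$pos[sel])]
    out$region_id[sel] <- split_regions(-log10(p_used[sel]))
  }

  structure(out, class = c("leaf_scan", class(out)),
            lambda_gc = lambda_gc, threshold = thr$p_threshold,
            m_independent = m_independent, alpha = alpha, traits = traits,
            vc = vc$fit, n_skipped = n_skipped)
}

#' @export
print.leaf_scan <- function(x, ...) {
  cat("<leaf_scan> ", nrow(x), " SNPs, ", length(attr(x, "traits")),
      " trait(s); lambda_GC = ", signif(attr(x, "lambda_gc"), 4),
      "; threshold = ", signif(attr(x, "threshold"), 3),
      " (m = ", attr(x, "m_independent"), "); ",
      sum(x$significant), " significant\n", sep = "")
  NextMethod()
}

#' Scan summary table for QQ plots
#'
#' Sorted observed versus expected \eqn{-\log_{10} p} quantiles.
#'
#' @param scan A `leaf_scan`.
#' @param use `"raw"` or `"gc"` p-values.
#' @return A tibble with `expected` and `observed` columns.
#' @export
qq_table <- function(scan, use = c("raw", "gc")) {
  use <- match.arg(use)
  p <- sort(if (use == "raw") scan$p_raw else scan$p_gc)
  m <- length(p)
  tibble::tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(p)
  )
}
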