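#' Build the fixed-effect design for one tested SNP
#'
#' Reference-coded design with an intercept (overall mean), block effects, and
#' the genotype-class effects of the tested SNP: `p = 1 + (n_blocks - 1) +
#' (g - 1)` columns, where `g` is the number of genotype classes observed
#' among the retained trees. Trees whose clone genotype is missing at the SNP
#' are dropped (complete-case per test); classes left with zero trees are
#' omitted and `g` reduced.
#'
#' @param phenotypes Phenotype tibble with `block` and `clone` columns.
#' @param snp_classes Named character vector of genotype classes per clone
#'   (`NA` = missing); `NULL` builds the no-SNP null design.
#' @return A list: `X` (n x p), `rows` (indices of retained trees), `geno_cols`
#'   (indices of the genotype-class columns), `g` (class count), `classes`.
#' @export
build_fixed_design <- function(phenotypes, snp_classes = NULL) {
  block <- factor(phenotypes$block)
  if (is.null(snp_classes)) {
    X <- model.matrix(~block)
    return(list(X = X, rows = seq_len(nrow(phenotypes)),
                geno_cols = integer(0), g = 1L, classes = character(0)))
  }
  cls <- unname(snp_classes[as.character(phenotypes$clone)])
  rows <- which(!is.na(cls))
  geno <- factor(cls[rows])
  g <- nlevels(geno)
  if (g < 2) {
    return(list(X = NULL, rows = rows, geno_cols = integer(0), g = g,
                classes = levels(geno)))
  }
  bl <- droplevels(block[rows])
  X <- model.matrix(~bl + geno)
  colnames(X) <- c("(Intercept)",
                   paste0("block", levels(bl)[-1]),
                   paste0("geno", levels(geno)[-1]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient", call. = FALSE)
  }
  list(X = X, rows = rows,
       geno_cols = seq(ncol(X) - g + 2L, ncol(X)),
       g = g, classes = levels(geno))
}

#' Generalized least squares for a multivariate response
#'
#' Fits \eqn{\mathrm{Vec}(Y) = (I_t \otimes X)\,\mathrm{Vec}(B) + \epsilon}
#' with \eqn{\mathrm{cov}(\epsilon) = V} by dense GLS. Intended for small
#' worked instances and as the reference implementation; genome scans use the
#' structured spectral path internally.
#'
#' @param Y Response matrix (n x t).
#' @param X Design matrix (n x p).
#' @param V Positive-definite nt x nt covariance of `Vec(Y)` (trait-major
#'   blocks, matching `as.vector(Y)`).
#' @return A `gls_fit` object: `B_hat` (p x t), `vcov` (pt x pt covariance of
#'   `Vec(B_hat)`), `RSS` (residual sum of squares in the `V^{-1}` metric),
#'   `n`, `p`, `t`.
#' @export
gls_fit <- function(Y, X, V) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); t <- ncol(Y); p <- ncol(X)
  if (!all(dim(V) == n * t)) stop("V must be nt x nt", call. = FALSE)
  Xk <- kronecker(diag(t), X)
  ch <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite", call. = FALSE)
  })
  y <- as.vector(Y)
  Wy <- backsolve(ch, forwardsolve(t(ch), y))
  WX <- backsolve(ch, forwardsolve(t(ch), Xk))
  S <- crossprod(Xk, WX)
  chS <- tryCatch(chol(S), error = function(e) {
    bad <- paste(colnames(X), collapse = ", ")
    stop("singular GLS normal equations (columns: ", bad, ")", call. = FALSE)
  })
  b <- backsolve(chS, forwardsolve(t(chS), crossprod(Xk, Wy)))
  r <- y - Xk %*% b
  Wr <- backsolve(ch, forwardsolve(t(ch), r))
  structure(
    list(B_hat = matrix(b, p, t, dimnames = list(colnames(X), colnames(Y))),
         vcov = chol2inv(chS), RSS = sum(r * Wr), n = n, p = p, t = t),
    class = "gls_fit"
  )
}

#' Multivariate F test of a linear hypothesis on the GLS coefficients
#'
#' Tests \eqn{M\,\mathrm{Vec}(B) = 0} for a full-rank q x pt contrast matrix:
#' \deqn{F = \frac{1}{q}\,(M\mathrm{Vec}(\hat B))'\,
#'   [M\,\mathrm{cov}(\mathrm{Vec}(\hat B))\,M']^{-1}\,(M\mathrm{Vec}(\hat B))}
#' on `q` and `t(n - p)` degrees of freedom. The default contrast selects all
#' genotype-class coefficients across all traits (`q = (g - 1) t`), the
#' natural test of "no SNP effect on any trait".
#'
#' @param fit A [gls_fit()] result.
#' @param M Contrast matrix (q x pt, `Vec(B)` trait-major), or `NULL` to use
#'   `geno_cols`.
#' @param geno_cols Column indices of the genotype-class effects in the design
#'   (used to build the default contrast).
#' @return An `f_test` list: `F`, `q`, `df2`, `p_value`.
#' @export
f_test <- function(fit, M = NULL, geno_cols = NULL) {
  stopifnot(inherits(fit, "gls_fit"))
  p <- fit$p; t <- fit$t
  if (is.null(M)) {
    if (is.null(geno_cols) || length(geno_cols) == 0) {
      stop("supply a contrast matrix M or geno_cols", call. = FALSE)
    }
    idx <- as.vector(outer(geno_cols, (seq_len(t) - 1) * p, `+`))
    M <- diag(p * t)[idx, , drop = FALSE]
  }
  q <- nrow(M)
  theta <- M %*% as.vector(fit$B_hat)
  Vt <- M %*% fit$vcov %*% t(M)
  Fstat <- as.numeric(crossprod(theta, solve(Vt, theta))) / q
  df2 <- t * (fit$n - p)
  list(F = Fstat, q = q, df2 = df2,
       p_value = pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Proportion of phenotypic variance explained by one SNP
#'
#' \eqn{R^2 = 1 - RSS/RSS_0} between the full model and the no-SNP null model,
#' both evaluated as weighted (\eqn{V^{-1}}-metric) residual sums of squares
#' under the same fitted covariance, so the comparison is a pure fixed-effects
#' one and the result stays in \[0, 1\].
#'
#' @param RSS,RSS0 Weighted residual sums of squares of the full and null
#'   models.
#' @return Fraction in \[0, 1\].
#' @export
pve <- function(RSS, RSS0) {
  if (RSS0 <= 0) stop("RSS0 must be positive", call. = FALSE)
  if (RSS < 0) stop("RSS must be non-negative", call. = FALSE)
  r2 <- 1 - RSS / RSS0
  if (r2 < 0) {
    warning("RSS exceeded RSS0; PVE clipped to 0")
    r2 <- 0
  }
  r2
}

# ---- structured per-SNP association (spectral path) ----

# Dense covariance of Vec(Y) for small problems: V_G x ZAZ' + V_E x I.
# Used by tests and the exact (non-P3D) mode on modest n.
vec_covariance <- function(V_G, V_E, clone, A = NULL) {
  clone <- as.factor(clone)
  c <- nlevels(clone)
  if (is.null(A)) A <- kinship_fullsib(c)
  Z <- model.matrix(~ 0 + clone)
  ZAZ <- Z %*% A %*% t(Z)
  kronecker(V_G, ZAZ) + kronecker(V_E, diag(nrow(Z)))
}

# Fit the fixed effects of one SNP (and its null) under fixed (V_G, V_E)
# using the spectral reduction; returns the F test, PVE, and bookkeeping.
# `tw` is the whitening of (V_G, V_E) from mv_whiten().
snp_gls_test <- function(Y, X, X0, clone, A, tw, geno_cols) {
  sp <- spectral_design(clone, A)
  t <- ncol(Y); p <- ncol(X)
  d <- sp$d
  Yt <- Y %*% tw$K  # whitened trait basis
  X1 <- rotate1(sp, X)
  Y1 <- rotate1(sp, Yt)
  X01 <- rotate1(sp, X0)
  Cxx0 <- crossprod(X) - crossprod(X1)
  Cxy0 <- crossprod(X, Yt) - crossprod(X1, Y1)
  Cyy0d <- colSums(Yt^2) - colSums(Y1^2)
  C0xx_null <- crossprod(X0) - crossprod(X01)
  C0xy_null <- crossprod(X0, Yt) - crossprod(X01, Y1)

  W <- outer(d, tw$lambda) + 1
  rss <- 0; rss0 <- 0
  Bt <- matrix(0, p, t)
  Sinv <- vector("list", t)
  for (a in seq_len(t)) {
    w <- W[, a]
    Sa <- crossprod(X1 / sqrt(w)) + Cxx0
    rhs <- crossprod(X1, Y1[, a] / w) + Cxy0[, a]
    ch <- chol(Sa)
    b <- backsolve(ch, forwardsolve(t(ch), rhs))
    Bt[, a] <- b
    Sinv[[a]] <- chol2inv(ch)
    rss <- rss + sum(Y1[, a]^2 / w) + Cyy0d[a] - sum(b * rhs)

    S0a <- crossprod(X01 / sqrt(w)) + C0xx_null
    rhs0 <- crossprod(X01, Y1[, a] / w) + C0xy_null[, a]
    b0 <- solve(S0a, rhs0)
    rss0 <- rss0 + sum(Y1[, a]^2 / w) + Cyy0d[a] - sum(b0 * rhs0)
  }

  # covariance of Vec(B) (trait-major) from the tilde-basis block diagonal:
  # B = Bt %*% Kinv, Vec(B) = (Kinv' x I_p) Vec(Bt)
  Kt <- kronecker(t(tw$Kinv), diag(p))
  Vb <- Kt %*% Matrix_blockdiag(Sinv) %*% t(Kt)
  B <- Bt %*% tw$Kinv

  n <- nrow(Y)
  g <- length(geno_cols) + 1L
  q <- (g - 1L) * t
  idx <- as.vector(outer(geno_cols, (seq_len(t) - 1L) * p, `+`))
  theta <- as.vector(B)[idx]
  Fstat <- as.numeric(crossprod(theta, solve(Vb[idx, idx, drop = FALSE],
                                             theta))) / q
  df2 <- t * (n - p)
  list(F = Fstat, q = q, df2 = df2,
       p_value = pf(Fstat, q, df2, lower.tail = FALSE),
       pve = pve(rss, rss0), g = g, n = n)
}

Matrix_blockdiag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}
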