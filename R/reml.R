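# Spectral reduction of the clone mixed model.
#
# With Z the n x c tree-to-clone incidence and A the clone relationship
# matrix, the nonzero spectrum of ZAZ' equals that of the c x c matrix
# N^{1/2} A N^{1/2} (N = diag of clone sizes): if N^{1/2} A N^{1/2} = Q D Q',
# then U1 = Z N^{-1/2} Q holds the eigenvectors of ZAZ' with eigenvalues D,
# and the orthogonal complement is a null space of ZAZ'. All REML and GLS
# quantities only need U1' M products (clone-weighted sums) plus total
# crossproducts, so nothing n x n is ever formed.

spectral_design <- function(clone, A) {
  clone <- as.factor(clone)
  cl_levels <- levels(clone)
  c <- length(cl_levels)
  if (!all(dim(A) == c)) {
    stop("kinship dimension does not match the number of clones", call. = FALSE)
  }
  nsz <- as.vector(table(clone))
  if (any(nsz == 0)) stop("every clone level must have at least one tree", call. = FALSE)
  sq <- sqrt(nsz)
  M <- sq * t(sq * A)  # N^{1/2} A N^{1/2}
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  list(clone = clone, levels = cl_levels, c = c, n = length(clone),
       nsz = nsz, d = d, Q = e$vectors)
}

# U1' M for a tree-level matrix M (n x k): Q' N^{-1/2} Z' M.
rotate1 <- function(sp, M) {
  M <- as.matrix(M)
  zm <- rowsum(M, sp$clone)  # c x k, ordered by factor levels
  crossprod(sp$Q, zm / sqrt(sp$nsz))
}

# Crossproduct split into the d > 0 rotated part and the null-space remainder:
# C0 = M1'M2 - (U1'M1)'(U1'M2).
cross_split <- function(sp, M1, M2, R1 = NULL, R2 = NULL) {
  R1 <- R1 %||% rotate1(sp, M1)
  R2 <- R2 %||% rotate1(sp, M2)
  list(full = crossprod(as.matrix(M1), as.matrix(M2)) - crossprod(R1, R2),
       r1 = R1, r2 = R2)
}

#' Univariate REML on the clone kinship
#'
#' Restricted maximum-likelihood estimation of the clone-level genetic
#' variance and the residual variance under
#' \eqn{y = X\beta + Zg + e}, \eqn{g \sim N(0, \sigma_g^2 A)},
#' \eqn{e \sim N(0, \sigma_e^2 I_n)}, via the one-time spectral reduction of
#' `ZAZ'` and a 1-D profile-likelihood search over the variance ratio
#' \eqn{\lambda = \sigma_g^2/\sigma_e^2} (log-scale grid plus local
#' refinement).
#'
#' @param y Response vector (length n).
#' @param X Fixed-effect design matrix (n x p, full column rank).
#' @param clone Clone identifier per tree (factor or character).
#' @param A Clone relationship matrix, or `"identity"` for independent clone
#'   effects.
#' @return A `reml_uni` object: `sigma_g2`, `sigma_e2`, `h2`, `lambda`,
#'   `loglik` (restricted, up to a constant), `converged`.
#' @export
reml_univariate <- function(y, X, clone, A = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than fixed effects", call. = FALSE)
  clone <- as.factor(clone)
  c <- nlevels(clone)
  if (is.null(A)) A <- kinship_fullsib(c)
  if (identical(A, "identity")) A <- diag(c)
  sp <- spectral_design(clone, A)
  X1 <- rotate1(sp, X)
  y1 <- rotate1(sp, y)
  C0xx <- crossprod(X) - crossprod(X1)
  C0xy <- crossprod(X, y) - crossprod(X1, y1)
  C0yy <- sum(y^2) - sum(y1^2)
  d <- sp$d

  nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    S <- crossprod(X1 / sqrt(w)) + C0xx
    rhs <- crossprod(X1, y1 / w) + C0xy
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    b <- backsolve(ch, forwardsolve(t(ch), rhs))
    rss <- sum(y1^2 / w) + C0yy - sum(b * rhs)
    if (rss <= 0) return(Inf)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(w)) + 2 * sum(log(diag(ch))) + (n - p))
  }

  grid <- seq(-18, 12, length.out = 61)
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(nll, c(lo, hi), tol = 1e-12)
  # treat a minimum pinned at the lower grid edge as the sigma_g2 = 0 boundary
  lam <- if (i == 1 && opt$objective >= vals[1] - 1e-10) 0 else exp(opt$minimum)

  w <- lam * d + 1
  S <- crossprod(X1 / sqrt(w)) + C0xx
  rhs <- crossprod(X1, y1 / w) + C0xy
  b <- solve(S, rhs)
  rss <- sum(y1^2 / w) + C0yy - sum(b * rhs)
  s2e <- rss / (n - p)
  structure(
    list(sigma_g2 = lam * s2e, sigma_e2 = s2e, lambda = lam,
         h2 = lam / (1 + lam),
         beta = setNames(as.vector(b), colnames(X)),
         loglik = -if (lam > 0) nll(log(lam)) else nll(-50),
         n = n, p = p, converged = TRUE),
    class = "reml_uni"
  )
}

#' Narrow-sense heritability
#'
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}: the clone-level genetic
#' fraction of phenotypic variance.
#'
#' @param sigma_g2,sigma_e2 Non-negative variance components (not both zero).
#' @return `h2` in \[0, 1\].
#' @export
heritability <- function(sigma_g2, sigma_e2) {
  if (sigma_g2 < 0 || sigma_e2 < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (sigma_g2 + sigma_e2 == 0) {
    stop("heritability undefined when both components are zero", call. = FALSE)
  }
  sigma_g2 / (sigma_g2 + sigma_e2)
}

#' Multivariate REML on the clone kinship (EM algorithm)
#'
#' Restricted maximum-likelihood estimation of the t x t genetic and residual
#' covariance matrices under
#' \deqn{\mathrm{Vec}(Y) \sim N\big((I_t \otimes X)\mathrm{Vec}(B),\;
#'       V_G \otimes ZAZ' + V_E \otimes I_n\big).}
#' Each EM iteration simultaneously diagonalizes the current
#' \eqn{(V_G, V_E)} pair, in which basis the model decouples into t
#' independent weighted least-squares problems on the spectral coordinates of
#' `ZAZ'`; conditional moments of the clone effects and residuals are then
#' closed-form and the M step is exact. Symmetric PSD projection is applied
#' each step. The restricted log-likelihood increases monotonically; iteration
#' stops when its relative change falls below `tol`.
#'
#' @param Y Response matrix (n x t).
#' @param X Fixed-effect design matrix (n x p, full column rank).
#' @param clone Clone identifier per tree.
#' @param A Clone relationship matrix, or `"identity"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum EM iterations.
#' @return A `reml_mv` object: `V_G`, `V_E` (t x t), `loglik` (restricted, up
#'   to a constant), `iterations`, `converged`.
#' @export
reml_multivariate <- function(Y, X, clone, A = NULL, tol = 1e-10,
                              maxit = 5000L) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y); t <- ncol(Y); p <- ncol(X)
  if (n <= p) stop("need more observations than fixed effects", call. = FALSE)
  if (t > n / 2) stop("t > n/2 is ill-posed for this fitter", call. = FALSE)
  clone <- as.factor(clone)
  c <- nlevels(clone)
  if (is.null(A)) A <- kinship_fullsib(c)
  if (identical(A, "identity")) A <- diag(c)
  sp <- spectral_design(clone, A)
  X1 <- rotate1(sp, X)
  Y1 <- rotate1(sp, Y)
  Cxx0 <- crossprod(X) - crossprod(X1)
  Cxy0 <- crossprod(X, Y) - crossprod(X1, Y1)
  Cyy0 <- crossprod(Y) - crossprod(Y1)
  d <- sp$d

  # moment initialization: split the OLS residual covariance
  qrX <- qr(X)
  R <- qr.resid(qrX, Y)
  S0 <- crossprod(R) / (n - p)
  V_G <- S0 / 2
  V_E <- S0 / 2

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    step <- mv_em_step(V_G, V_E, X1, Y1, Cxx0, Cxy0, Cyy0, d, n, c, p, t)
    V_G_new <- psd_project(step$V_G)
    V_E_new <- psd_project(step$V_E)
    if (is.finite(step$loglik) &&
        abs(step$loglik - ll_old) < tol * (abs(step$loglik) + 1)) {
      V_G <- V_G_new; V_E <- V_E_new
      ll_old <- step$loglik
      converged <- TRUE
      break
    }
    V_G <- V_G_new; V_E <- V_E_new
    ll_old <- step$loglik
  }
  dimnames(V_G) <- dimnames(V_E) <- list(colnames(Y), colnames(Y))
  structure(
    list(V_G = V_G, V_E = V_E, loglik = ll_old, iterations = iter,
         converged = converged, n = n, p = p, t = t),
    class = "reml_mv"
  )
}

# One EM-REML update. Returns the new (V_G, V_E) and the restricted
# log-likelihood of the INPUT pair (so the reported loglik matches the
# returned estimates only at convergence).
mv_em_step <- function(V_G, V_E, X1, Y1, Cxx0, Cxy0, Cyy0, d, n, c, p, t) {
  tw <- mv_whiten(V_G, V_E)
  K <- tw$K; lam <- tw$lambda; Kinv <- tw$Kinv

  Yt1 <- Y1 %*% K                       # c x t
  Cxy0t <- Cxy0 %*% K                   # p x t
  Cyy0t <- crossprod(K, Cyy0 %*% K)     # t x t

  W <- outer(d, lam) + 1                # c x t weights d_i * lambda_a + 1
  Bt <- matrix(0, p, t)
  Sinv <- vector("list", t)
  logdetS <- numeric(t)
  for (a in seq_len(t)) {
    Sa <- crossprod(X1 / sqrt(W[, a])) + Cxx0
    rhs <- crossprod(X1, Yt1[, a] / W[, a]) + Cxy0t[, a]
    ch <- chol(Sa)
    Bt[, a] <- backsolve(ch, forwardsolve(t(ch), rhs))
    Sinv[[a]] <- chol2inv(ch)
    logdetS[a] <- 2 * sum(log(diag(ch)))
  }

  Rt1 <- Yt1 - X1 %*% Bt                # rotated residuals, c x t
  H <- vapply(seq_len(t), function(a) {
    rowSums((X1 %*% Sinv[[a]]) * X1)    # leverages x1_i' S_a^{-1} x1_i
  }, numeric(c))                        # c x t

  # null-space residual crossproduct (t x t, tilde basis) and leverage traces
  Res0 <- Cyy0t - crossprod(Cxy0t, Bt) - crossprod(Bt, Cxy0t) +
    crossprod(Bt, Cxx0 %*% Bt)
  tr0 <- vapply(seq_len(t), function(a) sum(Sinv[[a]] * Cxx0), numeric(1))

  # restricted log-likelihood of the input (V_G, V_E)
  rss <- sum(Rt1^2 / W) + sum(diag(Res0))
  loglik <- -0.5 * (sum(log(W)) + n * tw$logdet_VE + sum(logdetS) +
                      2 * p * tw$logdet_K + rss)

  # --- M step ---
  # genetic component: sum over the c spectral rows
  Vt <- sweep(Rt1 / W, 2, lam, `*`)     # v_i = Lambda D_i^{-1} r_i
  term1 <- crossprod(Vt, d * Vt)
  diag_g <- c * lam - lam^2 * colSums(d / W) +
    lam^2 * colSums(d * H / W^2)
  Gt <- (term1 + diag(diag_g, t)) / c

  # residual component: spectral rows plus the null space
  Et <- Rt1 / W
  term1e <- crossprod(Et)
  diag_e <- c - colSums(1 / W) + colSums(H / W^2)
  Etilde <- (term1e + diag(diag_e, t) + Res0 + diag(tr0, t)) / n

  list(V_G = crossprod(Kinv, Gt %*% Kinv),
       V_E = crossprod(Kinv, Etilde %*% Kinv),
       loglik = loglik)
}

# Simultaneous diagonalization: K with K' V_E K = I and K' V_G K = diag(lambda).
mv_whiten <- function(V_G, V_E) {
  t <- nrow(V_E)
  # guard against a degenerate V_E collapsing the whitening
  e <- eigen((V_E + t(V_E)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-12)
  Rinv <- e$vectors %*% (1 / sqrt(vals) * t(e$vectors))  # V_E^{-1/2}
  C <- crossprod(Rinv, V_G %*% Rinv)
  e2 <- eigen((C + t(C)) / 2, symmetric = TRUE)
  K <- Rinv %*% e2$vectors
  Kinv <- crossprod(e2$vectors, e$vectors %*% (sqrt(vals) * t(e$vectors)))
  list(K = K, Kinv = Kinv, lambda = pmax(e2$values, 0),
       logdet_VE = sum(log(vals)), logdet_K = -0.5 * sum(log(vals)))
}

#' @export
print.reml_uni <- function(x, ...) {
  cat("<reml_uni> sigma_g2 = ", signif(x$sigma_g2, 5),
      ", sigma_e2 = ", signif(x$sigma_e2, 5),
      ", h2 = ", signif(x$h2, 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.reml_mv <- function(x, ...) {
  cat("<reml_mv> t = ", x$t, ", ", x$iterations, " EM iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("V_G diagonal:", signif(diag(x$V_G), 4), "\n")
  cat("V_E diagonal:", signif(diag(x$V_E), 4), "\n")
  invisible(x)
}
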