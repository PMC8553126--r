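#' @importFrom stats pchisq qchisq pf cor median optimize rnorm runif rbinom
#'   model.matrix sd var complete.cases setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Symmetric PSD square root; tolerates semidefinite input (e.g. a zero matrix).
psd_sqrt <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Project a symmetric matrix onto the PSD cone (clips tiny negative eigenvalues
# that arise from accumulated round-off).
psd_project <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (all(e$values >= 0)) return(M)
  vals <- pmax(e$values, 0)
  e$vectors %*% (vals * t(e$vectors))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
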