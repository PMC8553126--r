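#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a univariate REML fit
#'
#' @param x A `reml_uni` object.
#' @param ... Unused.
#' @return A tibble with one row per variance component.
#' @export
tidy.reml_uni <- function(x, ...) {
  tibble::tibble(
    component = c("genetic", "residual"),
    estimate = c(x$sigma_g2, x$sigma_e2)
  )
}

#' @rdname tidy.reml_uni
#' @export
glance.reml_uni <- function(x, ...) {
  tibble::tibble(h2 = x$h2, lambda = x$lambda, loglik = x$loglik,
                 n = x$n, p = x$p, converged = x$converged)
}

#' Tidy a multivariate REML fit
#'
#' @param x A `reml_mv` object.
#' @param ... Unused.
#' @return A tibble with one row per (component, trait pair) covariance entry.
#' @export
tidy.reml_mv <- function(x, ...) {
  t <- x$t
  nm <- colnames(x$V_G) %||% paste0("trait_", seq_len(t))
  grid <- expand.grid(row = seq_len(t), col = seq_len(t))
  grid <- grid[grid$row <= grid$col, ]
  dplyr::bind_rows(
    tibble::tibble(component = "genetic", trait_1 = nm[grid$row],
                   trait_2 = nm[grid$col],
                   estimate = x$V_G[cbind(grid$row, grid$col)]),
    tibble::tibble(component = "residual", trait_1 = nm[grid$row],
                   trait_2 = nm[grid$col],
                   estimate = x$V_E[cbind(grid$row, grid$col)])
  )
}

#' @rdname tidy.reml_mv
#' @export
glance.reml_mv <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, n = x$n, p = x$p, t = x$t)
}

#' Tidy a genome scan
#'
#' @param x A `leaf_scan` object.
#' @param ... Unused.
#' @return The per-SNP result tibble (without scan attributes).
#' @export
tidy.leaf_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "lambda_gc") <- NULL
  out
}

#' @rdname tidy.leaf_scan
#' @export
glance.leaf_scan <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    n_traits = length(attr(x, "traits")),
    lambda_gc = attr(x, "lambda_gc"),
    p_threshold = attr(x, "threshold"),
    m_independent = attr(x, "m_independent"),
    n_significant = sum(x$significant),
    n_skipped = attr(x, "n_skipped")
  )
}

#' Tidy a pruned SNP set
#'
#' @param x A `pruned_set` object.
#' @param ... Unused.
#' @return A one-row summary tibble.
#' @export
glance.pruned_set <- function(x, ...) {
  tibble::tibble(n_independent = x$n_independent, window = x$window,
                 step = x$step, r2_threshold = x$r2_threshold)
}
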