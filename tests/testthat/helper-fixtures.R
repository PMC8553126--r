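# Small shared fixtures, built in code at test time.

tiny_cross <- function(n_clones = 40, m = 10, seed = 11, missing_rate = 0,
                       chromosome_length = 2) {
  simulate_cross(cross_config(
    n_clones = n_clones, n_chromosomes = 1L, snps_per_chromosome = m,
    chromosome_length = chromosome_length, missing_rate = missing_rate,
    seed = seed
  ))
}

tiny_trial <- function(t = 2, seed = 21, ...) {
  trial_config(n_blocks = 2L, cuttings_per_plot = 3L, n_traits = t,
               V_G = diag(t), V_E = diag(t), survival_rate = 1,
               block_effects = matrix(0, 2, t), seed = seed, ...)
}

# analytic contour helpers
ellipse_contour <- function(a = 60, b = 40, n = 1200, normalized = TRUE) {
  th <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
  r <- a * b / sqrt(a^2 * cos(th)^2 + b^2 * sin(th)^2)
  leaf_contour(cbind(r * cos(th), r * sin(th)), normalized = normalized)
}

rect_contour <- function(h = 120, w = 80, normalized = TRUE) {
  leaf_contour(cbind(c(w, w, -w, -w) / 2, c(-h, h, h, -h) / 2),
               normalized = normalized)
}

# brute-force LD pruning oracle: literal reimplementation of the stated rule
# with dense r2 recomputation (no shortcuts shared with the implementation)
brute_prune <- function(codes, missing_fraction, window, step, r2_threshold) {
  m <- nrow(codes)
  keep <- rep(TRUE, m)
  r2 <- function(i, j) {
    ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
    x <- codes[i, ok]; y <- codes[j, ok]
    if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) return(0)
    stats::cor(x, y)^2
  }
  start <- 1
  repeat {
    win <- seq(start, min(start + window - 1, m))
    repeat {
      act <- win[keep[win]]
      if (length(act) < 2) break
      pairs <- t(utils::combn(act, 2))
      vals <- apply(pairs, 1, function(pr) r2(pr[1], pr[2]))
      if (max(vals) <= r2_threshold) break
      pr <- pairs[which.max(vals), ]
      mf <- missing_fraction[pr]
      drop <- if (mf[1] > mf[2]) pr[1] else if (mf[2] > mf[1]) pr[2] else max(pr)
      keep[drop] <- FALSE
    }
    if (start + window - 1 >= m) break
    start <- start + step
  }
  keep
}
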