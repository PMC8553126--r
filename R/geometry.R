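# Polygon primitives shared by the leaf renderer and the measurement pipeline.
# All functions take an open vertex matrix (n x 2, no repeated closing vertex)
# in counter-clockwise order unless stated otherwise.

poly_open <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) >= 2 && isTRUE(all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12))) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  xy
}

poly_signed_area <- function(xy) {
  xy <- poly_open(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Area-weighted centroid via the shoelace formula (not the vertex mean).
poly_centroid <- function(xy) {
  xy <- poly_open(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    stop("polygon has zero area; centroid undefined", call. = FALSE)
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second-order area moments about the origin, returned as the covariance matrix
# of the uniform distribution over the polygon interior.
poly_covariance <- function(xy) {
  xy <- poly_open(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  exx <- sum((x^2 + x * xn + xn^2) * cr) / (12 * a)
  eyy <- sum((y^2 + y * yn + yn^2) * cr) / (12 * a)
  exy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / (24 * a)
  ctr <- poly_centroid(xy)
  m <- matrix(c(exx - ctr[1]^2, exy - ctr[1] * ctr[2],
                exy - ctr[1] * ctr[2], eyy - ctr[2]^2), 2, 2)
  (m + t(m)) / 2
}

# Distance from the origin to the polygon boundary along each angle, computed
# by exact ray/segment intersection (equivalently, linear interpolation between
# the two boundary points bracketing the ray). When a ray crosses the boundary
# more than once (non-star-convex outline) the farthest intersection is kept.
# Returns list(radius, n_hits).
poly_radii <- function(xy, angles) {
  xy <- poly_open(xy)
  p1 <- xy
  p2 <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]
  ey <- p2[, 2] - p1[, 2]
  radius <- numeric(length(angles))
  n_hits <- integer(length(angles))
  for (k in seq_along(angles)) {
    ux <- cos(angles[k]); uy <- sin(angles[k])
    # solve r*u = p1 + s*e  =>  [u, -e] %*% c(r, s) = p1
    det <- -ux * ey + uy * ex
    ok <- abs(det) > 1e-14
    r <- (-p1[, 1] * ey + p1[, 2] * ex) / det
    s <- (ux * p1[, 2] - uy * p1[, 1]) / det
    hit <- ok & r > 1e-12 & s >= -1e-12 & s <= 1 + 1e-12
    if (!any(hit)) {
      radius[k] <- NA_real_
      next
    }
    rh <- r[hit]
    radius[k] <- max(rh)
    # count distinct crossings (shared vertices produce duplicate hits)
    n_hits[k] <- length(unique(round(rh, 9)))
  }
  if (anyNA(radius)) {
    stop("a ray from the origin did not intersect the contour; ",
         "is the centroid inside the outline?", call. = FALSE)
  }
  list(radius = radius, n_hits = n_hits)
}

# Horizontal chord widths of the polygon at a vector of heights
# (extreme-span convention: max crossing x minus min crossing x; 0 where the
# line misses the polygon). Vectorized over heights in chunks.
poly_chord_widths <- function(xy, y0s) {
  xy <- poly_open(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ex <- xn - x
  dy <- yn - y
  out <- numeric(length(y0s))
  chunk <- 128L
  for (at in seq(1, length(y0s), by = chunk)) {
    idx <- at:min(at + chunk - 1L, length(y0s))
    A <- outer(y, y0s[idx], `-`)          # y - y0
    B <- outer(yn, y0s[idx], `-`)         # yn - y0
    hit <- A * B < 0
    on_line <- abs(A) < 1e-12
    xs <- x + ex * (-A / dy)
    xs[!hit] <- NA_real_
    xs[on_line] <- x[row(xs)[on_line]]
    w <- suppressWarnings(
      apply(xs, 2, max, na.rm = TRUE) - apply(xs, 2, min, na.rm = TRUE)
    )
    w[!is.finite(w)] <- 0
    out[idx] <- w
  }
  out
}

poly_chord_width <- function(xy, y0) poly_chord_widths(xy, y0)

# Maximum horizontal chord over the whole outline. The width profile is
# piecewise linear between vertex heights, so the maximum is attained
# arbitrarily close to a vertex height; for dense outlines a uniform grid
# locates the maximum, which is then refined on the exact vertex-height
# candidates in its neighbourhood.
poly_max_chord <- function(xy) {
  xy <- poly_open(xy)
  ys <- sort(unique(xy[, 2]))
  if (length(ys) < 2) return(0)
  eps <- max(diff(range(ys)) * 1e-9, 1e-12)
  cand_exact <- unique(c(ys[-length(ys)] + eps, ys[-1] - eps,
                         (ys[-length(ys)] + ys[-1]) / 2))
  if (length(cand_exact) <= 2048) {
    return(max(poly_chord_widths(xy, cand_exact)))
  }
  grid <- seq(ys[1] + eps, ys[length(ys)] - eps, length.out = 1024)
  wg <- poly_chord_widths(xy, grid)
  best <- grid[which.max(wg)]
  band <- 2 * diff(grid)[1]
  near <- cand_exact[abs(cand_exact - best) <= band]
  max(max(wg), if (length(near)) max(poly_chord_widths(xy, near)) else 0)
}
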