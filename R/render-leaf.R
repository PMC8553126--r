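#' Parameters for a synthetic leaf silhouette
#'
#' Describes an analytic leaf-like outline used to exercise the image
#' phenotyping pipeline against known ground truth. Four families are
#' supported: `circle` (radius `a`), `ellipse` (semi-length `a` along the
#' length axis, semi-width `b` across it), `rectangle` (`2a` tall by `2b`
#' wide), and `parametric-leaf`, a tapered ellipse whose polar radius about
#' the shape origin is
#' \deqn{r(\theta) = r_{ell}(\theta)\,\frac{1 + \tau_t \sin\theta}
#'                                        {1 + \tau_b \sin\theta}}
#' so that positive `taper_tip` elongates the tip (at \eqn{+\pi/2}) and
#' positive `taper_base` blunts the base, giving a deltoid outline.
#'
#' @param family One of `"parametric-leaf"`, `"ellipse"`, `"circle"`,
#'   `"rectangle"`.
#' @param a Semi-length in mm (circle radius for `family = "circle"`).
#' @param b Semi-width in mm (ignored for circles).
#' @param taper_tip,taper_base Dimensionless taper coefficients in (-1, 1);
#'   only used by the parametric leaf.
#' @param pixels_per_mm Raster scale. The default 11.811 px/mm corresponds to
#'   a 300 dpi flatbed scan.
#' @param seed Optional integer recorded with the parameters (the renderer
#'   itself is deterministic; the seed documents provenance when parameters
#'   are drawn at random by [random_leaf_params()]).
#' @return An object of class `leaf_shape_params`.
#' @seealso [render_leaf()], [random_leaf_params()]
#' @export
leaf_shape_params <- function(family = c("parametric-leaf", "ellipse", "circle", "rectangle"),
                              a = 60, b = 40, taper_tip = 0.4, taper_base = 0.15,
                              pixels_per_mm = 11.811, seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  if (family != "circle" && (!is.numeric(b) || b <= 0)) {
    stop("`b` must be positive", call. = FALSE)
  }
  if (pixels_per_mm <= 0) stop("`pixels_per_mm` must be positive", call. = FALSE)
  if (family == "parametric-leaf" &&
      (abs(taper_tip) >= 1 || abs(taper_base) >= 1)) {
    stop("taper coefficients must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    list(family = family, a = a, b = if (family == "circle") a else b,
         taper_tip = taper_tip, taper_base = taper_base,
         pixels_per_mm = pixels_per_mm, seed = seed),
    class = "leaf_shape_params"
  )
}

#' Draw random leaf-shape parameters
#'
#' Convenience generator for batches of parametric leaves with varying size
#' and taper, e.g. to build a validation set for the measurement pipeline.
#'
#' @param n Number of leaves.
#' @param seed Integer seed.
#' @param pixels_per_mm Raster scale passed through to each leaf.
#' @return A list of `leaf_shape_params`.
#' @export
random_leaf_params <- function(n, seed = 1, pixels_per_mm = 11.811) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- runif(1, 35, 75)
      leaf_shape_params(
        family = "parametric-leaf",
        a = a,
        b = a * runif(1, 0.55, 0.95),
        taper_tip = runif(1, 0.1, 0.5),
        taper_base = runif(1, 0, 0.3),
        pixels_per_mm = pixels_per_mm,
        seed = seed
      )
    })
  })
}

# Polar radius of the outline about the shape origin (not the centroid).
shape_radius_fn <- function(params) {
  a <- params$a; b <- params$b
  switch(params$family,
    "circle" = function(theta) rep(a, length(theta)),
    "ellipse" = function(theta) {
      a * b / sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
    },
    "rectangle" = function(theta) {
      pmin(b / pmax(abs(cos(theta)), 1e-300), a / pmax(abs(sin(theta)), 1e-300))
    },
    "parametric-leaf" = function(theta) {
      rell <- a * b / sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
      rell * (1 + params$taper_tip * sin(theta)) / (1 + params$taper_base * sin(theta))
    }
  )
}

# Dense analytic polygon of the outline about the shape origin.
shape_polygon <- function(params, n = 8192L) {
  th <- seq(-pi, pi, length.out = n + 1L)[-(n + 1L)]
  r <- shape_radius_fn(params)(th)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Render a synthetic leaf image with ground truth
#'
#' Rasterizes the analytic outline onto a binary pixel grid (pixel centers are
#' classified by the exact inside test) and returns, alongside the image, the
#' analytic contour, the exact area centroid, ground-truth polar radii about
#' that centroid at any requested angles, and ground-truth classic size traits.
#' Circle/ellipse/rectangle truths are closed forms; the parametric leaf truth
#' is evaluated on a dense (8192-vertex) analytic polygon whose discretization
#' error is orders of magnitude below pixel-level error.
#'
#' @param params A [leaf_shape_params()] object.
#' @param margin_px Background margin around the shape, in pixels.
#' @return An object of class `leaf_render`: a list with elements `image`
#'   (0/1 matrix indexed `[x, y]`, x rightwards, y towards the leaf tip),
#'   `pixels_per_mm`, `origin_px` (pixel coordinates of the shape origin),
#'   `contour_mm` (analytic outline about the shape origin), `centroid_mm`
#'   (exact centroid relative to the shape origin), `radius_at` (function of
#'   angle vector returning ground-truth radii about the centroid), and
#'   `traits` (one-row tibble of ground-truth L, W, W13, W12, W23, A, LW).
#' @export
render_leaf <- function(params, margin_px = 4L) {
  stopifnot(inherits(params, "leaf_shape_params"))
  ppmm <- params$pixels_per_mm
  poly <- shape_polygon(params)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  x0 <- xr[1] - margin_px / ppmm
  y0 <- yr[1] - margin_px / ppmm
  nx <- ceiling((xr[2] - x0) * ppmm) + margin_px
  ny <- ceiling((yr[2] - y0) * ppmm) + margin_px

  # pixel centers in mm relative to the shape origin
  px <- x0 + (seq_len(nx) - 0.5) / ppmm
  py <- y0 + (seq_len(ny) - 0.5) / ppmm
  X <- matrix(px, nx, ny)
  Y <- matrix(py, nx, ny, byrow = TRUE)
  inside <- if (params$family == "rectangle") {
    abs(X) <= params$b & abs(Y) <= params$a
  } else {
    rfun <- shape_radius_fn(params)
    sqrt(X^2 + Y^2) <= rfun(atan2(Y, X))
  }
  img <- matrix(0L, nx, ny)
  img[inside] <- 1L

  ctr <- poly_centroid(poly)
  # express the truth in the measurement frame: centroid at the origin, tip
  # (the boundary extreme farthest from the centroid) at +y
  norm_poly <- sweep(poly, 2, ctr)
  if (max(norm_poly[, 2]) < -min(norm_poly[, 2])) norm_poly <- -norm_poly
  radius_at <- make_truth_radius_fn(params, norm_poly)
  traits <- truth_traits(params, norm_poly)

  structure(
    list(image = img, pixels_per_mm = ppmm,
         origin_px = c(x = -x0 * ppmm, y = -y0 * ppmm),
         contour_mm = norm_poly, centroid_mm = ctr,
         radius_at = radius_at, traits = traits, params = params),
    class = "leaf_render"
  )
}

make_truth_radius_fn <- function(params, norm_poly) {
  a <- params$a; b <- params$b
  if (params$family == "circle") {
    return(function(theta) rep(a, length(theta)))
  }
  if (params$family == "ellipse") {
    return(function(theta) a * b / sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2))
  }
  if (params$family == "rectangle") {
    return(function(theta) {
      pmin(b / pmax(abs(cos(theta)), 1e-300), a / pmax(abs(sin(theta)), 1e-300))
    })
  }
  function(theta) poly_radii(norm_poly, theta)$radius
}

truth_traits <- function(params, poly) {
  a <- params$a; b <- params$b
  tr <- switch(params$family,
    "circle" = {
      w3 <- 2 * a * sqrt(1 - (1 / 3)^2)
      list(L = 2 * a, W = 2 * a, W13 = w3, W12 = 2 * a, W23 = w3, A = pi * a^2)
    },
    "ellipse" = {
      w3 <- 2 * b * sqrt(1 - (1 / 3)^2)
      list(L = 2 * a, W = 2 * b, W13 = w3, W12 = 2 * b, W23 = w3, A = pi * a * b)
    },
    "rectangle" = list(L = 2 * a, W = 2 * b, W13 = 2 * b, W12 = 2 * b,
                       W23 = 2 * b, A = 4 * a * b),
    "parametric-leaf" = {
      ymin <- min(poly[, 2]); ymax <- max(poly[, 2])
      L <- ymax - ymin
      list(L = L,
           W = poly_max_chord(poly),
           W13 = poly_chord_width(poly, ymin + L / 3),
           W12 = poly_chord_width(poly, ymin + L / 2),
           W23 = poly_chord_width(poly, ymin + 2 * L / 3),
           A = abs(poly_signed_area(poly)))
    }
  )
  tibble::tibble(L = tr$L, W = tr$W, W13 = tr$W13, W12 = tr$W12,
                 W23 = tr$W23, A = tr$A, LW = tr$L / tr$W)
}

#' @export
print.leaf_render <- function(x, ...) {
  cat("<leaf_render> ", x$params$family, ": ",
      paste(dim(x$image), collapse = " x "), " px at ",
      signif(x$pixels_per_mm, 5), " px/mm\n", sep = "")
  invisible(x)
}

#' Write a rendered leaf to a PNG file
#'
#' @param render A [render_leaf()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_leaf_png <- function(render, path) {
  stopifnot(inherits(render, "leaf_render"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG files", call. = FALSE)
  }
  # PNG rows run top-to-bottom; flip the y axis and transpose [x, y] -> [row, col]
  m <- t(render$image[, rev(seq_len(ncol(render$image))), drop = FALSE])
  png::writePNG(m, path)
  invisible(path)
}
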