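#' Leaf contour objects
#'
#' A `leaf_contour` is a tibble of ordered boundary points `(x, y)` in mm,
#' counter-clockwise, with the first point repeated as the last row so the
#' polygon is explicitly closed. Attributes track the pixel scale used, whether
#' the contour has been orientation-normalized (principal axis vertical, tip at
#' +y, centroid at the origin), and audit flags (`border_touch`,
#' `non_star_convex`, `axis_ambiguous`).
#'
#' @param xy A two-column matrix or data frame of boundary coordinates in mm.
#' @param pixels_per_mm Pixel scale the coordinates were derived from
#'   (`NA` for analytic contours).
#' @param normalized Logical flag.
#' @param flags Named logical vector of audit flags.
#' @return A `leaf_contour` tibble.
#' @export
leaf_contour <- function(xy, pixels_per_mm = NA_real_, normalized = FALSE,
                         flags = character(0)) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  colnames(xy) <- c("x", "y")
  xy <- poly_open(xy)
  if (nrow(xy) < 3) stop("a contour needs at least 3 points", call. = FALSE)
  if (poly_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy <- rbind(xy, xy[1, , drop = FALSE])  # explicit closure
  out <- tibble::as_tibble(as.data.frame(xy))
  structure(out,
            class = c("leaf_contour", class(out)),
            pixels_per_mm = pixels_per_mm,
            normalized = normalized,
            flags = flags)
}

contour_matrix <- function(contour) {
  poly_open(cbind(contour$x, contour$y))
}

is_normalized <- function(contour) isTRUE(attr(contour, "normalized"))

contour_flags <- function(contour) attr(contour, "flags") %||% character(0)

add_flag <- function(contour, flag) {
  attr(contour, "flags") <- union(contour_flags(contour), flag)
  contour
}

#' Extract the leaf contour from a raster image
#'
#' Binarizes the image (Otsu threshold for grayscale input; 0/1 images pass
#' through), labels connected foreground components, keeps the largest, and
#' traces its boundary as an ordered closed polygon in mm. Traced pixel-center
#' coordinates are pushed half a pixel along the outward normal so the polygon
#' follows the true foreground/background interface rather than the centers of
#' the outermost foreground pixels.
#'
#' @param image A numeric matrix indexed `[x, y]` with values in \[0, 1\]
#'   (as produced by [render_leaf()]), an `EBImage::Image`, or a path to an
#'   image file readable by EBImage.
#' @param pixels_per_mm Pixel scale used to convert to mm.
#' @param foreground `"bright"` if the leaf is brighter than the background
#'   (the convention of the synthetic renderer), `"dark"` for dark leaves on a
#'   light scanner bed.
#' @return A [leaf_contour()] in mm, with the image origin at the corner of
#'   pixel (1, 1); a `border_touch` flag is set when the selected component
#'   touches the image border.
#' @export
extract_contour <- function(image, pixels_per_mm = 11.811,
                            foreground = c("bright", "dark")) {
  foreground <- match.arg(foreground)
  if (inherits(image, "leaf_render")) {
    pixels_per_mm <- image$pixels_per_mm
    image <- image$image
  }
  if (is.character(image)) {
    image <- EBImage::readImage(image)
  }
  if (inherits(image, "Image")) {
    img <- EBImage::imageData(image)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  } else {
    img <- as.matrix(image)
  }
  if (foreground == "dark") img <- max(img) - img
  vals <- unique(as.vector(img))
  mask <- if (all(vals %in% c(0, 1))) {
    img == 1
  } else {
    img > EBImage::otsu(EBImage::Image(img), range = range(img))
  }
  if (!any(mask)) stop("no leaf found: image has empty foreground", call. = FALSE)

  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  biggest <- which.max(sizes)
  comp <- labm == biggest

  border_touch <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
    any(comp[, 1]) || any(comp[, ncol(comp)])
  if (border_touch) {
    warning("leaf component touches the image border; measurements may be truncated")
  }

  oc <- EBImage::ocontour(EBImage::Image(comp * 1))[[1]]
  if (nrow(oc) < 3) stop("traced contour is degenerate", call. = FALSE)
  # ocontour returns 0-based pixel indices; pixel (i, j) center sits at
  # (i - 0.5, j - 0.5) px from the image corner
  pts <- oc + 0.5

  # half-pixel outward-normal correction
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  tang <- nxt - prv
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  normal <- cbind(tang[, 2], -tang[, 1]) / len
  ctr <- colMeans(pts)
  outward <- sum(rowSums(normal * sweep(pts, 2, ctr)))
  if (outward < 0) normal <- -normal
  pts <- pts + 0.5 * normal

  # light circular smoothing knocks down the staircase ripple of the
  # 8-connected chain (~0.2 px) without moving real curvature at leaf scale
  pts <- (pts + pts[c(2:n, 1), , drop = FALSE] +
            pts[c(n, 1:(n - 1)), , drop = FALSE]) / 3

  leaf_contour(pts / pixels_per_mm, pixels_per_mm = pixels_per_mm,
               flags = if (border_touch) "border_touch" else character(0))
}

#' Area centroid of a leaf contour
#'
#' Shoelace-based area-weighted centroid of the closed boundary polygon (the
#' point radii are measured from), robust to uneven vertex spacing.
#'
#' @param contour A [leaf_contour()].
#' @return Named numeric vector `c(x, y)` in mm.
#' @export
contour_centroid <- function(contour) {
  stopifnot(inherits(contour, "leaf_contour"))
  ctr <- poly_centroid(contour_matrix(contour))
  c(x = ctr[1], y = ctr[2])
}

#' Normalize leaf orientation
#'
#' Translates the centroid to the origin and rotates the contour so that its
#' principal axis (from the second-order area moments of the enclosed region)
#' is vertical, with the tip -- the boundary extreme farthest from the centroid
#' along the axis -- pointing towards +y. Near-circular outlines (principal
#' moment ratio < 1.05) are only centered, flagged `axis_ambiguous`, and left
#' unrotated.
#'
#' @param contour A [leaf_contour()].
#' @return A normalized `leaf_contour` (idempotent up to numerical tolerance).
#' @export
normalize_orientation <- function(contour) {
  stopifnot(inherits(contour, "leaf_contour"))
  xy <- contour_matrix(contour)
  ctr <- poly_centroid(xy)
  xy <- sweep(xy, 2, ctr)

  cv <- poly_covariance(xy)
  e <- eigen(cv, symmetric = TRUE)
  flags <- contour_flags(contour)
  if (e$values[1] / max(e$values[2], .Machine$double.eps) < 1.05) {
    warning("principal axis ambiguous (near-circular outline); contour centered only")
    return(leaf_contour(xy, pixels_per_mm = attr(contour, "pixels_per_mm"),
                        normalized = TRUE,
                        flags = union(flags, "axis_ambiguous")))
  }
  ax <- e$vectors[, 1]  # major axis
  # canonical eigenvector sign (towards +y) so an already-normalized contour
  # maps to itself; the tip rule below decides any 180-degree flip
  if (ax[2] < 0 || (ax[2] == 0 && ax[1] < 0)) ax <- -ax
  # rotate ax onto (0, 1): R = [[ax_y, -ax_x], [ax_x, ax_y]]
  rot <- matrix(c(ax[2], -ax[1], ax[1], ax[2]), 2, 2, byrow = TRUE)
  xy <- xy %*% t(rot)

  # tip = boundary extreme farthest from the centroid along the axis;
  # the small tolerance keeps perfectly symmetric outlines stable (idempotence)
  if (max(xy[, 2]) < -min(xy[, 2]) * (1 - 1e-9)) xy <- -xy  # rotate by pi
  leaf_contour(xy, pixels_per_mm = attr(contour, "pixels_per_mm"),
               normalized = TRUE, flags = flags)
}
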