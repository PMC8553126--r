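#' Regular polar radii of a normalized leaf contour
#'
#' Measures the distance from the centroid (the origin of a normalized
#' contour) to the leaf margin at `n` regular angles
#' \eqn{\theta_l = -\pi + (l-1)\,2\pi/n}, by exact intersection of each ray
#' with the boundary polygon (linear interpolation between the two boundary
#' points bracketing the ray). If a ray crosses the boundary more than once
#' (a non-star-convex outline, e.g. strong lobing), the farthest intersection
#' is kept and the profile is flagged `non_star_convex`.
#'
#' Angle 0 points to the leaf's right; the tip sits at \eqn{+\pi/2} and the
#' base at \eqn{-\pi/2}, so the right half of the leaf spans
#' \eqn{[-\pi/2, \pi/2]}.
#'
#' @param contour A normalized [leaf_contour()] (see [normalize_orientation()]).
#' @param n Number of regular angles (default 360, the full-resolution set).
#' @return A `radial_profile` tibble with columns `angle` (radians) and
#'   `radius` (mm); attributes `kind` (e.g. `"RD360"`), `flags`, and the
#'   source contour (used by [reduce_radii()]).
#' @export
radial_profile <- function(contour, n = 360L) {
  stopifnot(inherits(contour, "leaf_contour"))
  if (!is_normalized(contour)) {
    stop("contour must be normalized first (see normalize_orientation())",
         call. = FALSE)
  }
  if (!is_count(n) || n < 3) stop("`n` must be a count >= 3", call. = FALSE)
  xy <- contour_matrix(contour)
  ctr <- poly_centroid(xy)
  if (sqrt(sum(ctr^2)) > 1e-6 * max(abs(xy))) {
    xy <- sweep(xy, 2, ctr)
  }
  angles <- -pi + (seq_len(n) - 1) * 2 * pi / n
  pr <- poly_radii(xy, angles)
  flags <- contour_flags(contour)
  if (any(pr$n_hits > 1)) flags <- union(flags, "non_star_convex")
  new_radial_profile(angles, pr$radius,
                     kind = if (n == 360L) "RD360" else sprintf("RD%d", n),
                     flags = flags, contour = contour)
}

new_radial_profile <- function(angles, radii, kind, flags = character(0),
                               contour = NULL) {
  out <- tibble::tibble(angle = angles, radius = radii)
  structure(out,
            class = c("radial_profile", class(out)),
            kind = kind, flags = flags, contour = contour)
}

#' Reduced right-side radius sets
#'
#' Extracts `k` equally spaced radii spanning the right side of the leaf from
#' \eqn{-\pi/2} to \eqn{\pi/2} inclusive (spacing \eqn{180/(k-1)} degrees).
#' Because the poplar leaf is close to bilaterally symmetric, the right-side
#' radii carry nearly all the shape information of the full 360-radius set.
#' Radii are re-measured from the source contour at exactly the requested
#' angles, not snapped to the nearest 1-degree grid point.
#'
#' @param profile A `radial_profile` from [radial_profile()] (which carries its
#'   source contour), or a normalized [leaf_contour()].
#' @param k Number of radii: one of 6, 9, 11, 16, 61.
#' @return A `radial_profile` tibble of `k` rows with kind `"RD06"`, `"RD09"`,
#'   `"RD11"`, `"RD16"` or `"RD61"`.
#' @export
reduce_radii <- function(profile, k) {
  if (!k %in% c(6L, 9L, 11L, 16L, 61L)) {
    stop("`k` must be one of 6, 9, 11, 16, 61", call. = FALSE)
  }
  contour <- if (inherits(profile, "radial_profile")) {
    attr(profile, "contour")
  } else if (inherits(profile, "leaf_contour")) {
    profile
  } else {
    stop("`profile` must be a radial_profile or leaf_contour", call. = FALSE)
  }
  if (is.null(contour)) {
    stop("profile does not carry its source contour", call. = FALSE)
  }
  if (!is_normalized(contour)) {
    stop("contour must be normalized first", call. = FALSE)
  }
  xy <- contour_matrix(contour)
  ctr <- poly_centroid(xy)
  if (sqrt(sum(ctr^2)) > 1e-6 * max(abs(xy))) xy <- sweep(xy, 2, ctr)
  angles <- -pi / 2 + (seq_len(k) - 1) * pi / (k - 1)
  pr <- poly_radii(xy, angles)
  flags <- if (inherits(profile, "radial_profile")) {
    attr(profile, "flags") %||% character(0)
  } else {
    contour_flags(contour)
  }
  if (any(pr$n_hits > 1)) flags <- union(flags, "non_star_convex")
  new_radial_profile(angles, pr$radius, kind = sprintf("RD%02d", k),
                     flags = flags, contour = contour)
}

#' Classic leaf size traits
#'
#' Computes the standard scalar leaf descriptors from a normalized contour:
#' length `L` (vertical extent), maximum width `W` (widest horizontal chord),
#' the widths `W13`, `W12`, `W23` at one-third, half, and two-thirds of the
#' length from the base, the area `A` (shoelace polygon area), and the
#' length-to-width ratio `LW`.
#'
#' @param contour A normalized [leaf_contour()].
#' @return A one-row tibble with columns `L`, `W`, `W13`, `W12`, `W23`
#'   (mm), `A` (mm^2) and `LW`.
#' @export
classic_traits <- function(contour) {
  stopifnot(inherits(contour, "leaf_contour"))
  if (!is_normalized(contour)) {
    stop("contour must be normalized first (see normalize_orientation())",
         call. = FALSE)
  }
  xy <- contour_matrix(contour)
  ymin <- min(xy[, 2]); ymax <- max(xy[, 2])
  L <- ymax - ymin
  W <- poly_max_chord(xy)
  tibble::tibble(
    L = L,
    W = W,
    W13 = poly_chord_width(xy, ymin + L / 3),
    W12 = poly_chord_width(xy, ymin + L / 2),
    W23 = poly_chord_width(xy, ymin + 2 * L / 3),
    A = abs(poly_signed_area(xy)),
    LW = L / W
  )
}

#' Run the full measurement pipeline on one image
#'
#' Convenience wrapper: contour extraction, orientation normalization, classic
#' traits, and the requested radius sets for a single leaf image.
#'
#' @inheritParams extract_contour
#' @param radii Character vector of radius sets to extract, from
#'   `"RD360"`, `"RD61"`, `"RD16"`, `"RD11"`, `"RD09"`, `"RD06"`.
#' @return A list with elements `contour` (normalized), `traits` (one-row
#'   tibble) and `radii` (named list of `radial_profile`s).
#' @export
measure_leaf <- function(image, pixels_per_mm = 11.811,
                         foreground = c("bright", "dark"),
                         radii = c("RD360", "RD11")) {
  kinds <- c(RD360 = 360L, RD61 = 61L, RD16 = 16L, RD11 = 11L, RD09 = 9L,
             RD06 = 6L)
  radii <- match.arg(radii, names(kinds), several.ok = TRUE)
  contour <- normalize_orientation(
    extract_contour(image, pixels_per_mm, foreground)
  )
  full <- radial_profile(contour, 360L)
  out <- lapply(radii, function(kind) {
    if (kind == "RD360") full else reduce_radii(full, kinds[[kind]])
  })
  names(out) <- radii
  list(contour = contour, traits = classic_traits(contour), radii = out)
}
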