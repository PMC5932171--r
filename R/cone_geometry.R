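# Vote-cone membership and axis-aligned bounding volumes.
#
# All geometry is evaluated in physical space: lattice offsets are scaled
# per axis by the micrometer spacing before any angle or distance test, so
# membership is invariant to sampling resolution and anisotropy.

#' Vote cone specification
#'
#' A cone with apex at a lattice position, a unit direction, physical
#' length `radius_r` (micrometers) and full opening angle `aperture_phi`.
#'
#' @param apex numeric lattice position (pixels; may be fractional).
#' @param direction numeric vector, normalized internally; interpreted in
#'   physical space.
#' @param radius_r cone length in micrometers, > 0.
#' @param aperture_phi full opening angle in radians, in (0, pi/2].
#' @return a `cone_spec` object.
#' @export
cone_spec <- function(apex, direction, radius_r, aperture_phi) {
  apex <- as.numeric(apex)
  direction <- as.numeric(direction)
  if (length(apex) != length(direction))
    stop("apex and direction must have the same dimensionality")
  if (!length(apex) %in% 2:3) stop("cone must be 2D or 3D")
  if (!is.finite(radius_r) || radius_r <= 0) stop("radius_r must be > 0")
  if (!is.finite(aperture_phi) || aperture_phi <= 0 || aperture_phi > pi / 2)
    stop("aperture_phi must lie in (0, pi/2]")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  structure(list(apex = apex, direction = direction / nrm,
                 radius_r = radius_r, aperture_phi = aperture_phi),
            class = "cone_spec")
}

#' Cone membership test
#'
#' A position `p` is inside the vote cone iff the physical-space angle
#' between `p - apex` and the cone direction is strictly less than
#' `aperture_phi / 2` and the physical distance `|p - apex|` is strictly
#' less than `radius_r`.  The angle test uses the cosine form
#' `dot > 0 && dot^2 > cos^2(phi/2) * |q|^2` in both 2D and 3D (valid since
#' phi <= pi/2), identically to the compiled voting kernels.  The apex
#' itself is defined to be outside (a voter does not vote for itself).
#'
#' @param cone a [cone_spec()].
#' @param p lattice position, or a matrix with one position per row.
#' @param spacing physical pixel size per axis in micrometers.
#' @return logical vector, one entry per row of `p`.
#' @export
cone_contains <- function(cone, p, spacing = 1) {
  stopifnot(inherits(cone, "cone_spec"))
  p <- rbind(p)
  nd <- length(cone$apex)
  if (ncol(p) != nd) stop("p has wrong dimensionality")
  spacing <- rep_len(as.numeric(spacing), nd)
  q <- sweep(sweep(p, 2, cone$apex, `-`), 2, spacing, `*`)
  d2 <- rowSums(q^2)
  dot <- as.numeric(q %*% cone$direction)
  c2 <- cos(cone$aperture_phi / 2)^2
  d2 > 0 & d2 < cone$radius_r^2 & dot > 0 & dot * dot > c2 * d2
}

#' Tight axis-aligned bounding box of a vote cone
#'
#' The cone-plus-spherical-cap solid is a spherical sector and therefore
#' convex; its extreme along any axis direction `e` is
#' `r * cos(max(0, theta - phi/2))` clamped below at 0 (the apex), where
#' `theta` is the angle between the cone direction and `e`.  The box is
#' computed in physical space, converted to (possibly fractional) pixel
#' coordinates per axis, and optionally clipped to the lattice.  Every
#' lattice site passing [cone_contains()] lies inside the box.
#'
#' @param cone a [cone_spec()].
#' @param image_shape optional lattice extents; when given, the box is
#'   clipped to `[1, image_shape]` (1-based).
#' @param spacing physical pixel size per axis in micrometers.
#' @return a `bounding_box`: list with numeric `lower` and `upper` pixel
#'   coordinates per axis.
#' @export
cone_bounding_box <- function(cone, image_shape = NULL, spacing = 1) {
  stopifnot(inherits(cone, "cone_spec"))
  nd <- length(cone$apex)
  spacing <- rep_len(as.numeric(spacing), nd)
  ch <- cos(cone$aperture_phi / 2)
  sh <- sin(cone$aperture_phi / 2)
  ext <- function(ca) {
    # extent along an axis whose angle to the direction has cosine ca
    ifelse(ca >= ch, cone$radius_r, {
      cam <- ca * ch + sqrt(pmax(0, 1 - ca^2)) * sh
      pmax(0, cone$radius_r * cam)
    })
  }
  u <- cone$direction
  lower <- cone$apex - ext(-u) / spacing
  upper <- cone$apex + ext(u) / spacing
  if (!is.null(image_shape)) {
    lower <- pmax(lower, 1)
    upper <- pmin(upper, image_shape)
  }
  structure(list(lower = lower, upper = upper), class = "bounding_box")
}

# integer site range of a (continuous) bounding box, clipped to the lattice;
# returns NULL when empty
box_site_range <- function(box, image_shape) {
  lo <- pmax(1L, as.integer(ceiling(box$lower - 1e-9)))
  hi <- pmin(as.integer(image_shape), as.integer(floor(box$upper + 1e-9)))
  if (any(lo > hi)) return(NULL)
  list(lo = lo, hi = hi)
}

#' Enumerate lattice sites inside a vote cone
#'
#' Lists exactly the lattice sites within the cone's bounding box that pass
#' [cone_contains()], in storage order (x varying fastest, then y, then z)
#' — the deterministic order used for tie-breaking throughout.
#'
#' @inheritParams cone_bounding_box
#' @param image_shape lattice extents (required: sites are clipped to it).
#' @return integer matrix with one site (1-based) per row; zero rows when
#'   the cone misses the lattice.
#' @export
cone_member_sites <- function(cone, image_shape, spacing = 1) {
  nd <- length(cone$apex)
  box <- cone_bounding_box(cone, image_shape, spacing)
  rng <- box_site_range(box, image_shape)
  empty <- matrix(integer(0), ncol = nd)
  if (is.null(rng)) return(empty)
  axes <- lapply(seq_len(nd), function(a) rng$lo[a]:rng$hi[a])
  cand <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(cand) <- NULL
  keep <- cone_contains(cone, cand, spacing)
  if (!any(keep)) return(empty)
  cand[keep, , drop = FALSE]
}
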