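# The iterative core: vote accumulation, direction refinement, and the
# aperture-narrowing schedule.

new_vote_field <- function(scores, spacing, iteration_index = 0L, phi = NA_real_) {
  structure(list(scores = scores, shape = dim(scores), spacing = spacing,
                 iteration_index = iteration_index, phi = phi),
            class = "vote_field")
}

#' @export
print.vote_field <- function(x, ...) {
  cat("<vote_field> ", paste(x$shape, collapse = " x "),
      ", iteration ", x$iteration_index,
      ", total mass ", signif(sum(x$scores), 6), "\n", sep = "")
  invisible(x)
}

check_vote_params <- function(field, r, spacing) {
  if (!is.finite(r) || r < min(spacing))
    stop("cone length r = ", r, " um is smaller than one pixel (",
         min(spacing), " um)")
}

#' Cast votes from every voter into its cone (project formulation)
#'
#' The vote field starts at zero; each site with positive gradient
#' magnitude adds its magnitude to every lattice site inside its vote cone
#' (length `r` micrometers, full aperture `phi`).  Accumulation is
#' order-independent, and the returned field carries a `mass` attribute on
#' `scores` equal to `sum_t M(t) * |members(t)|` tallied per voter — the
#' bookkeeping identity `sum(scores) == mass` holds to floating tolerance.
#'
#' @param field a `gradient_field` from [compute_gradient()].
#' @param r cone length in micrometers.
#' @param phi full cone aperture in radians, in (0, pi/2].
#' @param spacing physical pixel size per axis (defaults to the field's).
#' @return a `vote_field`.
#' @export
cast_votes <- function(field, r, phi, spacing = field$spacing) {
  stopifnot(inherits(field, "gradient_field"))
  check_vote_params(field, r, spacing)
  v <- cpp_cast_votes(as.numeric(field$magnitude), direction_matrix(field),
                      as.integer(field$shape), as.numeric(spacing),
                      r, phi)
  mass <- attr(v, "mass")
  scores <- array(as.numeric(v), dim = field$shape)
  attr(scores, "mass") <- mass
  new_vote_field(scores, spacing, phi = phi)
}

#' Collect votes by exhaustive scan (reference formulation)
#'
#' For every lattice site, sums the magnitudes of all voters whose cone
#' contains it, scanning every voter with no bounding-box pruning.  This
#' is the slow dual of [cast_votes()]; the two agree to floating tolerance
#' and the equivalence is exercised in the test-suite.  Intended for small
#' fields only.
#'
#' @inheritParams cast_votes
#' @return a `vote_field`.
#' @export
collect_votes_oracle <- function(field, r, phi, spacing = field$spacing) {
  stopifnot(inherits(field, "gradient_field"))
  check_vote_params(field, r, spacing)
  nd <- length(field$shape)
  spacing <- rep_len(as.numeric(spacing), nd)
  mag <- as.numeric(field$magnitude)
  dm <- direction_matrix(field)
  voters <- which(mag > 0 & is.finite(dm[, 1]))
  axes <- lapply(field$shape, seq_len)
  sites <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  tpos <- sites[voters, , drop = FALSE]
  u <- dm[voters, , drop = FALSE]
  m <- mag[voters]
  c2 <- cos(phi / 2)^2
  scores <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    q <- sweep(sweep(tpos, 2, sites[i, ], `-`), 2, -spacing, `*`)
    # q = (p - t) * spacing for every voter t
    d2 <- rowSums(q^2)
    dot <- rowSums(q * u)
    inside <- d2 > 0 & d2 < r^2 & dot > 0 & dot * dot > c2 * d2
    scores[i] <- sum(m[inside])
  }
  new_vote_field(array(scores, dim = field$shape), spacing, phi = phi)
}

#' Re-orient voters toward their cone vote maximum
#'
#' Each voter finds the maximum of the vote field inside its cone and
#' points its new direction at that site (unit vector of the physical
#' offset).  Ties take the first site in storage order; voters whose cone
#' is empty or contains only zero scores keep their previous direction.
#' Gradient magnitudes are preserved exactly.
#'
#' @param field a `gradient_field`.
#' @param votes the `vote_field` produced with the same `r` and `phi`.
#' @inheritParams cast_votes
#' @return an updated `gradient_field`.
#' @export
update_directions <- function(field, votes, r, phi, spacing = field$spacing) {
  stopifnot(inherits(field, "gradient_field"), inherits(votes, "vote_field"))
  if (!identical(as.integer(field$shape), as.integer(votes$shape)))
    stop("gradient field and vote field have different shapes")
  newdir <- cpp_update_directions(as.numeric(field$magnitude),
                                  direction_matrix(field),
                                  as.numeric(votes$scores),
                                  as.integer(field$shape),
                                  as.numeric(spacing), r, phi)
  set_directions(field, newdir)
}

#' Aperture-narrowing iteration schedule
#'
#' The aperture starts at `phi0` (pi/2 by default — detection is
#' insensitive to larger values) and is multiplied by `shrink_factor` each
#' iteration; iteration stops once the cone is narrower than one pixel at
#' distance r, i.e. at the terminating aperture `phi_t = 1 / r_pixels`
#' (small-angle arc width).  The schedule lists every aperture actually
#' used; the final one is the first below `phi_t`.
#'
#' @param r_pixels minimum per-axis cone length in pixels (>= 1).
#' @param phi0 initial full aperture in radians (default pi/2).
#' @param shrink_factor per-iteration multiplier in (0, 1); the default
#'   1/2 halves the aperture (binary search on the angle).
#' @return an `iteration_schedule`: list with `phi0`, `phi_t`,
#'   `shrink_factor`, `n_iterations` and the aperture sequence `phis`.
#' @examples
#' make_schedule(10)$phis  # pi/2, pi/4, ..., pi/32 < 0.1
#' @export
make_schedule <- function(r_pixels, phi0 = pi / 2, shrink_factor = 0.5) {
  if (!is.finite(r_pixels) || r_pixels < 1)
    stop("r_pixels must be >= 1")
  if (phi0 <= 0 || phi0 > pi / 2) stop("phi0 must lie in (0, pi/2]")
  if (shrink_factor <= 0 || shrink_factor >= 1)
    stop("shrink_factor must lie in (0, 1)")
  phi_t <- 1 / r_pixels
  phis <- phi0
  while (phis[length(phis)] >= phi_t)
    phis <- c(phis, phis[length(phis)] * shrink_factor)
  structure(list(phi0 = phi0, phi_t = phi_t, shrink_factor = shrink_factor,
                 n_iterations = length(phis), phis = phis),
            class = "iteration_schedule")
}

#' @export
print.iteration_schedule <- function(x, ...) {
  cat("<iteration_schedule> ", x$n_iterations, " iterations, phi = ",
      paste(signif(x$phis, 4), collapse = ", "),
      " (phi_t = ", signif(x$phi_t, 4), ")\n", sep = "")
  invisible(x)
}

#' Run the full iterative voting pipeline
#'
#' Blur, gradient, then alternate vote casting and direction refinement
#' while narrowing the cone aperture per [make_schedule()]; the vote field
#' from the final (narrowest) aperture is returned.  Deterministic for
#' fixed inputs.
#'
#' @param image an [image_grid()].
#' @param radius_um maximum cell radius in micrometers; must exceed the
#'   largest per-axis spacing.
#' @param polarity `"dark"` or `"bright"` (see [compute_gradient()]).
#' @param sigma Gaussian blur width in pixels on the finest axis; the
#'   physical blur is kept isotropic by scaling per axis with the spacing
#'   ratio.  Default 2.
#' @param blur set `FALSE` to skip smoothing (high-SNR inputs).
#' @param phi0,shrink_factor schedule controls, see [make_schedule()].
#' @param trace when `TRUE`, attach a per-iteration data frame (aperture,
#'   field mass, per-voter bookkeeping mass) as attribute `"trace"`.
#' @param verbose log one line per iteration.
#' @return the final `vote_field` (with `iteration_index = n_iterations`).
#' @export
iterative_vote <- function(image, radius_um, polarity = c("dark", "bright"),
                           sigma = 2, blur = TRUE, phi0 = pi / 2,
                           shrink_factor = 0.5, trace = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(image, "image_grid"))
  polarity <- match.arg(polarity)
  if (!is.finite(radius_um) || radius_um <= max(image$spacing))
    stop("radius_um must exceed the largest per-axis spacing (",
         max(image$spacing), " um)")
  if (blur && sigma > 0) {
    sigma_axis <- sigma * min(image$spacing) / image$spacing
    image <- gaussian_blur(image, sigma_axis)
  }
  field <- compute_gradient(image, polarity)
  sched <- make_schedule(radius_um / max(image$spacing), phi0, shrink_factor)
  votes <- NULL
  tr <- vector("list", sched$n_iterations)
  for (i in seq_len(sched$n_iterations)) {
    phi <- sched$phis[i]
    votes <- cast_votes(field, radius_um, phi)
    if (trace)
      tr[[i]] <- data.frame(iteration = i, phi = phi,
                            vote_mass = sum(votes$scores),
                            bookkeeping_mass = attr(votes$scores, "mass"))
    if (verbose)
      message(sprintf("iteration %d/%d: phi = %.4f rad, vote mass = %.6g",
                      i, sched$n_iterations, phi, sum(votes$scores)))
    if (i < sched$n_iterations)
      field <- update_directions(field, votes, radius_um, phi)
  }
  votes$iteration_index <- sched$n_iterations
  if (trace) attr(votes, "trace") <- do.call(rbind, tr)
  votes
}
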