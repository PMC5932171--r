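# Phantom generator: 2D/3D images with known ground truth, emulating
# brightfield (dark nuclei on light neuropil, some with nucleolus-like
# cores) and fluorescence (bright nuclei on dark background) content.

#' Phantom specification
#'
#' Describes a synthetic image with ground truth.  Generation is a pure
#' function of the spec: the same seed always yields bit-identical output.
#'
#' @param shape lattice extents per axis (2 or 3 entries).
#' @param spacing physical pixel size per axis in micrometers.
#' @param n_cells number of cells to place (>= 0).
#' @param radius_range_um (min, max) cell radius in micrometers.
#' @param polarity `"dark"` (brightfield-like) or `"bright"`
#'   (fluorescence-like).
#' @param intensity_contrast cell-vs-background intensity difference in
#'   \[0, 1\].
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param min_separation_factor minimum center distance as a multiple of
#'   the mean radius.
#' @param hollow_fraction fraction of cells rendered with a contrasting
#'   core (nucleolus mimic) in \[0, 1\].
#' @param seed RNG seed.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape, spacing = 1, n_cells = 10,
                         radius_range_um = c(3, 8),
                         polarity = c("dark", "bright"),
                         intensity_contrast = 0.5, noise_sigma = 0.05,
                         min_separation_factor = 2.2, hollow_fraction = 0,
                         seed = 1L) {
  polarity <- match.arg(polarity)
  shape <- as.integer(shape)
  if (!length(shape) %in% 2:3 || any(shape < 3)) stop("invalid shape")
  spacing <- rep_len(as.numeric(spacing), length(shape))
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (n_cells < 0) stop("n_cells must be >= 0")
  radius_range_um <- as.numeric(radius_range_um)
  if (length(radius_range_um) != 2 || any(radius_range_um <= 0) ||
      diff(radius_range_um) < 0)
    stop("radius_range_um must be a positive (min, max) pair")
  if (hollow_fraction < 0 || hollow_fraction > 1)
    stop("hollow_fraction must lie in [0, 1]")
  if (intensity_contrast < 0 || intensity_contrast > 1)
    stop("intensity_contrast must lie in [0, 1]")
  structure(list(shape = shape, spacing = spacing,
                 n_cells = as.integer(n_cells),
                 radius_range_um = radius_range_um, polarity = polarity,
                 intensity_contrast = intensity_contrast,
                 noise_sigma = noise_sigma,
                 min_separation_factor = min_separation_factor,
                 hollow_fraction = hollow_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Named phantom presets
#'
#' `"kesm_like"`: dark, densely packed nuclei of 3-8 um radius on a light
#' neuropil-gray background, 30% carrying a contrasting nucleolus-like
#' core — the content that defeats naive blob detectors in brightfield
#' serial-section data.  `"fluor_like"`: sparse solid bright nuclei on a
#' dark background, as in confocal fluorescence stacks.
#'
#' @param preset `"kesm_like"` or `"fluor_like"`.
#' @param ... overrides passed to [phantom_spec()] (e.g. `shape`,
#'   `n_cells`, `seed`).
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(preset = c("kesm_like", "fluor_like"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    kesm_like = list(polarity = "dark", radius_range_um = c(3, 8),
                     hollow_fraction = 0.3, intensity_contrast = 0.5,
                     noise_sigma = 0.05, min_separation_factor = 2.2),
    fluor_like = list(polarity = "bright", radius_range_um = c(3, 8),
                      hollow_fraction = 0, intensity_contrast = 0.6,
                      noise_sigma = 0.03, min_separation_factor = 3))
  args <- list(...)
  do.call(phantom_spec, c(args, defaults[setdiff(names(defaults),
                                                 names(args))]))
}

# run fn with a private RNG stream; the caller's RNG state is untouched
with_private_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a phantom image with ground truth
#'
#' Centers are rejection-sampled to honor the minimum separation (in
#' physical units) and to keep each sphere fully inside the lattice.
#' Cells are rendered as anti-aliased spheres/disks (partial-volume edge
#' softening over one voxel); hollow cells additionally get a core of
#' 0.35x their radius whose intensity reverts to the background.  Additive
#' Gaussian noise is applied last and the image clamped to \[0, 1\].
#'
#' @param spec a [phantom_spec()] or [phantom_preset()].
#' @return a `phantom_truth`: list with `image` (an [image_grid()]),
#'   `centers` (matrix of 1-based pixel positions, one row per cell) and
#'   `radii_um`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_private_seed(spec$seed, function() generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  nd <- length(spec$shape)
  mean_r <- mean(spec$radius_range_um)
  min_sep <- spec$min_separation_factor * mean_r
  centers <- matrix(numeric(0), 0, nd)
  radii <- numeric(0)
  hollow <- logical(0)
  attempts <- 0
  while (nrow(centers) < spec$n_cells) {
    attempts <- attempts + 1
    if (attempts > 10000)
      stop("could not place ", spec$n_cells, " cells after 10000 attempts; ",
           "lower the density (fewer cells, smaller radii, or a larger image)")
    r <- runif(1, spec$radius_range_um[1], spec$radius_range_um[2])
    margin <- r / spec$spacing
    if (any(spec$shape - 2 * margin < 1)) next
    pos <- 1 + margin + runif(nd) * (spec$shape - 1 - 2 * margin)
    if (nrow(centers) > 0) {
      d2 <- colSums((t(lattice_to_um(centers, spec$spacing)) -
                       as.numeric(lattice_to_um(pos, spec$spacing)))^2)
      if (any(d2 < min_sep^2)) next
    }
    centers <- rbind(centers, pos)
    radii <- c(radii, r)
    hollow <- c(hollow, runif(1) < spec$hollow_fraction)
  }
  bg <- if (spec$polarity == "dark") 0.85 else 0.15
  delta <- if (spec$polarity == "dark") -spec$intensity_contrast else
    spec$intensity_contrast
  vals <- array(bg, dim = spec$shape)
  soft <- mean(spec$spacing)  # 1-voxel partial-volume softening
  for (k in seq_len(nrow(centers))) {
    vals <- render_ball(vals, centers[k, ], radii[k], spec$spacing,
                        delta, soft)
    if (hollow[k])
      vals <- render_ball(vals, centers[k, ], 0.35 * radii[k], spec$spacing,
                          -delta, soft)
  }
  if (spec$noise_sigma > 0)
    vals <- vals + array(rnorm(length(vals), 0, spec$noise_sigma),
                         dim = spec$shape)
  vals[] <- pmin(1, pmax(0, vals))
  rownames(centers) <- NULL
  structure(list(image = image_grid(vals, spec$spacing), centers = centers,
                 radii_um = radii, spec = spec),
            class = "phantom_truth")
}

# add delta * coverage(ball) to the value array within the ball's support
render_ball <- function(vals, center, radius_um, spacing, delta, soft) {
  nd <- length(dim(vals))
  shape <- dim(vals)
  ext <- (radius_um + soft) / spacing
  lo <- pmax(1L, as.integer(floor(center - ext)))
  hi <- pmin(shape, as.integer(ceiling(center + ext)))
  axes <- lapply(seq_len(nd), function(a) lo[a]:hi[a])
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  d <- sqrt(colSums((t(grid) - center)^2 * spacing^2))
  alpha <- pmin(1, pmax(0, (radius_um + soft / 2 - d) / soft))
  idx <- as.matrix(grid)
  lin <- idx[, 1]
  mult <- shape[1]
  for (a in seq_len(nd)[-1]) {
    lin <- lin + (idx[, a] - 1) * mult
    mult <- mult * shape[a]
  }
  vals[lin] <- vals[lin] + delta * alpha
  vals
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", nrow(x$centers), " cells in ",
      paste(x$image$shape, collapse = " x "), " (",
      x$spec$polarity, ")\n", sep = "")
  invisible(x)
}

#' Down-sample a phantom along z with corrected spacing
#'
#' Keeps every `z_factor`-th slice and multiplies the z spacing
#' accordingly, rescaling truth centers — an anisotropic acquisition of
#' the same scene, used to check that detection in physical units is
#' independent of sampling anisotropy.
#'
#' @param truth a `phantom_truth` (3D).
#' @param z_factor integer down-sampling factor >= 1.
#' @return a new `phantom_truth`.
#' @export
generate_anisotropic_variant <- function(truth, z_factor) {
  stopifnot(inherits(truth, "phantom_truth"))
  z_factor <- as.integer(z_factor)
  if (z_factor < 1) stop("z_factor must be >= 1")
  if (z_factor == 1) return(truth)
  img <- truth$image
  if (n_dim(img) != 3) stop("anisotropic variant requires a 3D phantom")
  keep <- seq(1, img$shape[3], by = z_factor)
  if (length(keep) < 3)
    stop("z_factor ", z_factor, " leaves fewer than 3 slices")
  vals <- img$values[, , keep, drop = FALSE]
  spacing <- img$spacing * c(1, 1, z_factor)
  centers <- truth$centers
  centers[, 3] <- (centers[, 3] - 1) / z_factor + 1
  out <- truth
  out$image <- image_grid(vals, spacing)
  out$centers <- centers
  out
}

#' Write a phantom as TIFF plus ground-truth CSV
#'
#' The truth CSV has columns `x, y, z` (0-based pixels; `z` omitted for
#' 2D) and `radius_um`.
#'
#' @param truth a `phantom_truth`.
#' @param image_path output TIFF path.
#' @param truth_path output CSV path.
#' @return invisibly, a list of the two paths.
#' @export
write_phantom <- function(truth, image_path, truth_path) {
  stopifnot(inherits(truth, "phantom_truth"))
  write_image_grid(truth$image, image_path)
  nd <- n_dim(truth$image)
  ax <- c("x", "y", "z")[seq_len(nd)]
  px <- truth$centers - 1
  if (nrow(px) == 0) px <- matrix(numeric(0), 0, nd)
  df <- data.frame(px, radius_um = truth$radii_um)
  names(df) <- c(ax, "radius_um")
  write.csv(df, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(image = image_path, truth = truth_path))
}

#' Read a ground-truth CSV written by [write_phantom()]
#'
#' @param path CSV path.
#' @return list with `centers` (1-based pixel matrix) and `radii_um`.
#' @export
read_truth_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("not a center CSV (needs x, y[, z] columns): ", path)
  nd <- if ("z" %in% names(df)) 3 else 2
  centers <- as.matrix(df[, c("x", "y", "z")[seq_len(nd)], drop = FALSE]) + 1
  if (nrow(df) == 0) centers <- matrix(numeric(0), 0, nd)
  radii <- if ("radius_um" %in% names(df)) df$radius_um else
    rep(NA_real_, nrow(df))
  list(centers = centers, radii_um = radii)
}
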