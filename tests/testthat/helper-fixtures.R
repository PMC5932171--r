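# Shared fixtures: hand-built gradient fields, brute-force cone oracles,
# and small rendered blobs.  Everything is generated in code.

# gradient field from raw parts (2D dir = angle array, 3D dir = unit-vector
# array with a trailing axis of length 3)
make_gradient_field <- function(mag, dir, spacing = 1, polarity = "bright") {
  structure(list(magnitude = mag, direction = dir, polarity = polarity,
                 shape = dim(mag),
                 spacing = rep_len(spacing, length(dim(mag)))),
            class = "gradient_field")
}

# random voter field: ~`density` of sites vote with random magnitude and
# uniformly random direction
random_gradient_field <- function(shape, spacing = 1, density = 0.7) {
  nd <- length(shape)
  n <- prod(shape)
  mag <- array(runif(n), dim = shape)
  mag[runif(n) > density] <- 0
  null <- mag == 0
  if (nd == 2) {
    th <- array(runif(n, 0, 2 * pi), dim = shape)
    th[null] <- NA_real_
    dir <- th
  } else {
    v <- matrix(rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    v[null, ] <- NA_real_
    dir <- array(v, dim = c(shape, 3))
  }
  make_gradient_field(mag, dir, spacing)
}

# full-window brute-force cone membership (no bounding-box pruning):
# scans every site within ceiling(r/spacing)+1 of the apex
brute_force_members <- function(cone, image_shape, spacing = 1) {
  nd <- length(cone$apex)
  spacing <- rep_len(spacing, nd)
  w <- ceiling(cone$radius_r / spacing) + 1
  lo <- pmax(1, floor(cone$apex - w))
  hi <- pmin(image_shape, ceiling(cone$apex + w))
  cand <- as.matrix(expand.grid(lapply(seq_len(nd), function(a) lo[a]:hi[a]),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(cand) <- NULL
  cand[cone_contains(cone, cand, spacing), , drop = FALSE]
}

# canonical row order for set comparison of site matrices
sort_sites <- function(m) {
  if (nrow(m) == 0) return(m)
  m[do.call(order, lapply(seq_len(ncol(m)), function(a) m[, a])), ,
    drop = FALSE]
}

random_cone <- function(nd, shape) {
  apex <- sapply(shape, function(s) sample(seq_len(s), 1))
  dir <- rnorm(nd)
  while (sum(dir^2) == 0) dir <- rnorm(nd)
  cone_spec(apex, dir, radius_r = runif(1, 1.5, 6),
            aperture_phi = runif(1, 0.15, pi / 2))
}

# detection set straight from centers/scores (bypasses peak finding)
make_dets <- function(centers, scores, r, spacing = 1) {
  centers <- rbind(centers)
  radvote:::new_detection_set(centers, scores, r,
                              rep_len(spacing, ncol(centers)))
}

# dark ball/disk of radius r_px (integer center) on a light background,
# with a 1-voxel linear edge ramp
render_dark_blob <- function(shape, center, r_px, bg = 0.85, fg = 0.35) {
  nd <- length(shape)
  axes <- lapply(seq_len(nd), function(a) (seq_len(shape[a]) - center[a])^2)
  d2 <- Reduce(`+`, lapply(seq_len(nd), function(a) {
    array(rep(axes[[a]], each = prod(shape[seq_len(a - 1)])), dim = shape)
  }))
  d <- sqrt(d2)
  alpha <- pmin(1, pmax(0, r_px + 0.5 - d))
  image_grid(array(bg + alpha * (fg - bg), dim = shape), 1)
}

rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])
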