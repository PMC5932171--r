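# Noise suppression and gradient-field initialization.

# 1D Gaussian convolution matrix with half-sample symmetric (reflective)
# boundaries.  The matrix is symmetric with unit row sums, so both the
# filter response to a constant and the total image mass are preserved.
gauss_conv_matrix <- function(n, sigma) {
  radius <- as.integer(ceiling(4 * sigma))
  if (radius < 1) return(diag(n))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  C <- matrix(0, n, n)
  for (off in -radius:radius) {
    w <- k[off + radius + 1]
    for (i in seq_len(n)) {
      j <- i + off
      # reflect about the half-sample edges: 0 -> 1, -1 -> 2, n+1 -> n, ...
      while (j < 1 || j > n) {
        if (j < 1) j <- 1 - j
        if (j > n) j <- 2 * n + 1 - j
      }
      C[i, j] <- C[i, j] + w
    }
  }
  C
}

# apply an n_a x n_a matrix along axis `axis` of an array
apply_along_axis <- function(values, axis, M) {
  d <- dim(values)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  v <- aperm(values, perm)
  v <- M %*% matrix(v, nrow = d[axis])
  v <- array(v, dim = d[perm])
  aperm(v, order(perm))
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable Gaussian blur; kernels are truncated at 4 sigma and applied
#' with half-sample symmetric boundary reflection, which conserves the
#' total intensity mass exactly.  `sigma = 0` along an axis leaves that
#' axis untouched.
#'
#' @param image an [image_grid()].
#' @param sigma standard deviation in pixels, scalar or per axis.
#' @return a blurred [image_grid()] with identical shape and spacing.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(inherits(image, "image_grid"))
  nd <- n_dim(image)
  sigma <- rep_len(as.numeric(sigma), nd)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be nonnegative along every axis")
  v <- image$values
  for (a in seq_len(nd)) {
    if (sigma[a] > 0) {
      C <- gauss_conv_matrix(image$shape[a], sigma[a])
      v <- apply_along_axis(v, a, C)
    }
  }
  out <- image
  out$values <- v
  out
}

# per-axis derivative in physical units: second-order central differences in
# the interior, first-order one-sided at the boundaries
axis_derivative <- function(values, axis, h) {
  d <- dim(values)
  nd <- length(d)
  n <- d[axis]
  idx <- function(i) {
    args <- rep(list(quote(expr = )), nd)
    args[[axis]] <- i
    do.call(`[`, c(list(values), args, list(drop = FALSE)))
  }
  der <- array(0, dim = d)
  asn <- function(i, val) {
    args <- rep(list(quote(expr = )), nd)
    args[[axis]] <- i
    do.call(`[<-`, c(list(der), args, list(value = val)))
  }
  der <- asn(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
  der <- asn(1, (idx(2) - idx(1)) / h)
  der <- asn(n, (idx(n) - idx(n - 1)) / h)
  der
}

#' Gradient magnitude and vote-direction field
#'
#' Derivatives use second-order central differences in the interior and
#' first-order one-sided differences on the boundary, divided by the
#' per-axis physical spacing so anisotropic stacks yield correct physical
#' orientations.  The stored direction is the unit gradient for
#' `polarity = "bright"` and the negated unit gradient for
#' `polarity = "dark"`, so the vote cone always opens from the cell
#' boundary toward the cell interior.  Sites with zero magnitude get a
#' null (NA) direction and never vote.
#'
#' @param image an [image_grid()].
#' @param polarity `"dark"` for dark cells on a light background
#'   (brightfield/thionine), `"bright"` for fluorescent nuclei.
#' @return a `gradient_field`: list with `magnitude` (array, um^-1 units),
#'   `direction` (2D: angle array in \[0, 2pi); 3D: array `c(shape, 3)` of
#'   unit vectors), `polarity`, `shape`, `spacing`.
#' @export
compute_gradient <- function(image, polarity = c("dark", "bright")) {
  stopifnot(inherits(image, "image_grid"))
  polarity <- match.arg(polarity)
  nd <- n_dim(image)
  ders <- lapply(seq_len(nd), function(a)
    axis_derivative(image$values, a, image$spacing[a]))
  mag <- sqrt(Reduce(`+`, lapply(ders, function(d) d^2)))
  # smoothing a constant region leaves O(1e-16) round-off in the
  # derivatives; sites below this floor are genuine non-voters
  mag[mag <= 1e-10] <- 0
  sgn <- if (polarity == "dark") -1 else 1
  null <- mag == 0
  if (nd == 2) {
    theta <- atan2(sgn * ders[[2]], sgn * ders[[1]]) %% (2 * pi)
    theta[null] <- NA_real_
    direction <- theta
  } else {
    direction <- array(NA_real_, dim = c(image$shape, 3))
    for (a in 1:3) {
      u <- sgn * ders[[a]] / mag
      u[null] <- NA_real_
      direction[, , , a] <- u
    }
  }
  structure(list(magnitude = mag, direction = direction, polarity = polarity,
                 shape = image$shape, spacing = image$spacing),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("<gradient_field> ", paste(x$shape, collapse = " x "),
      ", polarity=", x$polarity,
      ", voters=", sum(x$magnitude > 0), "\n", sep = "")
  invisible(x)
}

# direction as an n_vox x nd matrix of unit physical vectors (NaN = null),
# the layout the C++ kernels consume
direction_matrix <- function(field) {
  nd <- length(field$shape)
  if (nd == 2) {
    th <- as.numeric(field$direction)
    cbind(cos(th), sin(th))
  } else {
    matrix(field$direction, ncol = 3)
  }
}

# inverse of direction_matrix: store updated unit vectors back on the field
set_directions <- function(field, dirmat) {
  nd <- length(field$shape)
  null <- !(field$magnitude > 0)
  if (nd == 2) {
    th <- atan2(dirmat[, 2], dirmat[, 1]) %% (2 * pi)
    th[as.vector(null)] <- NA_real_
    field$direction <- array(th, dim = field$shape)
  } else {
    dirmat[as.vector(null), ] <- NA_real_
    field$direction <- array(dirmat, dim = c(field$shape, 3))
  }
  field
}
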