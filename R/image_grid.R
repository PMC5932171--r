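#' Scalar intensity lattice with physical spacing
#'
#' Container for a 2D image or 3D stack together with the physical size of
#' a pixel/voxel along each axis.  Arrays are stored with axis order
#' (x, y) or (x, y, z) and the first axis varying fastest, so "storage
#' order" (the deterministic tie-break used throughout the package) is x,
#' then y, then z.  Lattice indices are 1-based inside R; the CSV
#' interfaces are 0-based.
#'
#' @param values numeric matrix (2D) or 3-dimensional array (3D) of
#'   intensities.
#' @param spacing numeric vector of physical pixel sizes in micrometers,
#'   one entry per axis (recycled if scalar).
#' @return an `image_grid` object: a list with elements `values`, `shape`
#'   and `spacing`.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8), spacing = c(0.6, 0.6))
#' dim(img$values)
#' @export
image_grid <- function(values, spacing = 1) {
  if (!is.array(values) && !is.matrix(values))
    stop("`values` must be a matrix or array")
  nd <- length(dim(values))
  if (nd != 2 && nd != 3)
    stop("image dimensionality must be 2 or 3, got ", nd)
  if (any(dim(values) < 3))
    stop("every axis must have at least 3 sites (gradient stencil must fit)")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing entries must be strictly positive")
  structure(list(values = values, shape = dim(values), spacing = spacing),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = " x "),
      " px, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " um, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

n_dim <- function(img) length(img$shape)

#' Read a TIFF image or stack as an image_grid
#'
#' Single-page TIFFs load as 2D images; multi-page TIFFs load as 3D stacks
#' with the page index as z.  Intensities are converted to doubles in
#' [0, 1] (the `tiff` package already rescales integer samples).  TIFF
#' pages are stored row-major (y in rows); they are transposed so that the
#' in-memory axis order is (x, y, z).
#'
#' @param path TIFF file path.
#' @param spacing physical pixel size per axis in micrometers (scalar or
#'   one value per axis).
#' @return an [image_grid()].
#' @export
read_image_grid <- function(path, spacing = 1) {
  if (!file.exists(path)) stop("input image not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB(A)
    t(p)                                    # rows are y: transpose to (x, y)
  })
  if (length(pages) == 1) {
    vals <- pages[[1]]
  } else {
    vals <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) vals[, , k] <- pages[[k]]
  }
  vals[] <- pmin(1, pmax(0, vals))
  image_grid(vals, spacing)
}

#' Write an image_grid to (multi-page) TIFF
#'
#' Values are clamped to [0, 1] and written as 16-bit grayscale; 3D stacks
#' become one page per z slice.
#'
#' @param img an [image_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_grid <- function(img, path) {
  v <- img$values
  v[] <- pmin(1, pmax(0, v))
  if (n_dim(img) == 2) {
    pages <- t(v)
  } else {
    pages <- lapply(seq_len(img$shape[3]), function(k) t(v[, , k]))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

# physical coordinates (um) of 1-based lattice positions (matrix rows)
lattice_to_um <- function(pos, spacing) {
  pos <- rbind(pos)
  sweep(pos - 1, 2, spacing, `*`)
}
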