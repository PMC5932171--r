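# Extraction of cell centers from the converged vote field, score
# thresholding, and the Laplacian-of-Gaussian baseline detector.

new_detection_set <- function(centers, scores, radius_um, spacing) {
  nd <- length(spacing)
  centers <- matrix(as.numeric(centers), ncol = nd)
  ord <- order(-scores, lattice_rank(centers, rep(Inf, nd)))
  structure(list(centers = centers[ord, , drop = FALSE],
                 scores = as.numeric(scores)[ord],
                 radius_um = radius_um, spacing = spacing,
                 count = length(scores)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat("<detection_set> ", x$count, " detections (r = ", x$radius_um,
      " um)\n", sep = "")
  if (x$count > 0) {
    show <- head(cbind(x$centers, score = x$scores), 5)
    print(show)
    if (x$count > 5) cat("...\n")
  }
  invisible(x)
}

# storage-order rank of lattice sites (x fastest), used for deterministic
# tie-breaking; `shape` Inf entries fall back to plain lexicographic weight
lattice_rank <- function(centers, shape) {
  w <- 1
  rank <- numeric(nrow(centers))
  for (a in seq_len(ncol(centers))) {
    rank <- rank + (centers[, a] - 1) * w
    w <- w * (if (is.finite(shape[a])) shape[a] else 1e6)
  }
  rank
}

#' Locate vote-field peaks separated by the cell radius
#'
#' A site is a raw peak when its score is positive and >= every score in
#' the surrounding box window of per-axis half-width `ceiling(r /
#' spacing)` (physical radius r).  Raw peaks closer than `r` micrometers
#' are then clustered greedily by descending score (ties: first in storage
#' order) and only the highest survivor of each cluster kept, so every
#' pair of reported centers is separated by at least `r`.
#'
#' @param votes a `vote_field` (from [iterative_vote()]), or any object
#'   with `scores`, `shape`, `spacing`.
#' @param r minimum separation / cell radius in micrometers.
#' @param spacing physical pixel size per axis (defaults to the field's).
#' @return a `detection_set` with centers (1-based pixels) and descending
#'   scores.
#' @export
find_local_maxima <- function(votes, r, spacing = votes$spacing) {
  scores <- votes$scores
  shape <- dim(scores)
  nd <- length(shape)
  spacing <- rep_len(as.numeric(spacing), nd)
  halfw <- as.integer(ceiling(r / spacing))
  mx <- cpp_box_max(as.numeric(scores), as.integer(shape), halfw)
  sc <- as.numeric(scores)
  raw <- which(sc > 0 & sc >= mx)
  if (length(raw) == 0)
    return(new_detection_set(matrix(0, 0, nd), numeric(0), r, spacing))
  centers <- arrayInd(raw, shape)
  peak_scores <- sc[raw]
  # greedy minimum-separation clustering, descending score then storage order
  ord <- order(-peak_scores, raw)
  centers <- centers[ord, , drop = FALSE]
  peak_scores <- peak_scores[ord]
  um <- lattice_to_um(centers, spacing)
  keep <- logical(length(peak_scores))
  for (i in seq_along(peak_scores)) {
    sel <- which(keep)
    if (length(sel) == 0) {
      keep[i] <- TRUE
    } else {
      d2 <- colSums((t(um[sel, , drop = FALSE]) - um[i, ])^2)
      keep[i] <- all(d2 >= r^2)
    }
  }
  new_detection_set(centers[keep, , drop = FALSE], peak_scores[keep], r,
                    spacing)
}

# Otsu's threshold on a 256-bin histogram over the score range: maximizes
# the between-class variance; returns the boundary between the two classes
otsu_threshold <- function(scores, n_bins = 256) {
  if (length(scores) == 0)
    stop("Otsu thresholding needs a nonempty score list")
  rng <- range(scores)
  if (rng[1] == rng[2])
    stop("Otsu thresholding needs non-constant scores")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(n_bins, findInterval(scores, breaks)), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  k <- which.max(bcv[-n_bins])
  breaks[k + 1]
}

#' Filter detections by score
#'
#' Keeps detections with score >= the threshold.  `method = "otsu"`
#' computes the threshold automatically from a 256-bin histogram of the
#' scores (between-class variance maximization); `method = "otsu_log"`
#' applies the same procedure to the log scores, which is the appropriate
#' automated choice for vote scores: true-cell scores grow with the cell
#' boundary surface and span an order of magnitude, while noise peaks sit
#' orders of magnitude lower, so the raw-score histogram is a one-bin
#' spike plus a long tail and a linear split can land inside the true-cell
#' range.  `method = "manual"` uses `value`.
#'
#' @param dets a `detection_set`.
#' @param method `"manual"`, `"otsu"` or `"otsu_log"`.
#' @param value threshold score for `method = "manual"`.
#' @return the filtered `detection_set`, with the threshold used attached
#'   as attribute `"threshold"`.
#' @export
threshold_detections <- function(dets, method = c("manual", "otsu",
                                                  "otsu_log"),
                                 value = 0) {
  stopifnot(inherits(dets, "detection_set"))
  method <- match.arg(method)
  thr <- switch(method,
    manual = value,
    otsu = otsu_threshold(dets$scores),
    otsu_log = {
      if (any(dets$scores <= 0))
        stop("otsu_log needs strictly positive scores")
      exp(otsu_threshold(log(dets$scores)))
    })
  keep <- dets$scores >= thr
  out <- new_detection_set(dets$centers[keep, , drop = FALSE],
                           dets$scores[keep], dets$radius_um, dets$spacing)
  attr(out, "threshold") <- thr
  out
}

#' Laplacian-of-Gaussian baseline detector
#'
#' Scale-normalized LoG blob detection: the image is blurred with a
#' Gaussian of width `sigma` (pixels on the finest axis, kept physically
#' isotropic), the physical-space Laplacian taken by central second
#' differences, and the response multiplied by the squared physical scale.
#' The sign is chosen per polarity so cell centers are response maxima
#' (dark blobs have positive Laplacian).  Peaks are extracted with the
#' same minimum-separation machinery as [find_local_maxima()].
#'
#' @param image an [image_grid()].
#' @param sigma LoG scale in pixels (default 4, a good operating point for
#'   nucleus-sized blobs).
#' @param r minimum separation in micrometers (the cell radius).
#' @param spacing physical pixel size per axis (defaults to the image's).
#' @param polarity `"dark"` or `"bright"`, as in [compute_gradient()].
#' @return a `detection_set`.
#' @export
log_detector <- function(image, sigma = 4, r, spacing = image$spacing,
                         polarity = c("dark", "bright")) {
  stopifnot(inherits(image, "image_grid"))
  polarity <- match.arg(polarity)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  nd <- n_dim(image)
  spacing <- rep_len(as.numeric(spacing), nd)
  sigma_phys <- sigma * min(spacing)
  blurred <- gaussian_blur(image, sigma_phys / spacing)
  lap <- Reduce(`+`, lapply(seq_len(nd), function(a)
    axis_second_derivative(blurred$values, a, spacing[a])))
  sgn <- if (polarity == "dark") 1 else -1
  resp <- sgn * sigma_phys^2 * lap
  resp[resp <= 1e-10] <- 0  # clip negatives and flat-region round-off
  fld <- new_vote_field(resp, spacing)
  find_local_maxima(fld, r, spacing)
}

# second derivative in physical units; central stencil, shifted at edges
axis_second_derivative <- function(values, axis, h) {
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
  core <- (idx(3:n) - 2 * idx(2:(n - 1)) + idx(1:(n - 2))) / h^2
  der <- asn(2:(n - 1), core)
  der <- asn(1, (idx(3) - 2 * idx(2) + idx(1)) / h^2)
  der <- asn(n, (idx(n) - 2 * idx(n - 1) + idx(n - 2)) / h^2)
  der
}

#' Write detections as CSV
#'
#' Columns `x, y, z` (0-based pixel indices), `x_um, y_um, z_um` (physical
#' coordinates) and `score`; the z columns are omitted for 2D detections.
#'
#' @param dets a `detection_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  stopifnot(inherits(dets, "detection_set"))
  nd <- length(dets$spacing)
  px <- dets$centers - 1
  um <- lattice_to_um(dets$centers, dets$spacing)
  if (dets$count == 0) {
    px <- matrix(numeric(0), 0, nd)
    um <- matrix(numeric(0), 0, nd)
  }
  ax <- c("x", "y", "z")[seq_len(nd)]
  df <- data.frame(px, um, score = dets$scores)
  names(df) <- c(ax, paste0(ax, "_um"), "score")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detections CSV written by [write_detections_csv()]
#'
#' @param path CSV path.
#' @param spacing physical pixel size per axis.
#' @param radius_um the detection radius to record on the set.
#' @return a `detection_set`.
#' @export
read_detections_csv <- function(path, spacing = 1, radius_um = NA_real_) {
  df <- read.csv(path)
  if (!"score" %in% names(df))
    stop("no `score` column in ", path,
         " - is this a truth CSV rather than a detections CSV?")
  nd <- if ("z" %in% names(df)) 3 else 2
  spacing <- rep_len(as.numeric(spacing), nd)
  centers <- as.matrix(df[, c("x", "y", "z")[seq_len(nd)], drop = FALSE]) + 1
  new_detection_set(centers, df$score, radius_um, spacing)
}
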