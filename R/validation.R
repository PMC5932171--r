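# Detection scoring against ground truth: one-to-one matching under the
# 50%-of-maximum-radius distance criterion, precision-recall curves, AUC.

truth_parts <- function(truth, default_spacing) {
  if (inherits(truth, "phantom_truth")) {
    list(centers = truth$centers, spacing = truth$image$spacing)
  } else if (is.matrix(truth) || is.data.frame(truth)) {
    list(centers = as.matrix(truth), spacing = default_spacing)
  } else if (is.list(truth) && !is.null(truth$centers)) {
    list(centers = as.matrix(truth$centers), spacing = default_spacing)
  } else stop("truth must be a phantom_truth, a center matrix, or a ",
              "list with a `centers` element")
}

#' Match detections to ground-truth centers
#'
#' A detection is a true positive iff it is matched one-to-one to a truth
#' center within 50% of the maximum cell radius (`0.5 * r_max_um`) in
#' physical distance.  Matching is greedy by descending detection score:
#' each detection claims its nearest still-unmatched truth center inside
#' the criterion.  Unmatched detections are false positives; unmatched
#' truths are false negatives.
#'
#' @param dets a `detection_set`.
#' @param truth a `phantom_truth`, the list from [read_truth_csv()], or a
#'   matrix of 1-based pixel centers.
#' @param r_max_um maximum cell radius in micrometers (sets the matching
#'   criterion radius `0.5 * r_max_um`).
#' @param spacing pixel size used to convert matrix/CSV truth centers to
#'   micrometers (defaults to the detections' spacing).
#' @return a `match_report`: tp/fp/fn counts, precision, recall
#'   (precision is 1 when there are no detections), the matched
#'   (detection, truth) index `pairs`, and `criterion_radius_um`.
#' @export
match_detections <- function(dets, truth, r_max_um,
                             spacing = dets$spacing) {
  stopifnot(inherits(dets, "detection_set"))
  if (!is.finite(r_max_um) || r_max_um <= 0) stop("r_max_um must be > 0")
  tp <- truth_parts(truth, spacing)
  if (nrow(tp$centers) > 0 && ncol(tp$centers) != length(dets$spacing))
    stop("detections and truth have different dimensionality")
  tum <- lattice_to_um(tp$centers, rep_len(tp$spacing, length(dets$spacing)))
  dum <- lattice_to_um(dets$centers, dets$spacing)
  crit <- 0.5 * r_max_um
  n_det <- dets$count
  n_tr <- nrow(tum)
  taken <- logical(n_tr)
  pairs <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("detection", "truth")))
  for (i in seq_len(n_det)) {  # detections already sorted by score desc
    if (n_tr == 0) break
    d <- sqrt(colSums((t(tum) - dum[i, ])^2))
    d[taken] <- Inf
    j <- which.min(d)
    if (d[j] <= crit) {
      taken[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  tp <- nrow(pairs)
  fp <- n_det - tp
  fn <- n_tr - tp
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp == 0) 1 else tp / (tp + fp),
                 recall = if (tp + fn == 0) 1 else tp / (tp + fn),
                 pairs = pairs, criterion_radius_um = crit),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> TP %d, FP %d, FN %d | precision %.3f, recall %.3f (criterion %.2f um)\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$criterion_radius_um))
  invisible(x)
}

#' Precision-recall curve and area under it
#'
#' Sweeps a score threshold over the sorted unique detection scores,
#' matching the surviving detections against truth at each, and
#' integrates precision over recall by the trapezoid rule on the achieved
#' curve, anchored at (recall 0, precision of the highest threshold), over
#' recall in \[0, max recall\].
#'
#' @inheritParams match_detections
#' @return a `pr_curve`: list with `curve` (data frame of threshold, tp,
#'   fp, fn, precision, recall) and `auc`.
#' @export
precision_recall_curve <- function(dets, truth, r_max_um,
                                   spacing = dets$spacing) {
  stopifnot(inherits(dets, "detection_set"))
  if (dets$count == 0) {
    warning("no detections; AUC is 0")
    return(structure(list(curve = data.frame(threshold = numeric(0),
                                             tp = integer(0), fp = integer(0),
                                             fn = integer(0),
                                             precision = numeric(0),
                                             recall = numeric(0)),
                          auc = 0), class = "pr_curve"))
  }
  thresholds <- sort(unique(dets$scores), decreasing = TRUE)
  rows <- lapply(thresholds, function(thr) {
    sub <- threshold_detections(dets, "manual", thr)
    rep <- match_detections(sub, truth, r_max_um, spacing)
    data.frame(threshold = thr, tp = rep$tp, fp = rep$fp, fn = rep$fn,
               precision = rep$precision, recall = rep$recall)
  })
  curve <- do.call(rbind, rows)
  ord <- order(curve$recall)
  rec <- c(0, curve$recall[ord])
  prec <- c(curve$precision[1], curve$precision[ord])
  auc <- sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", nrow(x$curve), " thresholds, AUC = ",
      signif(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  ord <- order(x$curve$recall)
  plot(x$curve$recall[ord], x$curve$precision[ord], type = "b",
       xlab = "Recall", ylab = "Precision", xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("Precision-recall (AUC = %.3f)", x$auc), ...)
  invisible(x)
}

#' Write a match report as plain JSON text
#'
#' @param report a `match_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path) {
  stopifnot(inherits(report, "match_report"))
  jsonlite::write_json(
    list(tp = report$tp, fp = report$fp, fn = report$fn,
         precision = report$precision, recall = report$recall,
         criterion_radius_um = report$criterion_radius_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a precision-recall curve as CSV
#'
#' @param pr a `pr_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pr_csv <- function(pr, path) {
  stopifnot(inherits(pr, "pr_curve"))
  write.csv(pr$curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
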