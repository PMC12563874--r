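#' Confusion counts
#'
#' In open-image object detection true negatives are undefined; `tn` defaults
#' to 0, so the accuracy formula degenerates to `TP / (TP + FP + FN)`.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' A single detection: box, class, confidence
#' @param box an `oriented_box` or `horizontal_box`.
#' @param class_id integer class label.
#' @param confidence score in `[0, 1]`.
#' @return Object of class `detection`.
#' @export
detection <- function(box, class_id = 0L, confidence = 1) {
  stopifnot(confidence >= 0, confidence <= 1)
  structure(list(box = box, class_id = as.integer(class_id),
                 confidence = confidence), class = "detection")
}

.as_obb <- function(b) {
  if (inherits(b, "horizontal_box")) oriented_box(b$cx, b$cy, b$w, b$h, 0) else b
}

#' Intersection over union of two oriented boxes
#'
#' The intersection of two rectangles is a convex polygon, computed here by
#' Sutherland-Hodgman clipping; the IoU is its area over the union area.
#' Reduces exactly to axis-aligned IoU when both boxes have `theta = 0`.
#'
#' @param a,b `oriented_box` (or `horizontal_box`) objects.
#' @return Fraction in `[0, 1]`; symmetric; 1 iff the boxes coincide as point
#'   sets, 0 iff their interiors are disjoint.
#' @export
rotated_iou <- function(a, b) {
  a <- .as_obb(a); b <- .as_obb(b)
  ca <- obb_corners(a); cb <- obb_corners(b)
  inter <- polygon_area(convex_clip(ca, cb))
  aa <- a$w * a$h; ab <- b$w * b$h
  iou <- inter / (aa + ab - inter)
  min(max(iou, 0), 1)
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching in descending confidence order: each detection
#' claims the unmatched ground-truth box of the same class with the highest
#' IoU, provided it reaches `iou_thr` (ties broken by ground-truth index).
#' Unmatched detections count as FP, unmatched ground truths as FN; TN = 0.
#'
#' @param dets list of `detection` objects.
#' @param gts list of boxes, or of `list(box =, class_id =)` records.
#' @param iou_thr IoU threshold in `(0, 1)`.
#' @return List: `counts` (`confusion_counts`) and `matches` (data frame with
#'   columns det, gt, iou).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  gt_boxes <- lapply(gts, function(g) if (!is.null(g$box)) g$box else g)
  gt_class <- vapply(gts, function(g)
    if (!is.null(g$class_id)) as.integer(g$class_id) else NA_integer_, integer(1))
  conf <- vapply(dets, `[[`, numeric(1), "confidence")
  ord <- order(-conf, seq_along(dets))
  taken <- rep(FALSE, length(gt_boxes))
  matches <- data.frame(det = integer(0), gt = integer(0), iou = numeric(0))
  for (i in ord) {
    d <- dets[[i]]
    best_j <- 0L; best_iou <- 0
    for (j in seq_along(gt_boxes)) {
      if (taken[j]) next
      if (!is.na(gt_class[j]) && gt_class[j] != d$class_id) next
      iou <- rotated_iou(d$box, gt_boxes[[j]])
      if (iou > best_iou + 1e-12) { best_iou <- iou; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_thr) {
      taken[best_j] <- TRUE
      matches <- rbind(matches,
                       data.frame(det = i, gt = best_j, iou = best_iou))
    }
  }
  tp <- nrow(matches)
  list(counts = confusion_counts(tp = tp, tn = 0,
                                 fp = length(dets) - tp,
                                 fn = sum(!taken)),
       matches = matches)
}

#' Precision, recall and accuracy from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`.  A zero denominator yields
#' `NA` (undefined-metric sentinel), never an error.
#'
#' @param c a `confusion_counts`.
#' @return Named list `precision`, `recall`, `accuracy`.
#' @export
precision_recall_accuracy <- function(c) {
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(precision = frac(c$tp, c$tp + c$fp),
       recall = frac(c$tp, c$tp + c$fn),
       accuracy = frac(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn))
}

#' Average precision at IoU 0.5 for one class
#'
#' Detections are ranked by confidence; each is a TP if it claims an
#' unmatched ground truth with IoU >= `iou_thr`, else FP.  AP is the area
#' under the precision-recall curve using the all-points ("continuous")
#' precision envelope by default, or the 11-point interpolation.
#'
#' @param dets list of `detection`s (one class).
#' @param gts list of ground-truth boxes.
#' @param iou_thr IoU threshold (default 0.5).
#' @param interpolation `"continuous"` or `"elevenpoint"`.
#' @return AP in `[0, 1]`; `NA` when `gts` is empty.
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5,
                              interpolation = c("continuous", "elevenpoint")) {
  interpolation <- match.arg(interpolation)
  ngt <- length(gts)
  if (ngt == 0) return(NA_real_)
  if (length(dets) == 0) return(0)
  gt_boxes <- lapply(gts, function(g) if (!is.null(g$box)) g$box else g)
  conf <- vapply(dets, `[[`, numeric(1), "confidence")
  ord <- order(-conf, seq_along(dets))
  taken <- rep(FALSE, ngt)
  is_tp <- logical(length(dets))
  for (i in ord) {
    best_j <- 0L; best_iou <- 0
    for (j in seq_len(ngt)) {
      if (taken[j]) next
      iou <- rotated_iou(dets[[i]]$box, gt_boxes[[j]])
      if (iou > best_iou + 1e-12) { best_iou <- iou; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_thr) { taken[best_j] <- TRUE; is_tp[i] <- TRUE }
  }
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / ngt
  if (interpolation == "elevenpoint") {
    pts <- vapply(seq(0, 1, by = 0.1), function(r) {
      sel <- rec >= r - 1e-12
      if (any(sel)) max(prec[sel]) else 0
    }, numeric(1))
    return(mean(pts))
  }
  # all-points: integrate the running-max-from-the-right precision envelope
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  for (i in rev(seq_len(length(mpre) - 1))) mpre[i] <- max(mpre[i], mpre[i + 1])
  sum(diff(mrec) * mpre[-1])
}

#' Mean average precision at IoU 0.5 over classes
#'
#' `mAP50 = (1/N) * sum_i AP_{i,50}` over the `N` classes present in the
#' ground truth.
#'
#' @param dets list of `detection`s (mixed classes).
#' @param gts list of `list(box =, class_id =)` records.
#' @param iou_thr IoU threshold (default 0.5).
#' @param interpolation passed to [average_precision()].
#' @return mAP in `[0, 1]`; `NA` when there is no ground truth.
#' @export
map50 <- function(dets, gts, iou_thr = 0.5, interpolation = "continuous") {
  gt_class <- vapply(gts, function(g)
    if (!is.null(g$class_id)) as.integer(g$class_id) else 0L, integer(1))
  classes <- sort(unique(gt_class))
  if (length(classes) == 0) return(NA_real_)
  aps <- vapply(classes, function(cl) {
    dsub <- Filter(function(d) d$class_id == cl, dets)
    gsub <- lapply(gts[gt_class == cl], function(g)
      if (!is.null(g$box)) g$box else g)
    average_precision(dsub, gsub, iou_thr, interpolation)
  }, numeric(1))
  mean(aps)
}

#' Angular-deviation report: predicted vs reference pathways
#'
#' Per image, the unsigned angle (degrees, `[0, 90]`) between the predicted
#' pathway line and the reference line; the summary is their arithmetic mean
#' (mean absolute angular deviation).
#'
#' @param pred list of `implant_pathway` objects or `ipath_line`s.
#' @param truth list of `ipath_line`s (or 2 x 2 endpoint matrices), same
#'   length as `pred`.
#' @param deviations alternatively, a numeric vector of precomputed per-image
#'   deviations (then `pred`/`truth` are ignored).
#' @return Object of class `angular_report`: `per_image_deviation_deg`,
#'   `mean_deviation_deg`, `max_deviation_deg`, `n`.
#' @export
angular_deviation_report <- function(pred = NULL, truth = NULL,
                                     deviations = NULL) {
  if (is.null(deviations)) {
    if (length(pred) != length(truth))
      stop("pairing error: pred and truth differ in length", call. = FALSE)
    as_line <- function(x) {
      if (inherits(x, "implant_pathway")) x$line
      else if (inherits(x, "ipath_line")) x
      else if (is.matrix(x)) line_from_points(x[1, ], x[2, ])
      else stop("cannot interpret pathway input", call. = FALSE)
    }
    deviations <- mapply(function(p, t) angle_between(as_line(p), as_line(t)),
                         pred, truth)
    deviations <- as.numeric(deviations)
  }
  stopifnot(all(deviations >= 0), all(deviations <= 90))
  structure(list(per_image_deviation_deg = deviations,
                 mean_deviation_deg = mean(deviations),
                 max_deviation_deg = if (length(deviations)) max(deviations) else NA_real_,
                 n = length(deviations)),
            class = "angular_report")
}

#' @export
print.angular_report <- function(x, ...) {
  cat(sprintf("<angular deviation report> n = %d\n", x$n))
  cat("  per-image (deg):", paste(sprintf("%.3f", x$per_image_deviation_deg),
                                  collapse = ", "), "\n")
  cat(sprintf("  mean %.3f deg   max %.3f deg\n",
              x$mean_deviation_deg, x$max_deviation_deg))
  invisible(x)
}

#' Full detection evaluation report
#'
#' Bundles confusion counts, precision/recall/accuracy and mAP50, optionally
#' with an angular-deviation block.
#'
#' @param dets,gts as in [match_detections()] / [map50()].
#' @param iou_thr IoU threshold.
#' @param angular optional `angular_report`.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(dets, gts, iou_thr = 0.5, angular = NULL) {
  m <- match_detections(dets, gts, iou_thr)
  pra <- precision_recall_accuracy(m$counts)
  structure(list(counts = m$counts,
                 precision = pra$precision, recall = pra$recall,
                 accuracy = pra$accuracy,
                 map50 = map50(dets, gts, iou_thr),
                 angular = angular),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$counts)
  cat(sprintf("  precision %.4f  recall %.4f  accuracy %.4f  mAP50 %.4f\n",
              x$precision, x$recall, x$accuracy, x$map50))
  if (!is.null(x$angular)) print(x$angular)
  invisible(x)
}
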