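# Detection evaluation: greedy confidence-ranked matching, precision-recall
# curves, all-points-interpolated average precision and mAP@0.5.

#' Precision from confusion counts
#'
#' TP / (TP + FP); when no predictions were made the convention is 1.
#' @param c list or vector with TP and FP.
#' @export
det_precision <- function(c) {
  tp <- c[["TP"]]; fp <- c[["FP"]]
  if (tp + fp == 0) return(1)
  tp / (tp + fp)
}

#' Recall from confusion counts
#'
#' TP / (TP + FN); classes with no ground truth are skipped from mAP.
#' @param c list or vector with TP and FN.
#' @export
det_recall <- function(c) {
  tp <- c[["TP"]]; fn <- c[["FN"]]
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' Greedy matching of scored detections to ground-truth boxes
#'
#' Detections are processed in descending confidence; each is matched to the
#' unmatched ground truth of highest IoU (ties broken by lowest index) and is
#' a true positive iff that IoU is strictly greater than the threshold. Each
#' ground truth is matched at most once.
#'
#' @param det_boxes n x 4 corner matrix.
#' @param conf detection confidences.
#' @param gt_boxes m x 4 corner matrix.
#' @param iou_thr matching threshold (strictly greater).
#' @return list(tp = logical per detection in the original order,
#'   order = processing order, matched_gt = gt index or NA).
#' @export
match_detections <- function(det_boxes, conf, gt_boxes, iou_thr = 0.5) {
  nd <- nrow(det_boxes)
  ng <- nrow(gt_boxes)
  tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  used <- logical(ng)
  ord <- order(conf, decreasing = TRUE)
  for (i in ord) {
    if (ng == 0) break
    free <- which(!used)
    if (!length(free)) next
    ious <- box_iou(matrix(det_boxes[i, ], length(free), 4, byrow = TRUE),
                    gt_boxes[free, , drop = FALSE])
    best <- free[which.max(ious)]          # ties: lowest index
    if (max(ious) > iou_thr) {
      tp[i] <- TRUE
      used[best] <- TRUE
      matched_gt[i] <- best
    }
  }
  list(tp = tp, order = ord, matched_gt = matched_gt)
}

#' Precision-recall curve from ranked true-positive flags
#'
#' @param tp logical flags of detections.
#' @param conf confidences (the sweep order).
#' @param n_gt number of ground-truth objects of the class.
#' @return data frame (recall, precision) along the confidence sweep.
#' @export
pr_curve <- function(tp, conf, n_gt) {
  ord <- order(conf, decreasing = TRUE)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  data.frame(recall = if (n_gt > 0) ctp / n_gt else rep(0, length(tp)),
             precision = ctp / pmax(ctp + cfp, 1))
}

#' All-points-interpolated average precision
#'
#' Integral over recall of the precision envelope (running maximum of
#' precision for recall >= r).
#'
#' @param curve data frame with recall and precision columns.
#' @return AP in [0, 1]; 0 for an empty curve.
#' @export
average_precision <- function(curve) {
  if (nrow(curve) == 0) return(0)
  r <- c(0, curve$recall, 1)
  p <- c(0, curve$precision, 0)
  # precision envelope: running max from the right
  for (i in rev(seq_len(length(p) - 1))) p[i] <- max(p[i], p[i + 1])
  idx <- which(r[-1] != r[-length(r)])
  sum((r[idx + 1] - r[idx]) * p[idx + 1])
}

#' Mean average precision over evaluable classes
#'
#' @param aps per-class AP values (classes without ground truth excluded).
#' @export
mean_ap <- function(aps) {
  if (!length(aps)) stop("no evaluable classes")
  mean(aps)
}

#' Evaluate detections against ground truth (mAP@0.5)
#'
#' @param preds list per image: list(class, conf, boxes) (0-based classes).
#' @param gts list per image: list(class, boxes).
#' @param nc number of classes.
#' @param iou_thr matching threshold.
#' @param csv,json optional output paths for the per-class AP table and a
#'   JSON summary.
#' @return list(per_class data frame, map50).
#' @export
evaluate_detections <- function(preds, gts, nc, iou_thr = 0.5, csv = NULL,
                                json = NULL) {
  rows <- list()
  for (k in seq_len(nc) - 1L) {
    tp <- logical(0); conf <- numeric(0)
    n_gt <- 0L
    for (i in seq_along(gts)) {
      gsel <- gts[[i]]$class == k
      n_gt <- n_gt + sum(gsel)
      p <- preds[[i]]
      psel <- p$class == k
      if (!any(psel)) next
      m <- match_detections(p$boxes[psel, , drop = FALSE], p$conf[psel],
                            gts[[i]]$boxes[gsel, , drop = FALSE], iou_thr)
      tp <- c(tp, m$tp)
      conf <- c(conf, p$conf[psel])
    }
    ap <- if (n_gt == 0) NA_real_
          else average_precision(pr_curve(tp, conf, n_gt))
    rows[[k + 1L]] <- data.frame(class = k, n_gt = n_gt,
                                 n_det = length(tp), ap = ap)
  }
  tab <- do.call(rbind, rows)
  map50 <- mean_ap(tab$ap[!is.na(tab$ap)])
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(map50 = map50, per_class = tab), json,
                         auto_unbox = TRUE, digits = NA, na = "null")
  list(per_class = tab, map50 = map50)
}
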