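# Box algebra and the minimum-point-distance IoU (MPDIoU) regression score.
# Coordinate convention: continuous pixel coordinates, origin at the top-left
# corner, y increasing downward; a box is the closed rectangle
# [x1, x2] x [y1, y2] with x2 >= x1, y2 >= y1.

#' Construct an axis-aligned box
#'
#' @param x1,y1 top-left corner (pixels).
#' @param x2,y2 bottom-right corner (pixels).
#' @return numeric vector c(x1, y1, x2, y2) of class "box".
#' @export
box <- function(x1, y1, x2, y2) {
  if (any(x2 < x1) || any(y2 < y1))
    stop("invalid box: require x2 >= x1 and y2 >= y1")
  structure(c(x1 = x1, y1 = y1, x2 = x2, y2 = y2), class = "box")
}

as_box_matrix <- function(b) {
  if (is.matrix(b)) {
    dimnames(b) <- NULL
    return(b)
  }
  matrix(unclass(b), ncol = 4)
}

box_area <- function(b) {
  b <- as_box_matrix(b)
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

#' Intersection over union of two boxes
#'
#' Vectorised over rows when given n x 4 matrices. Pairs in which both boxes
#' have zero area are reported as IoU 0 (degenerate input).
#'
#' @param a,b boxes (vectors from [box()] or n x 4 matrices).
#' @return IoU in [0, 1].
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  uni <- box_area(a) + box_area(b) - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Area of the smallest rectangle enclosing two boxes
#'
#' @inheritParams box_iou
#' @return enclosing area in pixels squared.
#' @export
enclosing_rect_area <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  (pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])) *
    (pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2]))
}

#' Squared distances between corresponding corners of two boxes
#'
#' @param pred,gt boxes.
#' @return list with d1_sq (top-left) and d2_sq (bottom-right).
#' @export
corner_distances_sq <- function(pred, gt) {
  p <- as_box_matrix(pred); g <- as_box_matrix(gt)
  list(d1_sq = (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2,
       d2_sq = (p[, 3] - g[, 3])^2 + (p[, 4] - g[, 4])^2)
}

#' Minimum-point-distance IoU
#'
#' IoU minus the squared top-left and bottom-right corner distances, each
#' normalized by the squared frame diagonal w^2 + h^2. Equals IoU when the
#' corners coincide; at most 1; bounded below by -2 for boxes inside the frame.
#'
#' @param pred,gt boxes.
#' @param frame list or vector with elements w and h, the width and height of
#'   the network input frame (pixels), both positive.
#' @return score <= 1.
#' @export
mpdiou <- function(pred, gt, frame) {
  w <- frame[["w"]]; h <- frame[["h"]]
  if (w <= 0 || h <= 0) stop("frame dimensions must be positive")
  d <- corner_distances_sq(pred, gt)
  box_iou(pred, gt) - d$d1_sq / (w^2 + h^2) - d$d2_sq / (w^2 + h^2)
}

#' MPDIoU regression loss, 1 - MPDIoU
#'
#' @inheritParams mpdiou
#' @return non-negative loss; 0 iff the boxes coincide.
#' @export
mpdiou_loss <- function(pred, gt, frame) 1 - mpdiou(pred, gt, frame)

# gradient of mpdiou w.r.t. the predicted box corners (n x 4); subgradient 0
# at clamp boundaries of the intersection terms
mpdiou_grad <- function(pred, gt, frame) {
  p <- as_box_matrix(pred); g <- as_box_matrix(gt)
  w <- frame[["w"]]; h <- frame[["h"]]
  n <- nrow(p)
  iw <- pmin(p[, 3], g[, 3]) - pmax(p[, 1], g[, 1])
  ih <- pmin(p[, 4], g[, 4]) - pmax(p[, 2], g[, 2])
  inter <- pmax(0, iw) * pmax(0, ih)
  area_p <- box_area(p); area_g <- box_area(g)
  uni <- area_p + area_g - inter
  grad <- matrix(0, n, 4)
  pos <- iw > 0 & ih > 0 & uni > 0
  # d inter / d corners (only where the clamp is active)
  di <- matrix(0, n, 4)
  di[, 1] <- ifelse(pos & p[, 1] > g[, 1], -pmax(0, ih), 0)
  di[, 2] <- ifelse(pos & p[, 2] > g[, 2], -pmax(0, iw), 0)
  di[, 3] <- ifelse(pos & p[, 3] < g[, 3], pmax(0, ih), 0)
  di[, 4] <- ifelse(pos & p[, 4] < g[, 4], pmax(0, iw), 0)
  # d area_p / d corners
  da <- cbind(-(p[, 4] - p[, 2]), -(p[, 3] - p[, 1]),
              p[, 4] - p[, 2], p[, 3] - p[, 1])
  safe_uni <- ifelse(uni > 0, uni, 1)
  for (k in 1:4) {
    dunion <- da[, k] - di[, k]
    grad[, k] <- ifelse(uni > 0,
                        (di[, k] * uni - inter * dunion) / safe_uni^2, 0)
  }
  diag2 <- w^2 + h^2
  grad[, 1] <- grad[, 1] - 2 * (p[, 1] - g[, 1]) / diag2
  grad[, 2] <- grad[, 2] - 2 * (p[, 2] - g[, 2]) / diag2
  grad[, 3] <- grad[, 3] - 2 * (p[, 3] - g[, 3]) / diag2
  grad[, 4] <- grad[, 4] - 2 * (p[, 4] - g[, 4]) / diag2
  grad
}

#' Center/size parameterisation of a box
#'
#' @param b a box or n x 4 matrix.
#' @return matrix with columns cx, cy, w, h.
#' @export
box_geometry <- function(b) {
  b <- as_box_matrix(b)
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' Default training loss weights
#'
#' Box regression 7.5, classification 0.5, distribution-focal 1.5.
#' @param box,cls,dfl non-negative weights.
#' @export
loss_weights <- function(box = 7.5, cls = 0.5, dfl = 1.5) {
  if (box < 0 || cls < 0 || dfl < 0) stop("loss weights must be non-negative")
  list(box = box, cls = cls, dfl = dfl)
}

#' Weighted composite detection loss
#'
#' @param box_term,cls_term,dfl_term non-negative loss terms.
#' @param w weights from [loss_weights()].
#' @return scalar weighted sum.
#' @export
composite_loss <- function(box_term, cls_term, dfl_term, w = loss_weights()) {
  w$box * box_term + w$cls * cls_term + w$dfl * dfl_term
}

# ---- YOLO text label format --------------------------------------------------

#' Convert corner boxes to normalized YOLO rows
#'
#' @param b n x 4 corner matrix (pixels).
#' @param class_id integer vector of 0-based class ids.
#' @param img_w,img_h image dimensions.
#' @return n x 5 matrix (class, cx, cy, w, h), coordinates in [0, 1].
#' @export
boxes_to_yolo <- function(b, class_id, img_w, img_h) {
  geo <- box_geometry(b)
  cbind(class = class_id, cx = geo[, 1] / img_w, cy = geo[, 2] / img_h,
        w = geo[, 3] / img_w, h = geo[, 4] / img_h)
}

#' Convert normalized YOLO rows to corner boxes in pixels
#'
#' @param m n x >=5 matrix (class, cx, cy, w, h, [conf]).
#' @param img_w,img_h image dimensions.
#' @return list(class, boxes, conf); conf is NULL when absent.
#' @export
yolo_to_boxes <- function(m, img_w, img_h) {
  m <- matrix(m, ncol = ncol(as.matrix(m)))
  cx <- m[, 2] * img_w; cy <- m[, 3] * img_h
  w <- m[, 4] * img_w; h <- m[, 5] * img_h
  list(class = as.integer(m[, 1]),
       boxes = cbind(x1 = cx - w / 2, y1 = cy - h / 2,
                     x2 = cx + w / 2, y2 = cy + h / 2),
       conf = if (ncol(m) >= 6) m[, 6])
}

#' Read a YOLO-format label file
#'
#' @param path label .txt path; missing or empty files give a 0-row matrix.
#' @param ncol_out 5 for labels, 6 for detections with confidence.
#' @export
read_yolo_labels <- function(path, ncol_out = 5L) {
  if (!file.exists(path) || file.size(path) == 0)
    return(matrix(numeric(0), ncol = ncol_out))
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  m
}

#' Write YOLO-format label rows
#'
#' @param m n x 5 (or n x 6 with confidence) matrix.
#' @param path output path.
#' @export
write_yolo_labels <- function(m, path) {
  if (nrow(m) == 0) {
    file.create(path)
    return(invisible(path))
  }
  lines <- apply(m, 1, function(r) {
    paste(c(format(as.integer(r[1])),
            formatC(r[-1], format = "g", digits = 8)), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}
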