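# Training loss: task-aligned assignment, MPDIoU box regression,
# distribution-focal regression and binary cross-entropy classification,
# combined with weights (box, cls, dfl).

# flatten raw head outputs of image n into matrices over all anchors
flatten_head <- function(out, n) {
  box <- NULL; cls <- NULL; meta <- NULL
  for (i in seq_along(out)) {
    d <- dim(out[[i]]$box)
    A <- d[1] * d[2]
    box <- rbind(box, matrix(out[[i]]$box[, , , n], A, d[3]))
    cls <- rbind(cls, matrix(out[[i]]$cls[, , , n], A, dim(out[[i]]$cls)[3]))
    meta <- rbind(meta, cbind(level = i, H = d[1], W = d[2]))
  }
  list(box = box, cls = cls, meta = meta)
}

# anchors for all levels: centers (pixels) and strides
all_anchors <- function(out, strides) {
  ctr <- NULL; str <- NULL
  for (i in seq_along(out)) {
    d <- dim(out[[i]]$box)
    ctr <- rbind(ctr, anchor_centers(d[1], d[2], strides[i]))
    str <- c(str, rep(strides[i], d[1] * d[2]))
  }
  list(centers = ctr, strides = str)
}

# decode all anchors' boxes from DFL logits; returns boxes and softmax caches
decode_all <- function(box_raw, anc, reg_max) {
  A <- nrow(box_raw)
  proj <- 0:(reg_max - 1)
  e <- matrix(0, A, 4); P <- vector("list", 4)
  for (s in 1:4) {
    r <- dfl_expect(box_raw[, (s - 1) * reg_max + seq_len(reg_max),
                            drop = FALSE], proj)
    e[, s] <- r$e
    P[[s]] <- r$p
  }
  boxes <- cbind(anc$centers[, 1] - e[, 1] * anc$strides,
                 anc$centers[, 2] - e[, 2] * anc$strides,
                 anc$centers[, 1] + e[, 3] * anc$strides,
                 anc$centers[, 2] + e[, 4] * anc$strides)
  list(boxes = boxes, e = e, P = P)
}

# task-aligned assignment (no gradients flow through this step)
assign_targets <- function(scores, pred_boxes, anc, gt_class, gt_boxes,
                           topk = 10L, alpha = 0.5, beta = 6.0) {
  A <- nrow(scores)
  ng <- length(gt_class)
  assigned_gt <- integer(A)          # 0 = background
  target_scores <- matrix(0, A, ncol(scores))
  if (ng == 0)
    return(list(assigned_gt = assigned_gt, target_scores = target_scores))
  tmat <- matrix(0, A, ng); imat <- matrix(0, A, ng)
  for (j in seq_len(ng)) {
    inside <- anc$centers[, 1] > gt_boxes[j, 1] &
      anc$centers[, 1] < gt_boxes[j, 3] &
      anc$centers[, 2] > gt_boxes[j, 2] &
      anc$centers[, 2] < gt_boxes[j, 4]
    if (!any(inside)) next
    iou <- box_iou(pred_boxes, matrix(gt_boxes[j, ], A, 4, byrow = TRUE))
    t <- (scores[, gt_class[j] + 1L]^alpha) * (iou^beta)
    t[!inside] <- 0
    cand <- order(t, decreasing = TRUE)[seq_len(min(topk, sum(inside)))]
    cand <- cand[t[cand] > 0]
    tmat[cand, j] <- t[cand]
    imat[, j] <- iou
  }
  pos <- which(rowSums(tmat > 0) > 0)
  for (a in pos) {
    js <- which(tmat[a, ] > 0)
    assigned_gt[a] <- js[which.max(imat[a, js])]
  }
  # per-gt normalization: max alignment -> max IoU among its anchors
  for (j in seq_len(ng)) {
    aj <- which(assigned_gt == j)
    if (!length(aj)) next
    tj <- tmat[aj, j]
    norm <- max(imat[aj, j]) / max(max(tj), 1e-9)
    target_scores[cbind(aj, gt_class[j] + 1L)] <- tj * norm
  }
  list(assigned_gt = assigned_gt, target_scores = target_scores)
}

# loss and gradients for one image given a fixed assignment; gradients for
# the box and distribution-focal terms are returned separately so each can be
# scaled by its own weight
loss_given_assignment <- function(fh, dec, anc, assign, gt_boxes, frame,
                                  reg_max) {
  A <- nrow(fh$cls)
  scores <- sigmoid(fh$cls)
  ts <- assign$target_scores
  norm_cls <- max(sum(ts), 1)
  eps <- 1e-12
  cls_loss <- -sum(ts * log(scores + eps) +
                     (1 - ts) * log(1 - scores + eps)) / norm_cls
  dcls <- (scores - ts) / norm_cls
  dbox <- matrix(0, A, 4 * reg_max)
  ddfl <- matrix(0, A, 4 * reg_max)
  box_loss <- 0; dfl_loss <- 0
  pos <- which(assign$assigned_gt > 0)
  if (length(pos)) {
    j <- assign$assigned_gt[pos]
    w <- rowSums(ts[pos, , drop = FALSE])
    wsum <- max(sum(w), 1e-9)
    pb <- dec$boxes[pos, , drop = FALSE]
    gb <- gt_boxes[j, , drop = FALSE]
    mp <- mpdiou(pb, gb, frame)
    box_loss <- sum(w * (1 - mp)) / wsum
    dmp <- mpdiou_grad(pb, gb, frame)            # d mpdiou / d pred corners
    dpb <- -dmp * (w / wsum)                     # d box_loss / d corners
    # corners -> side distances (stride units): x1 = cx - l s, x2 = cx + r s
    st <- anc$strides[pos]
    dside <- cbind(-dpb[, 1] * st, -dpb[, 2] * st,
                   dpb[, 3] * st, dpb[, 4] * st)
    # DFL target distances in stride units
    tgt <- cbind((anc$centers[pos, 1] - gb[, 1]) / st,
                 (anc$centers[pos, 2] - gb[, 2]) / st,
                 (gb[, 3] - anc$centers[pos, 1]) / st,
                 (gb[, 4] - anc$centers[pos, 2]) / st)
    tgt <- pmin(pmax(tgt, 0), reg_max - 1 - 0.01)
    np <- length(pos)
    for (s in 1:4) {
      cols <- (s - 1) * reg_max + seq_len(reg_max)
      Pp <- dec$P[[s]][pos, , drop = FALSE]
      ev <- dec$e[pos, s]
      # expectation gradient through the per-side softmax
      dbox[pos, cols] <- Pp * (matrix(0:(reg_max - 1), np, reg_max,
                                      byrow = TRUE) - ev) * dside[, s]
      # cross-entropy against the two neighbouring integer bins
      tl <- floor(tgt[, s]); tu <- pmin(tl + 1, reg_max - 1)
      wl <- 1 - (tgt[, s] - tl); wu <- 1 - wl
      tdist <- matrix(0, np, reg_max)
      tdist[cbind(seq_len(np), tl + 1)] <- wl
      tdist[cbind(seq_len(np), tu + 1)] <- tdist[cbind(seq_len(np), tu + 1)] + wu
      dfl_loss <- dfl_loss + sum(w * (-rowSums(tdist * log(Pp + eps))))
      ddfl[pos, cols] <- (Pp - tdist) * (w / wsum) / 4
    }
    dfl_loss <- dfl_loss / wsum / 4
  }
  list(box = box_loss, cls = cls_loss, dfl = dfl_loss,
       dcls = dcls, dbox = dbox, ddfl = ddfl)
}

#' Detection loss and head-output gradients
#'
#' Task-aligned assignment of anchors to ground truth, MPDIoU box loss,
#' distribution-focal loss and binary cross-entropy classification loss,
#' combined as box_w * box + cls_w * cls + dfl_w * dfl.
#'
#' @param out raw head outputs (list per level of list(box, cls)).
#' @param targets list per image: list(class = 0-based ints, boxes = n x 4
#'   pixel corners).
#' @param frame list(w, h): network input size for MPDIoU normalization.
#' @param weights [loss_weights()].
#' @param strides head strides.
#' @param reg_max distribution-focal bins.
#' @return list(loss, box, cls, dfl, grads) where grads matches the head
#'   output structure.
#' @export
detection_loss <- function(out, targets, frame, weights = loss_weights(),
                           strides = c(8L, 16L, 32L), reg_max = 16L) {
  N <- dim(out[[1]]$box)[4]
  anc <- all_anchors(out, strides)
  grads <- lapply(out, function(l)
    list(box = array(0, dim = dim(l$box)), cls = array(0, dim = dim(l$cls))))
  box_t <- cls_t <- dfl_t <- 0
  for (n in seq_len(N)) {
    fh <- flatten_head(out, n)
    dec <- decode_all(fh$box, anc, reg_max)
    scores <- sigmoid(fh$cls)
    tg <- targets[[n]]
    assign <- assign_targets(scores, dec$boxes, anc, tg$class, tg$boxes)
    r <- loss_given_assignment(fh, dec, anc, assign, tg$boxes, frame, reg_max)
    box_t <- box_t + r$box / N
    cls_t <- cls_t + r$cls / N
    dfl_t <- dfl_t + r$dfl / N
    # scatter gradients (already d term / d raw) back to level arrays
    off <- 0L
    for (i in seq_along(out)) {
      d <- dim(out[[i]]$box)
      A <- d[1] * d[2]
      rows <- off + seq_len(A)
      grads[[i]]$box[, , , n] <-
        array((r$dbox[rows, ] * weights$box +
                 r$ddfl[rows, ] * weights$dfl) / N, dim = d[1:3]) +
        grads[[i]]$box[, , , n]
      grads[[i]]$cls[, , , n] <-
        array(r$dcls[rows, ] * weights$cls / N,
              dim = dim(out[[i]]$cls)[1:3]) + grads[[i]]$cls[, , , n]
      off <- off + A
    }
  }
  list(loss = composite_loss(box_t, cls_t, dfl_t, weights),
       box = box_t, cls = cls_t, dfl = dfl_t, grads = grads)
}
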