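# Decoupled anchor-free detection head with distribution-focal box regression,
# box decoding and non-maximum suppression.

detect_module <- function(nc, ch, reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1], min(nc, 100L))
  mods <- list()
  for (i in seq_along(ch)) {
    mods[[paste0("box", i, "_1")]] <- cbs_module(ch[i], c2, 3L)
    mods[[paste0("box", i, "_2")]] <- cbs_module(c2, c2, 3L)
    mods[[paste0("box", i, "_3")]] <- conv_module(c2, 4L * reg_max, 1L)
    mods[[paste0("cls", i, "_1")]] <- cbs_module(ch[i], c3, 3L)
    mods[[paste0("cls", i, "_2")]] <- cbs_module(c3, c3, 3L)
    mods[[paste0("cls", i, "_3")]] <- conv_module(c3, nc, 1L)
  }
  proj <- array(0:(reg_max - 1L), dim = c(reg_max))
  attr(proj, "trainable") <- FALSE
  det <- new_module("detect", params = list(dfl_proj = proj), ch = mods,
                    cfg = list(nc = nc, ch = ch, reg_max = reg_max,
                               strides = c(8L, 16L, 32L)))
  # bias priors: box offsets start at 1 cell; class logits at a low prior so
  # the initial objectness matches a sparse scene
  for (i in seq_along(ch)) {
    det$ch[[paste0("box", i, "_3")]]$params$b[] <- 1
    det$ch[[paste0("cls", i, "_3")]]$params$b[] <-
      log(5 / nc / (640 / det$cfg$strides[i])^2)
  }
  det
}

ym_forward.detect <- function(mod, x, training = FALSE) {
  # x: list of per-level feature maps
  levels <- list(); caches <- list()
  for (i in seq_along(x)) {
    cb <- list()
    f <- ym_forward(mod$ch[[paste0("box", i, "_1")]], x[[i]], training)
    cb$b1 <- f$cache
    f2 <- ym_forward(mod$ch[[paste0("box", i, "_2")]], f$y, training)
    cb$b2 <- f2$cache
    f3 <- ym_forward(mod$ch[[paste0("box", i, "_3")]], f2$y, training)
    cb$b3 <- f3$cache
    g <- ym_forward(mod$ch[[paste0("cls", i, "_1")]], x[[i]], training)
    cb$c1 <- g$cache
    g2 <- ym_forward(mod$ch[[paste0("cls", i, "_2")]], g$y, training)
    cb$c2 <- g2$cache
    g3 <- ym_forward(mod$ch[[paste0("cls", i, "_3")]], g2$y, training)
    cb$c3 <- g3$cache
    levels[[i]] <- list(box = f3$y, cls = g3$y)
    caches[[i]] <- cb
  }
  list(y = levels, cache = list(lv = caches))
}

ym_backward.detect <- function(mod, cache, dy) {
  # dy: list per level of list(box=, cls=); returns dx list per level
  dxs <- list()
  g <- ym_zero_grad(mod)
  for (i in seq_along(dy)) {
    cb <- cache$lv[[i]]
    b3 <- ym_backward(mod$ch[[paste0("box", i, "_3")]], cb$b3, dy[[i]]$box)
    b2 <- ym_backward(mod$ch[[paste0("box", i, "_2")]], cb$b2, b3$dx)
    b1 <- ym_backward(mod$ch[[paste0("box", i, "_1")]], cb$b1, b2$dx)
    c3 <- ym_backward(mod$ch[[paste0("cls", i, "_3")]], cb$c3, dy[[i]]$cls)
    c2 <- ym_backward(mod$ch[[paste0("cls", i, "_2")]], cb$c2, c3$dx)
    c1 <- ym_backward(mod$ch[[paste0("cls", i, "_1")]], cb$c1, c2$dx)
    g$ch[[paste0("box", i, "_3")]] <- g_add(g$ch[[paste0("box", i, "_3")]], b3$g)
    g$ch[[paste0("box", i, "_2")]] <- g_add(g$ch[[paste0("box", i, "_2")]], b2$g)
    g$ch[[paste0("box", i, "_1")]] <- g_add(g$ch[[paste0("box", i, "_1")]], b1$g)
    g$ch[[paste0("cls", i, "_3")]] <- g_add(g$ch[[paste0("cls", i, "_3")]], c3$g)
    g$ch[[paste0("cls", i, "_2")]] <- g_add(g$ch[[paste0("cls", i, "_2")]], c2$g)
    g$ch[[paste0("cls", i, "_1")]] <- g_add(g$ch[[paste0("cls", i, "_1")]], c1$g)
    dxs[[i]] <- b1$dx + c1$dx
  }
  list(dx = dxs, g = g)
}

# ---- decode ------------------------------------------------------------------

# anchor center coordinates (pixels) for a level
anchor_centers <- function(H, W, stride) {
  cx <- (rep(seq_len(W), each = H) - 0.5) * stride
  cy <- (rep(seq_len(H), times = W) - 0.5) * stride
  cbind(cx = cx, cy = cy)
}

# softmax expectation of the DFL bins; m: (A x reg_max) logits
dfl_expect <- function(m, proj) {
  p <- t(softmax_cols(t(m)))
  list(e = as.vector(p %*% proj), p = p)
}

# decode one level's raw outputs for image n -> matrix(A x (4 + nc))
decode_level <- function(level, stride, proj, n = 1L) {
  d <- dim(level$box)
  H <- d[1]; W <- d[2]
  reg_max <- length(proj)
  A <- H * W
  raw <- matrix(level$box[, , , n], A, 4L * reg_max)
  ctr <- anchor_centers(H, W, stride)
  lt <- dfl_expect(raw[, seq_len(reg_max), drop = FALSE], proj)$e
  tp <- dfl_expect(raw[, reg_max + seq_len(reg_max), drop = FALSE], proj)$e
  rt <- dfl_expect(raw[, 2 * reg_max + seq_len(reg_max), drop = FALSE], proj)$e
  bt <- dfl_expect(raw[, 3 * reg_max + seq_len(reg_max), drop = FALSE], proj)$e
  boxes <- cbind(x1 = ctr[, 1] - lt * stride, y1 = ctr[, 2] - tp * stride,
                 x2 = ctr[, 1] + rt * stride, y2 = ctr[, 2] + bt * stride)
  cls <- sigmoid(matrix(level$cls[, , , n], A, dim(level$cls)[3]))
  cbind(boxes, cls)
}

#' Non-maximum suppression
#'
#' Keeps detections in descending confidence order, suppressing any candidate
#' whose IoU with an already-kept detection is strictly greater than the
#' threshold (a pair at exactly the threshold is kept).
#'
#' @param boxes n x 4 corner matrix.
#' @param scores confidences.
#' @param iou_thr suppression threshold.
#' @return indices of kept rows.
#' @export
nms <- function(boxes, scores, iou_thr = 0.7) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) == 0) break
    ious <- box_iou(matrix(boxes[i, ], length(ord), 4, byrow = TRUE),
                    boxes[ord, , drop = FALSE])
    ord <- ord[!(ious > iou_thr)]
  }
  keep
}

#' Run a detector on images and decode detections
#'
#' @param model a detector from [build_baseline()] or [build_mu()].
#' @param images (H, W, 3, N) array in [0, 1] (or a single (H, W, 3) image).
#' @param conf_thres minimum class confidence.
#' @param iou_thr NMS IoU threshold.
#' @return list of per-image data frames (class, conf, x1, y1, x2, y2);
#'   class ids are 0-based.
#' @export
predict_detections <- function(model, images, conf_thres = 0.25,
                               iou_thr = 0.7) {
  images <- as_fmap(images)
  out <- ym_forward(model, images, training = FALSE)$y
  det <- model$ch$head
  proj <- as.vector(det$params$dfl_proj)
  strides <- det$cfg$strides
  N <- dim(images)[4]
  res <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- do.call(rbind, lapply(seq_along(out), function(i)
      decode_level(out[[i]], strides[i], proj, n)))
    cls <- rows[, -(1:4), drop = FALSE]
    best <- max.col(cls, ties.method = "first")
    conf <- cls[cbind(seq_len(nrow(cls)), best)]
    sel <- conf >= conf_thres
    df <- data.frame(class = integer(0), conf = numeric(0), x1 = numeric(0),
                     y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
    if (any(sel)) {
      b <- rows[sel, 1:4, drop = FALSE]
      cl <- best[sel] - 1L
      cf <- conf[sel]
      keep <- unlist(lapply(unique(cl), function(k) {
        idx <- which(cl == k)
        idx[nms(b[idx, , drop = FALSE], cf[idx], iou_thr)]
      }))
      keep <- keep[order(cf[keep], decreasing = TRUE)]
      df <- data.frame(class = cl[keep], conf = cf[keep],
                       x1 = b[keep, 1], y1 = b[keep, 2],
                       x2 = b[keep, 3], y2 = b[keep, 4])
    }
    res[[n]] <- df
  }
  res
}
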