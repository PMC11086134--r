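# Cross-stage-partial fast spatial pyramid pooling (SPPFCSPC) and efficient
# multi-scale attention (EMA), composed into the SPPFCSPC_EMA head module.

#' Fast pooling cascade: three chained 5x5 stride-1 max-pools
#'
#' S1 = maxpool(R), S2 = maxpool(S1), S3 = maxpool(S2); S2 and S3 equal single
#' 9x9 and 13x13 max-pools of R exactly. S4 concatenates the pyramid along
#' channels (optionally including the pre-pool map).
#'
#' @param R input feature map.
#' @param k pool size (odd; padding (k-1)/2 preserves spatial dims).
#' @param include_prepool prepend R itself to the concatenation.
#' @return list(S1, S2, S3, S4).
#' @export
sppf_cascade <- function(R, k = 5L, include_prepool = TRUE) {
  R <- as_fmap(R)
  p <- k %/% 2L
  s1 <- maxpool2d(R, k, 1L, p)$y
  s2 <- maxpool2d(s1, k, 1L, p)$y
  s3 <- maxpool2d(s2, k, 1L, p)$y
  parts <- if (include_prepool) list(R, s1, s2, s3) else list(s1, s2, s3)
  list(S1 = s1, S2 = s2, S3 = s3, S4 = cat_c(parts))
}

#' SPPFCSPC module
#'
#' Cross-stage-partial wiring around the fast pooling cascade: branch A runs a
#' 1x1/3x3/1x1 convolution stack, the pooling cascade, a 1x1 fuse of the
#' concatenated pyramid and a 3x3 convolution; branch B is a 1x1 projection of
#' the input; outputs are concatenated and fused by a final 1x1 convolution.
#'
#' @param c_in,c_out channel counts.
#' @param e hidden width ratio (hidden = e * c_out).
#' @param k pooling kernel.
#' @param include_prepool include the pre-pool features in the concatenation.
#' @export
sppfcspc_module <- function(c_in, c_out, e = 1.0, k = 5L,
                            include_prepool = TRUE) {
  h <- as.integer(round(e * c_out))
  npool <- if (include_prepool) 4L else 3L
  new_module("sppfcspc",
             ch = list(cv1 = cbs_module(c_in, h, 1L),
                       cv3 = cbs_module(h, h, 3L),
                       cv4 = cbs_module(h, h, 1L),
                       cv5 = cbs_module(npool * h, h, 1L),
                       cv6 = cbs_module(h, h, 3L),
                       cv2 = cbs_module(c_in, h, 1L),
                       cv7 = cbs_module(2L * h, c_out, 1L)),
             cfg = list(c_in = c_in, c_out = c_out, h = h, k = k,
                        include_prepool = include_prepool))
}

ym_forward.sppfcspc <- function(mod, x, training = FALSE) {
  k <- mod$cfg$k; p <- k %/% 2L
  cc <- list()
  f <- ym_forward(mod$ch$cv1, x, training); cc$cv1 <- f$cache
  f <- ym_forward(mod$ch$cv3, f$y, training); cc$cv3 <- f$cache
  f <- ym_forward(mod$ch$cv4, f$y, training); cc$cv4 <- f$cache
  x4 <- f$y
  p1 <- maxpool2d(x4, k, 1L, p)
  p2 <- maxpool2d(p1$y, k, 1L, p)
  p3 <- maxpool2d(p2$y, k, 1L, p)
  parts <- if (mod$cfg$include_prepool) list(x4, p1$y, p2$y, p3$y)
           else list(p1$y, p2$y, p3$y)
  f <- ym_forward(mod$ch$cv5, cat_c(parts), training); cc$cv5 <- f$cache
  f <- ym_forward(mod$ch$cv6, f$y, training); cc$cv6 <- f$cache
  ya <- f$y
  fb <- ym_forward(mod$ch$cv2, x, training); cc$cv2 <- fb$cache
  f7 <- ym_forward(mod$ch$cv7, cat_c(list(ya, fb$y)), training)
  cc$cv7 <- f7$cache
  list(y = f7$y,
       cache = list(ch = cc, idx = list(p1$idx, p2$idx, p3$idx),
                    d4 = dim(x4)))
}

ym_backward.sppfcspc <- function(mod, cache, dy) {
  d4 <- cache$d4
  h <- mod$cfg$h
  gch <- list()
  b7 <- ym_backward(mod$ch$cv7, cache$ch$cv7, dy); gch$cv7 <- b7$g
  dp <- split_c(b7$dx, c(h, h))
  bb <- ym_backward(mod$ch$cv2, cache$ch$cv2, dp[[2]]); gch$cv2 <- bb$g
  b6 <- ym_backward(mod$ch$cv6, cache$ch$cv6, dp[[1]]); gch$cv6 <- b6$g
  b5 <- ym_backward(mod$ch$cv5, cache$ch$cv5, b6$dx); gch$cv5 <- b5$g
  np <- if (mod$cfg$include_prepool) 4L else 3L
  dparts <- split_c(b5$dx, rep(h, np))
  off <- np - 3L
  d3 <- maxpool2d_bwd_cpp(cache$idx[[3]], dparts[[off + 3L]], as.integer(d4))
  d2 <- maxpool2d_bwd_cpp(cache$idx[[2]], dparts[[off + 2L]] + d3,
                          as.integer(d4))
  d1 <- maxpool2d_bwd_cpp(cache$idx[[1]], dparts[[off + 1L]] + d2,
                          as.integer(d4))
  dx4 <- if (mod$cfg$include_prepool) dparts[[1]] + d1 else d1
  b4 <- ym_backward(mod$ch$cv4, cache$ch$cv4, dx4); gch$cv4 <- b4$g
  b3 <- ym_backward(mod$ch$cv3, cache$ch$cv3, b4$dx); gch$cv3 <- b3$g
  b1 <- ym_backward(mod$ch$cv1, cache$ch$cv1, b3$dx); gch$cv1 <- b1$g
  list(dx = b1$dx + bb$dx, g = list(params = list(), ch = gch))
}

#' Efficient multi-scale attention (EMA)
#'
#' Channels are regrouped; two 1x1 pathways gate each group with sigmoid
#' responses to 1-D horizontal and vertical global pooling; a 3x3 pathway
#' preserves spatial detail; cross-pathway spatial attention maps are built
#' from per-group channel softmax of the globally pooled descriptors and
#' matrix dot products; a final sigmoid gate multiplies the input. Shape
#' preserving.
#'
#' @param channels input channels, divisible by groups.
#' @param groups number of channel groups.
#' @export
ema_module <- function(channels, groups = 4L) {
  if (channels %% groups != 0) stop("channels must be divisible by groups")
  cg <- channels %/% groups
  new_module("ema",
             ch = list(fc = linear_module(cg, cg),
                       conv3 = conv_module(cg, cg, 3L, bias = TRUE),
                       gn = inorm_module(cg)),
             cfg = list(channels = channels, groups = groups, cg = cg))
}

ym_forward.ema <- function(mod, x, training = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; cg <- mod$cfg$cg
  B <- mod$cfg$groups * d[4]
  xg <- x; dim(xg) <- c(H, W, cg, B)
  xh <- apply(xg, c(1, 3, 4), mean)              # (H, cg, B)
  xw <- apply(xg, c(2, 3, 4), mean)              # (W, cg, B)
  tok <- matrix(0, B * (H + W), cg)
  for (b in seq_len(B))
    tok[(b - 1L) * (H + W) + seq_len(H + W), ] <- rbind(xh[, , b], xw[, , b])
  fc <- linear_fwd(mod$ch$fc, tok)
  sh <- array(0, dim = c(H, cg, B)); sw <- array(0, dim = c(W, cg, B))
  for (b in seq_len(B)) {
    rows <- (b - 1L) * (H + W)
    sh[, , b] <- sigmoid(fc$y[rows + seq_len(H), , drop = FALSE])
    sw[, , b] <- sigmoid(fc$y[rows + H + seq_len(W), , drop = FALSE])
  }
  G <- array(0, dim = c(H, W, cg, B))
  for (b in seq_len(B)) for (c in seq_len(cg))
    G[, , c, b] <- outer(sh[, c, b], sw[, c, b])
  pre_gn <- xg * G
  gnf <- ym_forward(mod$ch$gn, pre_gn, training)
  x1 <- gnf$y
  c3 <- ym_forward(mod$ch$conv3, xg, training)
  x2 <- c3$y
  HW <- H * W
  gate <- array(0, dim = c(H, W, 1, B))
  z1 <- matrix(0, cg, B); z2 <- matrix(0, cg, B)
  m1 <- matrix(0, cg, B); m2 <- matrix(0, cg, B)
  wmap <- matrix(0, HW, B)
  for (b in seq_len(B)) {
    X1 <- matrix(x1[, , , b], HW, cg)
    X2 <- matrix(x2[, , , b], HW, cg)
    m1[, b] <- colMeans(X1); m2[, b] <- colMeans(X2)
    z1[, b] <- softmax_cols(matrix(m1[, b]))[, 1]
    z2[, b] <- softmax_cols(matrix(m2[, b]))[, 1]
    wmap[, b] <- X2 %*% z1[, b] + X1 %*% z2[, b]
    gate[, , 1, b] <- sigmoid(matrix(wmap[, b], H, W))
  }
  y <- xg  # gate broadcast over channels below
  for (b in seq_len(B)) for (c in seq_len(cg))
    y[, , c, b] <- xg[, , c, b] * gate[, , 1, b]
  dim(y) <- d
  list(y = y,
       cache = list(d = d, xg = xg, sh = sh, sw = sw, G = G, fc = fc$cache,
                    gn = gnf$cache, conv3 = c3$cache, x1 = x1, x2 = x2,
                    z1 = z1, z2 = z2, gate = gate, wmap = wmap, B = B))
}

ym_backward.ema <- function(mod, cache, dy) {
  d <- cache$d
  H <- d[1]; W <- d[2]; cg <- mod$cfg$cg; B <- cache$B
  HW <- H * W
  dyg <- dy; dim(dyg) <- c(H, W, cg, B)
  xg <- cache$xg
  dxg <- array(0, dim = dim(xg))
  dx1 <- array(0, dim = dim(xg)); dx2 <- array(0, dim = dim(xg))
  for (b in seq_len(B)) {
    gb <- cache$gate[, , 1, b]
    dwm <- matrix(0, H, W)
    for (c in seq_len(cg)) {
      dxg[, , c, b] <- dxg[, , c, b] + dyg[, , c, b] * gb
      dwm <- dwm + dyg[, , c, b] * xg[, , c, b]
    }
    dwmap <- as.vector(dwm * gb * (1 - gb))
    X1 <- matrix(cache$x1[, , , b], HW, cg)
    X2 <- matrix(cache$x2[, , , b], HW, cg)
    z1 <- cache$z1[, b]; z2 <- cache$z2[, b]
    dX2 <- outer(dwmap, z1); dX1 <- outer(dwmap, z2)
    dz1 <- crossprod(X2, dwmap)[, 1]
    dz2 <- crossprod(X1, dwmap)[, 1]
    dm1 <- softmax_cols_bwd(matrix(z1), matrix(dz1))[, 1]
    dm2 <- softmax_cols_bwd(matrix(z2), matrix(dz2))[, 1]
    dX1 <- dX1 + matrix(dm1, HW, cg, byrow = TRUE) / HW
    dX2 <- dX2 + matrix(dm2, HW, cg, byrow = TRUE) / HW
    dx1[, , , b] <- array(dX1, dim = c(H, W, cg))
    dx2[, , , b] <- array(dX2, dim = c(H, W, cg))
  }
  bgn <- ym_backward(mod$ch$gn, cache$gn, dx1)
  dpre <- bgn$dx
  dxg <- dxg + dpre * cache$G
  dG <- dpre * xg
  bc3 <- ym_backward(mod$ch$conv3, cache$conv3, dx2)
  dxg <- dxg + bc3$dx
  # gate gradients back through the 1-D pooling pathway
  dtok <- matrix(0, B * (H + W), cg)
  for (b in seq_len(B)) {
    dsh <- matrix(0, H, cg); dsw <- matrix(0, W, cg)
    for (c in seq_len(cg)) {
      dG_cb <- dG[, , c, b]
      dsh[, c] <- dG_cb %*% cache$sw[, c, b]
      dsw[, c] <- crossprod(dG_cb, cache$sh[, c, b])[, 1]
    }
    dah <- dsh * cache$sh[, , b] * (1 - cache$sh[, , b])
    daw <- dsw * cache$sw[, , b] * (1 - cache$sw[, , b])
    dtok[(b - 1L) * (H + W) + seq_len(H + W), ] <- rbind(dah, daw)
  }
  bfc <- linear_bwd(mod$ch$fc, cache$fc, dtok)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * (H + W)
    dxh <- bfc$dx[rows + seq_len(H), , drop = FALSE] / W
    dxw <- bfc$dx[rows + H + seq_len(W), , drop = FALSE] / H
    for (c in seq_len(cg)) {
      dxg[, , c, b] <- dxg[, , c, b] +
        matrix(dxh[, c], H, W) + matrix(dxw[, c], H, W, byrow = TRUE)
    }
  }
  dim(dxg) <- d
  list(dx = dxg,
       g = list(params = list(),
                ch = list(fc = bfc$g, conv3 = bc3$g, gn = bgn$g)))
}

#' Apply efficient multi-scale attention to a feature map
#'
#' @param x feature map.
#' @param g number of channel groups (used when mod is omitted).
#' @param mod an [ema_module()].
#' @export
ema_attention <- function(x, g = 4L, mod = NULL) {
  x <- as_fmap(x)
  if (is.null(mod)) mod <- ema_module(dim(x)[3], g)
  ym_forward(mod, x)$y
}

#' SPPFCSPC followed by EMA attention
#'
#' @inheritParams sppfcspc_module
#' @param ema_groups EMA channel groups.
#' @export
sppfcspc_ema_module <- function(c_in, c_out, e = 1.0, k = 5L,
                                ema_groups = 4L, include_prepool = TRUE) {
  new_module("sppfcspc_ema",
             ch = list(spp = sppfcspc_module(c_in, c_out, e, k,
                                             include_prepool),
                       ema = ema_module(c_out, ema_groups)),
             cfg = list(c_in = c_in, c_out = c_out))
}

ym_forward.sppfcspc_ema <- function(mod, x, training = FALSE) {
  f1 <- ym_forward(mod$ch$spp, x, training)
  f2 <- ym_forward(mod$ch$ema, f1$y, training)
  list(y = f2$y, cache = list(ch = list(spp = f1$cache, ema = f2$cache)))
}

ym_backward.sppfcspc_ema <- function(mod, cache, dy) {
  b2 <- ym_backward(mod$ch$ema, cache$ch$ema, dy)
  b1 <- ym_backward(mod$ch$spp, cache$ch$spp, b2$dx)
  list(dx = b1$dx,
       g = list(params = list(), ch = list(spp = b1$g, ema = b2$g)))
}
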