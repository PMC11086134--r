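# Window and shifted-window multi-head self-attention, and the C2fSTR block:
# a cross-stage-partial skeleton whose bottlenecks are Swin transformer layers.

#' Partition a feature map into square token windows
#'
#' @param x (H, W, C) or (H, W, C, N) array with H, W divisible by M.
#' @param M window side length.
#' @return (M, M, C, n_windows) array; windows ordered rows-first within each
#'   image, images consecutive.
#' @export
window_partition <- function(x, M) {
  x <- as_fmap(x)
  d <- dim(x)
  if (d[1] %% M != 0 || d[2] %% M != 0)
    stop("H and W must be divisible by M (pad first)")
  nh <- d[1] %/% M; nw <- d[2] %/% M
  out <- array(0, dim = c(M, M, d[3], nh * nw * d[4]))
  wi <- 0L
  for (n in seq_len(d[4])) for (j in seq_len(nw)) for (i in seq_len(nh)) {
    wi <- wi + 1L
    out[, , , wi] <- x[(i - 1L) * M + 1:M, (j - 1L) * M + 1:M, , n]
  }
  out
}

#' Reassemble windows into a feature map (inverse of [window_partition()])
#'
#' @param wins (M, M, C, n_windows) array.
#' @param H,W target spatial dims.
#' @export
window_reverse <- function(wins, H, W) {
  d <- dim(wins)
  M <- d[1]
  nh <- H %/% M; nw <- W %/% M
  N <- d[4] %/% (nh * nw)
  out <- array(0, dim = c(H, W, d[3], N))
  wi <- 0L
  for (n in seq_len(N)) for (j in seq_len(nw)) for (i in seq_len(nh)) {
    wi <- wi + 1L
    out[(i - 1L) * M + 1:M, (j - 1L) * M + 1:M, , n] <- wins[, , , wi]
  }
  out
}

#' Cyclic shift of a feature map toward the top-left
#'
#' @param x (H, W, C[, N]) array.
#' @param s shift in tokens; negative values shift back (inverse).
#' @export
cyclic_shift <- function(x, s) {
  x <- as_fmap(x)
  d <- dim(x)
  ih <- ((seq_len(d[1]) - 1L + s) %% d[1]) + 1L
  iw <- ((seq_len(d[2]) - 1L + s) %% d[2]) + 1L
  x[ih, iw, , , drop = FALSE]
}

#' Attention mask for shifted-window self-attention
#'
#' After a cyclic shift by s = floor(M/2), windows along the bottom/right edges
#' contain tokens from discontinuous source regions; pairs from different
#' regions receive a large negative additive value so normalized attention
#' cannot mix them.
#'
#' @param H,W map size (divisible by M).
#' @param M window size.
#' @param shift cyclic shift (0 gives an all-zero mask).
#' @param blocked the finite negative surrogate for -Inf.
#' @return (M^2, M^2, n_windows) array of additive mask values.
#' @export
build_shift_mask <- function(H, W, M, shift, blocked = -100) {
  rlab <- function(n) {
    i <- seq_len(n) - 1L
    ifelse(i < n - M, 0L, ifelse(i < n - shift, 1L, 2L))
  }
  lab <- outer(rlab(H), rlab(W), function(a, b) a * 3L + b)
  lw <- window_partition(array(lab, dim = c(H, W, 1, 1)), M)
  nw <- dim(lw)[4]
  Tn <- M * M
  mask <- array(0, dim = c(Tn, Tn, nw))
  if (shift == 0) return(mask)
  for (k in seq_len(nw)) {
    v <- as.vector(lw[, , 1, k])
    mask[, , k] <- ifelse(outer(v, v, "!=") , blocked, 0)
  }
  mask
}

# relative-position index matrix (T x T) into a (2M-1)^2 table, for effective
# window side me <= M (table built for M)
relpos_index <- function(me, M) {
  hh <- rep(seq_len(me), times = me)
  ww <- rep(seq_len(me), each = me)
  di <- outer(hh, hh, "-") + (M - 1L)
  dj <- outer(ww, ww, "-") + (M - 1L)
  di + (2L * M - 1L) * dj + 1L
}

#' Swin transformer layer
#'
#' Layer norm, (shifted-)window multi-head self-attention with relative
#' position bias, residual; layer norm, MLP, residual. Maps whose sides are
#' not divisible by the window are zero-padded then cropped; on maps smaller
#' than the configured window the effective window falls back to min(H, W).
#'
#' @param dim embedding (channel) dimension.
#' @param heads attention heads (dim divisible by heads).
#' @param M window side length.
#' @param shifted use the shifted configuration (cyclic shift by floor(M/2)).
#' @param mlp_ratio MLP hidden expansion.
#' @export
swin_block_module <- function(dim, heads = max(1L, dim %/% 32L), M = 7L,
                              shifted = FALSE, mlp_ratio = 4L) {
  if (dim %% heads != 0) stop("dim must be divisible by heads")
  new_module("swin",
             params = list(relpos = array(0, dim = c((2L * M - 1L)^2, heads))),
             ch = list(ln1 = ln_module(dim),
                       qkv = linear_module(dim, 3L * dim),
                       proj = linear_module(dim, dim),
                       ln2 = ln_module(dim),
                       fc1 = linear_module(dim, mlp_ratio * dim),
                       fc2 = linear_module(mlp_ratio * dim, dim)),
             cfg = list(dim = dim, heads = heads, M = M, shifted = shifted,
                        mlp_ratio = mlp_ratio))
}

# attention over one window's token matrix (T x 3D qkv), returns (T x D)
.attn_win <- function(qkv, heads, relbias, mask_w) {
  Tn <- nrow(qkv)
  D <- ncol(qkv) %/% 3L
  dh <- D %/% heads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, Tn, D)
  hc <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, D + cols, drop = FALSE]
    V <- qkv[, 2L * D + cols, drop = FALSE]
    S <- tcrossprod(Q, K) * scale + relbias[, , h]
    if (!is.null(mask_w)) S <- S + mask_w
    A <- t(softmax_cols(t(S)))          # softmax over rows
    out[, cols] <- A %*% V
    hc[[h]] <- list(Q = Q, K = K, V = V, A = A)
  }
  list(out = out, hc = hc, scale = scale)
}

.attn_win_bwd <- function(cache, dout, heads, M, ridx) {
  Tn <- nrow(dout)
  D <- ncol(dout)
  dh <- D %/% heads
  dqkv <- matrix(0, Tn, 3L * D)
  drel <- NULL
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    cc <- cache$hc[[h]]
    dO <- dout[, cols, drop = FALSE]
    dA <- tcrossprod(dO, cc$V)          # dO %*% t(V)
    dV <- crossprod(cc$A, dO)
    dS <- t(softmax_cols_bwd(t(cc$A), t(dA)))
    dS_rel <- dS
    dQ <- (dS %*% cc$K) * cache$scale
    dK <- (crossprod(dS, cc$Q)) * cache$scale
    dqkv[, cols] <- dQ
    dqkv[, D + cols] <- dK
    dqkv[, 2L * D + cols] <- dV
    dr <- numeric((2L * M - 1L)^2)
    tab <- tapply(as.vector(dS_rel), as.vector(ridx), sum)
    dr[as.integer(names(tab))] <- tab
    drel <- cbind(drel, dr)
  }
  list(dqkv = dqkv, drel = drel)
}

ym_forward.swin <- function(mod, x, training = FALSE) {
  cfg <- mod$cfg
  d0 <- dim(x)
  H <- d0[1]; W <- d0[2]; D <- cfg$dim; N <- d0[4]
  me <- min(cfg$M, H, W)
  s <- if (cfg$shifted && me > 1L) me %/% 2L else 0L
  Hp <- ceiling(H / me) * me
  Wp <- ceiling(W / me) * me
  xp <- x
  if (Hp != H || Wp != W) {
    xp <- array(0, dim = c(Hp, Wp, D, N))
    xp[1:H, 1:W, , ] <- x
  }
  Tn <- me * me
  ridx <- relpos_index(me, cfg$M)
  relbias <- array(0, dim = c(Tn, Tn, cfg$heads))
  for (h in seq_len(cfg$heads))
    relbias[, , h] <- matrix(mod$params$relpos[, h][ridx], Tn, Tn)
  mask <- if (s > 0L) build_shift_mask(Hp, Wp, me, s) else NULL
  nh <- Hp %/% me; nwn <- Wp %/% me
  tok <- matrix(aperm(xp, c(1, 2, 4, 3)), ncol = D)  # (Hp*Wp*N) x D
  ln1 <- ln_fwd(mod$ch$ln1, tok)
  xs <- array(aperm(array(ln1$y, dim = c(Hp, Wp, N, D)), c(1, 2, 4, 3)),
              dim = c(Hp, Wp, D, N))
  if (s > 0L) xs <- cyclic_shift(xs, s)
  wins <- window_partition(xs, me)
  nwtot <- dim(wins)[4]
  qkv_in <- matrix(0, nwtot * Tn, D)
  for (k in seq_len(nwtot))
    qkv_in[(k - 1L) * Tn + seq_len(Tn), ] <- matrix(wins[, , , k], Tn, D)
  qkv <- linear_fwd(mod$ch$qkv, qkv_in)
  attn_out <- matrix(0, nwtot * Tn, D)
  wcaches <- vector("list", nwtot)
  for (k in seq_len(nwtot)) {
    rows <- (k - 1L) * Tn + seq_len(Tn)
    mw <- if (!is.null(mask)) mask[, , ((k - 1L) %% (nh * nwn)) + 1L]
    aw <- .attn_win(qkv$y[rows, , drop = FALSE], cfg$heads, relbias, mw)
    attn_out[rows, ] <- aw$out
    wcaches[[k]] <- aw
  }
  proj <- linear_fwd(mod$ch$proj, attn_out)
  awins <- array(0, dim = c(me, me, D, nwtot))
  for (k in seq_len(nwtot))
    awins[, , , k] <- array(proj$y[(k - 1L) * Tn + seq_len(Tn), ],
                            dim = c(me, me, D))
  ya <- window_reverse(awins, Hp, Wp)
  if (s > 0L) ya <- cyclic_shift(ya, -s)
  ytok <- matrix(aperm(ya, c(1, 2, 4, 3)), ncol = D)
  h1 <- tok + ytok                                  # first residual
  ln2 <- ln_fwd(mod$ch$ln2, h1)
  f1 <- linear_fwd(mod$ch$fc1, ln2$y)
  a <- gelu(f1$y)
  f2 <- linear_fwd(mod$ch$fc2, a)
  h2 <- h1 + f2$y
  yp <- array(aperm(array(h2, dim = c(Hp, Wp, N, D)), c(1, 2, 4, 3)),
              dim = c(Hp, Wp, D, N))
  y <- yp[1:H, 1:W, , , drop = FALSE]
  list(y = y,
       cache = list(ln1 = ln1$cache, qkv = qkv$cache, wc = wcaches,
                    proj = proj$cache, ln2 = ln2$cache, f1 = f1$cache,
                    f2 = f2$cache, pre_act = f1$y, dims = c(H, W, D, N),
                    Hp = Hp, Wp = Wp, me = me, s = s, ridx = ridx))
}

ym_backward.swin <- function(mod, cache, dy) {
  cfg <- mod$cfg
  dm <- cache$dims
  H <- dm[1]; W <- dm[2]; D <- dm[3]; N <- dm[4]
  Hp <- cache$Hp; Wp <- cache$Wp; me <- cache$me; s <- cache$s
  Tn <- me * me
  dyp <- array(0, dim = c(Hp, Wp, D, N))
  dyp[1:H, 1:W, , ] <- dy
  dh2 <- matrix(aperm(dyp, c(1, 2, 4, 3)), ncol = D)
  b2 <- linear_bwd(mod$ch$fc2, cache$f2, dh2)
  da <- gelu_bwd(cache$pre_act, b2$dx)
  b1 <- linear_bwd(mod$ch$fc1, cache$f1, da)
  bl2 <- ln_bwd(mod$ch$ln2, cache$ln2, b1$dx)
  dh1 <- dh2 + bl2$dx
  # back through attention branch
  dya <- array(aperm(array(dh1, dim = c(Hp, Wp, N, D)), c(1, 2, 4, 3)),
               dim = c(Hp, Wp, D, N))
  if (s > 0L) dya <- cyclic_shift(dya, s)
  dwins <- window_partition(dya, me)
  nwtot <- dim(dwins)[4]
  dproj_out <- matrix(0, nwtot * Tn, D)
  for (k in seq_len(nwtot))
    dproj_out[(k - 1L) * Tn + seq_len(Tn), ] <- matrix(dwins[, , , k], Tn, D)
  bp <- linear_bwd(mod$ch$proj, cache$proj, dproj_out)
  dqkv_all <- matrix(0, nwtot * Tn, 3L * D)
  drel <- matrix(0, (2L * cfg$M - 1L)^2, cfg$heads)
  for (k in seq_len(nwtot)) {
    rows <- (k - 1L) * Tn + seq_len(Tn)
    bw <- .attn_win_bwd(cache$wc[[k]], bp$dx[rows, , drop = FALSE],
                        cfg$heads, cfg$M, cache$ridx)
    dqkv_all[rows, ] <- bw$dqkv
    drel <- drel + bw$drel
  }
  bq <- linear_bwd(mod$ch$qkv, cache$qkv, dqkv_all)
  dswin <- array(0, dim = c(me, me, D, nwtot))
  for (k in seq_len(nwtot))
    dswin[, , , k] <- array(bq$dx[(k - 1L) * Tn + seq_len(Tn), ],
                            dim = c(me, me, D))
  dxs <- window_reverse(dswin, Hp, Wp)
  if (s > 0L) dxs <- cyclic_shift(dxs, -s)
  dln1y <- matrix(aperm(dxs, c(1, 2, 4, 3)), ncol = D)
  bl1 <- ln_bwd(mod$ch$ln1, cache$ln1, dln1y)
  dtok <- dh1 + bl1$dx
  dxp <- array(aperm(array(dtok, dim = c(Hp, Wp, N, D)), c(1, 2, 4, 3)),
               dim = c(Hp, Wp, D, N))
  dx <- dxp[1:H, 1:W, , , drop = FALSE]
  list(dx = dx,
       g = list(params = list(relpos = drel),
                ch = list(ln1 = bl1$g, qkv = bq$g, proj = bp$g, ln2 = bl2$g,
                          fc1 = b1$g, fc2 = b2$g)))
}

#' Window multi-head self-attention over a stack of token windows
#'
#' Applies a Swin layer's attention (qkv projection, scaled dot product with
#' relative position bias, optional additive mask, output projection) to each
#' window independently.
#'
#' @param windows (M, M, C, n_windows) array from [window_partition()].
#' @param mod a [swin_block_module()] whose dim matches C.
#' @param mask optional (M^2, M^2, n_windows) additive mask.
#' @return attended windows, same shape.
#' @export
window_msa <- function(windows, mod, mask = NULL) {
  d <- dim(windows)
  me <- d[1]; D <- d[3]; nw <- d[4]
  Tn <- me * me
  ridx <- relpos_index(me, mod$cfg$M)
  relbias <- array(0, dim = c(Tn, Tn, mod$cfg$heads))
  for (h in seq_len(mod$cfg$heads))
    relbias[, , h] <- matrix(mod$params$relpos[, h][ridx], Tn, Tn)
  out <- windows
  for (k in seq_len(nw)) {
    tokmat <- matrix(windows[, , , k], Tn, D)
    qkv <- linear_fwd(mod$ch$qkv, tokmat)
    mw <- if (!is.null(mask)) mask[, , k]
    aw <- .attn_win(qkv$y, mod$cfg$heads, relbias, mw)
    proj <- linear_fwd(mod$ch$proj, aw$out)
    out[, , , k] <- array(proj$y, dim = c(me, me, D))
  }
  out
}

#' Two consecutive Swin layers (regular then shifted windows)
#'
#' @param dim,heads,M,mlp_ratio as in [swin_block_module()].
#' @export
swin_pair_module <- function(dim, heads = max(1L, dim %/% 32L), M = 7L,
                             mlp_ratio = 4L) {
  seq_module(list(swin_block_module(dim, heads, M, FALSE, mlp_ratio),
                  swin_block_module(dim, heads, M, TRUE, mlp_ratio)))
}

#' Apply a Swin block pair to a feature map
#'
#' @param x feature map.
#' @param mod a [swin_pair_module()].
#' @export
swin_block_pair <- function(x, mod) module_forward(mod, as_fmap(x))

#' C2fSTR: cross-stage-partial block with Swin transformer bottlenecks
#'
#' The C2f skeleton (1x1 projection, split, concatenation of all intermediate
#' parts, 1x1 fusion) with each Darknet bottleneck replaced by one Swin
#' transformer layer; layers alternate regular and shifted windows.
#'
#' @param c_in,c_out channel counts.
#' @param n number of Swin layers.
#' @param M window size.
#' @export
c2fstr_module <- function(c_in, c_out, n = 1L, M = 7L) {
  if (c_out %% 2L != 0L) stop("c_out must be even")
  hc <- c_out %/% 2L
  ch <- list(cv1 = cbs_module(c_in, 2L * hc, 1L))
  for (i in seq_len(n))
    ch[[paste0("m", i)]] <- swin_block_module(hc, M = M,
                                              shifted = (i %% 2L == 0L))
  ch$cv2 <- cbs_module((2L + n) * hc, c_out, 1L)
  m <- new_module("c2f", ch = ch,
                  cfg = list(n = n, hc = hc, c_in = c_in, c_out = c_out))
  class(m) <- c("c2fstr", class(m))  # same wiring as c2f; keep its methods
  m
}
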