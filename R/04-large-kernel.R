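# Large-kernel residual blocks with dilated-reparameterization: a dense K x K
# depth-wise convolution trained in parallel with dilated small-kernel branches
# whose outputs sum, mergeable after training into one dense kernel.

#' Equivalent dense kernel size of a dilated convolution
#'
#' A k x k kernel with dilation r covers the same receptive field as a dense
#' kernel of side (k - 1) * r + 1.
#'
#' @param k odd kernel size.
#' @param r dilation rate >= 1.
#' @return odd integer size.
#' @export
equivalent_kernel_size <- function(k, r) {
  if (any(k %% 2 == 0)) stop("kernel size must be odd")
  if (any(r < 1)) stop("dilation rate must be >= 1")
  (k - 1) * r + 1
}

#' Expand a dilated kernel to its dense equivalent
#'
#' Zero-insertion: entry (i, j) of the source kernel lands at (i*r, j*r) of a
#' ((k-1)r+1)^2 kernel. Convolving with the result (dilation 1) is exactly the
#' dilated convolution.
#'
#' @param w kernel array; the first two dims are the spatial k x k.
#' @param r dilation rate.
#' @export
dilate_to_dense <- function(w, r) {
  d <- dim(w)
  if (is.null(d)) stop("w must be an array")
  k <- d[1]
  if (r == 1) return(w)
  ke <- (k - 1L) * r + 1L
  out <- array(0, dim = c(ke, ke, d[-(1:2)]))
  idx <- seq(1L, ke, by = r)
  if (length(d) == 2) out[idx, idx] <- w
  else if (length(d) == 3) out[idx, idx, ] <- w
  else out[idx, idx, , ] <- w
  out
}

# zero-pad a dense kernel (first two dims) to K x K, centered
pad_kernel_to <- function(w, K) {
  d <- dim(w)
  k <- d[1]
  if (k == K) return(w)
  off <- (K - k) %/% 2L
  out <- array(0, dim = c(K, K, d[-(1:2)]))
  ii <- (off + 1L):(off + k)
  if (length(d) == 2) out[ii, ii] <- w
  else if (length(d) == 3) out[ii, ii, ] <- w
  else out[ii, ii, , ] <- w
  out
}

#' Fold frozen batch-norm statistics into convolution weights
#'
#' Returns weights w * gamma / sqrt(var + eps) (per output channel) and bias
#' beta - mean * gamma / sqrt(var + eps), plus any prior bias scaled the same
#' way; the fused convolution reproduces conv-then-BN exactly.
#'
#' @param layer list with w (kh, kw, cpg, co), optional b, and bn = list(mean,
#'   var, gamma, beta, eps).
#' @return list(w, b).
#' @export
fuse_conv_bn <- function(layer) {
  bn <- layer$bn
  if (any(bn$var + bn$eps <= 0)) stop("non-positive variance + eps")
  s <- bn$gamma / sqrt(bn$var + bn$eps)
  w <- layer$w
  co <- dim(w)[4]
  for (i in seq_len(co)) w[, , , i] <- w[, , , i] * s[i]
  b0 <- layer$b %||% numeric(co)
  list(w = w, b = bn$beta + (b0 - bn$mean) * s)
}

# module -> ConvBN spec for fuse_conv_bn
conv_bn_spec <- function(conv, bn) {
  list(w = conv$params$w, b = conv$params$b,
       bn = list(mean = bn$buffers$rm, var = bn$buffers$rv,
                 gamma = bn$params$gamma, beta = bn$params$beta,
                 eps = bn$cfg$eps))
}

#' Dilated reparameterization block
#'
#' Depth-wise dense K x K convolution plus parallel dilated small-kernel
#' branches, each with its own batch norm; outputs are summed. After training
#' the whole block merges exactly into a single dense K x K convolution.
#'
#' @param channels number of channels (depth-wise).
#' @param K dense kernel size (odd), default 9.
#' @param k small-kernel sizes of the parallel branches.
#' @param r dilation rates, same length as k.
#' @export
dilated_reparam_module <- function(channels, K = 9L, k = c(5L, 3L, 3L, 3L),
                                   r = c(1L, 2L, 3L, 4L)) {
  if (length(k) != length(r)) stop("k and r must have equal length")
  eq <- equivalent_kernel_size(k, r)
  if (any(eq > K)) stop("branch equivalent size exceeds K")
  ch <- list(lk = conv_module(channels, channels, K, groups = channels,
                              bias = FALSE),
             lk_bn = bn_module(channels))
  for (i in seq_along(k)) {
    ch[[paste0("b", i)]] <- conv_module(channels, channels, k[i],
                                        dilation = r[i], groups = channels,
                                        bias = FALSE)
    ch[[paste0("b", i, "_bn")]] <- bn_module(channels)
  }
  new_module("dreparam", ch = ch,
             cfg = list(channels = channels, K = K, k = k, r = r,
                        deploy = FALSE))
}

ym_forward.dreparam <- function(mod, x, training = FALSE) {
  if (mod$cfg$deploy) {
    y <- conv2d(x, mod$params$w_merged, mod$params$b_merged,
                pad = mod$cfg$K %/% 2L, groups = mod$cfg$channels)
    return(list(y = y, cache = list(x = x)))
  }
  caches <- list()
  f <- ym_forward(mod$ch$lk, x, training)
  fb <- ym_forward(mod$ch$lk_bn, f$y, training)
  caches$lk <- f$cache; caches$lk_bn <- fb$cache
  y <- fb$y
  for (i in seq_along(mod$cfg$k)) {
    fi <- ym_forward(mod$ch[[paste0("b", i)]], x, training)
    fbi <- ym_forward(mod$ch[[paste0("b", i, "_bn")]], fi$y, training)
    caches[[paste0("b", i)]] <- fi$cache
    caches[[paste0("b", i, "_bn")]] <- fbi$cache
    y <- y + fbi$y
  }
  list(y = y, cache = list(ch = caches))
}

ym_backward.dreparam <- function(mod, cache, dy) {
  if (mod$cfg$deploy) stop("backward not supported in deploy mode")
  gch <- list()
  bb <- ym_backward(mod$ch$lk_bn, cache$ch$lk_bn, dy)
  bc <- ym_backward(mod$ch$lk, cache$ch$lk, bb$dx)
  gch$lk_bn <- bb$g; gch$lk <- bc$g
  dx <- bc$dx
  for (i in seq_along(mod$cfg$k)) {
    bbi <- ym_backward(mod$ch[[paste0("b", i, "_bn")]],
                       cache$ch[[paste0("b", i, "_bn")]], dy)
    bci <- ym_backward(mod$ch[[paste0("b", i)]],
                       cache$ch[[paste0("b", i)]], bbi$dx)
    gch[[paste0("b", i, "_bn")]] <- bbi$g
    gch[[paste0("b", i)]] <- bci$g
    dx <- dx + bci$dx
  }
  list(dx = dx, g = list(params = list(), ch = gch))
}

#' Merge a dilated reparameterization block into one dense convolution
#'
#' Each branch is BN-fused, expanded to its dense equivalent, zero-padded to
#' K x K, and summed with the fused dense kernel. Requires frozen statistics.
#'
#' @param mod a dilated reparam module.
#' @return list(w, b) of the single K x K depth-wise convolution.
#' @export
merge_dilated_reparam <- function(mod) {
  K <- mod$cfg$K
  f <- fuse_conv_bn(conv_bn_spec(mod$ch$lk, mod$ch$lk_bn))
  w <- f$w; b <- f$b
  for (i in seq_along(mod$cfg$k)) {
    fi <- fuse_conv_bn(conv_bn_spec(mod$ch[[paste0("b", i)]],
                                    mod$ch[[paste0("b", i, "_bn")]]))
    w <- w + pad_kernel_to(dilate_to_dense(fi$w, mod$cfg$r[i]), K)
    b <- b + fi$b
  }
  list(w = w, b = b)
}

# ---- squeeze-and-excitation --------------------------------------------------

#' Squeeze-and-excitation channel recalibration
#'
#' Global average per channel, bottleneck transform, sigmoid gate in (0, 1),
#' channel-wise multiply.
#'
#' @param channels input channels, divisible by reduction.
#' @param reduction bottleneck reduction ratio.
#' @export
se_module <- function(channels, reduction = 4L) {
  if (channels %% reduction != 0)
    stop("channels must be divisible by the reduction ratio")
  new_module("se",
             ch = list(fc1 = linear_module(channels, channels %/% reduction),
                       fc2 = linear_module(channels %/% reduction, channels)),
             cfg = list(channels = channels, reduction = reduction))
}

ym_forward.se <- function(mod, x, training = FALSE) {
  d <- dim(x)
  z <- t(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])) |>
           matrix(d[3], d[4]))                       # (N x C)
  f1 <- linear_fwd(mod$ch$fc1, z)
  h <- pmax(f1$y, 0)
  f2 <- linear_fwd(mod$ch$fc2, h)
  s <- sigmoid(f2$y)                                 # (N x C)
  sb <- aperm(array(t(s), dim = c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  list(y = x * sb,
       cache = list(x = x, s = s, sb = sb, h = h, f1 = f1$cache,
                    f2 = f2$cache, d = d))
}

ym_backward.se <- function(mod, cache, dy) {
  d <- cache$d
  ds <- t(matrix(colSums(matrix(dy * cache$x, d[1] * d[2], d[3] * d[4])),
                 d[3], d[4]))                        # (N x C)
  dz2 <- sigmoid_bwd(cache$s, ds)
  b2 <- linear_bwd(mod$ch$fc2, cache$f2, dz2)
  dh <- b2$dx * (cache$h > 0)
  b1 <- linear_bwd(mod$ch$fc1, cache$f1, dh)
  dzb <- aperm(array(t(b1$dx), dim = c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  dx <- dy * cache$sb + dzb / (d[1] * d[2])
  list(dx = dx,
       g = list(params = list(), ch = list(fc1 = b1$g, fc2 = b2$g)))
}

#' Apply squeeze-and-excitation recalibration to a feature map
#'
#' @param x feature map (H, W, C, N).
#' @param mod an [se_module()]; a fresh one is created when omitted.
#' @param reduction reduction ratio used when mod is omitted.
#' @export
se_recalibrate <- function(x, mod = NULL, reduction = 4L) {
  x <- as_fmap(x)
  if (is.null(mod)) mod <- se_module(dim(x)[3], reduction)
  ym_forward(mod, x)$y
}

# ---- LarK / SmaK residual blocks ---------------------------------------------

#' Large-kernel (LarK) and small-kernel (SmaK) residual blocks
#'
#' A LarK block applies a depth-wise dilated-reparam convolution, batch norm,
#' squeeze-and-excitation, and a 4x feed-forward network, with a layer-scaled
#' residual connection. A SmaK block is identical except a depth-wise 3 x 3
#' convolution replaces the dilated-reparam layer.
#'
#' @param channels block width.
#' @param kind "lark" or "smak".
#' @param K,k,r dilated reparam geometry (LarK only).
#' @param ffn_ratio hidden expansion of the feed-forward network.
#' @param se_reduction squeeze-and-excitation reduction.
#' @export
lark_module <- function(channels, kind = c("lark", "smak"), K = 9L,
                        k = c(5L, 3L, 3L, 3L), r = c(1L, 2L, 3L, 4L),
                        ffn_ratio = 4L, se_reduction = 4L) {
  kind <- match.arg(kind)
  dw <- if (kind == "lark") dilated_reparam_module(channels, K, k, r)
        else conv_module(channels, channels, 3L, groups = channels,
                         bias = FALSE)
  ch <- list(dw = dw)
  if (kind == "smak") ch$dw_bn <- bn_module(channels)
  ch$norm1 <- bn_module(channels)
  ch$se <- se_module(channels, se_reduction)
  ch$norm2 <- bn_module(channels)
  ch$pw1 <- conv_module(channels, channels * ffn_ratio, 1L, bias = TRUE)
  ch$pw2 <- conv_module(channels * ffn_ratio, channels, 1L, bias = TRUE)
  new_module("lark", ch = ch,
             params = list(gamma = rep(1, channels)),
             cfg = list(channels = channels, kind = kind))
}

ym_forward.lark <- function(mod, x, training = FALSE) {
  caches <- list()
  f <- ym_forward(mod$ch$dw, x, training)
  caches$dw <- f$cache
  t <- f$y
  if (mod$cfg$kind == "smak") {
    f <- ym_forward(mod$ch$dw_bn, t, training)
    caches$dw_bn <- f$cache
    t <- f$y
  }
  f <- ym_forward(mod$ch$norm1, t, training); caches$norm1 <- f$cache
  f <- ym_forward(mod$ch$se, f$y, training); caches$se <- f$cache
  f <- ym_forward(mod$ch$norm2, f$y, training); caches$norm2 <- f$cache
  f1 <- ym_forward(mod$ch$pw1, f$y, training); caches$pw1 <- f1$cache
  a <- gelu(f1$y)
  f2 <- ym_forward(mod$ch$pw2, a, training); caches$pw2 <- f2$cache
  d <- dim(x)
  gb <- bcast_c(mod$params$gamma, d)
  list(y = x + gb * f2$y,
       cache = list(ch = caches, pre_act = f1$y, u = f2$y, gb = gb, d = d))
}

ym_backward.lark <- function(mod, cache, dy) {
  d <- cache$d
  du <- dy * cache$gb
  dgamma_full <- dy * cache$u
  dgamma <- colSums(matrix(aperm(dgamma_full, c(1, 2, 4, 3)), ncol = d[3]))
  gch <- list()
  b2 <- ym_backward(mod$ch$pw2, cache$ch$pw2, du); gch$pw2 <- b2$g
  da <- gelu_bwd(cache$pre_act, b2$dx)
  b1 <- ym_backward(mod$ch$pw1, cache$ch$pw1, da); gch$pw1 <- b1$g
  b <- ym_backward(mod$ch$norm2, cache$ch$norm2, b1$dx); gch$norm2 <- b$g
  b <- ym_backward(mod$ch$se, cache$ch$se, b$dx); gch$se <- b$g
  b <- ym_backward(mod$ch$norm1, cache$ch$norm1, b$dx); gch$norm1 <- b$g
  if (mod$cfg$kind == "smak") {
    b <- ym_backward(mod$ch$dw_bn, cache$ch$dw_bn, b$dx); gch$dw_bn <- b$g
  }
  b <- ym_backward(mod$ch$dw, cache$ch$dw, b$dx); gch$dw <- b$g
  list(dx = dy + b$dx,
       g = list(params = list(gamma = dgamma), ch = gch))
}

#' Stride-2 downsampling block
#'
#' Dense 3 x 3 convolution with stride 2, batch norm and SiLU; spatial
#' dimensions are halved (ceiling division under pad 1).
#'
#' @param c_in,c_out channel counts.
#' @export
downsample_module <- function(c_in, c_out) cbs_module(c_in, c_out, 3L, 2L)

# a stage: ordered sequence of blocks (used for LarK stages)
seq_module <- function(blocks) {
  names(blocks) <- paste0("m", seq_along(blocks))
  new_module("seq", ch = blocks)
}

ym_forward.seq <- function(mod, x, training = FALSE) {
  caches <- list()
  for (nm in names(mod$ch)) {
    f <- ym_forward(mod$ch[[nm]], x, training)
    caches[[nm]] <- f$cache
    x <- f$y
  }
  list(y = x, cache = list(ch = caches))
}

ym_backward.seq <- function(mod, cache, dy) {
  gch <- list()
  for (nm in rev(names(mod$ch))) {
    b <- ym_backward(mod$ch[[nm]], cache$ch[[nm]], dy)
    gch[[nm]] <- b$g
    dy <- b$dx
  }
  list(dx = dy, g = list(params = list(), ch = gch))
}
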