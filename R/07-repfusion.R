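# Reparameterizable convolution (RepBlock) and the ELAN-style neck fusion
# block that aggregates the intermediate outputs of its gradient paths.

#' Training/inference-dual convolution block (RepBlock)
#'
#' Training mode: parallel 3x3 conv-BN, 1x1 conv-BN and (when the channel
#' counts match) an identity BN branch, summed then activated. After
#' [merge_repblock()] the block runs a single fused 3x3 convolution.
#'
#' @param c_in,c_out channel counts.
#' @export
repblock_module <- function(c_in, c_out) {
  ch <- list(conv3 = conv_module(c_in, c_out, 3L, bias = FALSE),
             bn3 = bn_module(c_out),
             conv1 = conv_module(c_in, c_out, 1L, bias = FALSE),
             bn1 = bn_module(c_out))
  if (c_in == c_out) ch$bnid <- bn_module(c_out)
  new_module("repblock", ch = ch,
             cfg = list(c_in = c_in, c_out = c_out, deploy = FALSE))
}

ym_forward.repblock <- function(mod, x, training = FALSE) {
  if (mod$cfg$deploy) {
    pre <- conv2d(x, mod$params$w_merged, mod$params$b_merged, pad = 1L)
    return(list(y = silu(pre), cache = list(pre = pre)))
  }
  cc <- list()
  f3 <- ym_forward(mod$ch$conv3, x, training); cc$conv3 <- f3$cache
  fb3 <- ym_forward(mod$ch$bn3, f3$y, training); cc$bn3 <- fb3$cache
  f1 <- ym_forward(mod$ch$conv1, x, training); cc$conv1 <- f1$cache
  fb1 <- ym_forward(mod$ch$bn1, f1$y, training); cc$bn1 <- fb1$cache
  pre <- fb3$y + fb1$y
  if (!is.null(mod$ch$bnid)) {
    fid <- ym_forward(mod$ch$bnid, x, training); cc$bnid <- fid$cache
    pre <- pre + fid$y
  }
  list(y = silu(pre), cache = list(ch = cc, pre = pre))
}

ym_backward.repblock <- function(mod, cache, dy) {
  if (mod$cfg$deploy) stop("backward not supported in deploy mode")
  dpre <- silu_bwd(cache$pre, dy)
  gch <- list()
  b3 <- ym_backward(mod$ch$bn3, cache$ch$bn3, dpre); gch$bn3 <- b3$g
  bc3 <- ym_backward(mod$ch$conv3, cache$ch$conv3, b3$dx); gch$conv3 <- bc3$g
  b1 <- ym_backward(mod$ch$bn1, cache$ch$bn1, dpre); gch$bn1 <- b1$g
  bc1 <- ym_backward(mod$ch$conv1, cache$ch$conv1, b1$dx); gch$conv1 <- bc1$g
  dx <- bc3$dx + bc1$dx
  if (!is.null(mod$ch$bnid)) {
    bid <- ym_backward(mod$ch$bnid, cache$ch$bnid, dpre); gch$bnid <- bid$g
    dx <- dx + bid$dx
  }
  list(dx = dx, g = list(params = list(), ch = gch))
}

#' Merge a RepBlock into a single 3x3 convolution
#'
#' BN-fuses every branch, zero-pads the 1x1 kernel to 3x3 center, expresses
#' the identity branch as a center-one kernel, and sums kernels and biases.
#' Merging is idempotent.
#'
#' @param mod a [repblock_module()].
#' @return list(w, b).
#' @export
merge_repblock <- function(mod) {
  if (mod$cfg$deploy)
    return(list(w = mod$params$w_merged, b = mod$params$b_merged))
  f3 <- fuse_conv_bn(conv_bn_spec(mod$ch$conv3, mod$ch$bn3))
  f1 <- fuse_conv_bn(conv_bn_spec(mod$ch$conv1, mod$ch$bn1))
  w <- f3$w + pad_kernel_to(f1$w, 3L)
  b <- f3$b + f1$b
  if (!is.null(mod$ch$bnid)) {
    cin <- mod$cfg$c_in
    dirac <- array(0, dim = c(3, 3, cin, cin))
    for (c in seq_len(cin)) dirac[2, 2, c, c] <- 1
    fid <- fuse_conv_bn(list(w = dirac, b = NULL,
                             bn = list(mean = mod$ch$bnid$buffers$rm,
                                       var = mod$ch$bnid$buffers$rv,
                                       gamma = mod$ch$bnid$params$gamma,
                                       beta = mod$ch$bnid$params$beta,
                                       eps = mod$ch$bnid$cfg$eps)))
    w <- w + fid$w
    b <- b + fid$b
  }
  list(w = w, b = b)
}

#' ELAN-style neck fusion block
#'
#' Two parallel 1x1 projections adjust channels; the second stream runs a
#' chain of RepBlocks whose intermediate outputs are all retained (the
#' block's gradient paths); the concatenation of the first stream and every
#' retained tap is fused by a final 1x1 convolution. Drop-in replacement for
#' a neck C2f (same channel/resolution contract).
#'
#' @param c_in,c_out channel counts.
#' @param n number of RepBlock stages in the chain.
#' @param e width of both streams as a fraction of c_out.
#' @export
fusion_module <- function(c_in, c_out, n = 2L, e = 0.75) {
  h <- as.integer(round(e * c_out))
  ch <- list(cva = cbs_module(c_in, h, 1L),
             cvb = cbs_module(c_in, h, 1L))
  for (i in seq_len(n)) ch[[paste0("rep", i)]] <- repblock_module(h, h)
  ch$cvo <- cbs_module((2L + n) * h, c_out, 1L)
  new_module("fusion", ch = ch,
             cfg = list(c_in = c_in, c_out = c_out, h = h, n = n))
}

ym_forward.fusion <- function(mod, x, training = FALSE) {
  n <- mod$cfg$n
  cc <- list()
  fa <- ym_forward(mod$ch$cva, x, training); cc$cva <- fa$cache
  fb <- ym_forward(mod$ch$cvb, x, training); cc$cvb <- fb$cache
  taps <- list(fa$y, fb$y)
  cur <- fb$y
  for (i in seq_len(n)) {
    fi <- ym_forward(mod$ch[[paste0("rep", i)]], cur, training)
    cc[[paste0("rep", i)]] <- fi$cache
    cur <- fi$y
    taps[[2 + i]] <- cur
  }
  fo <- ym_forward(mod$ch$cvo, cat_c(taps), training); cc$cvo <- fo$cache
  list(y = fo$y, cache = list(ch = cc, h = mod$cfg$h, n = n))
}

ym_backward.fusion <- function(mod, cache, dy) {
  n <- cache$n; h <- cache$h
  bo <- ym_backward(mod$ch$cvo, cache$ch$cvo, dy)
  gch <- list(cvo = bo$g)
  dparts <- split_c(bo$dx, rep(h, 2 + n))
  dcur <- dparts[[2 + n]]
  for (i in rev(seq_len(n))) {
    bi <- ym_backward(mod$ch[[paste0("rep", i)]], cache$ch[[paste0("rep", i)]],
                      dcur)
    gch[[paste0("rep", i)]] <- bi$g
    dcur <- bi$dx + dparts[[1 + i]]
  }
  bb <- ym_backward(mod$ch$cvb, cache$ch$cvb, dcur); gch$cvb <- bb$g
  ba <- ym_backward(mod$ch$cva, cache$ch$cva, dparts[[1]]); gch$cva <- ba$g
  list(dx = ba$dx + bb$dx, g = list(params = list(), ch = gch))
}

# ---- deploy conversion -------------------------------------------------------

ym_deploy <- function(mod) UseMethod("ym_deploy")

ym_deploy.ym_module <- function(mod) {
  mod$ch <- lapply(mod$ch, ym_deploy)
  mod
}

ym_deploy.dreparam <- function(mod) {
  if (mod$cfg$deploy) return(mod)
  m <- merge_dilated_reparam(mod)
  mod$params <- list(w_merged = m$w, b_merged = m$b)
  mod$ch <- list()
  mod$cfg$deploy <- TRUE
  mod
}

ym_deploy.repblock <- function(mod) {
  if (mod$cfg$deploy) return(mod)
  m <- merge_repblock(mod)
  mod$params <- list(w_merged = m$w, b_merged = m$b)
  mod$ch <- list()
  mod$cfg$deploy <- TRUE
  mod
}
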