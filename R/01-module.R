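# Module framework: every network component is a list with class
# c(<type>, "ym_module") carrying
#   $params   named list of numeric arrays (attr "trainable" FALSE marks frozen)
#   $buffers  named list of running statistics (batch-norm)
#   $ch       named list of child modules
# Forward passes return list(y, cache); backward passes consume the cache and
# return list(dx, g) where g mirrors the module: g$params, g$ch[[name]].
# Training-mode caches may carry cache$.state (updated buffers), applied after
# the step with ym_apply_state().

new_module <- function(type, params = list(), buffers = list(), ch = list(),
                       ...) {
  structure(c(list(params = params, buffers = buffers, ch = ch), list(...)),
            class = c(type, "ym_module"))
}

#' Run a module forward
#'
#' Applies a network module (block, head, or full detector) to a feature map.
#'
#' @param mod a module created by one of the block constructors.
#' @param x input feature map, a (H, W, C, N) array.
#' @param training logical; use batch statistics in normalization layers.
#' @return the output feature map (list of per-scale maps for a detector).
#' @export
module_forward <- function(mod, x, training = FALSE) {
  ym_forward(mod, x, training = training)$y
}

ym_forward <- function(mod, x, training = FALSE) UseMethod("ym_forward")
ym_backward <- function(mod, cache, dy) UseMethod("ym_backward")

# zero gradient tree for a module
ym_zero_grad <- function(mod) {
  list(params = lapply(mod$params, function(p) array(0, dim = dim(p) %||% length(p))),
       ch = lapply(mod$ch, ym_zero_grad))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# elementwise sum of two gradient trees (b may be NULL)
g_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  list(params = mapply(function(x, y) x + y, a$params, b$params,
                       SIMPLIFY = FALSE),
       ch = mapply(g_add, a$ch, b$ch, SIMPLIFY = FALSE))
}

#' Count learnable parameters of a module
#'
#' Sums the element counts of every parameter array in the module tree,
#' including frozen arrays such as the distribution-focal projection (the
#' counting convention used by the reference detector family).
#'
#' @param mod a module.
#' @return integer scalar.
#' @export
count_parameters <- function(mod) {
  n <- sum(vapply(mod$params, length, 0))
  n + sum(vapply(mod$ch, count_parameters, 0))
}

# walk module and cache trees, applying cached buffer updates (BN running stats)
ym_apply_state <- function(mod, cache) {
  if (!is.null(cache$.state))
    mod$buffers[names(cache$.state)] <- cache$.state
  if (!is.null(cache$ch)) {
    for (nm in names(cache$ch)) {
      if (!is.null(mod$ch[[nm]]) && is.list(cache$ch[[nm]]))
        mod$ch[[nm]] <- ym_apply_state(mod$ch[[nm]], cache$ch[[nm]])
    }
  }
  mod
}

# flatten parameters to a named list path -> array; used by the optimizer
ym_flatten <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) {
    p <- mod$params[[nm]]
    if (!isFALSE(attr(p, "trainable")))
      out[[paste0(prefix, "params/", nm)]] <- p
  }
  for (nm in names(mod$ch))
    out <- c(out, ym_flatten(mod$ch[[nm]], paste0(prefix, "ch/", nm, "/")))
  out
}

ym_flatten_grads <- function(mod, g, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) {
    p <- mod$params[[nm]]
    if (!isFALSE(attr(p, "trainable")))
      out[[paste0(prefix, "params/", nm)]] <- g$params[[nm]]
  }
  for (nm in names(mod$ch))
    out <- c(out, ym_flatten_grads(mod$ch[[nm]], g$ch[[nm]],
                                   paste0(prefix, "ch/", nm, "/")))
  out
}

ym_set_param <- function(mod, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  rec <- function(m, parts) {
    if (parts[1] == "params") {
      old <- m$params[[parts[2]]]
      attributes(value) <- attributes(old)
      m$params[[parts[2]]] <- value
      return(m)
    }
    m$ch[[parts[2]]] <- rec(m$ch[[parts[2]]], parts[-(1:2)])
    m
  }
  rec(mod, parts)
}

# ---- plain convolution leaf --------------------------------------------------

conv_module <- function(c_in, c_out, k, stride = 1L, pad = NULL, dilation = 1L,
                        groups = 1L, bias = TRUE) {
  if (is.null(pad)) pad <- (dilation * (k - 1L)) %/% 2L  # "same" for stride 1
  w <- he_init(c(k, k, c_in %/% groups, c_out), fan_in = k * k * c_in / groups)
  params <- list(w = w)
  if (bias) params$b <- numeric(c_out)
  new_module("conv", params = params,
             cfg = list(stride = stride, pad = pad, dilation = dilation,
                        groups = groups, bias = bias,
                        c_in = c_in, c_out = c_out, k = k))
}

ym_forward.conv <- function(mod, x, training = FALSE) {
  cfg <- mod$cfg
  y <- conv2d(x, mod$params$w, mod$params$b, cfg$stride, cfg$pad,
              cfg$dilation, cfg$groups)
  list(y = y, cache = list(x = x))
}

ym_backward.conv <- function(mod, cache, dy) {
  cfg <- mod$cfg
  r <- conv2d_bwd(cache$x, mod$params$w, dy, cfg$bias, cfg$stride, cfg$pad,
                  cfg$dilation, cfg$groups)
  g <- list(params = list(w = r$dw), ch = list())
  if (cfg$bias) g$params$b <- r$db
  list(dx = r$dx, g = g)
}

# ---- batch normalization leaf ------------------------------------------------

bn_module <- function(c_out, eps = 1e-5, momentum = 0.03) {
  new_module("bn",
             params = list(gamma = rep(1, c_out), beta = rep(0, c_out)),
             buffers = list(rm = rep(0, c_out), rv = rep(1, c_out)),
             cfg = list(c = c_out, eps = eps, momentum = momentum))
}

# per-channel moments over (H, W, N)
bn_moments <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu * mu
  list(mu = mu, va = pmax(va, 0))
}

bcast_c <- function(v, d) {
  # broadcast a per-channel vector to (H, W, C, N)
  aperm(array(v, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

ym_forward.bn <- function(mod, x, training = FALSE) {
  d <- dim(x)
  eps <- mod$cfg$eps
  if (training) {
    mo <- bn_moments(x)
    mu <- mo$mu; va <- mo$va
    mm <- mod$cfg$momentum
    st <- list(rm = (1 - mm) * mod$buffers$rm + mm * mu,
               rv = (1 - mm) * mod$buffers$rv + mm * va)
  } else {
    mu <- mod$buffers$rm; va <- mod$buffers$rv
    st <- NULL
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (x - bcast_c(mu, d)) * bcast_c(istd, d)
  y <- xhat * bcast_c(mod$params$gamma, d) + bcast_c(mod$params$beta, d)
  list(y = y, cache = list(xhat = xhat, istd = istd, training = training,
                           d = d, .state = st))
}

ym_backward.bn <- function(mod, cache, dy) {
  d <- cache$d
  xhat <- cache$xhat
  m <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  mh <- matrix(aperm(xhat, c(1, 2, 4, 3)), ncol = d[3])
  dgamma <- colSums(m * mh)
  dbeta <- colSums(m)
  gi <- bcast_c(mod$params$gamma * cache$istd, d)
  if (cache$training) {
    M <- d[1] * d[2] * d[4]
    dx <- gi * (dy - bcast_c(dbeta / M, d) - xhat * bcast_c(dgamma / M, d))
  } else {
    dx <- gi * dy
  }
  list(dx = dx,
       g = list(params = list(gamma = dgamma, beta = dbeta), ch = list()))
}

# ---- conv + BN + SiLU (the CBS unit used throughout the detector) ------------

cbs_module <- function(c_in, c_out, k, stride = 1L, pad = NULL, dilation = 1L,
                       groups = 1L, act = TRUE) {
  new_module("cbs",
             ch = list(conv = conv_module(c_in, c_out, k, stride, pad,
                                          dilation, groups, bias = FALSE),
                       bn = bn_module(c_out)),
             cfg = list(act = act, c_in = c_in, c_out = c_out, k = k,
                        stride = stride))
}

ym_forward.cbs <- function(mod, x, training = FALSE) {
  f1 <- ym_forward(mod$ch$conv, x, training)
  f2 <- ym_forward(mod$ch$bn, f1$y, training)
  y <- if (mod$cfg$act) silu(f2$y) else f2$y
  list(y = y, cache = list(ch = list(conv = f1$cache, bn = f2$cache),
                           pre = if (mod$cfg$act) f2$y))
}

ym_backward.cbs <- function(mod, cache, dy) {
  if (mod$cfg$act) dy <- silu_bwd(cache$pre, dy)
  b2 <- ym_backward(mod$ch$bn, cache$ch$bn, dy)
  b1 <- ym_backward(mod$ch$conv, cache$ch$conv, b2$dx)
  list(dx = b1$dx,
       g = list(params = list(), ch = list(conv = b1$g, bn = b2$g)))
}

# ---- linear / layer-norm leaves (token operations) ---------------------------

linear_module <- function(d_in, d_out, bias = TRUE) {
  params <- list(w = he_init(c(d_in, d_out), fan_in = d_in))
  if (bias) params$b <- numeric(d_out)
  new_module("linear", params = params,
             cfg = list(d_in = d_in, d_out = d_out, bias = bias))
}

# x: (T x d_in) matrix
linear_fwd <- function(mod, x) {
  y <- x %*% mod$params$w
  if (mod$cfg$bias) y <- sweep(y, 2, mod$params$b, "+")
  list(y = y, cache = list(x = x))
}

linear_bwd <- function(mod, cache, dy) {
  g <- list(params = list(w = crossprod(cache$x, dy)), ch = list())
  if (mod$cfg$bias) g$params$b <- colSums(dy)
  list(dx = dy %*% t(mod$params$w), g = g)
}

ln_module <- function(d, eps = 1e-5) {
  new_module("ln", params = list(gamma = rep(1, d), beta = rep(0, d)),
             cfg = list(d = d, eps = eps))
}

# layer norm across columns of a (T x d) matrix
ln_fwd <- function(mod, x) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + mod$cfg$eps)
  xhat <- xc * istd
  y <- sweep(xhat * 1, 2, mod$params$gamma, "*")
  y <- sweep(y, 2, mod$params$beta, "+")
  list(y = y, cache = list(xhat = xhat, istd = istd))
}

ln_bwd <- function(mod, cache, dy) {
  xhat <- cache$xhat
  d <- ncol(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, mod$params$gamma, "*")
  dx <- cache$istd *
    (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx,
       g = list(params = list(gamma = dgamma, beta = dbeta), ch = list()))
}

# ---- per-channel instance norm (used by the multi-scale attention gate) ------

inorm_module <- function(c_out, eps = 1e-5) {
  new_module("inorm", params = list(gamma = rep(1, c_out), beta = rep(0, c_out)),
             cfg = list(c = c_out, eps = eps))
}

ym_forward.inorm <- function(mod, x, training = FALSE) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + mod$cfg$eps)
  xhat <- sweep(xc, 2, istd, "*")
  gam <- rep(mod$params$gamma, d[4])
  bet <- rep(mod$params$beta, d[4])
  y <- array(sweep(sweep(xhat, 2, gam, "*"), 2, bet, "+"), dim = d)
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d))
}

ym_backward.inorm <- function(mod, cache, dy) {
  d <- cache$d
  xhat <- cache$xhat
  m <- matrix(dy, d[1] * d[2], d[3] * d[4])
  dg_full <- colSums(m * xhat)
  db_full <- colSums(m)
  dgamma <- rowSums(matrix(dg_full, d[3], d[4]))
  dbeta <- rowSums(matrix(db_full, d[3], d[4]))
  gam <- rep(mod$params$gamma, d[4])
  dxh <- sweep(m, 2, gam, "*")
  dx <- sweep(dxh - matrix(colMeans(dxh), nrow(dxh), ncol(dxh), byrow = TRUE) -
                sweep(xhat, 2, colMeans(dxh * xhat), "*"),
              2, cache$istd, "*")
  list(dx = array(dx, dim = d),
       g = list(params = list(gamma = dgamma, beta = dbeta), ch = list()))
}
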