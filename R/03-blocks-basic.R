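# Baseline backbone/neck building blocks: Bottleneck, C2f, SPPF.

bottleneck_module <- function(c_in, c_out, shortcut = TRUE) {
  new_module("bottleneck",
             ch = list(cv1 = cbs_module(c_in, c_out, 3L),
                       cv2 = cbs_module(c_out, c_out, 3L)),
             cfg = list(add = shortcut && c_in == c_out))
}

ym_forward.bottleneck <- function(mod, x, training = FALSE) {
  f1 <- ym_forward(mod$ch$cv1, x, training)
  f2 <- ym_forward(mod$ch$cv2, f1$y, training)
  y <- if (mod$cfg$add) x + f2$y else f2$y
  list(y = y, cache = list(ch = list(cv1 = f1$cache, cv2 = f2$cache)))
}

ym_backward.bottleneck <- function(mod, cache, dy) {
  b2 <- ym_backward(mod$ch$cv2, cache$ch$cv2, dy)
  b1 <- ym_backward(mod$ch$cv1, cache$ch$cv1, b2$dx)
  dx <- if (mod$cfg$add) b1$dx + dy else b1$dx
  list(dx = dx, g = list(params = list(),
                         ch = list(cv1 = b1$g, cv2 = b2$g)))
}

#' Cross-stage-partial block with two-way split (C2f)
#'
#' Splits the 1x1-projected input into two halves, runs n bottlenecks on the
#' second half while retaining every intermediate, and fuses all parts with a
#' final 1x1 convolution.
#'
#' @param c_in,c_out channel counts.
#' @param n number of bottlenecks.
#' @param shortcut residual connections inside bottlenecks.
#' @return a module.
#' @export
c2f_module <- function(c_in, c_out, n = 1L, shortcut = FALSE) {
  hc <- c_out %/% 2L
  ch <- list(cv1 = cbs_module(c_in, 2L * hc, 1L))
  for (i in seq_len(n))
    ch[[paste0("m", i)]] <- bottleneck_module(hc, hc, shortcut)
  ch$cv2 <- cbs_module((2L + n) * hc, c_out, 1L)
  new_module("c2f", ch = ch,
             cfg = list(n = n, hc = hc, c_in = c_in, c_out = c_out))
}

ym_forward.c2f <- function(mod, x, training = FALSE) {
  n <- mod$cfg$n; hc <- mod$cfg$hc
  f1 <- ym_forward(mod$ch$cv1, x, training)
  parts <- split_c(f1$y, c(hc, hc))
  caches <- list(cv1 = f1$cache)
  ys <- parts
  cur <- parts[[2]]
  for (i in seq_len(n)) {
    fi <- ym_forward(mod$ch[[paste0("m", i)]], cur, training)
    caches[[paste0("m", i)]] <- fi$cache
    cur <- fi$y
    ys[[2 + i]] <- cur
  }
  f2 <- ym_forward(mod$ch$cv2, cat_c(ys), training)
  caches$cv2 <- f2$cache
  list(y = f2$y, cache = list(ch = caches, hc = hc, n = n))
}

ym_backward.c2f <- function(mod, cache, dy) {
  n <- cache$n; hc <- cache$hc
  b2 <- ym_backward(mod$ch$cv2, cache$ch$cv2, dy)
  dparts <- split_c(b2$dx, rep(hc, 2 + n))
  gch <- list(cv2 = b2$g)
  dcur <- dparts[[2 + n]]
  for (i in rev(seq_len(n))) {
    bi <- ym_backward(mod$ch[[paste0("m", i)]], cache$ch[[paste0("m", i)]],
                      dcur)
    gch[[paste0("m", i)]] <- bi$g
    dcur <- bi$dx + dparts[[1 + i]]
  }
  d1 <- cat_c(list(dparts[[1]], dcur))
  b1 <- ym_backward(mod$ch$cv1, cache$ch$cv1, d1)
  gch$cv1 <- b1$g
  list(dx = b1$dx, g = list(params = list(), ch = gch))
}

#' Fast spatial pyramid pooling (SPPF)
#'
#' @param c_in,c_out channel counts; k pooling kernel (stride 1).
#' @export
sppf_module <- function(c_in, c_out, k = 5L) {
  hc <- c_in %/% 2L
  new_module("sppf",
             ch = list(cv1 = cbs_module(c_in, hc, 1L),
                       cv2 = cbs_module(hc * 4L, c_out, 1L)),
             cfg = list(k = k, hc = hc, c_in = c_in, c_out = c_out))
}

ym_forward.sppf <- function(mod, x, training = FALSE) {
  k <- mod$cfg$k; p <- k %/% 2L
  f1 <- ym_forward(mod$ch$cv1, x, training)
  p1 <- maxpool2d(f1$y, k, 1L, p)
  p2 <- maxpool2d(p1$y, k, 1L, p)
  p3 <- maxpool2d(p2$y, k, 1L, p)
  f2 <- ym_forward(mod$ch$cv2, cat_c(list(f1$y, p1$y, p2$y, p3$y)), training)
  list(y = f2$y,
       cache = list(ch = list(cv1 = f1$cache, cv2 = f2$cache),
                    idx = list(p1$idx, p2$idx, p3$idx), d = dim(f1$y)))
}

ym_backward.sppf <- function(mod, cache, dy) {
  d <- cache$d
  b2 <- ym_backward(mod$ch$cv2, cache$ch$cv2, dy)
  dparts <- split_c(b2$dx, rep(d[3], 4))
  d3 <- maxpool2d_bwd_cpp(cache$idx[[3]], dparts[[4]], as.integer(d))
  d2 <- maxpool2d_bwd_cpp(cache$idx[[2]], dparts[[3]] + d3, as.integer(d))
  d1 <- maxpool2d_bwd_cpp(cache$idx[[1]], dparts[[2]] + d2, as.integer(d))
  b1 <- ym_backward(mod$ch$cv1, cache$ch$cv1, dparts[[1]] + d1)
  list(dx = b1$dx,
       g = list(params = list(), ch = list(cv1 = b1$g, cv2 = b2$g)))
}
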