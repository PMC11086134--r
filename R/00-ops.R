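#' @useDynLib yolomu, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- feature-map tensors -----------------------------------------------------
# Feature maps are dense double arrays with dim (H, W, C, N): spatial rows,
# spatial columns, channels, batch. All blocks operate on this layout.

#' Construct a feature map array
#'
#' @param data numeric vector (recycled) or array.
#' @param h,w,c,n dimensions (height, width, channels, batch).
#' @return a (h, w, c, n) double array.
#' @export
feature_map <- function(data = 0, h, w, c, n = 1L) {
  array(as.double(data), dim = c(h, w, c, n))
}

as_fmap <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array feature map")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must have 3 or 4 dimensions")
  storage.mode(x) <- "double"
  x
}

fm_h <- function(x) dim(x)[1]
fm_w <- function(x) dim(x)[2]
fm_c <- function(x) dim(x)[3]
fm_n <- function(x) dim(x)[4]

# concatenate along channel axis
cat_c <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 0)
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x)[3]
    out[, , (off + 1L):(off + ci), ] <- x
    off <- off + ci
  }
  out
}

# split channels into chunks of sizes cs
split_c <- function(x, cs) {
  out <- vector("list", length(cs))
  off <- 0L
  for (i in seq_along(cs)) {
    out[[i]] <- x[, , (off + 1L):(off + cs[i]), , drop = FALSE]
    off <- off + cs[i]
  }
  out
}

# backward of cat_c: split gradient back into chunks
uncat_c <- split_c

# ---- primitive ops with explicit backward ------------------------------------

conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L, dilation = 1L,
                   groups = 1L) {
  conv2d_fwd_cpp(as_fmap(x), w, bias, as.integer(stride), as.integer(pad),
                 as.integer(dilation), as.integer(groups))
}

conv2d_bwd <- function(x, w, dy, has_bias, stride = 1L, pad = 0L,
                       dilation = 1L, groups = 1L) {
  conv2d_bwd_cpp(x, w, dy, has_bias, as.integer(stride), as.integer(pad),
                 as.integer(dilation), as.integer(groups))
}

maxpool2d <- function(x, k, stride = k, pad = 0L) {
  maxpool2d_fwd_cpp(as_fmap(x), as.integer(k), as.integer(stride),
                    as.integer(pad))
}

upsample2x <- function(x) {
  d <- dim(x)
  ih <- rep(seq_len(d[1]), each = 2L)
  iw <- rep(seq_len(d[2]), each = 2L)
  x[ih, iw, , , drop = FALSE]
}

upsample2x_bwd <- function(dy) {
  d <- dim(dy)
  h <- d[1] %/% 2L
  w <- d[2] %/% 2L
  dy[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dy[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dy[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    dy[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
}

# ---- activations -------------------------------------------------------------

silu <- function(x) x * plogis(x)
silu_bwd <- function(x, dy) {
  s <- plogis(x)
  dy * (s * (1 + x * (1 - s)))
}

gelu <- function(x) x * pnorm(x)
gelu_bwd <- function(x, dy) dy * (pnorm(x) + x * dnorm(x))

sigmoid <- function(x) plogis(x)
sigmoid_bwd <- function(y, dy) dy * y * (1 - y)

# numerically stable softmax over first dimension of a matrix
softmax_cols <- function(m) {
  m <- sweep(m, 2, apply(m, 2, max), "-")
  e <- exp(m)
  sweep(e, 2, colSums(e), "/")
}
softmax_cols_bwd <- function(p, dp) {
  s <- colSums(p * dp)
  p * sweep(dp, 2, s, "-")
}

# ---- parameter initialisation ------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}
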