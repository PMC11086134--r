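# Window attention mechanics: partition/reverse, cyclic shift, shift masks,
# masked attention, transformer blocks and the C2fSTR skeleton.

test_that("window partition and reverse are exact inverses", {
  set.seed(41)
  x <- array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  w <- window_partition(x, 4L)
  expect_equal(dim(w)[4], 4L * 2L)
  expect_identical(window_reverse(w, 8L, 8L), x)
  for (M in c(2L, 3L, 6L)) {
    xx <- array(rnorm(6 * 12 * 2), dim = c(6, 12, 2, 1))
    expect_identical(window_reverse(window_partition(xx, M), 6L, 12L), xx)
  }
  expect_error(window_partition(x, 3L), "divisible")
})

test_that("naive shifted partitioning of a 2x2-window map makes 3x3 windows", {
  # without the cyclic trick, offsetting the window grid by M/2 over an
  # (2M x 2M) map creates a 3 x 3 grid of (partial) windows
  M <- 4L; H <- 2L * M
  edges <- unique(pmin(pmax(c(0, seq(M %/% 2, H, by = M), H), 0), H))
  n_windows_per_axis <- length(edges) - 1L
  expect_equal(n_windows_per_axis^2, 9L)
})

test_that("cyclic shift is invertible, count-preserving and constant-safe", {
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2, 1))
  s <- 3L
  expect_identical(cyclic_shift(cyclic_shift(x, s), -s), x)
  cst <- array(5, dim = c(6, 6, 1, 1))
  expect_identical(cyclic_shift(cst, 2L), cst)
  for (M in c(2L, 4L)) for (HW in c(8L, 12L)) {
    xx <- array(rnorm(HW * HW), dim = c(HW, HW, 1, 1))
    n0 <- dim(window_partition(xx, M))[4]
    n1 <- dim(window_partition(cyclic_shift(xx, M %/% 2L), M))[4]
    expect_equal(n1, n0)
  }
})

test_that("shift mask blocks exactly the cross-region token pairs", {
  # brute-force oracle: tokens of the shifted map are continuous iff their
  # source coordinates differ by their in-window offset along both axes
  H <- 4L; W <- 4L; M <- 2L; s <- 1L
  mask <- build_shift_mask(H, W, M, s)
  expect_equal(dim(mask), c(4L, 4L, 4L))
  src <- function(i, n) ((i - 1L + s) %% n)  # 0-based source coordinate
  blocked_oracle <- 0L; blocked_mask <- sum(mask < 0)
  wi <- 0L
  for (wj in 1:(W %/% M)) for (wii in 1:(H %/% M)) {
    wi <- wi + 1L
    coords <- expand.grid(h = (wii - 1L) * M + 1:M, w = (wj - 1L) * M + 1:M)
    ord <- order(coords$w, coords$h)  # partition flattens h fastest
    coords <- coords[ord, ]
    for (p in 1:(M * M)) for (q in 1:(M * M)) {
      okh <- src(coords$h[p], H) - src(coords$h[q], H) ==
        coords$h[p] - coords$h[q]
      okw <- src(coords$w[p], W) - src(coords$w[q], W) ==
        coords$w[p] - coords$w[q]
      if (!(okh && okw)) blocked_oracle <- blocked_oracle + 1L
      expect_equal(mask[p, q, wi] < 0, !(okh && okw))
    }
  }
  expect_equal(blocked_mask, blocked_oracle)
  # symmetric in token pairs; zero when shift = 0
  expect_equal(mask, aperm(mask, c(2, 1, 3)))
  expect_true(all(build_shift_mask(8L, 8L, 4L, 0L) == 0))
  # bottom-right window mixes the most regions (4 on a 2-region-per-axis map)
  lab <- outer(ifelse(seq_len(H) - 1 < H - M, 0, ifelse(seq_len(H) - 1 < H - s, 1, 2)),
               ifelse(seq_len(W) - 1 < W - M, 0, ifelse(seq_len(W) - 1 < W - s, 1, 2)),
               function(a, b) a * 3 + b)
  counts <- c(length(unique(as.vector(lab[1:2, 1:2]))),
              length(unique(as.vector(lab[3:4, 3:4]))))
  expect_equal(counts, c(1L, 4L))
})

test_that("window attention rows normalize and blocked masks isolate tokens", {
  set.seed(43)
  blk <- swin_block_module(8L, heads = 2L, M = 2L)
  x <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8, 1))
  wins <- window_partition(x, 2L)
  # attention rows sum to one: probe via the internal attention cache
  tok <- matrix(wins[, , , 1], 4, 8)
  qkv <- ns$linear_fwd(blk$ch$qkv, tok)
  aw <- ns$.attn_win(qkv$y, 2L, array(0, dim = c(4, 4, 2)), NULL)
  for (h in 1:2) expect_equal(rowSums(aw$hc[[h]]$A), rep(1, 4),
                              tolerance = 1e-6)
  # fully blocked off-diagonal: each token attends only to itself
  mask_diag <- array(-1e9, dim = c(4, 4, dim(wins)[4]))
  for (k in seq_len(dim(wins)[4])) diag(mask_diag[, , k]) <- 0
  att <- window_msa(wins, blk, mask_diag)
  # compare to the per-token value projection path
  D <- 8L
  for (k in 1:1) {
    tokk <- matrix(wins[, , , k], 4, D)
    q <- ns$linear_fwd(blk$ch$qkv, tokk)$y
    v <- q[, 2 * D + seq_len(D)]
    ref <- ns$linear_fwd(blk$ch$proj, v)$y
    expect_equal(matrix(att[, , , k], 4, D), ref, tolerance = 1e-8)
  }
  # single-token windows are the value projection of the input
  w1 <- window_partition(x, 1L)
  a1 <- window_msa(w1, swin_block_module(8L, heads = 2L, M = 1L))
  expect_equal(dim(a1), dim(w1))
})

test_that("masked shifted attention never mixes pre-shift regions", {
  set.seed(44)
  # one-hot probe: energy placed in one source region must not leak into
  # another region's tokens through attention
  blk <- swin_block_module(4L, heads = 1L, M = 4L, shifted = TRUE)
  H <- 8L; s <- 2L
  # region label in shifted coordinates (the coordinates the mask lives in)
  reg <- function(i) ifelse(i - 1 < H - 4L, 0L, ifelse(i - 1 < H - s, 1L, 2L))
  to_shifted <- function(o) ((o - 1L - s) %% H) + 1L
  x <- array(0, dim = c(H, H, 4, 1))
  x[3, 3, , 1] <- 10  # source token; shifted position (1, 1), region (0, 0)
  f <- ns$ym_forward(blk, x, training = FALSE)
  x0 <- array(0, dim = c(H, H, 4, 1))
  f0 <- ns$ym_forward(blk, x0, training = FALSE)
  moved <- which(apply(abs(f$y - f0$y), c(1, 2), max) > 1e-9, arr.ind = TRUE)
  expect_gt(nrow(moved), 0)
  expect_true(all(reg(to_shifted(moved[, 1])) == 0 &
                    reg(to_shifted(moved[, 2])) == 0))
})

test_that("swin block pairs preserve shape, reduce to identity at zero scale", {
  set.seed(45)
  pair <- swin_pair_module(8L, heads = 2L, M = 4L)
  x <- array(rnorm(8 * 8 * 8 * 2), dim = c(8, 8, 8, 2))
  y <- swin_block_pair(x, pair)
  expect_equal(dim(y), dim(x))
  # zero output projections in attention and MLP: the pair acts as identity
  p0 <- pair
  for (i in 1:2) {
    p0$ch[[i]]$ch$proj$params$w[] <- 0; p0$ch[[i]]$ch$proj$params$b[] <- 0
    p0$ch[[i]]$ch$fc2$params$w[] <- 0; p0$ch[[i]]$ch$fc2$params$b[] <- 0
  }
  expect_equal(swin_block_pair(x, p0), x, tolerance = 1e-12)
  # with shift disabled both blocks compute identically given equal weights
  b1 <- swin_block_module(8L, heads = 2L, M = 4L, shifted = FALSE)
  b2 <- b1; b2$cfg$shifted <- FALSE
  expect_equal(module_forward(b1, x), module_forward(b2, x))
  expect_lt(gradcheck_module(swin_block_module(8L, heads = 2L, M = 4L,
                                               shifted = TRUE),
                             c(8, 8, 8, 1)), 1e-6)
  # pad-then-crop path on non-divisible maps keeps shape
  xx <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8, 1))
  expect_equal(dim(module_forward(swin_block_module(8L, M = 4L), xx)),
               dim(xx))
})

test_that("C2fSTR matches the C2f contract and is trainable end to end", {
  set.seed(46)
  cs <- c2fstr_module(8L, 8L, n = 2L, M = 4L)
  cf <- c2f_module(8L, 8L, n = 2L)
  x <- array(rnorm(8 * 8 * 8 * 2), dim = c(8, 8, 8, 2))
  expect_equal(dim(module_forward(cs, x)), dim(module_forward(cf, x)))
  # zero-scale Swin residuals: C2fSTR equals the C2f skeleton with identity
  # bottlenecks (shared 1x1 convolutions)
  cs0 <- cs
  for (i in 1:2) {
    cs0$ch[[paste0("m", i)]]$ch$proj$params$w[] <- 0
    cs0$ch[[paste0("m", i)]]$ch$proj$params$b[] <- 0
    cs0$ch[[paste0("m", i)]]$ch$fc2$params$w[] <- 0
    cs0$ch[[paste0("m", i)]]$ch$fc2$params$b[] <- 0
  }
  # manual skeleton with identity bottlenecks: parts are (a, b, b, b)
  p1 <- module_forward(cs0$ch$cv1, x)
  a <- p1[, , 1:4, , drop = FALSE]
  b <- p1[, , 5:8, , drop = FALSE]
  manual <- module_forward(cs0$ch$cv2, ns$cat_c(list(a, b, b, b)))
  expect_equal(module_forward(cs0, x), manual, tolerance = 1e-12)
  # gradient flows into both split halves
  f <- ns$ym_forward(cs, x, training = TRUE)
  wr <- array(rnorm(length(f$y)), dim = dim(f$y))
  b <- ns$ym_backward(cs, f$cache, wr)
  expect_gt(sum(b$dx^2), 0)
  g1 <- b$g$ch$cv1$ch$conv$params$w
  expect_gt(sum(g1^2), 0)
})
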