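# Dilated-reparameterization algebra and the LarK/SmaK block family.

test_that("equivalent kernel size follows (k-1)r+1 and rejects even kernels", {
  expect_equal(equivalent_kernel_size(7, 2), 13)
  expect_equal(equivalent_kernel_size(3, 1), 3)
  expect_equal(equivalent_kernel_size(c(5, 7, 3, 3, 3), c(1, 2, 3, 4, 5)),
               c(5, 13, 7, 9, 11))
  expect_error(equivalent_kernel_size(4, 2), "odd")
  expect_error(equivalent_kernel_size(3, 0), "dilation")
  # monotone in both arguments
  for (k in c(3, 5, 7)) for (r in 1:4) {
    expect_gt(equivalent_kernel_size(k + 2, r), equivalent_kernel_size(k, r))
    expect_gt(equivalent_kernel_size(k, r + 1), equivalent_kernel_size(k, r))
  }
})

test_that("dilate_to_dense is exact: dense conv equals dilated conv", {
  set.seed(31)
  w <- array(rnorm(3 * 3 * 2 * 2), dim = c(3, 3, 2, 2))
  expect_identical(dilate_to_dense(w, 1), w)
  wd <- dilate_to_dense(w, 2)
  expect_equal(dim(wd)[1:2], c(5L, 5L))
  expect_equal(wd[c(1, 3, 5), c(1, 3, 5), , ], w, ignore_attr = TRUE)
  expect_equal(sum(wd != 0), sum(w != 0))
  x <- array(rnorm(10 * 10 * 2 * 2), dim = c(10, 10, 2, 2))
  y_dil <- naive_conv2d(x, w, NULL, 1, 2, 2, 1)
  y_dense <- naive_conv2d(x, wd, NULL, 1, 2, 1, 1)
  expect_equal(y_dil, y_dense, tolerance = 1e-12)
  w1 <- array(rnorm(1 * 1 * 2 * 2), dim = c(1, 1, 2, 2))
  expect_equal(dim(dilate_to_dense(w1, 4))[1:2], c(1L, 1L))
  # linear in the weights
  w2 <- array(rnorm(length(w)), dim = dim(w))
  expect_equal(dilate_to_dense(w + 2 * w2, 3),
               dilate_to_dense(w, 3) + 2 * dilate_to_dense(w2, 3))
})

test_that("fuse_conv_bn reproduces sequential conv-then-BN", {
  set.seed(32)
  layer <- list(w = array(rnorm(3 * 3 * 4 * 4), dim = c(3, 3, 4, 4)),
                b = rnorm(4),
                bn = list(mean = rnorm(4), var = runif(4, 0.5, 2),
                          gamma = runif(4, 0.5, 1.5), beta = rnorm(4),
                          eps = 1e-5))
  f <- fuse_conv_bn(layer)
  x <- array(rnorm(8 * 8 * 4 * 2), dim = c(8, 8, 4, 2))
  seqv <- naive_conv2d(x, layer$w, layer$b, 1, 1, 1, 1)
  for (c in 1:4)
    seqv[, , c, ] <- (seqv[, , c, ] - layer$bn$mean[c]) /
      sqrt(layer$bn$var[c] + 1e-5) * layer$bn$gamma[c] + layer$bn$beta[c]
  fused <- naive_conv2d(x, f$w, f$b, 1, 1, 1, 1)
  expect_lt(max(abs(fused - seqv)), 1e-5)
  # identity normalization leaves weights unchanged
  id <- fuse_conv_bn(list(w = layer$w, b = NULL,
                          bn = list(mean = rep(0, 4), var = rep(1 - 1e-5, 4),
                                    gamma = rep(1, 4), beta = rep(0, 4),
                                    eps = 1e-5)))
  expect_equal(id$w, layer$w)
  expect_equal(id$b, rep(0, 4))
  # gamma = 0 zeroes the weights, bias = beta
  z <- fuse_conv_bn(list(w = layer$w, b = NULL,
                         bn = list(mean = rnorm(4), var = runif(4, 0.5, 1),
                                   gamma = rep(0, 4), beta = 1:4, eps = 1e-5)))
  expect_true(all(z$w == 0))
  expect_equal(z$b, as.numeric(1:4))
  expect_error(fuse_conv_bn(list(w = layer$w,
                                 bn = list(mean = 0, var = -1, gamma = 1,
                                           beta = 0, eps = 1e-6))),
               "variance")
})

test_that("dilated reparam merges exactly into one dense kernel", {
  set.seed(33)
  for (rep in 1:20) {
    ch <- sample(c(2L, 4L, 8L), 1)
    dr <- randomize_bn(dilated_reparam_module(ch))
    x <- array(rnorm(16 * 16 * ch * 2), dim = c(16, 16, ch, 2))
    y1 <- module_forward(dr, x)
    m <- merge_dilated_reparam(dr)
    y2 <- ns$conv2d(x, m$w, m$b, pad = 4L, groups = ch)
    expect_lt(max(abs(y1 - y2)), 1e-4)
  }
  # zero-weight branches: merged equals the fused large kernel alone
  dr <- randomize_bn(dilated_reparam_module(3L))
  for (i in 1:4) {
    dr$ch[[paste0("b", i)]]$params$w[] <- 0
    dr$ch[[paste0("b", i, "_bn")]]$params$beta[] <- 0
    dr$ch[[paste0("b", i, "_bn")]]$buffers$rm[] <- 0
  }
  m <- merge_dilated_reparam(dr)
  f <- fuse_conv_bn(ns$conv_bn_spec(dr$ch$lk, dr$ch$lk_bn))
  expect_equal(m$w, f$w, tolerance = 1e-12)
  # enlarged K = 13 configuration pads every branch to 13 x 13
  dr13 <- dilated_reparam_module(2L, K = 13L, k = c(5L, 7L, 3L, 3L, 3L),
                                 r = c(1L, 2L, 3L, 4L, 5L))
  m13 <- merge_dilated_reparam(dr13)
  expect_equal(dim(m13$w)[1:2], c(13L, 13L))
  # branch exceeding K rejected
  expect_error(dilated_reparam_module(2L, K = 9L, k = 7L, r = 2L), "exceeds")
})

test_that("squeeze-and-excitation gates are sigmoid-bounded and exact at 0", {
  set.seed(34)
  se <- se_module(8L, 4L)
  x <- array(rnorm(5 * 5 * 8 * 2), dim = c(5, 5, 8, 2))
  # zero bottleneck weights: gate = sigmoid(0) = 1/2 everywhere
  se0 <- se
  se0$ch$fc1$params$w[] <- 0; se0$ch$fc2$params$w[] <- 0
  expect_equal(module_forward(se0, x), x / 2, tolerance = 1e-12)
  # hand-computed gate for a constant-channel input
  xc <- array(rep(1:8, each = 9), dim = c(3, 3, 8, 1))
  z <- as.numeric(1:8)
  h <- pmax(z %*% se$ch$fc1$params$w + rep(1, 1) %o% se$ch$fc1$params$b, 0)
  s <- plogis(h %*% se$ch$fc2$params$w + rep(1, 1) %o% se$ch$fc2$params$b)
  y <- module_forward(se, xc)
  for (c in 1:8) expect_equal(y[1, 1, c, 1], xc[1, 1, c, 1] * s[1, c],
                              tolerance = 1e-12)
  expect_true(all(s > 0 & s < 1))
  expect_error(se_module(6L, 4L), "divisible")
  expect_equal(dim(se_recalibrate(x, reduction = 4L)), dim(x))
})

test_that("LarK and SmaK blocks preserve shape and match after merge", {
  set.seed(35)
  lk <- randomize_bn(lark_module(8L))
  x <- array(rnorm(12 * 12 * 8 * 2), dim = c(12, 12, 8, 2))
  y <- module_forward(lk, x)
  expect_equal(dim(y), dim(x))
  # deploy-merged block equals the training block
  lkd <- ns$ym_deploy(lk)
  expect_lt(max(abs(module_forward(lkd, x) - y)), 1e-4)
  expect_lt(count_parameters(lkd), count_parameters(lk))
  # zero layer scale turns the block into the identity
  lk0 <- lk
  lk0$params$gamma[] <- 0
  expect_equal(module_forward(lk0, x), x)
  # SmaK equals LarK whose reparam spec degenerates to a single dense 3x3
  sm <- randomize_bn(lark_module(4L, "smak"))
  dr3 <- dilated_reparam_module(4L, K = 3L, k = integer(0), r = integer(0))
  dr3$ch$lk$params$w <- sm$ch$dw$params$w
  dr3$ch$lk_bn <- sm$ch$dw_bn
  lk_equiv <- sm
  lk_equiv$cfg$kind <- "lark"
  lk_equiv$ch$dw <- dr3
  lk_equiv$ch$dw_bn <- NULL
  xx <- array(rnorm(10 * 10 * 4), dim = c(10, 10, 4, 1))
  expect_equal(module_forward(lk_equiv, xx), module_forward(sm, xx),
               tolerance = 1e-12)
  expect_lt(gradcheck_module(randomize_bn(lark_module(4L)), c(8, 8, 4, 1)),
            1e-6)
})

test_that("downsampling block halves spatial dims with ceiling division", {
  set.seed(36)
  d <- downsample_module(3L, 8L)
  expect_equal(dim(module_forward(d, array(0, c(64, 64, 3, 1))))[1:2],
               c(32L, 32L))
  expect_equal(dim(module_forward(d, array(0, c(7, 7, 3, 1))))[1:2],
               c(4L, 4L))
  expect_equal(dim(module_forward(d, array(0, c(16, 16, 3, 1))))[3], 8L)
})
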