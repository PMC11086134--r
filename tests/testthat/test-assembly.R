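# Model assembly: shapes, placements, counting, deploy conversion, NMS.

test_that("baseline forward yields three prediction scales at strides 8/16/32", {
  set.seed(71)
  m <- build_baseline("n", 5L)
  x <- array(runif(160 * 160 * 3), dim = c(160, 160, 3, 1))
  out <- module_forward(m, x)
  expect_length(out, 3L)
  expect_equal(vapply(out, function(l) dim(l$box)[1], 0L), c(20L, 10L, 5L))
  expect_equal(dim(out[[1]]$box)[3], 64L)
  expect_equal(dim(out[[1]]$cls)[3], 5L)
  # every substitution preserves the inter-layer contracts at other sizes
  mu <- build_mu(model_config(input_size = 320L))
  out2 <- module_forward(mu, x)
  expect_equal(vapply(out2, function(l) dim(l$box)[1], 0L), c(20L, 10L, 5L))
})

test_that("parameter counting is exact and invariant to input size", {
  set.seed(72)
  cv <- ns$conv_module(3L, 16L, 3L)
  expect_equal(count_parameters(cv), 3 * 3 * 3 * 16 + 16)
  m1 <- build_baseline("n", 5L)
  set.seed(999)
  m2 <- build_baseline("n", 5L)
  expect_equal(count_parameters(m1), count_parameters(m2))
  # the parameter count matches the widely cited reference at 80 classes
  expect_equal(count_parameters(build_baseline("n", 80L)), 3157200)
})

test_that("disabling all substitutions reproduces the baseline summary", {
  cfg <- model_config(lark_positions = integer(0),
                      c2fstr_positions = integer(0),
                      neck_fusion_positions = integer(0),
                      use_sppfcspc_ema = FALSE)
  m <- build_mu(cfg)
  b <- build_baseline("n", 5L)
  expect_equal(count_parameters(m), count_parameters(b))
  expect_equal(vapply(m$ch, function(x) class(x)[1], ""),
               vapply(b$ch, function(x) class(x)[1], ""))
})

test_that("placements substitute the addressed slots only", {
  m <- build_baseline("n", 5L)
  m2 <- apply_placement(m, "lark", c(2, 3))
  expect_s3_class(m2$ch$b2, "seq")
  expect_s3_class(m2$ch$b3, "seq")
  expect_s3_class(m2$ch$b1, "c2f")
  expect_s3_class(m2$ch$b4, "c2f")
  m3 <- apply_placement(m, "c2fstr", 4)
  expect_s3_class(m3$ch$b4, "c2fstr")
  m4 <- apply_placement(m, "fusion", 1:4)
  for (i in 1:4) expect_s3_class(m4$ch[[paste0("n", i)]], "fusion")
  expect_error(apply_placement(m, "lark", 5), "1..4")
  # substituted models still run forward (contract preserved)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  for (mm in list(m2, m3, m4)) expect_length(module_forward(mm, x), 3L)
})

test_that("FLOP counting follows the closed-form MAC convention", {
  cv <- ns$conv_module(3L, 16L, 3L)
  r <- ns$ym_flops(cv, 640, 640)
  expect_equal(r$f / 1e9, 2 * (3 * 3 * 3) * 16 * 640^2 / 1e9,
               tolerance = 1e-12)
  # doubling the input side quadruples convolution FLOPs
  m <- build_baseline("n", 5L)
  expect_equal(count_flops(m, 640) / count_flops(m, 320), 4,
               tolerance = 0.01)
  # same order as the published baseline count
  expect_gt(count_flops(m, 640), 4)
  expect_lt(count_flops(m, 640), 16)
})

test_that("deploy conversion is exact, idempotent and strictly smaller", {
  set.seed(74)
  mu <- build_mu(model_config(input_size = 320L))
  mu <- randomize_bn(mu)
  x <- array(runif(96 * 96 * 3 * 2), dim = c(96, 96, 3, 2))
  out1 <- module_forward(mu, x)
  mud <- convert_to_deploy(mu)
  out2 <- module_forward(mud, x)
  dmax <- max(mapply(function(a, b)
    max(abs(a$box - b$box), abs(a$cls - b$cls)), out1, out2))
  expect_lt(dmax, 1e-3)
  expect_lt(count_parameters(mud), count_parameters(mu))
  mud2 <- convert_to_deploy(mud)
  expect_equal(count_parameters(mud2), count_parameters(mud))
  expect_identical(module_forward(mud2, x)[[1]]$box, out2[[1]]$box)
})

test_that("NMS follows the strict-greater suppression convention", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_length(nms(b, c(0.9, 0.8), 0.7), 1L)
  b2 <- rbind(c(0, 0, 10, 10), c(50, 50, 60, 60), c(100, 100, 110, 110))
  expect_length(nms(b2, c(0.9, 0.8, 0.7), 0.7), 3L)
  # hand-built pair at IoU exactly 0.7: kept under strict-greater
  a <- c(0, 0, 10, 17)
  bb <- c(0, 7, 10, 27)  # intersection 100, union 370 -> IoU = 10/37
  pair <- rbind(a, bb)
  iou <- box_iou(matrix(a, 1), matrix(bb, 1))
  expect_length(nms(pair, c(0.9, 0.8), iou), 2L)  # exactly at threshold
  expect_length(nms(pair, c(0.9, 0.8), iou - 1e-9), 1L)
})

test_that("YAML model configs round-trip through the builder", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("scale: n", "nc: 5", "lark_positions: [2, 3]",
               "c2fstr_positions: [4]", "neck_fusion_positions: [1, 2, 3, 4]",
               "use_sppfcspc_ema: yes", "input_size: 320"), f)
  cfg <- read_model_config(f)
  expect_equal(cfg$lark_positions, c(2L, 3L))
  expect_equal(count_parameters(build_mu(cfg)),
               count_parameters(build_mu(model_config(input_size = 320L))))
  writeLines("bogus_key: 1", f)
  expect_error(read_model_config(f), "unknown config keys")
})

test_that("model summary and checkpoints round-trip", {
  m <- build_baseline("n", 5L)
  s <- model_summary(m, 320)
  expect_equal(s$parameter_count, count_parameters(m))
  expect_output(print(s), "parameters")
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(count_parameters(m2), count_parameters(m))
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  expect_equal(module_forward(m2, x)[[1]]$box, module_forward(m, x)[[1]]$box)
})
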