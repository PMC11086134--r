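# Box algebra and the MPDIoU score/loss.

test_that("box constructor enforces corner ordering", {
  expect_error(box(5, 0, 2, 10), "invalid box")
  b <- box(0, 0, 10, 10)
  expect_equal(unname(unclass(b)), c(0, 0, 10, 10))
})

test_that("IoU handles identity, disjoint and partial overlap", {
  a <- box(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, box(20, 20, 30, 30)), 0)
  expect_equal(box_iou(a, box(5, 0, 15, 10)), 50 / 150)
  # degenerate: both zero-area
  expect_equal(box_iou(box(3, 3, 3, 3), box(3, 3, 3, 3)), 0)
})

test_that("IoU matches the pixel-grid counting oracle on integer boxes", {
  set.seed(101)
  for (i in 1:60) {
    a <- sort(sample(0:12, 2)); b <- sort(sample(0:12, 2))
    c1 <- sort(sample(0:12, 2)); d1 <- sort(sample(0:12, 2))
    bx1 <- c(a[1], b[1], a[2], b[2]); bx2 <- c(c1[1], d1[1], c1[2], d1[2])
    expect_equal(box_iou(matrix(bx1, 1), matrix(bx2, 1)),
                 pixel_grid_iou(bx1, bx2), tolerance = 1e-12)
  }
})

test_that("enclosing rectangle area follows the min/max corner formula", {
  a <- box(0, 0, 10, 10)
  expect_equal(enclosing_rect_area(a, a), 100)
  expect_equal(enclosing_rect_area(a, box(20, 20, 30, 30)), 900)
  expect_equal(enclosing_rect_area(box(0, 0, 30, 30), box(5, 5, 10, 10)), 900)
})

test_that("corner distances are squared Euclidean and translation symmetric", {
  gt <- box(0, 0, 10, 10)
  expect_equal(corner_distances_sq(gt, gt), list(d1_sq = 0, d2_sq = 0))
  d <- corner_distances_sq(box(3, 4, 13, 14), gt)
  expect_equal(d$d1_sq, 25)
  expect_equal(d$d2_sq, 25)
  set.seed(7)
  for (i in 1:20) {
    b <- random_box()
    dx <- rnorm(1); dy <- rnorm(1)
    tr <- b + c(dx, dy, dx, dy)
    ds <- corner_distances_sq(matrix(tr, 1), matrix(b, 1))
    expect_equal(ds$d1_sq, ds$d2_sq)
  }
})

test_that("mpdiou reproduces hand-derived values and its loss", {
  fr <- list(w = 100, h = 100)
  gt <- box(0, 0, 10, 10)
  expect_equal(mpdiou(gt, gt, fr), 1)
  pred <- box(3, 4, 13, 14)
  expected <- 42 / 158 - 25 / 20000 - 25 / 20000
  expect_equal(mpdiou(pred, gt, fr), expected, tolerance = 1e-9)
  expect_equal(mpdiou_loss(pred, gt, fr), 1 - expected, tolerance = 1e-9)
  expect_equal(mpdiou_loss(gt, gt, fr), 0)
  # disjoint boxes score strictly negative
  expect_lt(mpdiou(box(0, 0, 5, 5), box(50, 50, 60, 60), fr), 0)
  expect_error(mpdiou(pred, gt, list(w = 0, h = 100)), "positive")
})

test_that("mpdiou is bounded by IoU, symmetric, and >= -2 in frame", {
  set.seed(11)
  fr <- list(w = 100, h = 100)
  for (i in 1:1000) {
    a <- matrix(random_box(), 1); b <- matrix(random_box(), 1)
    m <- mpdiou(a, b, fr)
    expect_lte(m, box_iou(a, b) + 1e-12)
    expect_equal(m, mpdiou(b, a, fr), tolerance = 1e-12)
    expect_gte(m, -2)
  }
  # equality iff corners coincide
  a <- matrix(random_box(), 1)
  expect_equal(mpdiou(a, a, fr), box_iou(a, a))
})

test_that("mpdiou gradient matches finite differences", {
  set.seed(13)
  fr <- list(w = 64, h = 64)
  for (i in 1:25) {
    p <- matrix(random_box(60), 1)
    g <- matrix(random_box(60), 1)
    an <- ns$mpdiou_grad(p, g, fr)
    eps <- 1e-6
    for (k in 1:4) {
      pp <- p; pp[k] <- pp[k] + eps
      pm <- p; pm[k] <- pm[k] - eps
      # skip probes that cross a clamp boundary (kink in the subgradient)
      num <- (mpdiou(pp, g, fr) - mpdiou(pm, g, fr)) / (2 * eps)
      expect_equal(an[1, k], num, tolerance = 1e-4)
    }
  }
})

test_that("box geometry derives centers and sizes", {
  expect_equal(unname(box_geometry(box(0, 0, 10, 10))[1, ]), c(5, 5, 10, 10))
  expect_equal(unname(box_geometry(box(2, 4, 8, 10))[1, ]), c(5, 7, 6, 6))
  expect_equal(unname(box_geometry(box(3, 3, 3, 3))[1, ]), c(3, 3, 0, 0))
})

test_that("composite loss is the documented weighted sum and linear", {
  expect_equal(composite_loss(0, 0, 0), 0)
  expect_equal(composite_loss(1, 1, 1), 9.5)
  expect_equal(composite_loss(2, 2, 2), 2 * composite_loss(1, 1, 1))
  expect_equal(composite_loss(1, 2, 3, loss_weights(1, 1, 1)), 6)
  expect_error(loss_weights(-1, 0, 0), "non-negative")
})

test_that("YOLO text round trip preserves boxes", {
  set.seed(17)
  b <- rbind(c(10, 20, 50, 80), c(0, 0, 32, 32))
  m <- boxes_to_yolo(b, c(0L, 3L), 100, 100)
  expect_true(all(m[, 2:5] >= 0 & m[, 2:5] <= 1))
  r <- yolo_to_boxes(m, 100, 100)
  expect_equal(r$boxes, b, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(r$class, c(0L, 3L))
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(m, f)
  m2 <- read_yolo_labels(f)
  expect_equal(m2, unname(cbind(m[, 1], m[, -1])), tolerance = 1e-6,
               ignore_attr = TRUE)
})
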