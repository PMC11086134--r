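# Precision/recall/AP/mAP evaluation against brute-force oracles.

test_that("precision and recall follow the documented conventions", {
  expect_equal(det_precision(c(TP = 5, FP = 0)), 1)
  expect_equal(det_precision(c(TP = 3, FP = 1)), 0.75)
  expect_equal(det_precision(c(TP = 0, FP = 0)), 1)  # no predictions
  expect_equal(det_recall(c(TP = 4, FN = 0)), 1)
  expect_equal(det_recall(c(TP = 1, FN = 3)), 0.25)
  expect_true(is.na(det_recall(c(TP = 0, FN = 0))))  # class skipped
})

test_that("greedy matcher applies one-to-one, strict-threshold rules", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  m <- match_detections(matrix(c(0, 0, 10, 10), 1), 0.9, gt)
  expect_true(m$tp)
  # two detections on one gt: only the higher-confidence one is TP
  d2 <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11))
  m2 <- match_detections(d2, c(0.5, 0.9), gt)
  expect_equal(m2$tp, c(FALSE, TRUE))
  # strictly-greater threshold: IoU exactly 0.5 is a FP
  dhalf <- matrix(c(0, 0, 10, 5), 1)          # IoU with gt = 50/100 = 0.5
  expect_false(match_detections(dhalf, 1, gt, iou_thr = 0.5)$tp)
})

test_that("matcher and AP agree with brute-force oracles on random scenes", {
  set.seed(81)
  for (scene in 1:1000) {
    ng <- sample(0:6, 1)
    nd <- sample(0:6, 1)
    gt <- if (ng) t(replicate(ng, random_box(40))) else
      matrix(numeric(0), 0, 4)
    det <- if (nd) t(replicate(nd, {
      if (ng && runif(1) < 0.6) gt[sample(ng, 1), ] + rnorm(4, sd = 3)
      else random_box(40)
    })) else matrix(numeric(0), 0, 4)
    det[, 3] <- pmax(det[, 3], det[, 1]); det[, 4] <- pmax(det[, 4], det[, 2])
    conf <- if (nd) runif(nd) else numeric(0)
    m <- match_detections(det, conf, gt)
    expect_identical(m$tp, oracle_match(det, conf, gt))
    if (ng > 0) {
      ap <- average_precision(pr_curve(m$tp, conf, ng))
      expect_equal(ap, oracle_ap(m$tp, conf, ng), tolerance = 1e-12)
    }
  }
})

test_that("AP reproduces hand-derived envelope values", {
  # 2 gts, ranking [TP, FP]: points (0.5, 1.0), (0.5, 0.5) -> AP 0.5
  expect_equal(average_precision(pr_curve(c(TRUE, FALSE), c(0.9, 0.8), 2)),
               0.5)
  # perfect ranking at full recall
  expect_equal(average_precision(pr_curve(c(TRUE, TRUE), c(0.9, 0.8), 2)), 1)
  # all false positives
  expect_equal(average_precision(pr_curve(c(FALSE, FALSE), c(0.9, 0.8), 2)),
               0)
  # recall is non-decreasing along the sweep and all values are in [0, 1]
  set.seed(82)
  tp <- runif(30) > 0.5
  cur <- pr_curve(tp, runif(30), sum(tp) + 5)
  expect_true(all(diff(cur$recall) >= 0))
  expect_true(all(cur$recall >= 0 & cur$recall <= 1 &
                    cur$precision >= 0 & cur$precision <= 1))
})

test_that("AP is rank-only and duplicates never help", {
  set.seed(83)
  tp <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  conf <- c(0.9, 0.7, 0.6, 0.4, 0.2)
  ap1 <- average_precision(pr_curve(tp, conf, 4))
  ap2 <- average_precision(pr_curve(tp, conf * 0.31, 4))
  expect_equal(ap1, ap2)
  # adding a duplicate (necessarily FP) of an already-matched detection
  ap3 <- average_precision(pr_curve(c(tp, FALSE), c(conf, 0.1), 4))
  expect_lte(ap3, ap1)
})

test_that("mean AP averages evaluable classes and rejects empty input", {
  expect_equal(mean_ap(c(1, 1)), 1)
  expect_equal(mean_ap(c(0.8, 0.4)), 0.6)
  expect_error(mean_ap(numeric(0)), "no evaluable")
})

test_that("evaluator summarizes per-class APs and skips empty classes", {
  set.seed(84)
  gts <- list(list(class = c(0L, 1L),
                   boxes = rbind(c(0, 0, 10, 10), c(20, 20, 40, 40))),
              list(class = 0L, boxes = matrix(c(5, 5, 15, 15), 1)))
  preds <- list(list(class = c(0L, 1L), conf = c(0.9, 0.8),
                     boxes = rbind(c(0, 0, 10, 10), c(21, 21, 41, 41))),
                list(class = 0L, conf = 0.7,
                     boxes = matrix(c(5, 5, 15, 15), 1)))
  r <- evaluate_detections(preds, gts, nc = 3L)
  expect_equal(nrow(r$per_class), 3L)
  expect_true(is.na(r$per_class$ap[3]))      # class 2 has no ground truth
  expect_equal(r$map50, 1)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  evaluate_detections(preds, gts, nc = 3L, csv = csv, json = js)
  expect_true(file.exists(csv) && file.exists(js))
  expect_equal(jsonlite::read_json(js)$map50, 1)
})
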