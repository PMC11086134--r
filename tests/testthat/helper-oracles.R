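# Independent oracles and small utilities shared across the test files.
# Oracles are deliberately naive implementations (loops, enumeration, lattice
# counting) kept separate from the code paths they verify.

ns <- asNamespace("yolomu")

# direct 2-D convolution by explicit loops (supports stride/pad/dilation/groups)
naive_conv2d <- function(x, w, bias = NULL, stride = 1, pad = 0, dilation = 1,
                         groups = 1) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- wd[1]; kw <- wd[2]; cpg <- wd[3]; co <- wd[4]
  copg <- co / groups
  Ho <- (H + 2 * pad - dilation * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dilation * (kw - 1) - 1) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, co, N))
  for (n in 1:N) for (o in 1:co) {
    g <- ceiling(o / copg)
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(bias)) 0 else bias[o]
      for (ci in 1:cpg) {
        cin <- (g - 1) * cpg + ci
        for (ki in 1:kh) for (kj in 1:kw) {
          hi <- (ho - 1) * stride - pad + (ki - 1) * dilation + 1
          wi <- (wo - 1) * stride - pad + (kj - 1) * dilation + 1
          if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
            acc <- acc + x[hi, wi, cin, n] * w[ki, kj, ci, o]
        }
      }
      y[ho, wo, o, n] <- acc
    }
  }
  y
}

# IoU of integer-coordinate boxes by counting unit lattice cells
pixel_grid_iou <- function(a, b) {
  cells <- function(bx) {
    if (bx[3] <= bx[1] || bx[4] <= bx[2]) return(matrix(numeric(0), 0, 2))
    as.matrix(expand.grid(x = bx[1]:(bx[3] - 1), y = bx[2]:(bx[4] - 1)))
  }
  ca <- cells(a); cb <- cells(b)
  if (nrow(ca) == 0 && nrow(cb) == 0) return(0)
  key <- function(m) paste(m[, 1], m[, 2])
  inter <- length(intersect(key(ca), key(cb)))
  uni <- length(union(key(ca), key(cb)))
  inter / uni
}

# exhaustive matcher: recursively enumerate assignments, preferring, in
# descending confidence order, matching with the highest-IoU still-free
# ground truth (lexicographic greedy optimum)
oracle_match <- function(det_boxes, conf, gt_boxes, iou_thr = 0.5) {
  nd <- nrow(det_boxes); ng <- nrow(gt_boxes)
  ord <- order(conf, decreasing = TRUE)
  tp <- logical(nd)
  used <- logical(ng)
  for (i in ord) {
    best <- 0; bi <- NA
    if (ng > 0) for (j in seq_len(ng)) {
      if (used[j]) next
      iou <- yolomu::box_iou(matrix(det_boxes[i, ], 1, 4),
                             matrix(gt_boxes[j, ], 1, 4))
      if (iou > best) { best <- iou; bi <- j }
    }
    if (!is.na(bi) && best > iou_thr) { tp[i] <- TRUE; used[bi] <- TRUE }
  }
  tp
}

# AP by explicit envelope over sorted PR points (independent loop structure)
oracle_ap <- function(tp, conf, n_gt) {
  if (n_gt == 0) return(NA_real_)
  ord <- order(conf, decreasing = TRUE)
  tp <- tp[ord]
  rec <- cumsum(tp) / n_gt
  prec <- cumsum(tp) / seq_along(tp)
  ap <- 0
  prev_r <- 0
  for (r in unique(rec[rec > 0])) {
    p <- max(prec[rec >= r])
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# assign plausible random frozen statistics to every BN in a module tree
randomize_bn <- function(mod) {
  for (nm in names(mod$ch)) {
    child <- mod$ch[[nm]]
    if (inherits(child, "bn")) {
      cc <- length(child$params$gamma)
      child$buffers$rm <- rnorm(cc, sd = 0.5)
      child$buffers$rv <- runif(cc, 0.5, 2)
      child$params$gamma <- runif(cc, 0.5, 1.5)
      child$params$beta <- rnorm(cc, sd = 0.5)
      mod$ch[[nm]] <- child
    } else if (length(child$ch)) {
      mod$ch[[nm]] <- randomize_bn(child)
    }
  }
  mod
}

# finite-difference gradient check: returns max relative error over probes
gradcheck_module <- function(mod, xdim, training = TRUE, eps = 1e-5,
                             nprobe = 5, nparam = 6) {
  x <- array(rnorm(prod(xdim)), dim = xdim)
  f0 <- ns$ym_forward(mod, x, training = training)
  wr <- array(rnorm(length(f0$y)), dim = dim(f0$y))
  lossfn <- function(m, xx)
    sum(ns$ym_forward(m, xx, training = training)$y * wr)
  b <- ns$ym_backward(mod, f0$cache, wr)
  errs <- c()
  for (i in sample(length(x), nprobe)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (lossfn(mod, xp) - lossfn(mod, xm)) / (2 * eps)
    errs <- c(errs, abs(num - b$dx[i]) / max(1, abs(num)))
  }
  flat <- ns$ym_flatten(mod)
  gflat <- ns$ym_flatten_grads(mod, b$g)
  for (nm in sample(names(flat), min(nparam, length(flat)))) {
    p <- flat[[nm]]
    i <- sample(length(p), 1)
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (lossfn(ns$ym_set_param(mod, nm, pp), x) -
              lossfn(ns$ym_set_param(mod, nm, pm), x)) / (2 * eps)
    errs <- c(errs, abs(num - gflat[[nm]][i]) / max(1, abs(num)))
  }
  max(errs)
}

random_box <- function(lim = 100) {
  x <- sort(runif(2, 0, lim)); y <- sort(runif(2, 0, lim))
  c(x[1], y[1], x[2], y[2])
}
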