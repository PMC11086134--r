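# Detector assembly: baseline backbone/neck/head, substitution of the bespoke
# blocks at configurable positions, parameter/FLOP accounting, deploy
# conversion and checkpoints.

scale_widths <- function(scale) {
  switch(scale,
         n = list(w = c(16L, 32L, 64L, 128L, 256L), depth = c(1L, 2L, 2L, 1L)),
         s = list(w = c(32L, 64L, 128L, 256L, 512L), depth = c(1L, 2L, 2L, 1L)),
         stop("unknown scale: ", scale))
}

#' Model configuration
#'
#' The default configuration is the full model preset: LarK blocks at the
#' middle two backbone positions, C2fSTR at the last, SPPFCSPC_EMA in place of
#' SPPF, fusion blocks at all four neck positions, MPDIoU box loss with
#' weights (7.5, 0.5, 1.5).
#'
#' @param scale width preset, "n" or "s".
#' @param nc number of object classes.
#' @param lark_positions backbone C2f slots (1-4, shallow to deep) replaced by
#'   LarK stages.
#' @param c2fstr_positions backbone slots replaced by C2fSTR.
#' @param neck_fusion_positions neck C2f slots (1-4, in forward order)
#'   replaced by fusion blocks.
#' @param use_sppfcspc_ema replace SPPF with SPPFCSPC_EMA.
#' @param loss weights from [loss_weights()].
#' @param input_size network input side (pixels).
#' @export
model_config <- function(scale = "n", nc = 5L,
                         lark_positions = c(2L, 3L),
                         c2fstr_positions = 4L,
                         neck_fusion_positions = 1:4,
                         use_sppfcspc_ema = TRUE,
                         loss = loss_weights(),
                         input_size = 640L) {
  stopifnot(all(lark_positions %in% 1:4), all(c2fstr_positions %in% 1:4),
            all(neck_fusion_positions %in% 1:4))
  if (length(intersect(lark_positions, c2fstr_positions)) > 0)
    stop("a backbone slot cannot host both a LarK stage and a C2fSTR")
  list(scale = scale, nc = as.integer(nc),
       lark_positions = as.integer(lark_positions),
       c2fstr_positions = as.integer(c2fstr_positions),
       neck_fusion_positions = as.integer(neck_fusion_positions),
       use_sppfcspc_ema = isTRUE(use_sppfcspc_ema),
       loss = loss, input_size = as.integer(input_size))
}

#' Read a model configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [model_config()]; missing keys
#' take the defaults.
#'
#' @param path YAML file path.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$loss)) y$loss <- do.call(loss_weights, y$loss)
  # YAML 1.1 reads a bare `n` as FALSE; recover the scale letter
  if (is.logical(y$scale)) y$scale <- if (y$scale) "y" else "n"
  do.call(model_config, y)
}

# (c_in, c_out, n) of the four backbone C2f slots and four neck C2f slots
backbone_slots <- function(sw) {
  lapply(1:4, function(i) list(c = sw$w[i + 1L], n = sw$depth[i]))
}
neck_slots <- function(sw) {
  w <- sw$w
  list(list(c_in = w[4] + w[5], c_out = w[4]),
       list(c_in = w[3] + w[4], c_out = w[3]),
       list(c_in = w[3] + w[4], c_out = w[4]),
       list(c_in = w[4] + w[5], c_out = w[5]))
}

#' Build the baseline anchor-free detector
#'
#' Four-stage C2f backbone, SPPF, FPN/PAN neck with C2f fusion, decoupled
#' head with distribution-focal box regression (strides 8/16/32).
#'
#' @param scale "n" or "s".
#' @param nc number of classes.
#' @export
build_baseline <- function(scale = "n", nc = 5L) {
  sw <- scale_widths(scale)
  w <- sw$w
  bs <- backbone_slots(sw)
  ns <- neck_slots(sw)
  ch <- list(
    l0 = cbs_module(3L, w[1], 3L, 2L),
    l1 = cbs_module(w[1], w[2], 3L, 2L),
    b1 = c2f_module(w[2], w[2], bs[[1]]$n, TRUE),
    l3 = cbs_module(w[2], w[3], 3L, 2L),
    b2 = c2f_module(w[3], w[3], bs[[2]]$n, TRUE),
    l5 = cbs_module(w[3], w[4], 3L, 2L),
    b3 = c2f_module(w[4], w[4], bs[[3]]$n, TRUE),
    l7 = cbs_module(w[4], w[5], 3L, 2L),
    b4 = c2f_module(w[5], w[5], bs[[4]]$n, TRUE),
    spp = sppf_module(w[5], w[5]),
    n1 = c2f_module(ns[[1]]$c_in, ns[[1]]$c_out, 1L, FALSE),
    n2 = c2f_module(ns[[2]]$c_in, ns[[2]]$c_out, 1L, FALSE),
    d1 = cbs_module(w[3], w[3], 3L, 2L),
    n3 = c2f_module(ns[[3]]$c_in, ns[[3]]$c_out, 1L, FALSE),
    d2 = cbs_module(w[4], w[4], 3L, 2L),
    n4 = c2f_module(ns[[4]]$c_in, ns[[4]]$c_out, 1L, FALSE),
    head = detect_module(nc, c(w[3], w[4], w[5]))
  )
  new_module("detector", ch = ch,
             cfg = list(scale = scale, nc = as.integer(nc), widths = w,
                        depths = sw$depth, strides = c(8L, 16L, 32L),
                        config = model_config(scale = scale, nc = nc,
                                              lark_positions = integer(0),
                                              c2fstr_positions = integer(0),
                                              neck_fusion_positions = integer(0),
                                              use_sppfcspc_ema = FALSE)))
}

#' Substitute bespoke blocks at given positions
#'
#' @param model a detector.
#' @param kind "lark", "c2fstr" (backbone slots) or "fusion" (neck slots).
#' @param positions slot indices 1-4.
#' @export
apply_placement <- function(model, kind = c("lark", "c2fstr", "fusion"),
                            positions) {
  kind <- match.arg(kind)
  if (!all(positions %in% 1:4)) stop("positions must be in 1..4")
  sw <- scale_widths(model$cfg$scale)
  bs <- backbone_slots(sw)
  ns <- neck_slots(sw)
  for (p in positions) {
    if (kind == "lark") {
      c <- bs[[p]]$c
      model$ch[[paste0("b", p)]] <-
        seq_module(lapply(seq_len(bs[[p]]$n), function(i) lark_module(c)))
      model$cfg$config$lark_positions <-
        sort(union(model$cfg$config$lark_positions, p))
    } else if (kind == "c2fstr") {
      c <- bs[[p]]$c
      model$ch[[paste0("b", p)]] <- c2fstr_module(c, c, bs[[p]]$n)
      model$cfg$config$c2fstr_positions <-
        sort(union(model$cfg$config$c2fstr_positions, p))
    } else {
      model$ch[[paste0("n", p)]] <- fusion_module(ns[[p]]$c_in, ns[[p]]$c_out)
      model$cfg$config$neck_fusion_positions <-
        sort(union(model$cfg$config$neck_fusion_positions, p))
    }
  }
  model
}

#' Build a detector from a configuration
#'
#' With the default [model_config()] this assembles the full improved model;
#' with all substitutions disabled it reproduces the baseline exactly.
#'
#' @param config a [model_config()].
#' @export
build_mu <- function(config = model_config()) {
  m <- build_baseline(config$scale, config$nc)
  if (length(config$lark_positions))
    m <- apply_placement(m, "lark", config$lark_positions)
  if (length(config$c2fstr_positions))
    m <- apply_placement(m, "c2fstr", config$c2fstr_positions)
  if (length(config$neck_fusion_positions))
    m <- apply_placement(m, "fusion", config$neck_fusion_positions)
  if (config$use_sppfcspc_ema) {
    w5 <- scale_widths(config$scale)$w[5]
    m$ch$spp <- sppfcspc_ema_module(w5, w5)
    m$cfg$config$use_sppfcspc_ema <- TRUE
  }
  m$cfg$config$loss <- config$loss
  m$cfg$config$input_size <- config$input_size
  m
}

ym_forward.detector <- function(mod, x, training = FALSE) {
  cc <- list()
  run <- function(nm, inp) {
    f <- ym_forward(mod$ch[[nm]], inp, training)
    cc[[nm]] <<- f$cache
    f$y
  }
  x0 <- run("l0", as_fmap(x))
  x1 <- run("l1", x0)
  x2 <- run("b1", x1)
  x3 <- run("l3", x2)
  x4 <- run("b2", x3)
  x5 <- run("l5", x4)
  x6 <- run("b3", x5)
  x7 <- run("l7", x6)
  x8 <- run("b4", x7)
  x9 <- run("spp", x8)
  u1 <- upsample2x(x9)
  x12 <- run("n1", cat_c(list(u1, x6)))
  u2 <- upsample2x(x12)
  x15 <- run("n2", cat_c(list(u2, x4)))
  x16 <- run("d1", x15)
  x18 <- run("n3", cat_c(list(x16, x12)))
  x19 <- run("d2", x18)
  x21 <- run("n4", cat_c(list(x19, x9)))
  fh <- ym_forward(mod$ch$head, list(x15, x18, x21), training)
  cc$head <- fh$cache
  list(y = fh$y,
       cache = list(ch = cc,
                    dims = list(x6 = dim(x6), x4 = dim(x4), x9 = dim(x9),
                                x12 = dim(x12))))
}

ym_backward.detector <- function(mod, cache, dy) {
  cc <- cache$ch
  w <- mod$cfg$widths
  gch <- list()
  bwd <- function(nm, d) {
    b <- ym_backward(mod$ch[[nm]], cc[[nm]], d)
    gch[[nm]] <<- b$g
    b$dx
  }
  bh <- ym_backward(mod$ch$head, cc$head, dy)
  gch$head <- bh$g
  d21 <- bh$dx[[3]]
  dc4 <- bwd("n4", d21)
  sp <- split_c(dc4, c(w[4], w[5]))
  d19 <- sp[[1]]; d9a <- sp[[2]]
  d18 <- bh$dx[[2]] + bwd("d2", d19)
  dc3 <- bwd("n3", d18)
  sp <- split_c(dc3, c(w[3], w[4]))
  d16 <- sp[[1]]; d12a <- sp[[2]]
  d15 <- bh$dx[[1]] + bwd("d1", d16)
  dc2 <- bwd("n2", d15)
  sp <- split_c(dc2, c(w[4], w[3]))
  d12 <- d12a + upsample2x_bwd(sp[[1]])
  d4a <- sp[[2]]
  dc1 <- bwd("n1", d12)
  sp <- split_c(dc1, c(w[5], w[4]))
  d9 <- d9a + upsample2x_bwd(sp[[1]])
  d6a <- sp[[2]]
  d8 <- bwd("spp", d9)
  d7 <- bwd("b4", d8)
  d6 <- d6a + bwd("l7", d7)
  d5 <- bwd("b3", d6)
  d4 <- d4a + bwd("l5", d5)
  d3 <- bwd("b2", d4)
  d2 <- bwd("l3", d3)
  d1 <- bwd("b1", d2)
  d0 <- bwd("l1", d1)
  dx <- bwd("l0", d0)
  list(dx = dx, g = list(params = list(), ch = gch))
}

#' Convert a detector to its single-path deploy form
#'
#' Merges every dilated-reparam block and RepBlock into single convolutions.
#' Head outputs agree with the training-form model; the parameter count
#' strictly decreases when any reparameterizable block is present. Idempotent.
#'
#' @param model a detector.
#' @export
convert_to_deploy <- function(model) ym_deploy(model)

# ---- FLOP accounting ---------------------------------------------------------
# Convention: 2 operations per multiply-add; convolution, linear and attention
# matrix products counted; normalization/activation/pooling excluded.

ym_flops <- function(mod, H, W) UseMethod("ym_flops")

ym_flops.conv <- function(mod, H, W) {
  cfg <- mod$cfg
  Ho <- (H + 2 * cfg$pad - cfg$dilation * (cfg$k - 1) - 1) %/% cfg$stride + 1
  Wo <- (W + 2 * cfg$pad - cfg$dilation * (cfg$k - 1) - 1) %/% cfg$stride + 1
  list(f = 2 * cfg$k^2 * (cfg$c_in / cfg$groups) * cfg$c_out * Ho * Wo,
       H = Ho, W = Wo)
}

ym_flops.bn <- function(mod, H, W) list(f = 0, H = H, W = W)
ym_flops.inorm <- ym_flops.bn

ym_flops.cbs <- function(mod, H, W) ym_flops(mod$ch$conv, H, W)

seq_flops <- function(mods, H, W) {
  f <- 0
  for (m in mods) {
    r <- ym_flops(m, H, W)
    f <- f + r$f; H <- r$H; W <- r$W
  }
  list(f = f, H = H, W = W)
}

ym_flops.bottleneck <- function(mod, H, W) seq_flops(mod$ch, H, W)
ym_flops.seq <- function(mod, H, W) seq_flops(mod$ch, H, W)

ym_flops.c2f <- function(mod, H, W) {
  f <- ym_flops(mod$ch$cv1, H, W)$f + ym_flops(mod$ch$cv2, H, W)$f
  for (i in seq_len(mod$cfg$n))
    f <- f + ym_flops(mod$ch[[paste0("m", i)]], H, W)$f
  list(f = f, H = H, W = W)
}

ym_flops.sppf <- function(mod, H, W) {
  list(f = ym_flops(mod$ch$cv1, H, W)$f + ym_flops(mod$ch$cv2, H, W)$f,
       H = H, W = W)
}

ym_flops.dreparam <- function(mod, H, W) {
  if (mod$cfg$deploy)
    return(list(f = 2 * mod$cfg$K^2 * mod$cfg$channels * H * W, H = H, W = W))
  f <- 2 * mod$cfg$K^2 * mod$cfg$channels * H * W +
    sum(2 * mod$cfg$k^2 * mod$cfg$channels * H * W)
  list(f = f, H = H, W = W)
}

ym_flops.se <- function(mod, H, W) {
  d <- mod$cfg$channels
  list(f = 2 * d * (d / mod$cfg$reduction) * 2, H = H, W = W)
}

ym_flops.lark <- function(mod, H, W) {
  f <- ym_flops(mod$ch$dw, H, W)$f + ym_flops(mod$ch$se, H, W)$f +
    ym_flops(mod$ch$pw1, H, W)$f + ym_flops(mod$ch$pw2, H, W)$f
  list(f = f, H = H, W = W)
}

ym_flops.swin <- function(mod, H, W) {
  cfg <- mod$cfg
  D <- cfg$dim
  me <- min(cfg$M, H, W)
  Hp <- ceiling(H / me) * me; Wp <- ceiling(W / me) * me
  Tn <- Hp * Wp
  f <- 2 * Tn * D * 3 * D + 2 * Tn * D * D +       # qkv + proj
    2 * 2 * Tn * (me * me) * D +                   # scores + weighted sum
    2 * 2 * Tn * D * cfg$mlp_ratio * D             # MLP
  list(f = f, H = H, W = W)
}

ym_flops.ema <- function(mod, H, W) {
  cg <- mod$cfg$cg; g <- mod$cfg$groups
  f <- g * (2 * (H + W) * cg * cg + 2 * 9 * cg * cg * H * W +
              2 * 2 * H * W * cg)
  list(f = f, H = H, W = W)
}

ym_flops.sppfcspc <- function(mod, H, W) {
  f <- sum(vapply(mod$ch, function(m) ym_flops(m, H, W)$f, 0))
  list(f = f, H = H, W = W)
}
ym_flops.sppfcspc_ema <- ym_flops.sppfcspc

ym_flops.repblock <- function(mod, H, W) {
  cfg <- mod$cfg
  if (cfg$deploy)
    return(list(f = 2 * 9 * cfg$c_in * cfg$c_out * H * W, H = H, W = W))
  list(f = 2 * (9 + 1) * cfg$c_in * cfg$c_out * H * W, H = H, W = W)
}

ym_flops.fusion <- function(mod, H, W) {
  f <- sum(vapply(mod$ch, function(m) ym_flops(m, H, W)$f, 0))
  list(f = f, H = H, W = W)
}

ym_flops.detect <- function(mod, H, W) {
  # H, W: stride-8 level dims; deeper levels halve
  f <- 0
  for (i in 1:3) {
    h <- H %/% (2^(i - 1)); w <- W %/% (2^(i - 1))
    for (p in c("box", "cls")) for (j in 1:3)
      f <- f + ym_flops(mod$ch[[paste0(p, i, "_", j)]], h, w)$f
  }
  list(f = f, H = H, W = W)
}

#' Count forward FLOPs of a detector
#'
#' Multiply-add convention (2 ops per MAC) at the given square input size.
#'
#' @param model a detector.
#' @param input_size input side in pixels.
#' @return GFLOPs (billions of operations).
#' @export
count_flops <- function(model, input_size = 640L) {
  s <- input_size
  f <- 0
  track <- function(nm, H, W) {
    r <- ym_flops(model$ch[[nm]], H, W)
    f <<- f + r$f
    r
  }
  r <- track("l0", s, s)
  r <- track("l1", r$H, r$W); h2 <- r$H
  r <- track("b1", r$H, r$W)
  r <- track("l3", r$H, r$W); r <- track("b2", r$H, r$W); h8 <- r$H
  r <- track("l5", r$H, r$W); r <- track("b3", r$H, r$W); h16 <- r$H
  r <- track("l7", r$H, r$W); r <- track("b4", r$H, r$W); h32 <- r$H
  track("spp", h32, h32)
  track("n1", h16, h16)
  track("n2", h8, h8)
  track("d1", h8, h8)
  track("n3", h16, h16)
  track("d2", h16, h16)
  track("n4", h32, h32)
  track("head", h8, h8)
  f / 1e9
}

#' Model summary: parameters, FLOPs and per-module table
#'
#' @param model a detector.
#' @param input_size input side for the FLOP count.
#' @return list with parameter_count, gflops and module_table.
#' @export
model_summary <- function(model, input_size = 640L) {
  tab <- data.frame(
    module = names(model$ch),
    type = vapply(model$ch, function(m) class(m)[1], ""),
    params = vapply(model$ch, count_parameters, 0))
  structure(list(parameter_count = count_parameters(model),
                 gflops = count_flops(model, input_size),
                 module_table = tab,
                 scale = model$cfg$scale, nc = model$cfg$nc,
                 input_size = input_size),
            class = "yolomu_summary")
}

#' @export
print.yolomu_summary <- function(x, ...) {
  cat(sprintf("detector (scale %s, %d classes)\n", x$scale, x$nc))
  cat(sprintf("parameters: %d (%.2f M)\n", x$parameter_count,
              x$parameter_count / 1e6))
  cat(sprintf("FLOPs at %d^2: %.2f G\n", x$input_size, x$gflops))
  print(x$module_table, row.names = FALSE)
  invisible(x)
}

#' @export
print.ym_module <- function(x, ...) {
  cat(sprintf("<%s> %d parameters\n", class(x)[1], count_parameters(x)))
  if (length(x$ch))
    cat("children:", paste(names(x$ch), collapse = ", "), "\n")
  invisible(x)
}

# ---- checkpoints -------------------------------------------------------------

#' Save / load a detector checkpoint
#'
#' A checkpoint is a serialized list with the model configuration header and
#' the full module tree. [convert_to_deploy()]-converted models are written
#' with a ".fused" suffix by the conversion CLI.
#'
#' @param model a detector.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$cfg$config, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$model
}
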