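# SGD training loop: momentum 0.937, weight decay 5e-4, constant learning
# rate 1e-2 (the published schedule lists identical initial and final rates),
# with a short linear warmup and global gradient-norm clipping for stability
# on freshly initialized models.

#' Load a batch of images and labels from a dataset directory
#'
#' @param dir dataset root written by [write_dataset()].
#' @param split "train" or "val".
#' @param indices which images (default all).
#' @return list(images = (H, W, 3, N) array, targets = per-image list(class,
#'   boxes), files).
#' @export
load_image_batch <- function(dir, split = "train", indices = NULL) {
  img_dir <- file.path(dir, "images", split)
  files <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  if (!is.null(indices)) files <- files[indices]
  if (!length(files)) stop("no images found in ", img_dir)
  imgs <- lapply(files, png::readPNG)
  H <- dim(imgs[[1]])[1]; W <- dim(imgs[[1]])[2]
  x <- array(0, dim = c(H, W, 3, length(files)))
  targets <- vector("list", length(files))
  for (i in seq_along(files)) {
    x[, , , i] <- imgs[[i]][, , 1:3]
    lab <- read_yolo_labels(file.path(dir, "labels", split,
                                      sub("\\.png$", ".txt",
                                          basename(files[i]))))
    if (nrow(lab)) {
      yb <- yolo_to_boxes(lab, W, H)
      targets[[i]] <- list(class = yb$class, boxes = yb$boxes)
    } else {
      targets[[i]] <- list(class = integer(0),
                           boxes = matrix(numeric(0), 0, 4))
    }
  }
  list(images = x, targets = targets, files = files)
}

clip_global_norm <- function(grads, max_norm) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(tot) && tot > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / tot))
  grads
}

#' Train a detector with SGD
#'
#' @param model a detector.
#' @param data list(images, targets) as from [load_image_batch()].
#' @param iterations number of SGD steps.
#' @param batch_size images per step (cycled deterministically).
#' @param lr learning rate (constant schedule).
#' @param momentum,weight_decay SGD hyperparameters.
#' @param warmup_iters linear learning-rate warmup steps.
#' @param clip gradient-norm clip.
#' @param verbose print per-iteration losses.
#' @return list(model, log) where log is a data frame of loss terms per
#'   iteration.
#' @export
train_detector <- function(model, data, iterations = 20L, batch_size = 16L,
                           lr = 1e-2, momentum = 0.937, weight_decay = 5e-4,
                           warmup_iters = 3L, clip = 10, verbose = FALSE) {
  N <- dim(data$images)[4]
  frame <- list(w = dim(data$images)[2], h = dim(data$images)[1])
  weights <- model$cfg$config$loss %||% loss_weights()
  vel <- NULL
  log <- data.frame(iter = integer(0), loss = numeric(0), box = numeric(0),
                    cls = numeric(0), dfl = numeric(0))
  idx_all <- rep(seq_len(N), length.out = iterations * batch_size)
  for (it in seq_len(iterations)) {
    idx <- idx_all[(it - 1L) * batch_size + seq_len(batch_size)]
    xb <- data$images[, , , idx, drop = FALSE]
    tb <- data$targets[idx]
    fw <- ym_forward(model, xb, training = TRUE)
    ls <- detection_loss(fw$y, tb, frame, weights,
                         strides = model$cfg$strides)
    bw <- ym_backward(model, fw$cache, ls$grads)
    model <- ym_apply_state(model, fw$cache)
    params <- ym_flatten(model)
    grads <- ym_flatten_grads(model, bw$g)
    grads <- clip_global_norm(grads, clip)
    if (is.null(vel)) vel <- lapply(grads, function(g) g * 0)
    lr_t <- if (it <= warmup_iters) lr * it / warmup_iters else lr
    for (nm in names(params)) {
      g <- grads[[nm]] + weight_decay * params[[nm]]
      vel[[nm]] <- momentum * vel[[nm]] - lr_t * g
      model <- ym_set_param(model, nm, params[[nm]] + vel[[nm]])
    }
    log <- rbind(log, data.frame(iter = it, loss = ls$loss, box = ls$box,
                                 cls = ls$cls, dfl = ls$dfl))
    if (verbose)
      message(sprintf("iter %3d  loss %.4f (box %.4f cls %.4f dfl %.4f)",
                      it, ls$loss, ls$box, ls$cls, ls$dfl))
  }
  list(model = model, log = log)
}
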