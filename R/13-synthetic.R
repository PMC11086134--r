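# Synthetic benthic scene generator: turbid low-contrast underwater imagery
# with five procedural organism classes (urchin, starfish, sea cucumber,
# scallop, waterweeds), blue-green color cast, blur and exact YOLO labels
# recorded before degradation. Fully deterministic under the spec seed.

#' Synthetic scene specification
#'
#' @param size image side in pixels (square scenes).
#' @param n_objects integer range c(min, max) of objects per scene.
#' @param classes class names; the five defaults mirror the benthic classes
#'   of the URPC-style surveys.
#' @param blur_sigma Gaussian blur radius (pixels) applied to the scene.
#' @param color_cast strength of the blue-green water cast in [0, 1].
#' @param contrast contrast retention factor in (0, 1]; lower is murkier.
#' @param overlap_prob probability that a new object is placed near an
#'   existing one (overlapping benthic clusters).
#' @param seed RNG seed; scenes are bit-reproducible given the spec.
#' @export
scene_spec <- function(size = 320L, n_objects = c(3L, 8L),
                       classes = c("echinus", "starfish", "holothurian",
                                   "scallop", "waterweeds"),
                       blur_sigma = 1.2, color_cast = 0.5, contrast = 0.6,
                       overlap_prob = 0.3, seed = 1L) {
  list(size = as.integer(size), n_objects = as.integer(n_objects),
       classes = classes, blur_sigma = blur_sigma, color_cast = color_cast,
       contrast = contrast, overlap_prob = overlap_prob,
       seed = as.integer(seed))
}

# low-frequency value noise upsampled to (n x n)
value_noise <- function(n, cells = 8L, amp = 1) {
  g <- matrix(stats::rnorm(cells * cells), cells, cells)
  xi <- seq(1, cells, length.out = n)
  i0 <- pmin(floor(xi), cells - 1L); fi <- xi - i0
  up_rows <- g[i0, , drop = FALSE] * (1 - fi) + g[i0 + 1L, , drop = FALSE] * fi
  up <- up_rows[, i0, drop = FALSE] * matrix(1 - fi, n, n, byrow = TRUE) +
    up_rows[, i0 + 1L, drop = FALSE] * matrix(fi, n, n, byrow = TRUE)
  up * amp
}

# class-specific procedural silhouette on the pixel grid; returns a mask
shape_mask <- function(class_id, cx, cy, R, size, aspect = 1, rot = 0) {
  xs <- matrix(rep(seq_len(size), each = size), size, size) - cx  # columns
  ys <- matrix(rep(seq_len(size), times = size), size, size) - cy # rows
  xr <- cos(rot) * xs + sin(rot) * ys
  yr <- -sin(rot) * xs + cos(rot) * ys
  r <- sqrt(xr^2 + (yr / aspect)^2)
  th <- atan2(yr / aspect, xr)
  switch(class_id + 1L,
         { # echinus: spiked disc
           spikes <- 1 + 0.35 * abs(sin(9 * th))
           r < R * 0.75 * spikes
         },
         { # starfish: five-armed star
           arms <- 0.55 + 0.45 * cos(5 * th)
           r < R * pmax(arms, 0.25)
         },
         { # holothurian: elongated blob
           sqrt((xr / 1.8)^2 + (yr / 0.7)^2) < R * 0.8 *
             (1 + 0.15 * sin(3 * th))
         },
         { # scallop: fan (half disc with ridges)
           (r < R * (0.9 + 0.08 * sin(11 * th))) & (yr < 0.15 * R)
         },
         { # waterweeds: filament cluster
           fil <- FALSE
           for (k in 1:4) {
             phase <- k * 1.7
             fil <- fil | (abs(xr - 0.35 * R * sin(yr / R * 3 + phase) -
                                 (k - 2.5) * 0.35 * R) <
                             0.09 * R & abs(yr) < R)
           }
           fil
         })
}

class_color <- function(class_id) {
  switch(class_id + 1L,
         c(0.15, 0.12, 0.10),  # echinus: dark
         c(0.75, 0.45, 0.30),  # starfish: orange
         c(0.30, 0.28, 0.18),  # holothurian: olive
         c(0.80, 0.72, 0.60),  # scallop: pale
         c(0.10, 0.45, 0.20))  # waterweeds: green
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(2.5 * sigma))
  k1 <- stats::dnorm(-rad:rad, sd = sigma)
  k1 <- k1 / sum(k1)
  kk <- outer(k1, k1)
  d <- dim(img)
  w <- array(0, dim = c(2 * rad + 1, 2 * rad + 1, 1, 3))
  for (c in 1:3) w[, , 1, c] <- kk
  x <- array(img, dim = c(d[1], d[2], 3, 1))
  out <- conv2d(x, w, NULL, stride = 1L, pad = rad, groups = 3L)
  array(out, dim = d)
}

#' Generate one synthetic benthic scene
#'
#' @param spec a [scene_spec()].
#' @param id scene index; scenes with different ids draw from
#'   deterministically different RNG streams.
#' @return list(image = (size, size, 3) array in [0, 1], class = 0-based
#'   vector, boxes = n x 4 pixel corners, yolo = n x 5 normalized rows).
#' @export
generate_scene <- function(spec, id = 0L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed + 7919L * as.integer(id))
  n <- spec$size
  # seabed background with blue-green cast
  base <- 0.45 + 0.1 * value_noise(n, 6) + 0.05 * value_noise(n, 16)
  img <- array(0, dim = c(n, n, 3))
  cast <- spec$color_cast
  img[, , 1] <- base * (1 - 0.55 * cast)
  img[, , 2] <- base * (1 - 0.10 * cast) + 0.08 * cast
  img[, , 3] <- base * (1 - 0.25 * cast) + 0.12 * cast
  n_obj <- if (spec$n_objects[1] >= spec$n_objects[2]) spec$n_objects[1]
           else sample(spec$n_objects[1]:spec$n_objects[2], 1)
  cls <- integer(0)
  boxes <- matrix(numeric(0), 0, 4)
  placed <- list()
  for (i in seq_len(n_obj)) {
    k <- sample(0:(length(spec$classes) - 1L), 1)
    R <- stats::runif(1, 0.05, 0.12) * n
    ok <- FALSE
    for (try in 1:8) {
      if (length(placed) && stats::runif(1) < spec$overlap_prob) {
        ref <- placed[[sample(length(placed), 1)]]
        cx <- ref[1] + stats::runif(1, -1.2, 1.2) * R
        cy <- ref[2] + stats::runif(1, -1.2, 1.2) * R
      } else {
        cx <- stats::runif(1, 1.3 * R, n - 1.3 * R)
        cy <- stats::runif(1, 1.3 * R, n - 1.3 * R)
      }
      if (cx > 1.2 * R && cx < n - 1.2 * R && cy > 1.2 * R &&
            cy < n - 1.2 * R) { ok <- TRUE; break }
    }
    if (!ok) next
    rot <- stats::runif(1, 0, 2 * pi)
    m <- shape_mask(k, cx, cy, R, n, rot = rot)
    if (!any(m)) next
    col <- class_color(k) * stats::runif(1, 0.8, 1.2)
    tex <- 1 + 0.15 * value_noise(n, 12)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[m] <- pmin(1, pmax(0, col[c] * tex[m]))
      img[, , c] <- ch
    }
    rows <- which(rowSums(m) > 0)
    colsx <- which(colSums(m) > 0)
    boxes <- rbind(boxes, c(min(colsx) - 1, min(rows) - 1, max(colsx),
                            max(rows)))
    cls <- c(cls, k)
    placed[[length(placed) + 1L]] <- c(cx, cy)
  }
  # degradations applied after the exact boxes are recorded
  img <- gaussian_blur(img, spec$blur_sigma)
  mu <- mean(img)
  img <- mu + spec$contrast * (img - mu)
  img[img < 0] <- 0
  img[img > 1] <- 1
  yolo <- if (nrow(boxes)) boxes_to_yolo(boxes, cls, n, n)
          else matrix(numeric(0), 0, 5)
  list(image = img, class = cls, boxes = boxes, yolo = yolo)
}

#' Write scenes as a YOLO-layout dataset
#'
#' Produces images/{split}/*.png, labels/{split}/*.txt and a data.yaml
#' manifest naming the class list and split folders.
#'
#' @param scenes list of scenes from [generate_scene()].
#' @param out_dir output directory.
#' @param split named ratios, e.g. c(train = 0.8, val = 0.2).
#' @param classes class names for the manifest.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return path of the manifest.
#' @export
write_dataset <- function(scenes, out_dir, split = c(train = 0.8, val = 0.2),
                          classes = scene_spec()$classes, overwrite = FALSE) {
  if (!length(scenes)) stop("no scenes to write")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory exists and is non-empty (use overwrite = TRUE)")
  ns <- length(scenes)
  ntr <- round(ns * split[[1]] / sum(split))
  assign_split <- c(rep(names(split)[1], ntr), rep(names(split)[2], ns - ntr))
  for (s in unique(assign_split)) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (i in seq_len(ns)) {
    s <- assign_split[i]
    stem <- sprintf("scene_%04d", i)
    png::writePNG(scenes[[i]]$image,
                  file.path(out_dir, "images", s, paste0(stem, ".png")))
    write_yolo_labels(scenes[[i]]$yolo,
                      file.path(out_dir, "labels", s, paste0(stem, ".txt")))
  }
  manifest <- list(path = normalizePath(out_dir),
                   train = "images/train", val = "images/val",
                   nc = length(classes), names = as.list(classes))
  yaml::write_yaml(manifest, file.path(out_dir, "data.yaml"))
  invisible(file.path(out_dir, "data.yaml"))
}

#' Read a dataset manifest
#'
#' @param dir dataset root containing data.yaml.
#' @export
read_dataset_manifest <- function(dir) {
  yaml::read_yaml(file.path(dir, "data.yaml"))
}

#' Emit perfect predictions for a written dataset
#'
#' Detections identical to the labels with confidence 1.0: the mAP = 1 oracle
#' input for the evaluator.
#'
#' @param dir dataset root.
#' @param split which split.
#' @param out_dir output directory for prediction files (class cx cy w h conf).
#' @export
perfect_predictions <- function(dir, split = "val",
                                out_dir = file.path(dir, "predictions",
                                                    split)) {
  lab_dir <- file.path(dir, "labels", split)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(lab_dir, pattern = "\\.txt$")) {
    m <- read_yolo_labels(file.path(lab_dir, f))
    out <- if (nrow(m)) cbind(m, conf = 1) else matrix(numeric(0), 0, 6)
    write_yolo_labels(out, file.path(out_dir, f))
  }
  invisible(out_dir)
}
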