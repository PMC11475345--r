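# YOLO-format dataset input/output and the train/val/test split.
#
# Behaviour classes follow the dataset column order:
# 0 = standing, 1 = walking, 2 = eating, 3 = lying.

#' Behaviour class names
#' @export
cattle_classes <- c("standing", "walking", "eating", "lying")

#' Construct a ground-truth / detection box table
#'
#' Boxes use the YOLO convention: class index plus normalized center-size
#' coordinates in `[0, 1]`.  `score` is `NA` for ground truth.
#'
#' @param cls integer class indices (0-based).
#' @param cx,cy,w,h normalized center and size.
#' @param score optional confidences in `[0, 1]`.
#' @param n_classes number of valid classes.
#' @return data.frame with columns `cls, cx, cy, w, h, score`.
#' @export
yolo_boxes <- function(cls = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric(), score = NA_real_,
                       n_classes = 4) {
  if (length(score) == 1 && length(cls) != 1)
    score <- rep(score, length(cls))
  df <- data.frame(cls = as.integer(cls), cx = as.numeric(cx),
                   cy = as.numeric(cy), w = as.numeric(w),
                   h = as.numeric(h), score = as.numeric(score))
  validate_boxes(df, n_classes)
  df
}

validate_boxes <- function(df, n_classes = 4, where = "box table") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$cls < 0 | df$cls >= n_classes))
    stop(where, ": class index outside 0..", n_classes - 1)
  if (any(df$cx < 0 | df$cx > 1 | df$cy < 0 | df$cy > 1))
    stop(where, ": center coordinates must lie in [0, 1]")
  if (any(df$w <= 0 | df$w > 1 | df$h <= 0 | df$h > 1))
    stop(where, ": sizes must lie in (0, 1]")
  invisible(df)
}

#' Convert normalized boxes to pixel corner coordinates
#'
#' Corners are continuous 0-based coordinates `(x1, y1, x2, y2)` clipped to
#' the image bounds, with `x1 < x2` and `y1 < y2`.
#'
#' @param boxes a [yolo_boxes()] table.
#' @param image_size `(H, W)` in pixels.
#' @return `n x 4` matrix of corners.
#' @export
boxes_to_pixels <- function(boxes, image_size) {
  H <- image_size[1]; W <- image_size[2]
  x1 <- pmax(0, (boxes$cx - boxes$w / 2) * W)
  y1 <- pmax(0, (boxes$cy - boxes$h / 2) * H)
  x2 <- pmin(W, (boxes$cx + boxes$w / 2) * W)
  y2 <- pmin(H, (boxes$cy + boxes$h / 2) * H)
  cbind(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Convert pixel corners back to normalized boxes
#'
#' @param corners `n x 4` matrix `(x1, y1, x2, y2)`.
#' @param cls class indices.
#' @param image_size `(H, W)`.
#' @param score optional scores.
#' @return a [yolo_boxes()] table.
#' @export
pixels_to_boxes <- function(corners, cls, image_size, score = NA_real_) {
  corners <- as_box_matrix(corners)
  H <- image_size[1]; W <- image_size[2]
  yolo_boxes(cls = cls,
             cx = (corners[, 1] + corners[, 3]) / 2 / W,
             cy = (corners[, 2] + corners[, 4]) / 2 / H,
             w = (corners[, 3] - corners[, 1]) / W,
             h = (corners[, 4] - corners[, 2]) / H,
             score = score)
}

#' Read a YOLO label file
#'
#' One line per object: `class cx cy w h`, whitespace separated and
#' normalized.  Malformed lines and out-of-range values raise errors naming
#' the offending line.
#'
#' @param path label-file path.
#' @param n_classes number of valid classes.
#' @return a [yolo_boxes()] table (empty for an empty file).
#' @export
read_yolo_labels <- function(path, n_classes = 4) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(yolo_boxes(n_classes = n_classes))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5)
      stop(path, " line ", i, ": expected 5 fields, found ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(path, " line ", i, ": non-numeric field")
    v
  })
  m <- do.call(rbind, rows)
  df <- data.frame(cls = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                   w = m[, 4], h = m[, 5], score = NA_real_)
  validate_boxes(df, n_classes, where = path)
  df
}

#' Write a YOLO label file
#'
#' Fixed 6-decimal format; [read_yolo_labels()] of the result reproduces the
#' input to 6 decimals, order preserved.
#'
#' @param boxes a [yolo_boxes()] table.
#' @param path output path.
#' @export
write_yolo_labels <- function(boxes, path) {
  validate_boxes(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   boxes$cls, boxes$cx, boxes$cy, boxes$w, boxes$h)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(ok)
}

#' Train/validation/test split specification
#'
#' @param train,val,test fractions summing to 1 (default 8:1:1).
#' @param seed RNG seed making the split deterministic.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train = 0.8, val = 0.1, test = 0.1, seed = 0) {
  if (abs(train + val + test - 1) > 1e-9)
    stop("split fractions must sum to 1")
  structure(list(train = train, val = val, test = test, seed = seed),
            class = "split_spec")
}

#' Randomly partition items into train/val/test
#'
#' A deterministic (seeded) disjoint and exhaustive partition with sizes
#' equal to the rounded fractions (the test set absorbs the rounding
#' remainder).
#'
#' @param items vector or list of items (length >= 3).
#' @param spec a [split_spec()].
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(items, spec = split_spec()) {
  n <- length(items)
  stopifnot(n >= 3)
  n_train <- round(spec$train * n)
  n_val <- round(spec$val * n)
  n_test <- n - n_train - n_val
  perm <- with_seed(spec$seed, sample.int(n))
  list(train = items[perm[seq_len(n_train)]],
       val = items[perm[n_train + seq_len(n_val)]],
       test = items[perm[n_train + n_val + seq_len(n_test)]])
}

# evaluate `expr` under a temporary RNG seed, restoring the global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Read a dataset configuration YAML
#'
#' The usual detection-dataset layout: `train`/`val`/`test` image
#' directories and a `names` class list.
#'
#' @param path YAML file path.
#' @return list with `train`, `val`, `test`, `names`.
#' @export
read_dataset_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$names)) stop(path, ": missing `names:` class list")
  cfg
}

#' Write a dataset configuration YAML
#'
#' @param cfg list with `train`, `val`, `test` paths and `names`.
#' @param path output path.
#' @export
write_dataset_yaml <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load an image + label pair
#'
#' @param image_path PNG image path.
#' @param label_path YOLO label path (defaults to the image path with a
#'   `.txt` extension).
#' @return a labeled image: list with `pixels` (H x W x 3 array in `[0,1]`),
#'   `boxes` and `source_id`.
#' @export
load_labeled_image <- function(image_path,
                               label_path = sub("\\.png$", ".txt", image_path)) {
  px <- png::readPNG(image_path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3]
  boxes <- if (file.exists(label_path)) read_yolo_labels(label_path)
           else yolo_boxes()
  labeled_image(px, boxes, source_id = basename(image_path))
}

#' Save an image + label pair
#'
#' @param img a labeled image.
#' @param image_path PNG output path.
#' @param label_path label output path.
#' @export
save_labeled_image <- function(img, image_path,
                               label_path = sub("\\.png$", ".txt", image_path)) {
  png::writePNG(img$pixels, image_path)
  write_yolo_labels(img$boxes, label_path)
  invisible(image_path)
}

#' Construct a labeled image
#'
#' @param pixels H x W x 3 array with values in `[0, 1]` (the 8-bit image
#'   scale divided by 255); H and W must be at least 32.
#' @param boxes a [yolo_boxes()] table.
#' @param source_id identifier string.
#' @return a `labeled_image` list.
#' @export
labeled_image <- function(pixels, boxes = yolo_boxes(), source_id = "") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 32, dim(pixels)[2] >= 32)
  validate_boxes(boxes)
  structure(list(pixels = pixels, boxes = boxes, source_id = source_id),
            class = "labeled_image")
}
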