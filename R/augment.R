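# Standard training augmentation: random cropping, HSV colour jitter,
# Gaussian noise, horizontal flip and scaling.  Geometric transforms remap
# the boxes consistently with the pixels; photometric ones leave them
# untouched.  Boxes whose remaining visible area after cropping falls below
# `min_visibility` of their original area are dropped.

#' Augmentation configuration
#'
#' @param p_crop,p_flip,p_scale probabilities of the geometric transforms.
#' @param crop_range fraction of each image dimension kept by the crop.
#' @param scale_range multiplicative resize range.
#' @param hsv_h,hsv_s,hsv_v HSV jitter gains (fractional: hue shift, and
#'   multiplicative ranges `1 +/- gain` for saturation/value).
#' @param noise_sd_max Gaussian pixel-noise sd upper bound (fraction of the
#'   dynamic range); sd is drawn uniformly from `[0, noise_sd_max]`.
#' @param p_hsv,p_noise probabilities of the photometric transforms.
#' @param min_visibility minimum visible-area fraction for a box to survive
#'   a crop.
#' @return an `augment_config` list.
#' @export
augment_config <- function(p_crop = 0.5, p_flip = 0.5, p_scale = 0.3,
                           crop_range = c(0.6, 1), scale_range = c(0.75, 1.25),
                           hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                           noise_sd_max = 0.05, p_hsv = 0.7, p_noise = 0.3,
                           min_visibility = 0.2) {
  structure(list(p_crop = p_crop, p_flip = p_flip, p_scale = p_scale,
                 crop_range = crop_range, scale_range = scale_range,
                 hsv_h = hsv_h, hsv_s = hsv_s, hsv_v = hsv_v,
                 noise_sd_max = noise_sd_max, p_hsv = p_hsv,
                 p_noise = p_noise, min_visibility = min_visibility),
            class = "augment_config")
}

# nearest-neighbour resize of an (H, W, 3) array
resize_nn <- function(px, H2, W2) {
  H <- dim(px)[1]; W <- dim(px)[2]
  yi <- pmin(H, pmax(1, round((seq_len(H2) - 0.5) * H / H2 + 0.5)))
  xi <- pmin(W, pmax(1, round((seq_len(W2) - 0.5) * W / W2 + 0.5)))
  px[yi, xi, , drop = FALSE]
}

rgb_to_hsv_arr <- function(px) {
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

hsv_to_rgb_arr <- function(hsv, d) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = d)
}

#' Augment a labeled image
#'
#' Applies (with the configured probabilities, in order) random crop,
#' scaling, horizontal flip, HSV jitter and Gaussian noise.  Geometry and
#' labels stay consistent; re-deriving an object's tight box from the
#' transformed pixels matches the transformed label.
#'
#' @param img a [labeled_image()].
#' @param cfg an [augment_config()]; with all probabilities 0 the image is
#'   returned unchanged.
#' @param seed optional seed for a reproducible draw.
#' @return an augmented [labeled_image()].
#' @export
augment <- function(img, cfg = augment_config(), seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, augment(img, cfg)))
  px <- img$pixels; boxes <- img$boxes
  H <- dim(px)[1]; W <- dim(px)[2]
  # random crop
  if (stats::runif(1) < cfg$p_crop) {
    fh <- stats::runif(1, cfg$crop_range[1], cfg$crop_range[2])
    fw <- stats::runif(1, cfg$crop_range[1], cfg$crop_range[2])
    ch <- round(H * fh); cw <- round(W * fw)
    if (ch < 32 || cw < 32)
      stop("crop window smaller than 32 px; raise crop_range")
    y0 <- sample.int(H - ch + 1, 1) - 1L
    x0 <- sample.int(W - cw + 1, 1) - 1L
    px <- px[y0 + seq_len(ch), x0 + seq_len(cw), , drop = FALSE]
    if (nrow(boxes) > 0) {
      corners <- boxes_to_pixels(boxes, c(H, W))
      area0 <- (corners[, 3] - corners[, 1]) * (corners[, 4] - corners[, 2])
      nx1 <- pmax(corners[, 1] - x0, 0); ny1 <- pmax(corners[, 2] - y0, 0)
      nx2 <- pmin(corners[, 3] - x0, cw); ny2 <- pmin(corners[, 4] - y0, ch)
      vis <- pmax(0, nx2 - nx1) * pmax(0, ny2 - ny1) / area0
      keep <- vis >= cfg$min_visibility & nx2 > nx1 & ny2 > ny1
      boxes <- if (any(keep)) {
        pixels_to_boxes(cbind(nx1, ny1, nx2, ny2)[keep, , drop = FALSE],
                        boxes$cls[keep], c(ch, cw), boxes$score[keep])
      } else yolo_boxes()
    }
    H <- ch; W <- cw
  }
  # scaling (pure resize: normalized boxes are unchanged)
  if (stats::runif(1) < cfg$p_scale) {
    s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    H2 <- max(32, round(H * s)); W2 <- max(32, round(W * s))
    px <- resize_nn(px, H2, W2)
    H <- H2; W <- W2
  }
  # horizontal flip
  if (stats::runif(1) < cfg$p_flip) {
    px <- px[, rev(seq_len(W)), , drop = FALSE]
    if (nrow(boxes) > 0) boxes$cx <- 1 - boxes$cx
  }
  # HSV jitter (photometric; boxes unchanged)
  if (stats::runif(1) < cfg$p_hsv) {
    hsv <- rgb_to_hsv_arr(px)
    hsv[1, ] <- (hsv[1, ] + stats::runif(1, -cfg$hsv_h, cfg$hsv_h)) %% 1
    hsv[2, ] <- pmin(1, pmax(0, hsv[2, ] * stats::runif(1, 1 - cfg$hsv_s, 1 + cfg$hsv_s)))
    hsv[3, ] <- pmin(1, pmax(0, hsv[3, ] * stats::runif(1, 1 - cfg$hsv_v, 1 + cfg$hsv_v)))
    px <- hsv_to_rgb_arr(hsv, dim(px))
  }
  # Gaussian noise
  if (stats::runif(1) < cfg$p_noise) {
    sd <- stats::runif(1, 0, cfg$noise_sd_max)
    px <- pmin(pmax(px + array(stats::rnorm(length(px), 0, sd), dim(px)), 0), 1)
  }
  labeled_image(px, boxes, img$source_id)
}
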