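# Synthetic labeled scenes.
#
# The generator emulates the structure of paddock photographs the detector
# is trained on: a textured ground/vegetation background and several
# animal-like textured blobs with class-specific silhouettes
# (standing = tall body on legs, walking = body with offset legs,
# eating = head lowered to the ground, lying = low flat ellipse), with
# optional constructed partial occlusion between consecutive instances.
# Ground-truth boxes are tight around the painted silhouette, so augmented
# copies can be re-verified geometrically.

# low-frequency random field in [0,1], (H x W)
smooth_noise <- function(H, W, cells = 6) {
  gh <- max(2, cells); gw <- max(2, cells)
  coarse <- matrix(stats::runif(gh * gw), gh, gw)
  # bilinear upsample to H x W
  yi <- seq(1, gh, length.out = H)
  xi <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(yi), gh - 1); x0 <- pmin(floor(xi), gw - 1)
  fy <- yi - y0; fx <- xi - x0
  a <- coarse[cbind(rep(y0, W), rep(x0, each = H))]
  b <- coarse[cbind(rep(y0 + 1, W), rep(x0, each = H))]
  cc <- coarse[cbind(rep(y0, W), rep(x0 + 1, each = H))]
  d <- coarse[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
  fyr <- rep(fy, W); fxr <- rep(fx, each = H)
  matrix(a * (1 - fyr) * (1 - fxr) + b * fyr * (1 - fxr) +
         cc * (1 - fyr) * fxr + d * fyr * fxr, H, W)
}

# class-specific silhouette mask on a local grid of size (bh x bw)
animal_mask <- function(cls, bh, bw) {
  m <- matrix(FALSE, bh, bw)
  yy <- matrix(seq_len(bh), bh, bw)
  xx <- matrix(seq_len(bw), bh, bw, byrow = TRUE)
  ell <- function(cy, cx, ry, rx) ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  rect <- function(y1, y2, x1, x2) yy >= y1 & yy <= y2 & xx >= x1 & xx <= x2
  if (cls == 3L) {  # lying: low flat ellipse filling the box
    m <- ell(bh * 0.55, bw * 0.5, bh * 0.42, bw * 0.48)
  } else {
    # body in the upper part, legs below
    m <- ell(bh * 0.38, bw * 0.5, bh * 0.30, bw * 0.44)
    leg_w <- max(1, round(bw * 0.07))
    leg_x <- if (cls == 1L) {  # walking: legs offset / spread
      round(bw * c(0.18, 0.38, 0.62, 0.88))
    } else {
      round(bw * c(0.22, 0.36, 0.64, 0.78))
    }
    for (lx in leg_x)
      m <- m | rect(round(bh * 0.5), bh, max(1, lx - leg_w), min(bw, lx + leg_w))
    if (cls == 2L) {  # eating: head lowered to the ground at the front
      m <- m | rect(round(bh * 0.35), bh,
                    round(bw * 0.86), bw)
    }
  }
  m
}

#' Generate a synthetic labeled scene
#'
#' @param n_instances number of animals to paint (0 gives background only).
#' @param image_size `(H, W)` in pixels (at least 32 each).
#' @param occlusion_prob probability that an instance is placed to overlap
#'   the previous one by at least 30% of the smaller box area.
#' @param classes candidate class indices sampled uniformly.
#' @param size_range instance height as a fraction of the image height.
#' @param seed optional seed; when given the scene is a pure function of it.
#' @return a [labeled_image()] with tight ground-truth boxes.
#' @export
generate_synthetic_scene <- function(n_instances = 3, image_size = c(128, 128),
                                     occlusion_prob = 0.3, classes = 0:3,
                                     size_range = c(0.25, 0.5), seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_synthetic_scene(
    n_instances, image_size, occlusion_prob, classes, size_range)))
  H <- image_size[1]; W <- image_size[2]
  stopifnot(H >= 32, W >= 32, n_instances >= 0)
  base <- smooth_noise(H, W, 5)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- 0.35 + 0.25 * base
  px[, , 2] <- 0.45 + 0.25 * base
  px[, , 3] <- 0.25 + 0.15 * base
  boxes <- NULL
  prev_box <- NULL
  for (i in seq_len(n_instances)) {
    cls <- sample(classes, 1)
    bh <- round(stats::runif(1, size_range[1], size_range[2]) * H)
    asp <- stats::runif(1, 1.1, 1.5)            # cattle are wider than tall
    if (cls == 3L) asp <- stats::runif(1, 1.5, 2.0)
    bw <- min(W - 2, round(bh * asp))
    bh <- min(H - 2, max(12, bh)); bw <- max(12, bw)
    occlude <- !is.null(prev_box) && stats::runif(1) < occlusion_prob
    if (occlude) {
      # constructed partial occlusion: align vertically with the previous
      # instance and solve for the horizontal offset giving the target
      # overlap fraction of the smaller placement box (enough to occlude,
      # while the earlier instance stays substantially visible)
      v <- stats::runif(1, 0.40, 0.55)
      y1 <- min(max(1, prev_box[1]), H - bh)
      ih <- max(1, min(prev_box[3], y1 + bh) - max(prev_box[1], y1))
      amin <- min(bh * bw, (prev_box[3] - prev_box[1]) *
                           (prev_box[4] - prev_box[2]))
      iw <- min(max(4, ceiling(v * amin / ih)), bw,
                prev_box[4] - prev_box[2])
      x1r <- prev_box[4] - iw              # overlap the previous right edge
      x1l <- prev_box[2] - bw + iw         # or its left edge
      x1 <- if (x1r >= 1 && x1r + bw <= W) x1r else x1l
      x1 <- min(max(1, round(x1)), W - bw)
    } else {
      y1 <- sample.int(max(1, H - bh), 1)
      x1 <- sample.int(max(1, W - bw), 1)
      y1 <- min(max(1, y1), H - bh); x1 <- min(max(1, x1), W - bw)
    }
    mask <- animal_mask(cls, bh, bw)
    tone <- stats::runif(1, 0.15, 0.85)
    tex <- smooth_noise(bh, bw, 4) * 0.25
    col <- c(tone, tone * stats::runif(1, 0.6, 0.9), tone * stats::runif(1, 0.5, 0.8))
    sel <- which(mask, arr.ind = TRUE)
    for (ch in 1:3) {
      idx <- cbind(sel[, 1] + y1 - 1, sel[, 2] + x1 - 1, ch)
      px[idx] <- pmin(1, pmax(0, col[ch] + tex[sel]))
    }
    # tight box around the painted silhouette
    ys <- range(sel[, 1]) + y1 - 1; xs <- range(sel[, 2]) + x1 - 1
    bx <- c(ys[1] - 1, xs[1] - 1, ys[2], xs[2])  # 0-based y1,x1,y2,x2
    prev_box <- c(y1, x1, y1 + bh, x1 + bw)
    boxes <- rbind(boxes, c(cls, (bx[2] + bx[4]) / 2 / W, (bx[1] + bx[3]) / 2 / H,
                            (bx[4] - bx[2]) / W, (bx[3] - bx[1]) / H))
  }
  bdf <- if (is.null(boxes)) yolo_boxes()
         else yolo_boxes(cls = boxes[, 1], cx = boxes[, 2], cy = boxes[, 3],
                         w = boxes[, 4], h = boxes[, 5])
  labeled_image(px, bdf, source_id = sprintf("synthetic_%d", n_instances))
}

#' Generate a synthetic dataset
#'
#' @param n number of scenes.
#' @param image_size per-scene pixel size.
#' @param n_range instances per scene (inclusive range, sampled uniformly).
#' @param occlusion_prob see [generate_synthetic_scene()].
#' @param seed dataset seed.
#' @return list of [labeled_image()].
#' @export
generate_synthetic_dataset <- function(n = 16, image_size = c(128, 128),
                                       n_range = c(1, 4), occlusion_prob = 0.3,
                                       seed = 0) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    k <- sample(seq(n_range[1], n_range[2]), 1)
    img <- generate_synthetic_scene(k, image_size, occlusion_prob)
    img$source_id <- sprintf("synthetic_%03d", i)
    img
  }))
}
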