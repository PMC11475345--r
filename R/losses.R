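# IoU-family bounding-box regression measures.
#
# All functions work on pixel-coordinate corner boxes (x1, y1, x2, y2),
# either a length-4 vector or an n x 4 matrix (row-wise pairs), on
# continuous coordinates.  The training loss for a pair is 1 - measure.

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  stopifnot(ncol(b) == 4)
  b
}

check_boxes <- function(b, what = "box") {
  bad <- b[, 3] <= b[, 1] | b[, 4] <= b[, 2]
  if (any(bad)) warning("degenerate zero-area ", what, "; IoU treated as 0")
  bad
}

#' Intersection over union of axis-aligned boxes
#'
#' @param a,b corner boxes `(x1, y1, x2, y2)`: length-4 vectors or
#'   row-matched `n x 4` matrices.
#' @return IoU values in `[0, 1]`; degenerate zero-area boxes give 0 with a
#'   warning.
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  bad <- check_boxes(a, "first box") | check_boxes(b, "second box")
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  ua <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
        (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  out <- ifelse(ua > 0, inter / ua, 0)
  out[bad] <- 0
  out
}

#' Center-preserving auxiliary ("inner") box
#'
#' Scales a box about its center by `ratio`; the area scales by `ratio^2`.
#'
#' @param b corner box(es).
#' @param ratio scale factor (> 0; the usual working range is 0.5-1.5).
#' @return scaled box(es), same shape as the input.
#' @export
inner_box <- function(b, ratio) {
  stopifnot(ratio > 0)
  vec <- is.null(dim(b))
  b <- as_box_matrix(b)
  cx <- (b[, 1] + b[, 3]) / 2; cy <- (b[, 2] + b[, 4]) / 2
  hw <- (b[, 3] - b[, 1]) * ratio / 2; hh <- (b[, 4] - b[, 2]) * ratio / 2
  out <- cbind(cx - hw, cy - hh, cx + hw, cy + hh)
  if (vec && nrow(out) == 1) as.numeric(out) else out
}

#' Minimum-point-distance IoU
#'
#' `IoU - d1^2/(w^2 + h^2) - d2^2/(w^2 + h^2)` where `d1`/`d2` are the
#' Euclidean distances between the top-left and bottom-right corners of the
#' two boxes and `w`, `h` normalise them.  With `norm = "image"` (the
#' default) `w`, `h` are the input-frame dimensions; `norm = "gtbox"` uses
#' the second box's own width/height.
#'
#' @param pred,gt corner boxes.
#' @param frame_w,frame_h frame dimensions used by `norm = "image"`.
#' @param norm `"image"` or `"gtbox"`.
#' @return values in `(-2, 1]`; 1 iff the boxes coincide.
#' @export
mpdiou <- function(pred, gt, frame_w, frame_h, norm = c("image", "gtbox")) {
  norm <- match.arg(norm)
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  if (norm == "image") {
    stopifnot(frame_w > 0, frame_h > 0)
    den <- frame_w^2 + frame_h^2
  } else {
    den <- (gt[, 3] - gt[, 1])^2 + (gt[, 4] - gt[, 2])^2
  }
  d1 <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  d2 <- (pred[, 3] - gt[, 3])^2 + (pred[, 4] - gt[, 4])^2
  box_iou(pred, gt) - d1 / den - d2 / den
}

#' Inner-MPDIoU
#'
#' The minimum-point-distance measure with its overlap term computed on the
#' center-preserving auxiliary boxes (both boxes scaled by `ratio`), while
#' the corner-distance penalties stay on the original boxes.  `ratio = 1`
#' reduces exactly to [mpdiou()].  The training loss is `1 - inner_mpdiou`.
#'
#' @inheritParams mpdiou
#' @param ratio auxiliary-box scale factor.
#' @return measure values; 1 iff the boxes coincide (any ratio).
#' @export
inner_mpdiou <- function(pred, gt, frame_w, frame_h, ratio = 0.7,
                         norm = c("image", "gtbox")) {
  norm <- match.arg(norm)
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  if (norm == "image") {
    stopifnot(frame_w > 0, frame_h > 0)
    den <- frame_w^2 + frame_h^2
  } else {
    den <- (gt[, 3] - gt[, 1])^2 + (gt[, 4] - gt[, 2])^2
  }
  d1 <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  d2 <- (pred[, 3] - gt[, 3])^2 + (pred[, 4] - gt[, 4])^2
  box_iou(inner_box(pred, ratio), inner_box(gt, ratio)) - d1 / den - d2 / den
}

#' Complete IoU (CIoU)
#'
#' The YOLOv8 default criterion: IoU minus the squared center distance over
#' the squared enclosing-box diagonal, minus the aspect-ratio consistency
#' term `alpha * v`.
#'
#' @inheritParams mpdiou
#' @return CIoU values.
#' @export
ciou <- function(pred, gt) {
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  iou <- box_iou(pred, gt)
  pcx <- (pred[, 1] + pred[, 3]) / 2; pcy <- (pred[, 2] + pred[, 4]) / 2
  gcx <- (gt[, 1] + gt[, 3]) / 2; gcy <- (gt[, 2] + gt[, 4]) / 2
  rho2 <- (pcx - gcx)^2 + (pcy - gcy)^2
  cw <- pmax(pred[, 3], gt[, 3]) - pmin(pred[, 1], gt[, 1])
  chh <- pmax(pred[, 4], gt[, 4]) - pmin(pred[, 2], gt[, 2])
  c2 <- cw^2 + chh^2 + 1e-9
  wp <- pred[, 3] - pred[, 1]; hp <- pred[, 4] - pred[, 2]
  wg <- gt[, 3] - gt[, 1]; hg <- gt[, 4] - gt[, 2]
  v <- (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

#' Plain inner-IoU (overlap of the auxiliary boxes only)
#'
#' @inheritParams inner_mpdiou
#' @return IoU of the two ratio-scaled boxes.
#' @export
inner_iou <- function(pred, gt, ratio = 0.7) {
  box_iou(inner_box(pred, ratio), inner_box(gt, ratio))
}

# Analytic gradient of box_iou w.r.t. the first box's corners (n x 4).
grad_box_iou_pred <- function(pred, gt) {
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  iw <- pmin(pred[, 3], gt[, 3]) - pmax(pred[, 1], gt[, 1])
  ih <- pmin(pred[, 4], gt[, 4]) - pmax(pred[, 2], gt[, 2])
  pos <- iw > 0 & ih > 0
  inter <- pmax(0, iw) * pmax(0, ih)
  wp <- pred[, 3] - pred[, 1]; hp <- pred[, 4] - pred[, 2]
  ua <- wp * hp + (gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2]) - inter
  dI <- cbind(-ih * (pos & pred[, 1] >= gt[, 1]),
              -iw * (pos & pred[, 2] >= gt[, 2]),
               ih * (pos & pred[, 3] <= gt[, 3]),
               iw * (pos & pred[, 4] <= gt[, 4]))
  dA <- cbind(-hp, -wp, hp, wp)
  # d(I/U)/dz = (dI * U - I * (dA - dI)) / U^2
  out <- (dI * ua - inter * (dA - dI)) / ua^2
  out[ua <= 0, ] <- 0
  out
}

#' Gradient of the Inner-MPDIoU measure w.r.t. the predicted corners
#'
#' Analytic reverse-mode gradient used by the detection criterion; verified
#' against central finite differences in the test-suite.
#'
#' @inheritParams inner_mpdiou
#' @return `n x 4` matrix `d(inner_mpdiou)/d(x1, y1, x2, y2)` of the
#'   predicted box.
#' @export
grad_inner_mpdiou <- function(pred, gt, frame_w, frame_h, ratio = 0.7,
                              norm = c("image", "gtbox")) {
  norm <- match.arg(norm)
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  den <- if (norm == "image") frame_w^2 + frame_h^2
         else (gt[, 3] - gt[, 1])^2 + (gt[, 4] - gt[, 2])^2
  gi <- grad_box_iou_pred(inner_box(pred, ratio), inner_box(gt, ratio))
  # chain through the center-preserving scaling of the pred box
  a <- (1 + ratio) / 2; b <- (1 - ratio) / 2
  diou <- cbind(gi[, 1] * a + gi[, 3] * b,
                gi[, 2] * a + gi[, 4] * b,
                gi[, 1] * b + gi[, 3] * a,
                gi[, 2] * b + gi[, 4] * a)
  dpen <- cbind(2 * (pred[, 1] - gt[, 1]), 2 * (pred[, 2] - gt[, 2]),
                2 * (pred[, 3] - gt[, 3]), 2 * (pred[, 4] - gt[, 4])) / den
  diou - dpen
}
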