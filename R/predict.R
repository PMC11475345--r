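# Anchor-free decode of raw head outputs and non-maximum suppression.
#
# The regression branch predicts, for every grid cell, four discrete
# distributions over `reg_max` bins (distribution-focal regression); the
# decoded distance of each box side is the expectation of its distribution,
# in units of the level stride.  Boxes are reconstructed around the cell
# centers, class probabilities are sigmoids of the logits, and per-class
# greedy NMS removes overlapping detections.

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

# raw reg array (H, W, 4*reg_max) for one sample -> A x 4 pixel boxes,
# anchors ordered column-major (a = h + H*(w-1))
decode_level <- function(reg, stride, reg_max) {
  H <- dim(reg)[1]; W <- dim(reg)[2]
  A <- H * W
  rm_ <- matrix(reg, A, 4 * reg_max)
  bins <- 0:(reg_max - 1)
  dist <- matrix(0, A, 4)
  for (s in 1:4) {
    p <- softmax_rows(rm_[, (s - 1) * reg_max + seq_len(reg_max), drop = FALSE])
    dist[, s] <- p %*% bins
  }
  ax <- (rep(seq_len(W), each = H) - 0.5) * stride
  ay <- (rep(seq_len(H), W) - 0.5) * stride
  cbind(ax - dist[, 1] * stride, ay - dist[, 2] * stride,
        ax + dist[, 3] * stride, ay + dist[, 4] * stride)
}

#' Greedy non-maximum suppression
#'
#' @param boxes `n x 4` pixel-corner matrix.
#' @param scores confidences.
#' @param iou_thr suppression IoU threshold.
#' @return indices of the kept boxes, score-descending.
#' @export
nms <- function(boxes, scores, iou_thr = 0.5) {
  if (length(scores) == 0) return(integer(0))
  boxes <- as_box_matrix(boxes)
  o <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(o) > 0) {
    i <- o[1]
    keep <- c(keep, i)
    o <- o[-1]
    if (length(o) == 0) break
    ious <- box_iou(matrix(boxes[i, ], length(o), 4, byrow = TRUE),
                    boxes[o, , drop = FALSE])
    o <- o[ious <= iou_thr]
  }
  keep
}

#' Run a detector on images and decode detections
#'
#' @param model a `cbr_model`.
#' @param images a [labeled_image()], a list of them, or an
#'   `(H, W, 3[, N])` pixel array in `[0, 1]`.
#' @param conf_thr minimum class probability.
#' @param nms_iou per-class NMS threshold.
#' @return for a single image, a [yolo_boxes()] table with scores
#'   (possibly empty); for several, a list of tables.
#' @export
predict_boxes <- function(model, images, conf_thr = 0.25, nms_iou = 0.5) {
  single <- FALSE
  if (inherits(images, "labeled_image")) { images <- list(images); single <- TRUE }
  if (is.array(images) && length(dim(images)) == 3) {
    images <- list(labeled_image(images)); single <- TRUE
  }
  px <- lapply(images, function(im)
    if (inherits(im, "labeled_image")) im$pixels else im)
  H <- dim(px[[1]])[1]; W <- dim(px[[1]])[2]
  x <- array(0, c(H, W, 3, length(px)))
  for (i in seq_along(px)) x[, , , i] <- px[[i]]
  fw <- nn_forward(model$graph, x, training = FALSE)
  out <- lapply(seq_along(px), function(n) {
    boxes <- NULL; scores <- NULL; clss <- NULL
    for (lv in 1:3) {
      reg <- fw$outputs[[2 * lv - 1]]
      cls <- fw$outputs[[2 * lv]]
      rb <- decode_level(reg[, , , n, drop = TRUE], model$strides[lv],
                         model$reg_max)
      Hc <- dim(cls)[1]; Wc <- dim(cls)[2]
      pm <- 1 / (1 + exp(-matrix(cls[, , , n], Hc * Wc, model$nc)))
      best <- max.col(pm, ties.method = "first")
      bs <- pm[cbind(seq_len(nrow(pm)), best)]
      sel <- bs >= conf_thr
      if (any(sel)) {
        boxes <- rbind(boxes, rb[sel, , drop = FALSE])
        scores <- c(scores, bs[sel])
        clss <- c(clss, best[sel] - 1L)
      }
    }
    if (is.null(boxes)) return(yolo_boxes(n_classes = model$nc))
    # clip to the image
    boxes[, 1] <- pmax(0, pmin(W, boxes[, 1]))
    boxes[, 3] <- pmax(0, pmin(W, boxes[, 3]))
    boxes[, 2] <- pmax(0, pmin(H, boxes[, 2]))
    boxes[, 4] <- pmax(0, pmin(H, boxes[, 4]))
    ok <- boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2]
    boxes <- boxes[ok, , drop = FALSE]; scores <- scores[ok]; clss <- clss[ok]
    keep <- integer(0)
    for (cl in unique(clss)) {
      idx <- which(clss == cl)
      keep <- c(keep, idx[nms(boxes[idx, , drop = FALSE], scores[idx], nms_iou)])
    }
    keep <- keep[order(scores[keep], decreasing = TRUE)]
    if (length(keep) == 0) return(yolo_boxes(n_classes = model$nc))
    pixels_to_boxes(boxes[keep, , drop = FALSE], clss[keep], c(H, W),
                    score = scores[keep])
  })
  if (single) out[[1]] else out
}
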