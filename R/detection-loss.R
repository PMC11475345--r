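# Detection training criterion.
#
# Anchor-free YOLO-style loss: task-aligned assignment of grid cells to
# ground-truth boxes, then three components -
#   box: 1 - <measure> on assigned cells, where <measure> is selected by
#        the config key (ciou / inner_iou / mpdiou / inner_mpdiou),
#   cls: binary cross-entropy on all cells with the soft aligned targets,
#   dfl: distribution-focal cross-entropy to the two bins adjacent to the
#        target distance (applied to the overlap-term distances only; the
#        inner scaling never touches the distribution regression).
# Gains lambda_box = 7.5, lambda_cls = 0.5, lambda_dfl = 1.5.
# The function also returns the analytic gradients with respect to the raw
# head outputs, which feed [nn_backward()] during training.

tal_topk <- 10
tal_alpha <- 0.5
tal_beta <- 6

# box measure + gradient wrt pred corners for the selected criterion
box_measure <- function(key, pred, gt, frame_w, frame_h, ratio, norm) {
  switch(key,
    inner_mpdiou = inner_mpdiou(pred, gt, frame_w, frame_h, ratio, norm),
    mpdiou = mpdiou(pred, gt, frame_w, frame_h, norm),
    inner_iou = inner_iou(pred, gt, ratio),
    ciou = ciou(pred, gt),
    stop("unknown loss key: ", key))
}

box_measure_grad <- function(key, pred, gt, frame_w, frame_h, ratio, norm) {
  if (key == "inner_mpdiou")
    return(grad_inner_mpdiou(pred, gt, frame_w, frame_h, ratio, norm))
  if (key == "mpdiou")
    return(grad_inner_mpdiou(pred, gt, frame_w, frame_h, ratio = 1, norm))
  # central finite differences for the remaining measures
  pred <- as_box_matrix(pred)
  out <- matrix(0, nrow(pred), 4)
  eps <- 1e-4
  for (j in 1:4) {
    p1 <- pred; p1[, j] <- p1[, j] + eps
    p2 <- pred; p2[, j] <- p2[, j] - eps
    out[, j] <- (box_measure(key, p1, gt, frame_w, frame_h, ratio, norm) -
                 box_measure(key, p2, gt, frame_w, frame_h, ratio, norm)) /
                (2 * eps)
  }
  out
}

# flatten one sample of the interleaved (reg, cls) outputs
flatten_preds <- function(outputs, n, strides, reg_max, nc) {
  regs <- NULL; clss <- NULL; ax <- NULL; ay <- NULL; st <- NULL
  meta <- list()
  for (lv in 1:3) {
    reg <- outputs[[2 * lv - 1]]; cls <- outputs[[2 * lv]]
    H <- dim(reg)[1]; W <- dim(reg)[2]
    A <- H * W
    regs <- rbind(regs, matrix(reg[, , , n], A, 4 * reg_max))
    clss <- rbind(clss, matrix(cls[, , , n], A, nc))
    ax <- c(ax, (rep(seq_len(W), each = H) - 0.5) * strides[lv])
    ay <- c(ay, (rep(seq_len(H), W) - 0.5) * strides[lv])
    st <- c(st, rep(strides[lv], A))
    meta[[lv]] <- c(H = H, W = W, A = A)
  }
  list(reg = regs, cls = clss, ax = ax, ay = ay, stride = st, meta = meta)
}

# task-aligned assignment for one sample
assign_targets <- function(pred_boxes, cls_prob, ax, ay, gt_boxes, gt_cls) {
  ng <- nrow(gt_boxes)
  A <- length(ax)
  inside <- matrix(FALSE, A, ng)
  overlaps <- matrix(0, A, ng)
  align <- matrix(0, A, ng)
  for (g in seq_len(ng)) {
    inside[, g] <- ax > gt_boxes[g, 1] & ax < gt_boxes[g, 3] &
                   ay > gt_boxes[g, 2] & ay < gt_boxes[g, 4]
    gtm <- matrix(gt_boxes[g, ], A, 4, byrow = TRUE)
    overlaps[, g] <- box_iou(pred_boxes, gtm)
    align[, g] <- cls_prob[, gt_cls[g] + 1L]^tal_alpha *
                  overlaps[, g]^tal_beta
  }
  align[!inside] <- 0
  mask <- matrix(FALSE, A, ng)
  for (g in seq_len(ng)) {
    cand <- which(inside[, g])
    if (length(cand) == 0) next
    k <- min(tal_topk, length(cand))
    top <- cand[order(align[cand, g], decreasing = TRUE)[seq_len(k)]]
    mask[top[align[top, g] > 0 | seq_along(top) == 1], g] <- TRUE
  }
  # an anchor claimed by several boxes goes to the one it overlaps most
  multi <- rowSums(mask) > 1
  for (a in which(multi)) {
    g_keep <- which.max(ifelse(mask[a, ], overlaps[a, ], -1))
    mask[a, ] <- FALSE; mask[a, g_keep] <- TRUE
  }
  assigned_gt <- rep(NA_integer_, A)
  score <- numeric(A)
  for (g in seq_len(ng)) {
    sel <- which(mask[, g])
    if (length(sel) == 0) next
    amax <- max(align[sel, g]); omax <- max(overlaps[sel, g])
    norm <- if (amax > 0) align[sel, g] / amax * omax
            else rep(omax, length(sel))
    assigned_gt[sel] <- g
    score[sel] <- norm
  }
  list(assigned_gt = assigned_gt, score = score)
}

#' Detection loss (and its gradients) for a batch of raw predictions
#'
#' @param model a `cbr_model`.
#' @param outputs value of `nn_forward(model$graph, x, training = TRUE)$outputs`.
#' @param targets list (one per batch sample) of lists with `boxes`
#'   (`m x 4` pixel corners) and `cls` (0-based classes); `m = 0` allowed.
#' @param img_size `(H, W)` of the network input in pixels.
#' @param lambda the three component gains.
#' @return list with `total`, `components` (box/cls/dfl), and `grads` (six
#'   arrays aligned with the graph outputs, `d total / d raw`).
#' @export
detection_loss <- function(model, outputs, targets, img_size,
                           lambda = c(box = 7.5, cls = 0.5, dfl = 1.5)) {
  if (any(!vapply(outputs, function(o) all(is.finite(o)), logical(1))))
    stop("non-finite values in raw predictions (diverged training?)")
  N <- dim(outputs[[1]])[4]
  rm_ <- model$reg_max; nc <- model$nc
  key <- model$cfg$loss; ratio <- model$cfg$inner_ratio
  norm <- model$cfg$mpd_norm
  grads <- lapply(outputs, function(o) array(0, dim(o)))
  tot_box <- 0; tot_cls <- 0; tot_dfl <- 0
  bins <- 0:(rm_ - 1)
  for (n in seq_len(N)) {
    fp <- flatten_preds(outputs, n, model$strides, rm_, nc)
    A <- nrow(fp$reg)
    # softmax distributions and expected distances per side
    P <- vector("list", 4)
    dist <- matrix(0, A, 4)
    for (s in 1:4) {
      P[[s]] <- softmax_rows(fp$reg[, (s - 1) * rm_ + seq_len(rm_), drop = FALSE])
      dist[, s] <- P[[s]] %*% bins
    }
    pred_boxes <- cbind(fp$ax - dist[, 1] * fp$stride,
                        fp$ay - dist[, 2] * fp$stride,
                        fp$ax + dist[, 3] * fp$stride,
                        fp$ay + dist[, 4] * fp$stride)
    cls_prob <- 1 / (1 + exp(-fp$cls))
    tg <- targets[[n]]
    ng <- if (is.null(tg$boxes)) 0 else nrow(tg$boxes)
    Tmat <- matrix(0, A, nc)
    wsum <- 1
    asg <- NULL
    if (ng > 0) {
      asg <- assign_targets(pred_boxes, cls_prob, fp$ax, fp$ay,
                            tg$boxes, tg$cls)
      sel <- which(!is.na(asg$assigned_gt))
      if (length(sel) > 0) {
        Tmat[cbind(sel, tg$cls[asg$assigned_gt[sel]] + 1L)] <- asg$score[sel]
        wsum <- max(sum(asg$score), 1)
      }
    }
    # classification
    z <- fp$cls
    bce <- pmax(z, 0) - z * Tmat + log1p(exp(-abs(z)))
    tot_cls <- tot_cls + sum(bce) / wsum
    gcls <- (cls_prob - Tmat) / wsum
    # box + dfl on assigned anchors
    greg <- matrix(0, A, 4 * rm_)
    if (!is.null(asg)) {
      sel <- which(!is.na(asg$assigned_gt))
      if (length(sel) > 0) {
        gtb <- tg$boxes[asg$assigned_gt[sel], , drop = FALSE]
        pb <- pred_boxes[sel, , drop = FALSE]
        w <- asg$score[sel]
        mv <- box_measure(key, pb, gtb, img_size[2], img_size[1], ratio, norm)
        tot_box <- tot_box + sum(w * (1 - mv)) / wsum
        gmv <- box_measure_grad(key, pb, gtb, img_size[2], img_size[1],
                                ratio, norm)
        gcorner <- -gmv * (w / wsum)        # d box-loss / d corner
        # chain corners -> expected distances (bin units)
        sgn <- c(-1, -1, 1, 1)
        # dfl targets: distances from anchor to the gt sides, bin units
        tdist <- cbind((fp$ax[sel] - gtb[, 1]) / fp$stride[sel],
                       (fp$ay[sel] - gtb[, 2]) / fp$stride[sel],
                       (gtb[, 3] - fp$ax[sel]) / fp$stride[sel],
                       (gtb[, 4] - fp$ay[sel]) / fp$stride[sel])
        tdist <- pmin(pmax(tdist, 0), rm_ - 1 - 1e-3)
        dfl_n <- 0
        for (s in 1:4) {
          ddist <- gcorner[, s] * sgn[s] * fp$stride[sel]
          p <- P[[s]][sel, , drop = FALSE]
          # gradient of the box term through the softmax expectation
          gl_box <- p * (matrix(bins, length(sel), rm_, byrow = TRUE) -
                           dist[sel, s]) * ddist
          # distribution-focal term
          li <- floor(tdist[, s]); wl <- li + 1 - tdist[, s]; wr <- 1 - wl
          pli <- p[cbind(seq_along(sel), li + 1L)]
          pri <- p[cbind(seq_along(sel), pmin(li + 2L, rm_))]
          dfl_n <- dfl_n + sum(w * (-(wl * log(pmax(pli, 1e-12)) +
                                      wr * log(pmax(pri, 1e-12)))) / 4)
          coef <- unname(lambda["dfl"]) * w / (4 * wsum)
          onehot <- matrix(0, length(sel), rm_)
          onehot[cbind(seq_along(sel), li + 1L)] <- wl
          onehot[cbind(seq_along(sel), pmin(li + 2L, rm_))] <-
            onehot[cbind(seq_along(sel), pmin(li + 2L, rm_))] + wr
          gl_dfl <- (p - onehot) * coef
          cols <- (s - 1) * rm_ + seq_len(rm_)
          greg[sel, cols] <- greg[sel, cols] +
            unname(lambda["box"]) * gl_box + gl_dfl
        }
        tot_dfl <- tot_dfl + dfl_n / wsum
      }
    }
    # scatter flattened gradients back into the level arrays
    at <- 0
    for (lv in 1:3) {
      Hl <- fp$meta[[lv]]["H"]; Wl <- fp$meta[[lv]]["W"]; Al <- fp$meta[[lv]]["A"]
      rows <- at + seq_len(Al)
      grads[[2 * lv - 1]][, , , n] <- array(greg[rows, ], c(Hl, Wl, 4 * rm_))
      grads[[2 * lv]][, , , n] <-
        array(unname(lambda["cls"]) * gcls[rows, ], c(Hl, Wl, nc))
      at <- at + Al
    }
  }
  comp <- c(box = tot_box / N, cls = tot_cls / N, dfl = tot_dfl / N)
  total <- unname(lambda["box"] * comp["box"] + lambda["cls"] * comp["cls"] +
                  lambda["dfl"] * comp["dfl"])
  grads <- lapply(grads, function(g) g / N)
  list(total = unname(total), components = comp, grads = grads)
}
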