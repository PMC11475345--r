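# Detection evaluation: greedy matching, per-class average precision with
# all-point (precision-envelope) interpolation, precision/recall and
# mAP@0.5 = unweighted mean of the per-class APs.

#' Match detections to ground truth within one image
#'
#' Greedy one-to-one matching in descending score order: each detection
#' claims the yet-unmatched ground-truth box of the same class with the
#' highest IoU at or above `iou_thr` (ties broken by ground-truth index).
#'
#' @param det_boxes `n x 4` pixel-corner matrix of detections.
#' @param det_cls,det_scores detection classes and scores.
#' @param gt_boxes `m x 4` pixel-corner matrix of ground truth.
#' @param gt_cls ground-truth classes.
#' @param iou_thr IoU matching threshold (default 0.5).
#' @return list with logical `tp`/`fp` per detection (in the sorted order
#'   given by `order`), the permutation `order`, and `fn` (unmatched
#'   ground-truth count).
#' @export
match_detections <- function(det_boxes, det_cls, det_scores,
                             gt_boxes, gt_cls, iou_thr = 0.5) {
  nd <- if (is.null(det_boxes)) 0 else nrow(as_box_matrix(det_boxes))
  ng <- if (is.null(gt_boxes)) 0 else nrow(as_box_matrix(gt_boxes))
  if (nd == 0) return(list(tp = logical(0), fp = logical(0),
                           order = integer(0), fn = ng))
  det_boxes <- as_box_matrix(det_boxes)
  o <- order(det_scores, decreasing = TRUE)
  tp <- logical(nd)
  matched <- logical(ng)
  for (j in seq_len(nd)) {
    i <- o[j]
    if (ng == 0) next
    cand <- which(!matched & gt_cls == det_cls[i])
    if (length(cand) == 0) next
    ious <- box_iou(matrix(det_boxes[i, ], length(cand), 4, byrow = TRUE),
                    as_box_matrix(gt_boxes)[cand, , drop = FALSE])
    best <- which.max(ious)          # first max: ties go to lowest gt index
    if (ious[best] >= iou_thr) {
      tp[j] <- TRUE
      matched[cand[best]] <- TRUE
    }
  }
  list(tp = tp, fp = !tp, order = o, fn = sum(!matched))
}

#' Average precision from ranked true/false-positive flags
#'
#' Area under the precision-recall curve with all-point interpolation (the
#' running-maximum precision envelope integrated over recall).
#'
#' @param tp,fp logical flags in descending-score order.
#' @param n_gt number of ground-truth objects of the class.
#' @return AP in `[0, 1]`; `NA` when `n_gt == 0` and there are no
#'   detections (undefined class, excluded from mAP).
#' @export
average_precision <- function(tp, fp, n_gt) {
  if (n_gt == 0) return(if (length(tp) == 0) NA_real_ else 0)
  if (length(tp) == 0) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # precision envelope, integrated over the recall steps
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Evaluate a detector over a labeled dataset
#'
#' Detections are pooled over images per class, ranked by confidence, and
#' scored at the given IoU threshold; mAP@0.5 is the unweighted mean of the
#' defined per-class APs.  The single reported precision/recall operating
#' point is the confidence maximising F1 over the pooled ranking.
#'
#' @param detector function `(labeled_image) -> data.frame` with columns
#'   `cls, cx, cy, w, h, score` (e.g. a wrapper around [predict_boxes()]).
#' @param dataset non-empty list of [labeled_image()].
#' @param iou_thr IoU matching threshold.
#' @param n_classes number of classes.
#' @return an `eval_report`: list with `map50`, `ap_per_class`,
#'   `precision`, `recall`, and per-class `tp`/`fp`/`fn` counts.
#' @export
evaluate_detector <- function(detector, dataset, iou_thr = 0.5,
                              n_classes = 4) {
  if (length(dataset) == 0) stop("empty dataset")
  scores_c <- rep(list(numeric(0)), n_classes)
  tp_c <- rep(list(logical(0)), n_classes)
  ngt <- numeric(n_classes)
  for (img in dataset) {
    H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
    dets <- detector(img)
    gt_corners <- boxes_to_pixels(img$boxes, c(H, W))
    for (cl in seq_len(n_classes) - 1L) {
      gsel <- img$boxes$cls == cl
      ngt[cl + 1] <- ngt[cl + 1] + sum(gsel)
      dsel <- which(dets$cls == cl)
      if (length(dsel) == 0) next
      dcorn <- boxes_to_pixels(dets[dsel, , drop = FALSE], c(H, W))
      m <- match_detections(dcorn, dets$cls[dsel], dets$score[dsel],
                            gt_corners[gsel, , drop = FALSE],
                            img$boxes$cls[gsel], iou_thr)
      scores_c[[cl + 1]] <- c(scores_c[[cl + 1]], dets$score[dsel][m$order])
      tp_c[[cl + 1]] <- c(tp_c[[cl + 1]], m$tp)
    }
  }
  ap <- numeric(n_classes)
  for (cl in seq_len(n_classes)) {
    o <- order(scores_c[[cl]], decreasing = TRUE)
    ap[cl] <- average_precision(tp_c[[cl]][o], !tp_c[[cl]][o], ngt[cl])
  }
  defined <- !is.na(ap)
  map50 <- mean(ap[defined])
  # pooled F1-maximising operating point
  all_scores <- unlist(scores_c); all_tp <- unlist(tp_c)
  o <- order(all_scores, decreasing = TRUE)
  ctp <- cumsum(all_tp[o]); cfp <- cumsum(!all_tp[o])
  prec <- ctp / (ctp + cfp); rec <- ctp / max(1, sum(ngt))
  f1 <- 2 * prec * rec / pmax(1e-12, prec + rec)
  k <- if (length(f1)) which.max(f1) else integer(0)
  tp_counts <- vapply(tp_c, sum, numeric(1))
  fp_counts <- vapply(tp_c, function(z) sum(!z), numeric(1))
  structure(list(map50 = map50, ap_per_class = ap,
                 precision = if (length(k)) prec[k] else NA_real_,
                 recall = if (length(k)) rec[k] else NA_real_,
                 conf_at_f1 = if (length(k)) all_scores[o][k] else NA_real_,
                 tp = tp_counts, fp = fp_counts, fn = ngt - tp_counts,
                 n_gt = ngt, classes = cattle_classes[seq_len(n_classes)]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>  mAP@0.5:", round(x$map50, 4), "\n")
  cat("  precision:", round(x$precision, 4),
      " recall:", round(x$recall, 4), "\n")
  for (i in seq_along(x$ap_per_class))
    cat(sprintf("  AP %-10s %s  (gt %d)\n", x$classes[i],
                format(round(x$ap_per_class[i], 4), nsmall = 4), x$n_gt[i]))
  invisible(x)
}
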