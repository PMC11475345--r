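# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# IoU by rasterization: count cells of a `res`-pitch grid whose centers lie
# inside a box; intersection/union from the counts, averaged over two
# half-cell grid offsets (antithetic shifts cancel the quantization bias).
raster_iou <- function(a, b, res = 0.01) {
  one <- function(off) {
    cells <- function(lo, hi) {
      # centers (i + 0.5) * res + off strictly inside (lo, hi)
      n <- floor((hi - off) / res - 0.5) - ceiling((lo - off) / res - 0.5) + 1
      max(0, n)
    }
    ia <- cells(a[1], a[3]) * cells(a[2], a[4])
    ib <- cells(b[1], b[3]) * cells(b[2], b[4])
    ix <- cells(max(a[1], b[1]), min(a[3], b[3]))
    iy <- cells(max(a[2], b[2]), min(a[4], b[4]))
    inter <- if (min(a[3], b[3]) > max(a[1], b[1]) &&
                 min(a[4], b[4]) > max(a[2], b[2])) ix * iy else 0
    if (ia + ib - inter <= 0) return(0)
    inter / (ia + ib - inter)
  }
  (one(0) + one(res / 2)) / 2
}

# independent scalar CIoU (different code path from the package's)
ciou_ref <- function(p, g) {
  ix <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  iy <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- ix * iy
  un <- (p[3] - p[1]) * (p[4] - p[2]) + (g[3] - g[1]) * (g[4] - g[2]) - inter
  iou <- inter / un
  rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
          ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
  c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
        (max(p[4], g[4]) - min(p[2], g[2]))^2 + 1e-9
  v <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2])) -
                   atan((p[3] - p[1]) / (p[4] - p[2])))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

# brute-force all-point AP: for every true positive, the best precision at
# any rank below or equal to ranks reaching at least its recall
ap_bruteforce <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  ap <- 0
  for (j in which(tp)) {
    ap <- ap + max(prec[j:length(tp)]) / n_gt
  }
  ap
}

# random valid box inside a frame
rand_box <- function(W = 100, H = 100, min_side = 2) {
  x1 <- runif(1, 0, W - min_side); y1 <- runif(1, 0, H - min_side)
  c(x1, y1, runif(1, x1 + min_side, W), runif(1, y1 + min_side, H))
}

# finite-difference gradient of a scalar box measure w.r.t. pred corners
fd_box_grad <- function(f, pred, eps = 1e-5) {
  out <- numeric(4)
  for (j in 1:4) {
    p1 <- pred; p1[j] <- p1[j] + eps
    p2 <- pred; p2[j] <- p2[j] - eps
    out[j] <- (f(p1) - f(p2)) / (2 * eps)
  }
  out
}

# a tiny model stub carrying just what detection_loss() needs
loss_model_stub <- function(loss = "inner_mpdiou", nc = 4, reg_max = 16,
                            ratio = 0.7) {
  list(strides = c(8, 16, 32), nc = nc, reg_max = reg_max,
       cfg = list(loss = loss, inner_ratio = ratio, mpd_norm = "image"))
}

# raw head outputs for an img_size-square input, all logits constant
blank_outputs <- function(img_size, nc = 4, reg_max = 16, cls_logit = -6) {
  out <- list()
  for (lv in 1:3) {
    s <- c(8, 16, 32)[lv]
    H <- img_size %/% s
    out[[2 * lv - 1]] <- array(0, c(H, H, 4 * reg_max, 1))
    out[[2 * lv]] <- array(cls_logit, c(H, H, nc, 1))
  }
  out
}
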