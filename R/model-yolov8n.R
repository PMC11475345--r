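# YOLOv8n reference graph: CSP/C2f backbone, SPPF, FPN-PAN neck, decoupled
# head with distribution-focal box regression.  Serves as the structural
# baseline the lightweight detector is compared against.

# C2f: split-transform-merge CSP block with n inner bottlenecks.
build_c2f <- function(g, from, c1, c2, n, shortcut, tag) {
  c <- c2 %/% 2
  cv1 <- nn_cba(g, from, c1, 2 * c, k = 1, tag = tag)
  a <- nn_slice(g, cv1, 1, c, tag = tag)
  b <- nn_slice(g, cv1, c + 1, 2 * c, tag = tag)
  parts <- c(a, b)
  cur <- b
  for (i in seq_len(n)) {
    h1 <- nn_cba(g, cur, c, c, k = 3, tag = tag)
    h2 <- nn_cba(g, h1, c, c, k = 3, tag = tag)
    cur <- if (shortcut) nn_sum(g, c(cur, h2), tag = tag) else h2
    parts <- c(parts, cur)
  }
  cat_id <- nn_concat(g, parts, tag = tag)
  nn_cba(g, cat_id, (2 + n) * c, c2, k = 1, tag = tag)
}

# SPPF: three serial 5x5 stride-1 max-pools, concatenated and projected.
build_sppf <- function(g, from, c1, c2, tag, n_pools = 3) {
  ch <- c1 %/% 2
  cv1 <- nn_cba(g, from, c1, ch, k = 1, tag = tag)
  pools <- cv1
  cur <- cv1
  for (i in seq_len(n_pools)) {
    cur <- nn_maxpool(g, cur, 5, 1, 2, tag = tag)
    pools <- c(pools, cur)
  }
  cat_id <- nn_concat(g, pools, tag = tag)
  nn_cba(g, cat_id, (n_pools + 1) * ch, c2, k = 1, tag = tag)
}

# Backbone of YOLOv8n (width multiple 0.25, depth multiple 1/3).
build_v8_backbone <- function(g, use_lska = FALSE, lska_cfg = NULL,
                              sppf_pools = 3) {
  w <- c(16, 32, 64, 128, 256)
  tagb <- "backbone"
  x <- nn_cba(g, 0, 3, w[1], k = 3, s = 2, tag = tagb)
  x <- nn_cba(g, x, w[1], w[2], k = 3, s = 2, tag = tagb)
  x <- build_c2f(g, x, w[2], w[2], 1, TRUE, tagb)
  x <- nn_cba(g, x, w[2], w[3], k = 3, s = 2, tag = tagb)
  p3 <- build_c2f(g, x, w[3], w[3], 2, TRUE, tagb)
  x <- nn_cba(g, p3, w[3], w[4], k = 3, s = 2, tag = tagb)
  p4 <- build_c2f(g, x, w[4], w[4], 2, TRUE, tagb)
  x <- nn_cba(g, p4, w[4], w[5], k = 3, s = 2, tag = tagb)
  x <- build_c2f(g, x, w[5], w[5], 1, TRUE, tagb)
  p5 <- if (use_lska) {
    build_sppf_lska(g, x, w[5], w[5], lska_cfg, tag = "sppf", n_pools = sppf_pools)
  } else {
    build_sppf(g, x, w[5], w[5], tag = "sppf", n_pools = sppf_pools)
  }
  list(ids = c(p3, p4, p5), channels = c(w[3], w[4], w[5]))
}

# FPN-PAN neck of YOLOv8n; `chs` are the P3/P4/P5 channel counts coming in,
# widths are the standard v8n neck output widths.
build_v8_neck <- function(g, ids, chs, widths = c(64, 128, 256)) {
  tagn <- "neck"
  p3 <- ids[1]; p4 <- ids[2]; p5 <- ids[3]
  up5 <- nn_upsample(g, p5, tag = tagn)
  cat1 <- nn_concat(g, c(up5, p4), tag = tagn)
  t4 <- build_c2f(g, cat1, chs[3] + chs[2], widths[2], 1, FALSE, tagn)
  up4 <- nn_upsample(g, t4, tag = tagn)
  cat2 <- nn_concat(g, c(up4, p3), tag = tagn)
  n3 <- build_c2f(g, cat2, widths[2] + chs[1], widths[1], 1, FALSE, tagn)
  d3 <- nn_cba(g, n3, widths[1], widths[1], k = 3, s = 2, tag = tagn)
  cat3 <- nn_concat(g, c(d3, t4), tag = tagn)
  n4 <- build_c2f(g, cat3, widths[1] + widths[2], widths[2], 1, FALSE, tagn)
  d4 <- nn_cba(g, n4, widths[2], widths[2], k = 3, s = 2, tag = tagn)
  cat4 <- nn_concat(g, c(d4, p5), tag = tagn)
  n5 <- build_c2f(g, cat4, widths[2] + chs[3], widths[3], 1, FALSE, tagn)
  list(ids = c(n3, n4, n5), channels = widths)
}

# Decoupled detection head of YOLOv8: per-level twin branches
# (box: 2 x Conv 3x3 + 1x1 to 4*reg_max ; cls: 2 x Conv 3x3 + 1x1 to nc).
build_v8_head <- function(g, ids, chs, nc, reg_max = 16) {
  tagh <- "head"
  c2 <- max(16, chs[1] %/% 4, reg_max * 4)
  c3 <- max(chs[1], min(nc, 100))
  outs <- integer(0)
  for (i in 1:3) {
    bx <- nn_cba(g, ids[i], chs[i], c2, k = 3, tag = tagh)
    bx <- nn_cba(g, bx, c2, c2, k = 3, tag = tagh)
    bx <- nn_conv(g, bx, c2, 4 * reg_max, k = 1, bias = TRUE, bias_init = 1,
                  tag = tagh)
    cl <- nn_cba(g, ids[i], chs[i], c3, k = 3, tag = tagh)
    cl <- nn_cba(g, cl, c3, c3, k = 3, tag = tagh)
    cl <- nn_conv(g, cl, c3, nc, k = 1, bias = TRUE,
                  bias_init = -log((1 - 0.01) / 0.01), tag = tagh)
    outs <- c(outs, bx, cl)
  }
  outs
}
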