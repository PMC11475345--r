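# Multi-Convolutional Focused Pyramid (MCFP) neck.
#
# All backbone levels are first aligned to a common channel count with 1x1
# convolutions.  A top-down pass (nearest up-sampling + add + 3x3
# refinement) propagates semantics downwards; the three aligned paths are
# then fused at the middle (stride-16) scale - the P3 path through ADown
# down-sampling, the P5 path through up-sampling - and passed through an
# inception-style parallel depthwise context block.  The contextualised map
# is finally "diffused": resampled back to every level, projected by a
# level-specific 1x1, and residually added, so each output scale carries
# the aggregated multi-scale context.

#' MCFP configuration
#'
#' @param neck_width common channel count after 1x1 alignment.
#' @param band_kernel length of the 1xk / kx1 depthwise band pair in the
#'   inception-style context block.
#' @param use_adown use ADown for the P3-path down-sampling (a plain
#'   stride-2 convolution otherwise).
#' @return an `mcfp_config` list.
#' @export
mcfp_config <- function(neck_width = 80, band_kernel = 7, use_adown = TRUE) {
  structure(list(neck_width = neck_width, band_kernel = band_kernel,
                 use_adown = use_adown),
            class = "mcfp_config")
}

# ADown: dual-branch halving of resolution.  A 2x2 stride-1 average pool
# spreads context, channels are split in two; one half goes through a 3x3
# stride-2 conv, the other through a 3x3 stride-2 max-pool and a 1x1 conv.
build_adown <- function(g, from, c_in, c_out, tag) {
  stopifnot(c_in %% 2 == 0, c_out %% 2 == 0)
  ap <- nn_avgpool(g, from, 2, 1, 0, tag = tag)
  h1 <- nn_slice(g, ap, 1, c_in %/% 2, tag = tag)
  h1 <- nn_cba(g, h1, c_in %/% 2, c_out %/% 2, k = 3, s = 2, tag = tag)
  h2 <- nn_slice(g, ap, c_in %/% 2 + 1, c_in, tag = tag)
  h2 <- nn_maxpool(g, h2, 3, 2, 1, tag = tag)
  h2 <- nn_cba(g, h2, c_in %/% 2, c_out %/% 2, k = 1, tag = tag)
  nn_concat(g, c(h1, h2), tag = tag)
}

adown_params <- function(c_in, c_out) {
  (9 * (c_in / 2) * (c_out / 2) + c_out) + ((c_in / 2) * (c_out / 2) + c_out)
}

# Inception-style context block: parallel depthwise branches (identity,
# 3x3, 1xk + kx1 bands) summed, a pointwise mixing conv, residual add.
build_inception_context <- function(g, from, w, band_k, tag) {
  dw3 <- nn_conv(g, from, w, w, k = 3, groups = w, bias = FALSE, tag = tag)
  dw3 <- nn_bn(g, dw3, w, tag = tag)
  band <- nn_conv(g, from, w, w, k = c(1, band_k), groups = w, bias = FALSE, tag = tag)
  band <- nn_conv(g, band, w, w, k = c(band_k, 1), groups = w, bias = FALSE, tag = tag)
  band <- nn_bn(g, band, w, tag = tag)
  mix <- nn_sum(g, c(from, dw3, band), tag = tag)
  pw <- nn_cba(g, mix, w, w, k = 1, tag = tag)
  nn_sum(g, c(from, pw), tag = tag)
}

# Full neck; `ids`/`chs` are the backbone P3/P4/P5 layer ids and channels.
build_mcfp <- function(g, ids, chs, cfg) {
  w <- cfg$neck_width
  tagn <- "neck"
  a3 <- nn_cba(g, ids[1], chs[1], w, k = 1, tag = tagn)
  a4 <- nn_cba(g, ids[2], chs[2], w, k = 1, tag = tagn)
  a5 <- nn_cba(g, ids[3], chs[3], w, k = 1, tag = tagn)
  # top-down semantic pass
  up5 <- nn_upsample(g, a5, tag = tagn)
  t4 <- nn_cba(g, nn_sum(g, c(a4, up5), tag = tagn), w, w, k = 3, tag = tagn)
  up4 <- nn_upsample(g, t4, tag = tagn)
  t3 <- nn_cba(g, nn_sum(g, c(a3, up4), tag = tagn), w, w, k = 3, tag = tagn)
  # fuse the three paths at the middle scale
  d3 <- if (cfg$use_adown) build_adown(g, t3, w, w, tagn)
        else nn_cba(g, t3, w, w, k = 3, s = 2, tag = tagn)
  fuse <- nn_sum(g, c(d3, t4, up5), tag = tagn)
  ctx <- build_inception_context(g, fuse, w, cfg$band_kernel, tagn)
  # diffusion: resample the context to each level, project, residual-add
  c3 <- nn_cba(g, nn_upsample(g, ctx, tag = tagn), w, w, k = 1, tag = tagn)
  n3 <- nn_sum(g, c(t3, c3), tag = tagn)
  c4 <- nn_cba(g, ctx, w, w, k = 1, tag = tagn)
  n4 <- nn_sum(g, c(t4, c4), tag = tagn)
  c5 <- nn_cba(g, nn_avgpool(g, ctx, 2, 2, 0, tag = tagn), w, w, k = 1, tag = tagn)
  n5 <- nn_sum(g, c(a5, c5), tag = tagn)
  list(ids = c(n3, n4, n5), channels = c(w, w, w))
}
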