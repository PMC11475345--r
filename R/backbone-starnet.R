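# StarNet backbone: four-stage hierarchy of star-operation blocks.
#
# The star operation maps a feature map through two parallel pointwise
# expansions and multiplies them elementwise, which implicitly lifts the
# representation into a high-dimensional feature space at the cost of a
# single elementwise product.  Each stage starts with an ordinary 3x3
# stride-2 convolution (the only spatial down-sampling), followed by a
# stack of star blocks whose depthwise 7x7 convolutions provide spatial
# context at stride 1.  Widths double at every stage.

#' StarNet configuration
#'
#' @param base_width channels produced by the stem; stage widths are
#'   `base_width * c(1, 2, 4, 8)`.
#' @param depths number of star blocks per stage (4 integers).
#' @param expansion pointwise channel expansion factor inside a star block.
#' @param dw_kernel depthwise kernel size (stride 1).
#' @param down_kernel kernel of the stride-2 stage convolutions.
#' @return a `starnet_config` list.
#' @export
starnet_config <- function(base_width = 18, depths = c(1, 2, 4, 2),
                           expansion = 4, dw_kernel = 7, down_kernel = 3) {
  stopifnot(length(depths) == 4, all(depths >= 0), base_width >= 1)
  structure(list(base_width = base_width, depths = depths,
                 expansion = expansion, dw_kernel = dw_kernel,
                 down_kernel = down_kernel),
            class = "starnet_config")
}

# One star block at width w (shape preserving, residual).
build_star_block <- function(g, from, w, expansion, dwk, tag) {
  dw1 <- nn_conv(g, from, w, w, k = dwk, groups = w, bias = FALSE, tag = tag)
  dw1 <- nn_bn(g, dw1, w, tag = tag)
  f1 <- nn_conv(g, dw1, w, expansion * w, k = 1, bias = TRUE, tag = tag)
  f1a <- nn_act(g, f1, "relu6", tag = tag)
  f2 <- nn_conv(g, dw1, w, expansion * w, k = 1, bias = TRUE, tag = tag)
  star <- nn_mul(g, c(f1a, f2), tag = tag)
  proj <- nn_conv(g, star, expansion * w, w, k = 1, bias = FALSE, tag = tag)
  proj <- nn_bn(g, proj, w, tag = tag)
  dw2 <- nn_conv(g, proj, w, w, k = dwk, groups = w, bias = FALSE, tag = tag)
  dw2 <- nn_bn(g, dw2, w, tag = tag)
  nn_sum(g, c(from, dw2), tag = tag)
}

# Closed-form parameter count of one star block (checked against the graph).
star_block_params <- function(w, expansion = 4, dwk = 7) {
  dw <- dwk^2 * w + 2 * w                     # depthwise conv + BN
  f12 <- 2 * (expansion * w^2 + expansion * w)  # two pointwise expansions
  proj <- expansion * w^2 + 2 * w             # projection + BN
  2 * dw + f12 + proj
}

# Full backbone: stem (stride 2) then 4 stages (strides 4/8/16/32);
# P3/P4/P5 are the outputs of the last three stages.
build_starnet <- function(g, cfg) {
  b <- cfg$base_width
  tagb <- "backbone"
  widths <- b * c(1, 2, 4, 8)
  x <- nn_cba(g, 0, 3, b, k = cfg$down_kernel, s = 2, act = "relu6", tag = tagb)
  prev <- b
  outs <- integer(4)
  for (st in 1:4) {
    w <- widths[st]
    x <- nn_cba(g, x, prev, w, k = cfg$down_kernel, s = 2, act = "relu6",
                tag = tagb)
    for (i in seq_len(cfg$depths[st]))
      x <- build_star_block(g, x, w, cfg$expansion, cfg$dw_kernel, tagb)
    outs[st] <- x
    prev <- w
  }
  list(ids = outs[2:4], channels = widths[2:4], stem_channels = b)
}
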