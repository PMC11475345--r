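# SPPF augmented with Large Separable Kernel Attention (LSKA).
#
# LSKA factorises a large k x k depthwise kernel into a cascade of 1-D
# depthwise convolutions: a plain pair (1 x k1 then k1 x 1 with
# k1 = 2d - 1) that captures local structure, followed by a dilated pair
# (1 x k2 then k2 x 1 with dilation d) that extends the receptive field,
# and a final 1x1 convolution producing a per-pixel attention map that
# multiplies the input (Hadamard product).

#' LSKA configuration
#'
#' @param k effective large-kernel size the cascade emulates.
#' @param d dilation rate of the long-range 1-D pair.
#' @return an `lska_config` with the derived 1-D kernel sizes: `k1 = 2d - 1`
#'   and `k2 = ceiling(k/d)` rounded down to the nearest odd size so all
#'   kernels stay odd and the cascade receptive field `k1 + d*(k2 - 1)`
#'   equals `k` at the default `k = 11, d = 3`.
#' @export
lska_config <- function(k = 11, d = 3) {
  k2 <- ceiling(k / d)
  if (k2 %% 2 == 0) k2 <- k2 - 1
  k2 <- max(k2, 1)
  structure(list(k = k, d = d, k1 = 2 * d - 1, k2 = k2,
                 rf = (2 * d - 1) + d * (k2 - 1)),
            class = "lska_config")
}

# Attention cascade on C channels; output has the input's shape.
build_lska <- function(g, from, C, cfg, tag) {
  k1 <- cfg$k1; k2 <- cfg$k2; d <- cfg$d
  x <- nn_conv(g, from, C, C, k = c(1, k1), groups = C, bias = FALSE, tag = tag)
  x <- nn_conv(g, x, C, C, k = c(k1, 1), groups = C, bias = FALSE, tag = tag)
  x <- nn_conv(g, x, C, C, k = c(1, k2), d = d, groups = C, bias = FALSE, tag = tag)
  x <- nn_conv(g, x, C, C, k = c(k2, 1), d = d, groups = C, bias = FALSE, tag = tag)
  att <- nn_conv(g, x, C, C, k = 1, bias = TRUE, tag = tag)
  nn_mul(g, c(att, from), tag = tag)
}

# Closed-form LSKA parameter count (depthwise cascades + the 1x1).
lska_params <- function(C, cfg) {
  C * (2 * cfg$k1 + 2 * cfg$k2) + C^2 + C
}

# SPPF with LSKA applied to the concatenated pyramid (the richest map),
# before the final projection.
build_sppf_lska <- function(g, from, c1, c2, lska_cfg, tag, n_pools = 3) {
  ch <- c1 %/% 2
  cv1 <- nn_cba(g, from, c1, ch, k = 1, tag = tag)
  pools <- cv1
  cur <- cv1
  for (i in seq_len(n_pools)) {
    cur <- nn_maxpool(g, cur, 5, 1, 2, tag = tag)
    pools <- c(pools, cur)
  }
  cat_id <- nn_concat(g, pools, tag = tag)
  ccat <- (n_pools + 1) * ch
  att <- build_lska(g, cat_id, ccat, lska_cfg, tag = tag)
  nn_cba(g, att, ccat, c2, k = 1, tag = tag)
}
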