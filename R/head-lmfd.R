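# Lightweight Multi-Scale Feature Fusion Detection head (LMFD).
#
# Each pyramid level is reduced by a level-specific 1x1 conv + GroupNorm +
# SiLU, then passed through a 3x3 conv + GroupNorm + SiLU whose parameters
# are shared across the three levels, and finally through shared 1x1
# regression (4*reg_max distribution bins) and classification (n_classes)
# convolutions.  A per-level learnable scalar on the regression branch
# absorbs the different dynamic range of the three strides (FCOS-style
# Scale).  GroupNorm keeps the head batch-size independent.

#' LMFD head configuration
#'
#' @param hidden head width after the level-specific 1x1 reduction.
#' @param gn_groups GroupNorm groups (must divide `hidden`).
#' @param reg_max number of distribution-focal bins per box side.
#' @param n_classes number of behaviour classes.
#' @return an `lmfd_config` list.
#' @export
lmfd_config <- function(hidden = 86, gn_groups = 2, reg_max = 16,
                        n_classes = 4) {
  stopifnot(hidden %% gn_groups == 0)
  structure(list(hidden = hidden, gn_groups = gn_groups, reg_max = reg_max,
                 n_classes = n_classes),
            class = "lmfd_config")
}

# Head builder; returns the interleaved (reg, cls) output ids per level.
build_lmfd <- function(g, ids, chs, cfg) {
  h <- cfg$hidden
  tagh <- "head"
  outs <- integer(0)
  shared_conv <- NA_integer_; shared_gn <- NA_integer_
  shared_reg <- NA_integer_; shared_cls <- NA_integer_
  for (i in 1:3) {
    x <- nn_conv(g, ids[i], chs[i], h, k = 1, bias = FALSE, tag = tagh)
    x <- nn_gn(g, x, h, cfg$gn_groups, tag = tagh)
    x <- nn_act(g, x, "silu", tag = tagh)
    if (i == 1) {
      shared_conv <- nn_conv(g, x, h, h, k = 3, bias = FALSE, tag = tagh)
      x <- shared_conv
      shared_gn <- nn_gn(g, x, h, cfg$gn_groups, tag = tagh)
      x <- shared_gn
    } else {
      x <- nn_conv(g, x, h, h, k = 3, bias = FALSE, tag = tagh,
                   share_with = shared_conv)
      x <- nn_add(g, "gn", x,
                  cfg = list(c = h, ngroups = cfg$gn_groups, eps = 1e-5),
                  share_with = shared_gn, tag = tagh)
    }
    x <- nn_act(g, x, "silu", tag = tagh)
    if (i == 1) {
      shared_reg <- nn_conv(g, x, h, 4 * cfg$reg_max, k = 1, bias = TRUE,
                            bias_init = 1, tag = tagh)
      reg <- shared_reg
      shared_cls <- nn_conv(g, x, h, cfg$n_classes, k = 1, bias = TRUE,
                            bias_init = -log((1 - 0.01) / 0.01), tag = tagh)
      cls <- shared_cls
    } else {
      reg <- nn_conv(g, x, h, 4 * cfg$reg_max, k = 1, bias = TRUE, tag = tagh,
                     share_with = shared_reg)
      cls <- nn_conv(g, x, h, cfg$n_classes, k = 1, bias = TRUE, tag = tagh,
                     share_with = shared_cls)
    }
    reg <- nn_scale(g, reg, init = 1, tag = tagh)
    outs <- c(outs, reg, cls)
  }
  outs
}

#' Closed-form parameter count of the LMFD head
#'
#' Audits the head parameter budget symbolically: level-specific 1x1 convs
#' and GroupNorms, the weight-shared 3x3 conv + GroupNorm, the shared 1x1
#' regression/classification convolutions (with biases) and the three
#' per-level scale scalars.
#'
#' @param chs input channels of the three pyramid levels.
#' @param cfg an [lmfd_config()].
#' @return integer parameter count.
#' @export
lmfd_param_count <- function(chs, cfg) {
  h <- cfg$hidden
  per_level <- sum(chs * h) + 3 * 2 * h          # 1x1 convs + GN affine
  shared <- 9 * h^2 + 2 * h                      # shared 3x3 + GN affine
  reg <- h * 4 * cfg$reg_max + 4 * cfg$reg_max
  cls <- h * cfg$n_classes + cfg$n_classes
  per_level + shared + reg + cls + 3
}
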