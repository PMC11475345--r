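#' @useDynLib cbryolo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Static-graph conv-net engine.
#
# A network is a list of primitive layers wired by index ("from" = ids of the
# producing layers, 0 = network input).  Feature maps are numeric arrays with
# dim (H, W, C, N).  The same graph supports three interpreters:
#   * nn_forward()  - numeric evaluation (training or inference mode),
#   * nn_backward() - reverse-mode gradients for all trainable parameters,
#   * nn_trace()    - symbolic shape propagation with exact per-layer
#                     parameter and FLOP accounting (no pixels touched).
# Parameter sharing (e.g. a detection-head conv applied at every pyramid
# level) is expressed with `share_with`: the layer re-uses the parameters of
# an earlier layer and gradients accumulate there.
# ---------------------------------------------------------------------------

nn_new <- function() {
  g <- new.env(parent = emptyenv())
  g$layers <- list()
  g$outputs <- integer(0)
  class(g) <- "nn_graph"
  g
}

nn_add <- function(g, type, from, cfg = list(), params = list(),
                   share_with = NA_integer_, tag = NULL, trainable = TRUE) {
  from <- as.integer(from)  # force now: `from` may itself append layers
  id <- length(g$layers) + 1L
  g$layers[[id]] <- list(id = id, type = type, from = as.integer(from),
                         cfg = cfg, params = params, share_with = share_with,
                         tag = tag, trainable = trainable)
  id
}

n_params_layer <- function(ly) {
  if (!is.na(ly$share_with) || !ly$trainable) return(0L)
  sum(vapply(ly$params, length, integer(1)))
}

#' Number of trainable parameters in a network graph
#'
#' Shared layers are counted once (at their owning layer) and frozen layers
#' (for example the fixed integral-projection conv of the DFL decode) are
#' excluded, so the count matches the usual "trainable parameters" summary of
#' deep-learning frameworks.
#'
#' @param g an `nn_graph`.
#' @param by_tag if `TRUE`, return a named vector of counts grouped by the
#'   layer tags assigned at construction time (untagged layers fall under
#'   `"other"`).
#' @return integer total, or named integer vector when `by_tag = TRUE`.
#' @export
nn_params <- function(g, by_tag = FALSE) {
  counts <- vapply(g$layers, n_params_layer, integer(1))
  if (!by_tag) return(sum(counts))
  tags <- vapply(g$layers, function(l) if (is.null(l$tag)) "other" else l$tag,
                 character(1))
  tapply(counts, tags, sum)
}

# -- parameter initialisation ------------------------------------------------

init_conv_w <- function(kh, kw, cin_g, cout) {
  fan_in <- kh * kw * cin_g
  array(stats::rnorm(kh * kw * cin_g * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin_g, cout))
}

# -- layer helpers used by the architecture builders -------------------------

nn_conv <- function(g, from, cin, cout, k = 3, s = 1, p = NULL, d = 1,
                    groups = 1, bias = TRUE, bias_init = 0, tag = NULL,
                    share_with = NA_integer_, trainable = TRUE, w_init = NULL) {
  if (length(k) == 1) k <- c(k, k)
  if (is.null(p)) p <- c(d * (k[1] - 1) %/% 2, d * (k[2] - 1) %/% 2)
  if (length(p) == 1) p <- c(p, p)
  params <- list()
  if (is.na(share_with)) {
    w <- if (is.null(w_init)) init_conv_w(k[1], k[2], cin %/% groups, cout) else w_init
    params$w <- w
    if (bias) params$b <- rep(bias_init, cout)
  }
  nn_add(g, "conv", from,
         cfg = list(k = k, s = s, p = p, d = d, groups = groups,
                    cin = cin, cout = cout, bias = bias),
         params = params, share_with = share_with, tag = tag,
         trainable = trainable)
}

nn_bn <- function(g, from, c, tag = NULL) {
  id <- nn_add(g, "bn", from, cfg = list(c = c, eps = 1e-5, momentum = 0.1),
               params = list(gamma = rep(1, c), beta = rep(0, c)), tag = tag)
  g$layers[[id]]$state <- list(rm = rep(0, c), rv = rep(1, c))
  id
}

nn_gn <- function(g, from, c, ngroups, tag = NULL) {
  stopifnot(c %% ngroups == 0)
  nn_add(g, "gn", from, cfg = list(c = c, ngroups = ngroups, eps = 1e-5),
         params = list(gamma = rep(1, c), beta = rep(0, c)), tag = tag)
}

nn_act <- function(g, from, fun = "silu", tag = NULL) {
  nn_add(g, "act", from, cfg = list(fun = fun), tag = tag)
}

nn_maxpool <- function(g, from, k, s, p, tag = NULL) {
  nn_add(g, "maxpool", from, cfg = list(k = k, s = s, p = p), tag = tag)
}

nn_avgpool <- function(g, from, k, s, p, tag = NULL) {
  nn_add(g, "avgpool", from, cfg = list(k = k, s = s, p = p), tag = tag)
}

nn_upsample <- function(g, from, tag = NULL) nn_add(g, "upsample", from, tag = tag)

nn_sum <- function(g, from, tag = NULL) nn_add(g, "add", from, tag = tag)

nn_mul <- function(g, from, tag = NULL) nn_add(g, "mul", from, tag = tag)

nn_concat <- function(g, from, tag = NULL) nn_add(g, "concat", from, tag = tag)

nn_slice <- function(g, from, ch1, ch2, tag = NULL) {
  nn_add(g, "slice", from, cfg = list(ch = c(ch1, ch2)), tag = tag)
}

nn_scale <- function(g, from, init = 1, tag = NULL) {
  nn_add(g, "scale", from, params = list(s = init), tag = tag)
}

# ConvBN(+act) composite used throughout the YOLO family
nn_cba <- function(g, from, cin, cout, k = 3, s = 1, p = NULL, d = 1,
                   groups = 1, act = "silu", tag = NULL) {
  id <- nn_conv(g, from, cin, cout, k, s, p, d, groups, bias = FALSE, tag = tag)
  id <- nn_bn(g, id, cout, tag = tag)
  if (!is.null(act)) id <- nn_act(g, id, act, tag = tag)
  id
}

param_owner <- function(g, i) {
  sw <- g$layers[[i]]$share_with
  if (is.na(sw)) i else sw
}

# -- numeric forward ---------------------------------------------------------

silu <- function(x) x / (1 + exp(-x))
sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Run a network graph forward
#'
#' @param g an `nn_graph`.
#' @param x input array with dim `(H, W, C, N)`.
#' @param training use batch statistics in batch-norm layers and keep the
#'   caches needed by [nn_backward()].
#' @return list with `outputs` (values of `g$outputs`) and, when
#'   `training = TRUE`, the cache of intermediate values.
#' @export
nn_forward <- function(g, x, training = FALSE) {
  stopifnot(length(dim(x)) == 4)
  L <- length(g$layers)
  vals <- vector("list", L + 1L)
  extras <- vector("list", L + 1L)
  vals[[1]] <- x
  for (i in seq_len(L)) {
    ly <- g$layers[[i]]
    ins <- lapply(ly$from, function(f) vals[[f + 1L]])
    pid <- param_owner(g, i)
    pp <- g$layers[[pid]]$params
    r <- layer_fw(ly, ins, pp, g, pid, training)
    vals[[i + 1L]] <- r$out
    extras[[i + 1L]] <- r$extra
  }
  outs <- lapply(g$outputs, function(o) vals[[o + 1L]])
  if (training) list(outputs = outs, vals = vals, extras = extras)
  else list(outputs = outs)
}

layer_fw <- function(ly, ins, pp, g, pid, training) {
  cfg <- ly$cfg
  x <- ins[[1]]
  switch(ly$type,
    conv = {
      b <- if (isTRUE(cfg$bias)) pp$b else NULL
      out <- conv2d_fw(x, dim(x), pp$w, b, cfg$k[1], cfg$k[2], cfg$s, cfg$s,
                       cfg$p[1], cfg$p[2], cfg$d, cfg$d, cfg$groups, cfg$cout)
      list(out = out, extra = NULL)
    },
    bn = {
      d <- dim(x)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N) x C
      if (training || is.null(g$layers[[pid]]$state)) {
        mu <- colMeans(xm)
        va <- colMeans(sweep(xm, 2, mu)^2)
        if (training) {
          st <- g$layers[[pid]]$state
          if (is.null(st)) st <- list(rm = mu * 0, rv = mu * 0 + 1)
          m <- cfg$momentum
          g$layers[[pid]]$state <- list(rm = (1 - m) * st$rm + m * mu,
                                        rv = (1 - m) * st$rv + m * va)
        }
      } else {
        st <- g$layers[[pid]]$state
        mu <- st$rm; va <- st$rv
      }
      istd <- 1 / sqrt(va + cfg$eps)
      xh <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
      ym <- sweep(sweep(xh, 2, pp$gamma, `*`), 2, pp$beta, `+`)
      out <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
      list(out = out, extra = if (training) list(xh = xh, istd = istd, d = d))
    },
    gn = {
      d <- dim(x); C <- d[3]; G <- cfg$ngroups; cg <- C %/% G
      out <- x; xh_all <- x; istd <- matrix(0, G, d[4]); mu <- istd
      for (n in seq_len(d[4])) for (gi in seq_len(G)) {
        idx <- ((gi - 1) * cg + 1):(gi * cg)
        blk <- x[, , idx, n, drop = FALSE]
        m <- mean(blk); v <- mean((blk - m)^2)
        is_ <- 1 / sqrt(v + cfg$eps)
        xh_all[, , idx, n] <- (blk - m) * is_
        istd[gi, n] <- is_; mu[gi, n] <- m
      }
      gam <- array(rep(pp$gamma, each = d[1] * d[2]), dim = d[1:3])
      bet <- array(rep(pp$beta, each = d[1] * d[2]), dim = d[1:3])
      for (n in seq_len(d[4])) {
        tmp <- xh_all[, , , n, drop = FALSE]
        dim(tmp) <- d[1:3]
        out[, , , n] <- tmp * gam + bet
      }
      list(out = out, extra = if (training) list(xh = xh_all, istd = istd))
    },
    act = {
      out <- switch(cfg$fun,
        silu = silu(x),
        relu6 = pmin(pmax(x, 0), 6),
        sigmoid = sigmoid_(x))
      list(out = out, extra = NULL)
    },
    maxpool = {
      r <- maxpool_fw(x, dim(x), cfg$k, cfg$s, cfg$p)
      list(out = r$out, extra = if (training) r$idx)
    },
    avgpool = list(out = avgpool_fw(x, dim(x), cfg$k, cfg$s, cfg$p), extra = NULL),
    upsample = list(out = upsample2x_fw(x, dim(x)), extra = NULL),
    add = {
      out <- ins[[1]]
      for (j in seq_along(ins)[-1]) out <- out + ins[[j]]
      list(out = out, extra = NULL)
    },
    mul = list(out = ins[[1]] * ins[[2]], extra = NULL),
    concat = {
      d1 <- dim(ins[[1]])
      cs <- vapply(ins, function(a) dim(a)[3], numeric(1))
      out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
      at <- 0
      for (j in seq_along(ins)) {
        out[, , (at + 1):(at + cs[j]), ] <- ins[[j]]
        at <- at + cs[j]
      }
      list(out = out, extra = NULL)
    },
    slice = list(out = x[, , cfg$ch[1]:cfg$ch[2], , drop = FALSE], extra = NULL),
    scale = list(out = x * pp$s, extra = NULL),
    stop("unknown layer type: ", ly$type)
  )
}

# -- reverse mode ------------------------------------------------------------

#' Back-propagate through a network graph
#'
#' @param g an `nn_graph`.
#' @param fw the value of `nn_forward(g, x, training = TRUE)`.
#' @param dout list of gradient arrays, one per entry of `g$outputs`.
#' @return named list: `grads` (per owning layer id, a list of parameter
#'   gradients) and `dx` (gradient w.r.t. the network input).
#' @export
nn_backward <- function(g, fw, dout, keep_dvals = FALSE) {
  L <- length(g$layers)
  dvals <- vector("list", L + 1L)
  grads <- vector("list", L)
  for (j in seq_along(g$outputs)) {
    o <- g$outputs[j] + 1L
    dvals[[o]] <- if (is.null(dvals[[o]])) dout[[j]] else dvals[[o]] + dout[[j]]
  }
  acc <- function(slot, val) if (is.null(slot)) val else slot + val
  for (i in rev(seq_len(L))) {
    gy <- dvals[[i + 1L]]
    if (is.null(gy)) next
    ly <- g$layers[[i]]
    ins <- lapply(ly$from, function(f) fw$vals[[f + 1L]])
    pid <- param_owner(g, i)
    pp <- g$layers[[pid]]$params
    r <- layer_bw(ly, ins, pp, gy, fw$vals[[i + 1L]], fw$extras[[i + 1L]])
    for (j in seq_along(ly$from)) {
      f <- ly$from[j] + 1L
      if (!is.null(r$dins[[j]])) dvals[[f]] <- acc(dvals[[f]], r$dins[[j]])
    }
    if (!is.null(r$dpar) && ly$trainable) {
      if (is.null(grads[[pid]])) grads[[pid]] <- r$dpar
      else grads[[pid]] <- mapply(`+`, grads[[pid]], r$dpar, SIMPLIFY = FALSE)
    }
  }
  out <- list(grads = grads, dx = dvals[[1]])
  if (keep_dvals) out$dvals <- dvals
  out
}

layer_bw <- function(ly, ins, pp, gy, y, extra) {
  cfg <- ly$cfg
  x <- ins[[1]]
  switch(ly$type,
    conv = {
      r <- conv2d_bw(x, dim(x), pp$w, gy, isTRUE(cfg$bias), cfg$k[1], cfg$k[2],
                     cfg$s, cfg$s, cfg$p[1], cfg$p[2], cfg$d, cfg$d,
                     cfg$groups, cfg$cout, TRUE)
      dpar <- list(w = array(r$dw, dim = dim(pp$w)))
      if (isTRUE(cfg$bias)) dpar$b <- as.numeric(r$db)
      list(dins = list(r$dx), dpar = dpar)
    },
    bn = {
      d <- extra$d
      gm <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = d[3])
      xh <- extra$xh; istd <- extra$istd
      dgamma <- colSums(gm * xh)
      dbeta <- colSums(gm)
      m <- nrow(gm)
      gxh <- sweep(gm, 2, pp$gamma, `*`)
      dxm <- sweep(gxh - matrix(colMeans(gxh), m, d[3], byrow = TRUE) -
                     xh * matrix(colMeans(gxh * xh), m, d[3], byrow = TRUE),
                   2, istd, `*`)
      dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
      list(dins = list(dx), dpar = list(gamma = dgamma, beta = dbeta))
    },
    gn = {
      d <- dim(x); C <- d[3]; G <- cfg$ngroups; cg <- C %/% G
      xh <- extra$xh; istd <- extra$istd
      gam <- array(rep(pp$gamma, each = d[1] * d[2]), dim = d[1:3])
      dgamma <- numeric(C); dbeta <- numeric(C)
      dx <- x
      for (n in seq_len(d[4])) {
        gyn <- gy[, , , n, drop = FALSE]
        dgamma <- dgamma + apply(gyn[, , , 1, drop = FALSE] * xh[, , , n, drop = FALSE],
                                 3, sum)
        dbeta <- dbeta + apply(gyn, 3, sum)
        gxh <- gy[, , , n, drop = FALSE]
        dim(gxh) <- d[1:3]
        gxh <- gxh * gam
        for (gi in seq_len(G)) {
          idx <- ((gi - 1) * cg + 1):(gi * cg)
          blkg <- gxh[, , idx, drop = FALSE]
          blkx <- xh[, , idx, n, drop = FALSE]
          dim(blkx) <- dim(blkg)
          m1 <- mean(blkg); m2 <- mean(blkg * blkx)
          dx[, , idx, n] <- (blkg - m1 - blkx * m2) * istd[gi, n]
        }
      }
      list(dins = list(dx), dpar = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      dx <- switch(cfg$fun,
        silu = { s <- sigmoid_(x); gy * (s * (1 + x * (1 - s))) },
        relu6 = gy * (x > 0 & x < 6),
        sigmoid = gy * y * (1 - y))
      list(dins = list(dx), dpar = NULL)
    },
    maxpool = list(dins = list(maxpool_bw(gy, extra, dim(x))), dpar = NULL),
    avgpool = list(dins = list(avgpool_bw(gy, dim(x), cfg$k, cfg$s, cfg$p)), dpar = NULL),
    upsample = list(dins = list(upsample2x_bw(gy, dim(x))), dpar = NULL),
    add = list(dins = rep(list(gy), length(ins)), dpar = NULL),
    mul = list(dins = list(gy * ins[[2]], gy * ins[[1]]), dpar = NULL),
    concat = {
      dins <- vector("list", length(ins)); at <- 0
      for (j in seq_along(ins)) {
        cj <- dim(ins[[j]])[3]
        dins[[j]] <- gy[, , (at + 1):(at + cj), , drop = FALSE]
        at <- at + cj
      }
      list(dins = dins, dpar = NULL)
    },
    slice = {
      dx <- array(0, dim = dim(x))
      dx[, , cfg$ch[1]:cfg$ch[2], ] <- gy
      list(dins = list(dx), dpar = NULL)
    },
    scale = list(dins = list(gy * pp$s), dpar = list(s = sum(gy * x))),
    stop("unknown layer type: ", ly$type)
  )
}

# -- symbolic trace: shapes, params, FLOPs -----------------------------------

#' Trace a graph symbolically: output shapes, parameters and FLOPs per layer
#'
#' FLOPs are reported under two conventions. `eq11` applies, to every
#' convolution, the per-layer formula
#' `Cin/g * Cout * Kh * Kw * Hout * Wout + Cout * Hout * Wout`
#' (one operation per multiply-accumulate plus the per-output add).
#' `table` is the whole-network profiler convention of the YOLO tooling:
#' two operations per multiply-accumulate on convolutions, plus the bias
#' adds; normalisation, activation, pooling and resampling layers are not
#' charged, as in the thop-style profilers those totals are quoted from.
#'
#' @param g an `nn_graph`.
#' @param input_shape `(H, W, C)` of the network input.
#' @return data.frame with one row per layer: type, tag, output shape,
#'   parameter count and FLOPs under both conventions.
#' @export
nn_trace <- function(g, input_shape) {
  L <- length(g$layers)
  shapes <- vector("list", L + 1L)
  shapes[[1]] <- input_shape
  out <- data.frame(id = seq_len(L), type = "", tag = "", H = 0, W = 0, C = 0,
                    params = 0, flops_eq11 = 0, flops_table = 0,
                    stringsAsFactors = FALSE)
  pool_shape <- function(s, k, st, p) {
    c((s[1] + 2 * p - k) %/% st + 1, (s[2] + 2 * p - k) %/% st + 1, s[3])
  }
  for (i in seq_len(L)) {
    ly <- g$layers[[i]]
    cfg <- ly$cfg
    s_in <- lapply(ly$from, function(f) shapes[[f + 1L]])
    s1 <- s_in[[1]]
    fl_eq <- 0; fl_tb <- 0
    s_out <- switch(ly$type,
      conv = {
        ho <- (s1[1] + 2 * cfg$p[1] - cfg$d * (cfg$k[1] - 1) - 1) %/% cfg$s + 1
        wo <- (s1[2] + 2 * cfg$p[2] - cfg$d * (cfg$k[2] - 1) - 1) %/% cfg$s + 1
        stopifnot(s1[3] == cfg$cin)
        mac <- (cfg$cin / cfg$groups) * cfg$cout * cfg$k[1] * cfg$k[2] * ho * wo
        fl_eq <- mac + cfg$cout * ho * wo
        fl_tb <- 2 * mac + if (isTRUE(cfg$bias)) cfg$cout * ho * wo else 0
        c(ho, wo, cfg$cout)
      },
      bn = s1, gn = s1, act = s1,
      maxpool = pool_shape(s1, cfg$k, cfg$s, cfg$p),
      avgpool = pool_shape(s1, cfg$k, cfg$s, cfg$p),
      upsample = c(2 * s1[1], 2 * s1[2], s1[3]),
      add = s1, mul = s1,
      concat = c(s1[1], s1[2], sum(vapply(s_in, function(s) s[3], numeric(1)))),
      slice = c(s1[1], s1[2], cfg$ch[2] - cfg$ch[1] + 1),
      scale = s1,
      stop("unknown layer type: ", ly$type)
    )
    shapes[[i + 1L]] <- s_out
    out$type[i] <- ly$type
    out$tag[i] <- if (is.null(ly$tag)) "other" else ly$tag
    out$H[i] <- s_out[1]; out$W[i] <- s_out[2]; out$C[i] <- s_out[3]
    out$params[i] <- n_params_layer(ly)
    out$flops_eq11[i] <- fl_eq
    out$flops_table[i] <- fl_tb
  }
  attr(out, "shapes") <- shapes
  out
}
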