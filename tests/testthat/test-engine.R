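# Numeric verification of the graph engine against a naive convolution
# oracle and central finite differences.

conv_ref <- function(x, w, b, s, p, d, groups) {
  H <- dim(x)[1]; W <- dim(x)[2]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cing <- dim(w)[3]; cout <- dim(w)[4]
  coutg <- cout / groups
  Ho <- (H + 2 * p - d * (kh - 1) - 1) %/% s + 1
  Wo <- (W + 2 * p - d * (kw - 1) - 1) %/% s + 1
  out <- array(0, c(Ho, Wo, cout, N))
  for (n in 1:N) for (co in 1:cout) {
    gi <- (co - 1) %/% coutg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in 1:cing) for (i in 1:kh) for (j in 1:kw) {
        hi <- (ho - 1) * s - p + (i - 1) * d + 1
        wi <- (wo - 1) * s - p + (j - 1) * d + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[hi, wi, gi * cing + ci, n] * w[i, j, ci, co]
      }
      out[ho, wo, co, n] <- acc
    }
  }
  out
}

test_that("convolution matches a naive oracle for plain/depthwise/dilated", {
  e <- asNamespace("cbryolo")
  set.seed(1)
  cases <- list(list(C = 4, N = 2, cout = 6, k = 3, s = 1, p = 1, d = 1, g = 1, bias = TRUE),
                list(C = 6, N = 1, cout = 6, k = 7, s = 1, p = 3, d = 1, g = 6, bias = FALSE),
                list(C = 4, N = 2, cout = 8, k = 3, s = 2, p = 1, d = 1, g = 2, bias = TRUE),
                list(C = 3, N = 1, cout = 3, k = 3, s = 1, p = 3, d = 3, g = 3, bias = FALSE))
  for (cs in cases) {
    x <- array(rnorm(9 * 9 * cs$C * cs$N), c(9, 9, cs$C, cs$N))
    w <- array(rnorm(cs$k^2 * (cs$C / cs$g) * cs$cout),
               c(cs$k, cs$k, cs$C / cs$g, cs$cout))
    b <- if (cs$bias) rnorm(cs$cout) else NULL
    got <- e$conv2d_fw(x, dim(x), w, b, cs$k, cs$k, cs$s, cs$s, cs$p, cs$p,
                       cs$d, cs$d, cs$g, cs$cout)
    expect_lt(max(abs(got - conv_ref(x, w, b, cs$s, cs$p, cs$d, cs$g))), 1e-10)
  }
})

test_that("every layer's parameter gradient passes a finite-difference check", {
  e <- asNamespace("cbryolo")
  set.seed(2)
  g <- e$nn_new()
  id <- e$nn_cba(g, 0, 3, 8, k = 3, s = 2)
  id2 <- e$nn_conv(g, id, 8, 8, k = 1)
  id2 <- e$nn_gn(g, id2, 8, 4)
  id2 <- e$nn_act(g, id2, "relu6")
  id3 <- e$nn_sum(g, c(id, id2))
  id4 <- e$nn_mul(g, c(id, id3))
  ids <- e$nn_scale(g, id4, init = 0.7)
  mp <- e$nn_maxpool(g, ids, 5, 1, 2)
  g$outputs <- mp
  x <- array(rnorm(12 * 12 * 3 * 2), c(12, 12, 3, 2))
  fw <- e$nn_forward(g, x, training = TRUE)
  gy <- array(rnorm(length(fw$outputs[[1]])), dim(fw$outputs[[1]]))
  bw <- e$nn_backward(g, fw, list(gy))
  f_all <- function() sum(e$nn_forward(g, x, training = TRUE)$outputs[[1]] * gy)
  eps <- 1e-5
  for (lid in seq_along(g$layers)) {
    pars <- g$layers[[lid]]$params
    if (length(pars) == 0) next
    for (nm in names(pars)) {
      obj <- pars[[nm]]
      idx <- sample(length(obj), min(3, length(obj)))
      fd <- vapply(idx, function(ii) {
        g$layers[[lid]]$params[[nm]][ii] <- obj[ii] + eps; a1 <- f_all()
        g$layers[[lid]]$params[[nm]][ii] <- obj[ii] - eps; a2 <- f_all()
        g$layers[[lid]]$params[[nm]][ii] <- obj[ii]
        (a1 - a2) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(fd - bw$grads[[lid]][[nm]][idx])), 1e-6)
    }
  }
})

test_that("the symbolic trace agrees with numeric forward shapes", {
  e <- asNamespace("cbryolo")
  set.seed(3)
  m <- build_model(cbr_config(img_size = 64), seed = 1)
  tr <- e$nn_trace(m$graph, c(64, 64, 3))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fw <- e$nn_forward(m$graph, x)
  for (j in seq_along(m$graph$outputs)) {
    o <- m$graph$outputs[j]
    expect_equal(unname(dim(fw$outputs[[j]])[1:3]),
                 unname(c(tr$H[o], tr$W[o], tr$C[o])))
  }
})
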