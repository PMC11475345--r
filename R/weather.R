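# Weather synthesis by atmospheric transmittance blending.
#
# A weathered image is the per-pixel convex combination
#   I(x) = J(x) * t(x) + A * (1 - t(x))
# of the clean image J and the atmospheric light A, where the transmittance
# map t encodes how much scene radiance survives the simulated atmosphere.
# Each weather kind is a recipe for (t, A) parameterised by a single
# `intensity` in [0, 1]; at intensity 0 every recipe degenerates to t = 1
# (no weather).  Both intensity and location of the disturbances are
# random.

weather_kinds <- c("rain", "fog", "flare", "overexposure", "snow")

#' Generate a transmittance map and atmospheric light for a weather kind
#'
#' Recipes: fog = smooth low-frequency field with mean `1 - 0.6*intensity`
#' (A near 0.9); rain = elongated angled streaks where t drops (A near 1);
#' snow = round flakes (A near 0.95); flare = radial falloff around a
#' random center (A = 1); overexposure = spatially uniform
#' `t = 1 - 0.5*intensity` (A = 1).
#'
#' @param kind one of `"rain"`, `"fog"`, `"flare"`, `"overexposure"`,
#'   `"snow"`.
#' @param image_size `(H, W)`.
#' @param intensity weather strength in `[0, 1]`; 0 gives `t == 1`.
#' @param seed optional seed for a reproducible map.
#' @return list with `t` (H x W in `[0, 1]`), `A` (scalar in `[0, 1]`) and
#'   `kind`.
#' @export
make_transmittance <- function(kind, image_size, intensity, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, make_transmittance(kind, image_size, intensity)))
  kind <- match.arg(kind, weather_kinds)
  stopifnot(intensity >= 0, intensity <= 1)
  H <- image_size[1]; W <- image_size[2]
  t <- matrix(1, H, W)
  A <- 1
  if (kind == "fog") {
    field <- smooth_noise(H, W, 5) - 0.5          # zero-mean modulation
    t <- 1 - 0.6 * intensity + 0.15 * intensity * field
    t <- t - (mean(t) - (1 - 0.6 * intensity))    # pin the mean exactly
    t <- pmin(pmax(t, 0), 1)
    A <- stats::runif(1, 0.8, 1.0)
  } else if (kind == "overexposure") {
    t <- matrix(1 - 0.5 * intensity, H, W)
    A <- 1
  } else if (kind == "flare") {
    cy <- stats::runif(1, 0.2, 0.8) * H; cx <- stats::runif(1, 0.2, 0.8) * W
    sig <- 0.35 * sqrt(H * W)
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    r2 <- (yy - cy)^2 + (xx - cx)^2
    t <- 1 - 0.85 * intensity * exp(-r2 / (2 * sig^2))
    A <- 1
  } else if (kind == "rain" || kind == "snow") {
    A <- if (kind == "rain") stats::runif(1, 0.85, 1.0)
         else stats::runif(1, 0.9, 1.0)
    n <- round(intensity * H * W / 220)
    drop <- 0.7 * intensity
    if (n > 0) for (i in seq_len(n)) {
      y <- sample.int(H, 1); x <- sample.int(W, 1)
      if (kind == "rain") {
        # elongated angled streak
        len <- sample(6:14, 1); ang <- stats::runif(1, pi / 3, 2 * pi / 3)
        ys <- round(y + sin(ang) * seq(0, len)); xs <- round(x + cos(ang) * seq(0, len))
        ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
        t[cbind(ys[ok], xs[ok])] <- pmax(0, t[cbind(ys[ok], xs[ok])] - drop)
      } else {
        # round flake
        r <- sample(1:2, 1)
        for (dy in -r:r) for (dx in -r:r) if (dy^2 + dx^2 <= r^2) {
          yy <- y + dy; xx <- x + dx
          if (yy >= 1 && yy <= H && xx >= 1 && xx <= W)
            t[yy, xx] <- max(0, t[yy, xx] - drop)
        }
      }
    }
  }
  list(t = t, A = A, kind = kind)
}

#' Blend a clean image with atmospheric light
#'
#' `I = J * t + A * (1 - t)` per pixel and channel: a convex combination,
#' so `min(J, A) <= I <= max(J, A)` elementwise and no clipping is needed
#' for inputs in `[0, 1]`.
#'
#' @param J clean image: `(H, W)` matrix or `(H, W, 3)` array in `[0, 1]`.
#' @param t transmittance map `(H, W)` in `[0, 1]`.
#' @param A atmospheric light, scalar in `[0, 1]`.
#' @return blended image, same shape as `J`.
#' @export
blend <- function(J, t, A) {
  stopifnot(all(J >= 0 & J <= 1), all(t >= 0 & t <= 1), A >= 0, A <= 1)
  dj <- dim(J)
  if (length(dj) == 3) {
    if (!all(dj[1:2] == dim(t))) stop("image / transmittance shape mismatch")
    tt <- array(rep(t, dj[3]), dim = dj)
  } else {
    if (!all(dj == dim(t))) stop("image / transmittance shape mismatch")
    tt <- t
  }
  J * tt + A * (1 - tt)
}

#' Apply random weather to a labeled image
#'
#' Photometric only: the boxes are untouched.
#'
#' @param img a [labeled_image()].
#' @param kind weather kind (default: sampled uniformly).
#' @param intensity strength in `[0, 1]` (default: uniform in
#'   `[0.3, 0.8]`, the "moderate" band).
#' @param seed optional seed.
#' @return weathered [labeled_image()]; the applied kind and intensity are
#'   stored in attributes `weather_kind` / `weather_intensity`.
#' @export
apply_weather <- function(img, kind = NULL, intensity = NULL, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, apply_weather(img, kind, intensity)))
  if (is.null(kind)) kind <- sample(weather_kinds, 1)
  if (is.null(intensity)) intensity <- stats::runif(1, 0.3, 0.8)
  wp <- make_transmittance(kind, dim(img$pixels)[1:2], intensity)
  out <- labeled_image(blend(img$pixels, wp$t, wp$A), img$boxes,
                       img$source_id)
  attr(out, "weather_kind") <- kind
  attr(out, "weather_intensity") <- intensity
  out
}

#' Weather-augment a fraction of a training split
#'
#' A deterministic (seeded) random subset of `round(fraction * N)` images
#' receives a weathered copy with a uniformly sampled kind.  By default the
#' copies extend the set (originals are kept); `mode = "replace"`
#' substitutes them.
#'
#' @param images list of [labeled_image()].
#' @param fraction subset fraction in `[0, 1]` (default 0.5).
#' @param kinds candidate weather kinds (non-empty).
#' @param mode `"extend"` or `"replace"`.
#' @param seed RNG seed.
#' @return list of labeled images.
#' @export
weatherize_split <- function(images, fraction = 0.5, kinds = weather_kinds,
                             mode = c("extend", "replace"), seed = 0) {
  mode <- match.arg(mode)
  if (length(kinds) == 0) stop("kinds must be a non-empty weather list")
  kinds <- vapply(kinds, function(k) match.arg(k, weather_kinds), "")
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(images)
  k <- round(fraction * n)
  if (k == 0) return(images)
  with_seed(seed, {
    pick <- sample.int(n, k)
    weathered <- lapply(pick, function(i)
      apply_weather(images[[i]], kind = sample(kinds, 1)))
    if (mode == "replace") {
      images[pick] <- weathered
      images
    } else {
      c(images, weathered)
    }
  })
}
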