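# SGD training loop with the standard detection hyper-parameters.

#' Training configuration
#'
#' Defaults are the usual single-stage detector settings: SGD with initial
#' learning rate 0.01, momentum 0.937, weight decay 5e-4, batch size 32,
#' 640 px inputs.  `epochs` defaults to 300 for full runs; the desk-scale
#' smoke tests use far fewer.  `workers` is accepted for interface parity
#' but computation here is single-threaded.
#'
#' @param lr0 initial learning rate.
#' @param lrf final learning rate as a fraction of `lr0` (linear decay).
#' @param momentum SGD momentum factor.
#' @param weight_decay L2 penalty on convolution weights.
#' @param batch batch size.
#' @param img_size training image size.
#' @param epochs number of epochs.
#' @param warmup_epochs linear warm-up length.
#' @param workers kept for interface compatibility (unused).
#' @param seed RNG seed covering shuffling and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                         weight_decay = 5e-4, batch = 32, img_size = 640,
                         epochs = 300, warmup_epochs = 3, workers = 12,
                         seed = 0) {
  stopifnot(lr0 > 0, momentum >= 0, momentum < 1, weight_decay >= 0,
            batch >= 1, img_size %% 32 == 0, epochs >= 1)
  structure(list(lr0 = lr0, lrf = lrf, momentum = momentum,
                 weight_decay = weight_decay, batch = batch,
                 img_size = img_size, epochs = epochs,
                 warmup_epochs = warmup_epochs, workers = workers,
                 seed = seed),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear warm-up over `warmup_epochs` (reaching `lr0` right after warm-up)
#' followed by linear decay to `lrf * lr0` at the final epoch; deterministic
#' and non-increasing after warm-up.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  wu <- cfg$warmup_epochs
  if (epoch < wu) return(cfg$lr0 * (epoch + 1) / (wu + 1))
  if (cfg$epochs <= wu + 1) return(cfg$lr0)
  frac <- (epoch - wu) / (cfg$epochs - 1 - wu)
  frac <- min(1, max(0, frac))
  cfg$lr0 * (1 - frac * (1 - cfg$lrf))
}

# stack a list of labeled images into an (H, W, 3, N) batch
stack_images <- function(imgs) {
  d <- dim(imgs[[1]]$pixels)
  x <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]$pixels
  x
}

image_targets <- function(img) {
  d <- dim(img$pixels)
  list(boxes = boxes_to_pixels(img$boxes, d[1:2]), cls = img$boxes$cls)
}

#' Train a detector
#'
#' Plain SGD with momentum and weight decay on the detection criterion
#' selected by the model configuration.  Fully seeded: data order and
#' parameter updates are reproducible, and two runs with the same seed give
#' identical first-epoch losses.
#'
#' @param model a `cbr_model` (modified in place and returned).
#' @param dataset list of [labeled_image()] of one common size.
#' @param cfg a [train_config()] (its `img_size` must match the data).
#' @param val_dataset optional validation set; when given, mAP@0.5 is
#'   logged each `val_every` epochs and the best epoch is reported.
#' @param val_every validation period in epochs.
#' @param verbose print a line per epoch.
#' @return list with `model`, `history` (per-epoch data.frame of loss
#'   components and learning rate) and `best_map` (if validated).
#' @export
train <- function(model, dataset, cfg = train_config(), val_dataset = NULL,
                  val_every = 10, verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  d <- dim(dataset[[1]]$pixels)
  img_size <- d[1:2]
  g <- model$graph
  set.seed(cfg$seed)
  vel <- vector("list", length(g$layers))
  history <- NULL
  best_map <- -Inf
  last_good <- NULL
  targets_all <- lapply(dataset, image_targets)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_schedule(epoch, cfg)
    ord <- sample(length(dataset))
    comp_sum <- c(box = 0, cls = 0, dfl = 0); nb <- 0; tot <- 0
    for (b0 in seq(1, length(ord), by = cfg$batch)) {
      idx <- ord[b0:min(b0 + cfg$batch - 1, length(ord))]
      x <- stack_images(dataset[idx])
      fw <- nn_forward(g, x, training = TRUE)
      ls <- tryCatch(
        detection_loss(model, fw$outputs, targets_all[idx], img_size),
        error = function(e) e)
      if (inherits(ls, "error") || !is.finite(ls$total)) {
        msg <- if (inherits(ls, "error")) conditionMessage(ls) else "NaN loss"
        stop("training aborted at epoch ", epoch, ": ", msg,
             if (!is.null(last_good)) " (last good epoch logged in history)")
      }
      bw <- nn_backward(g, fw, ls$grads)
      for (li in seq_along(g$layers)) {
        gr <- bw$grads[[li]]
        if (is.null(gr)) next
        pp <- g$layers[[li]]$params
        if (is.null(vel[[li]]))
          vel[[li]] <- lapply(pp, function(p) p * 0)
        for (nm in names(pp)) {
          gnm <- gr[[nm]]
          if (is.null(gnm)) next
          if (nm == "w" && g$layers[[li]]$type == "conv")
            gnm <- gnm + cfg$weight_decay * pp[[nm]]
          vel[[li]][[nm]] <- cfg$momentum * vel[[li]][[nm]] - lr * gnm
          g$layers[[li]]$params[[nm]] <- pp[[nm]] + vel[[li]][[nm]]
        }
      }
      comp_sum <- comp_sum + ls$components; tot <- tot + ls$total; nb <- nb + 1
    }
    row <- data.frame(epoch = epoch, lr = lr, total = tot / nb,
                      box = comp_sum["box"] / nb, cls = comp_sum["cls"] / nb,
                      dfl = comp_sum["dfl"] / nb, map50 = NA_real_)
    if (!is.null(val_dataset) &&
        (epoch %% val_every == 0 || epoch == cfg$epochs - 1)) {
      det <- function(im) predict_boxes(model, im, conf_thr = 0.25)
      ev <- evaluate_detector(det, val_dataset, n_classes = model$nc)
      row$map50 <- ev$map50
      if (ev$map50 >= best_map) best_map <- ev$map50
    }
    history <- rbind(history, row)
    last_good <- epoch
    if (verbose)
      cat(sprintf("epoch %3d lr %.5f loss %.4f (box %.4f cls %.4f dfl %.4f)%s\n",
                  epoch, lr, tot / nb, comp_sum["box"] / nb,
                  comp_sum["cls"] / nb, comp_sum["dfl"] / nb,
                  if (is.na(row$map50)) "" else sprintf(" mAP %.3f", row$map50)))
  }
  rownames(history) <- NULL
  list(model = model, history = history,
       best_map = if (is.finite(best_map)) best_map else NA_real_)
}
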