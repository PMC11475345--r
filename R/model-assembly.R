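# Model assembly: compose backbone / attention / neck / head into a
# detector graph, for both the lightweight detector and the YOLOv8n
# baseline, and provide exact parameter and FLOP accounting.

#' Full detector configuration
#'
#' Defaults are the calibrated lightweight configuration: StarNet backbone,
#' SPPF with large separable kernel attention, MCFP neck and LMFD head.
#' The ablation flags reproduce every intermediate architecture between the
#' YOLOv8n baseline (`backbone = "yolov8n-csp"`, all flags off) and the full
#' model.
#'
#' @param img_size input image size (square, divisible by 32).
#' @param n_classes number of object classes (4 behaviours).
#' @param backbone `"starnet"` or `"yolov8n-csp"`.
#' @param use_lska replace SPPF by SPPF-LSKA.
#' @param use_mcfp replace the FPN-PAN neck by MCFP.
#' @param use_lmfd replace the decoupled head by LMFD.
#' @param loss box-regression criterion key: `"ciou"`, `"inner_iou"`,
#'   `"mpdiou"` or `"inner_mpdiou"`.
#' @param inner_ratio auxiliary-box scale of the inner-IoU term.
#' @param mpd_norm normalisation of the corner distances: `"image"` (input
#'   frame dimensions) or `"gtbox"` (ground-truth box dimensions).
#' @param starnet,lska,mcfp,lmfd sub-configurations, see
#'   [starnet_config()], [lska_config()], [mcfp_config()], [lmfd_config()].
#' @param sppf_pools number of serial 5x5 max-pools in (LSKA-)SPPF.
#' @return a `cbr_config` list.
#' @export
cbr_config <- function(img_size = 640, n_classes = 4,
                       backbone = "starnet",
                       use_lska = TRUE, use_mcfp = TRUE, use_lmfd = TRUE,
                       loss = "inner_mpdiou", inner_ratio = 0.7,
                       mpd_norm = "image",
                       starnet = starnet_config(),
                       lska = lska_config(),
                       mcfp = mcfp_config(),
                       lmfd = lmfd_config(n_classes = n_classes),
                       sppf_pools = 3) {
  stopifnot(img_size %% 32 == 0)
  backbone <- match.arg(backbone, c("starnet", "yolov8n-csp"))
  loss <- match.arg(loss, c("ciou", "inner_iou", "mpdiou", "inner_mpdiou"))
  mpd_norm <- match.arg(mpd_norm, c("image", "gtbox"))
  structure(list(img_size = img_size, n_classes = n_classes,
                 backbone = backbone, use_lska = use_lska,
                 use_mcfp = use_mcfp, use_lmfd = use_lmfd,
                 loss = loss, inner_ratio = inner_ratio, mpd_norm = mpd_norm,
                 starnet = starnet, lska = lska, mcfp = mcfp, lmfd = lmfd,
                 sppf_pools = sppf_pools),
            class = "cbr_config")
}

#' Build a detector from a configuration
#'
#' Composes backbone -> SPPF(-LSKA) -> neck -> head into one computation
#' graph.  The graph outputs are, per pyramid level (strides 8/16/32), the
#' raw box-distribution maps (`4 * reg_max` channels) and class-logit maps
#' (`n_classes` channels), in that interleaved order.
#'
#' @param cfg a [cbr_config()].
#' @param seed integer seed for the (deterministic) weight initialisation.
#' @return a `cbr_model`: list with the graph, configuration, strides and
#'   bookkeeping used by [predict_boxes()], [count_params()] and
#'   [count_flops()].
#' @export
build_model <- function(cfg = cbr_config(), seed = 0) {
  set.seed(seed)
  g <- nn_new()
  bb <- if (cfg$backbone == "starnet") {
    r <- build_starnet(g, cfg$starnet)
    p5c <- r$channels[3]
    sp <- if (cfg$use_lska) {
      build_sppf_lska(g, r$ids[3], p5c, p5c, cfg$lska, tag = "sppf",
                      n_pools = cfg$sppf_pools)
    } else {
      build_sppf(g, r$ids[3], p5c, p5c, tag = "sppf",
                 n_pools = cfg$sppf_pools)
    }
    list(ids = c(r$ids[1], r$ids[2], sp), channels = r$channels)
  } else {
    build_v8_backbone(g, use_lska = cfg$use_lska, lska_cfg = cfg$lska,
                      sppf_pools = cfg$sppf_pools)
  }
  nk <- if (cfg$use_mcfp) build_mcfp(g, bb$ids, bb$channels, cfg$mcfp)
        else build_v8_neck(g, bb$ids, bb$channels)
  reg_max <- cfg$lmfd$reg_max
  outs <- if (cfg$use_lmfd) build_lmfd(g, nk$ids, nk$channels, cfg$lmfd)
          else build_v8_head(g, nk$ids, nk$channels, cfg$n_classes, reg_max)
  g$outputs <- outs
  structure(list(graph = g, cfg = cfg, strides = c(8, 16, 32),
                 nc = cfg$n_classes, reg_max = reg_max,
                 neck_channels = nk$channels),
            class = "cbr_model")
}

#' Build the YOLOv8n reference detector
#'
#' Faithful YOLOv8n graph (C2f backbone, SPPF, FPN-PAN, decoupled head,
#' `reg_max = 16`), used as the structural baseline for parameter and FLOP
#' comparison and as the ablation starting point.
#'
#' @param n_classes number of classes.
#' @param seed weight-initialisation seed.
#' @return a `cbr_model`.
#' @export
build_yolov8n_baseline <- function(n_classes = 4, seed = 0) {
  cfg <- cbr_config(n_classes = n_classes, backbone = "yolov8n-csp",
                    use_lska = FALSE, use_mcfp = FALSE, use_lmfd = FALSE,
                    loss = "ciou")
  build_model(cfg, seed = seed)
}

#' Count trainable parameters of a detector
#'
#' @param model a `cbr_model`.
#' @param per_module also return the per-module breakdown
#'   (backbone / sppf / neck / head), which sums to the total.
#' @return integer total, or a list with `total` and `by_module`.
#' @export
count_params <- function(model, per_module = FALSE) {
  total <- nn_params(model$graph)
  if (!per_module) return(total)
  by_tag <- nn_params(model$graph, by_tag = TRUE)
  list(total = total, by_module = by_tag)
}

#' Count FLOPs of a detector at a given input size
#'
#' Two conventions are provided.  `"eq11"` charges every convolution
#' `Cin/g * Cout * Kh * Kw * Hout * Wout + Cout * Hout * Wout` operations
#' (one per multiply-accumulate, plus the per-output accumulation).
#' `"table"` is the profiler convention detection models are usually quoted
#' under: two operations per multiply-accumulate plus bias adds, summed over
#' the whole network.
#'
#' @param model a `cbr_model`.
#' @param img_size input size (divisible by 32); defaults to the model's.
#' @param convention `"table"` (default) or `"eq11"`.
#' @return FLOP count (numeric, in raw operations; divide by 1e9 for G).
#' @export
count_flops <- function(model, img_size = NULL,
                        convention = c("table", "eq11")) {
  convention <- match.arg(convention)
  if (is.null(img_size)) img_size <- model$cfg$img_size
  stopifnot(img_size %% 32 == 0)
  tr <- nn_trace(model$graph, c(img_size, img_size, 3))
  sum(if (convention == "table") tr$flops_table else tr$flops_eq11)
}

#' @export
print.cbr_model <- function(x, ...) {
  p <- count_params(x, per_module = TRUE)
  cat("<cbr_model> ", x$cfg$backbone,
      if (x$cfg$use_lska) "+LSKA", if (x$cfg$use_mcfp) "+MCFP",
      if (x$cfg$use_lmfd) "+LMFD", "\n")
  cat("  classes:", x$nc, " reg_max:", x$reg_max, "\n")
  cat("  parameters:", format(p$total, big.mark = ","), "\n")
  cat("  GFLOPs (", x$cfg$img_size, "px, 2xMAC): ",
      round(count_flops(x) / 1e9, 1), "\n", sep = "")
  invisible(x)
}
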