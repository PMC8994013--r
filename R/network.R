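## The two-stream reference-guided segmentation network: a Siamese
## (weight-shared) residual encoder on the main stream (current frame +
## guidance mask) and the reference stream (reference frame + its
## annotation), per-stream feature pyramids P3-P7, per-level fusion by
## channel concatenation + 1x1 reduction, anchor classification and box
## regression subnets, and an RoIAlign-fed mask subnet.  Inference
## propagates each frame's predicted mask to the next frame as guidance.

#' Network configuration
#'
#' Two presets are provided: `"full"` mirrors the five-stage residual
#' (bottleneck) backbone with a 256-channel feature pyramid on 128 x 256
#' inputs, and `"reduced"` is a width- and depth-reduced variant (channels
#' divided by 8, one bottleneck per stage, 64 x 128 inputs) sized for CPU
#' training on phantom data.
#'
#' @param preset `"reduced"` or `"full"`.
#' @param input_shape `c(height, width)` of the network input; defaults
#'   by preset.
#' @param anchors An [anchor_config()]; its strides must match the
#'   pyramid (8..128).
#' @param roi_output_size RoIAlign output grid (mask head input).
#' @param mask_threshold Probability threshold binarising the mask head
#'   output.
#' @param seed Seed for weight initialisation.
#' @return Object of class `echo_net_config`.
#' @export
network_config <- function(preset = c("reduced", "full"),
                           input_shape = NULL,
                           anchors = anchor_config(),
                           roi_output_size = 14L,
                           mask_threshold = 0.5,
                           seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "full") {
    cfg <- list(stem_channels = 64L, stage_channels = c(256L, 512L, 1024L, 2048L),
                inner_channels = c(64L, 128L, 256L, 512L),
                blocks = c(3L, 4L, 6L, 3L), pyramid_channels = 256L,
                input_shape = input_shape %||% c(128L, 256L))
  } else {
    cfg <- list(stem_channels = 8L, stage_channels = c(32L, 64L, 128L, 256L),
                inner_channels = c(8L, 16L, 32L, 64L),
                blocks = c(1L, 1L, 1L, 1L), pyramid_channels = 32L,
                input_shape = input_shape %||% c(64L, 128L))
  }
  structure(c(cfg, list(preset = preset, anchors = anchors,
                        roi_output_size = as.integer(roi_output_size),
                        mask_crop_size = 2L * as.integer(roi_output_size),
                        mask_threshold = mask_threshold,
                        seed = as.integer(seed))),
            class = "echo_net_config")
}

## He-normal initialised convolution parameters
conv_p <- function(kh, kw, cin, cout, bias = 0) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       b = rep(bias, cout))
}

bottleneck_p <- function(cin, inner, cout, stride) {
  p <- list(conv1 = conv_p(1L, 1L, cin, inner),
            conv2 = conv_p(3L, 3L, inner, inner),
            conv3 = conv_p(1L, 1L, inner, cout))
  if (cin != cout || stride != 1L) p$proj <- conv_p(1L, 1L, cin, cout)
  p
}

init_params <- function(config) {
  pc <- config$pyramid_channels
  A <- config$anchors$A
  sc <- config$stage_channels; ic <- config$inner_channels
  params <- list()
  params$stem1 <- conv_p(7L, 7L, 2L, config$stem_channels)
  params$stem2 <- conv_p(3L, 3L, config$stem_channels, config$stem_channels)
  cin <- config$stem_channels
  stages <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- vector("list", config$blocks[s])
    stride1 <- if (s == 1L) 1L else 2L
    for (b in seq_len(config$blocks[s])) {
      blocks[[b]] <- bottleneck_p(cin, ic[s], sc[s],
                                  if (b == 1L) stride1 else 1L)
      cin <- sc[s]
    }
    stages[[s]] <- blocks
  }
  params$stages <- stages
  params$fpn <- list(
    lat3 = conv_p(1L, 1L, sc[2L], pc), lat4 = conv_p(1L, 1L, sc[3L], pc),
    lat5 = conv_p(1L, 1L, sc[4L], pc),
    smooth3 = conv_p(3L, 3L, pc, pc), smooth4 = conv_p(3L, 3L, pc, pc),
    smooth5 = conv_p(3L, 3L, pc, pc),
    p6 = conv_p(3L, 3L, sc[4L], pc), p7 = conv_p(3L, 3L, pc, pc))
  params$fuse <- conv_p(1L, 1L, 2L * pc, pc)
  head_stack <- function(cout, bias_out = 0) {
    list(c1 = conv_p(3L, 3L, pc, pc), c2 = conv_p(3L, 3L, pc, pc),
         c3 = conv_p(3L, 3L, pc, pc), c4 = conv_p(3L, 3L, pc, pc),
         out = conv_p(3L, 3L, pc, cout, bias = bias_out))
  }
  ## prior-probability bias so the untrained classifier scores ~0.01
  params$cls <- head_stack(A, bias_out = -log((1 - 0.01) / 0.01))
  params$reg <- head_stack(4L * A)
  params$mask <- list(c1 = conv_p(3L, 3L, pc, pc), c2 = conv_p(3L, 3L, pc, pc),
                      c3 = conv_p(3L, 3L, pc, pc), c4 = conv_p(3L, 3L, pc, pc),
                      c5 = conv_p(3L, 3L, pc, pc),
                      out = conv_p(1L, 1L, pc, 1L))
  params
}

#' Build the two-stream segmentation network
#'
#' @param config A [network_config()].
#' @return Object of class `echo_net` (configuration + weights).
#' @export
build_echo_net <- function(config = network_config()) {
  params <- with_seed(config$seed, init_params(config))
  structure(list(config = config, params = params), class = "echo_net")
}

n_params <- function(p) {
  if (is.list(p)) return(sum(vapply(p, n_params, numeric(1L))))
  length(p)
}

#' @export
print.echo_net <- function(x, ...) {
  cat(sprintf(
    paste0("echo_net (%s preset): input %dx%d, pyramid P3-P7 @ %d channels,\n",
           "  %d anchors/location, RoIAlign %dx%d, %s trainable parameters\n"),
    x$config$preset, x$config$input_shape[1L], x$config$input_shape[2L],
    x$config$pyramid_channels, x$config$anchors$A,
    x$config$roi_output_size, x$config$roi_output_size,
    format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

#' Copy backbone weights from a trained model
#'
#' Transfer initialisation: the encoder (stem + residual stages) of
#' `target` is replaced by the weights of `source`; all other layers keep
#' their random initial weights.  Used to seed the RV model from a
#' trained LV model.
#'
#' @param target,source `echo_net` objects with identical backbone
#'   configuration.
#' @return `target` with the transferred backbone.
#' @export
transfer_backbone <- function(target, source) {
  stopifnot(inherits(target, "echo_net"), inherits(source, "echo_net"),
            identical(target$config$stage_channels,
                      source$config$stage_channels))
  target$params$stem1 <- source$params$stem1
  target$params$stem2 <- source$params$stem2
  target$params$stages <- source$params$stages
  target
}

## ---- forward passes -----------------------------------------------------

conv_block <- function(tape, x, p, stride = 1L, pad = 1L, relu = TRUE) {
  out <- op_conv2d(tape, x, p$w, p$b, stride = stride, pad = pad)
  if (relu) op_relu(tape, out) else out
}

bottleneck_forward <- function(tape, x, pn, stride) {
  h <- conv_block(tape, x, pn$conv1, stride = 1L, pad = 0L)
  h <- conv_block(tape, h, pn$conv2, stride = stride, pad = 1L)
  h <- conv_block(tape, h, pn$conv3, stride = 1L, pad = 0L, relu = FALSE)
  short <- if (!is.null(pn$proj))
    conv_block(tape, x, pn$proj, stride = stride, pad = 0L, relu = FALSE)
  else x
  op_relu(tape, op_add(tape, h, short))
}

backbone_forward <- function(tape, pn, x) {
  h <- conv_block(tape, x, pn$stem1, stride = 2L, pad = 3L)
  h <- conv_block(tape, h, pn$stem2, stride = 2L, pad = 1L)
  outs <- vector("list", 4L)
  for (s in 1:4) {
    stride1 <- if (s == 1L) 1L else 2L
    for (b in seq_along(pn$stages[[s]])) {
      h <- bottleneck_forward(tape, h, pn$stages[[s]][[b]],
                              if (b == 1L) stride1 else 1L)
    }
    outs[[s]] <- h
  }
  list(c3 = outs[[2L]], c4 = outs[[3L]], c5 = outs[[4L]])
}

fpn_forward <- function(tape, pn, bb) {
  l5 <- conv_block(tape, bb$c5, pn$lat5, pad = 0L, relu = FALSE)
  l4 <- conv_block(tape, bb$c4, pn$lat4, pad = 0L, relu = FALSE)
  l3 <- conv_block(tape, bb$c3, pn$lat3, pad = 0L, relu = FALSE)
  d4 <- dim(l4$val); d3 <- dim(l3$val)
  p5 <- l5
  p4 <- op_add(tape, l4, op_crop_hw(tape, op_upsample2(tape, p5),
                                    d4[1L], d4[2L]))
  p3 <- op_add(tape, l3, op_crop_hw(tape, op_upsample2(tape, p4),
                                    d3[1L], d3[2L]))
  p3 <- conv_block(tape, p3, pn$smooth3, pad = 1L, relu = FALSE)
  p4 <- conv_block(tape, p4, pn$smooth4, pad = 1L, relu = FALSE)
  p5 <- conv_block(tape, p5, pn$smooth5, pad = 1L, relu = FALSE)
  p6 <- conv_block(tape, bb$c5, pn$p6, stride = 2L, pad = 1L, relu = FALSE)
  p7 <- conv_block(tape, op_relu(tape, p6), pn$p7, stride = 2L, pad = 1L,
                   relu = FALSE)
  list(p3, p4, p5, p6, p7)
}

## Two-channel main batch (H, W, 2, N) and reference input (H, W, 2, 1)
## through the shared encoder + FPN; per-level fusion of the two streams.
fused_pyramid <- function(tape, model, main_x, ref_x, pnodes = NULL) {
  pn <- pnodes %||% wrap_params(NULL, model$params)
  N <- dim(main_x$val)[4L]
  main_p <- fpn_forward(tape, pn$fpn, backbone_forward(tape, pn, main_x))
  ref_p <- fpn_forward(tape, pn$fpn, backbone_forward(tape, pn, ref_x))
  lapply(seq_along(main_p), function(i) {
    r <- op_broadcast_n(tape, ref_p[[i]], N)
    op_relu(tape, conv_block(tape, op_concat_c(tape, main_p[[i]], r),
                             pn$fuse, pad = 0L, relu = FALSE))
  })
}

head_forward <- function(tape, pn, x, sigmoid = FALSE) {
  h <- conv_block(tape, x, pn$c1, pad = 1L)
  h <- conv_block(tape, h, pn$c2, pad = 1L)
  h <- conv_block(tape, h, pn$c3, pad = 1L)
  h <- conv_block(tape, h, pn$c4, pad = 1L)
  h <- conv_block(tape, h, pn$out, pad = 1L, relu = FALSE)
  if (sigmoid) op_sigmoid(tape, h) else h
}

mask_head_forward <- function(tape, pn, crops) {
  h <- conv_block(tape, crops, pn$c1, pad = 1L)
  h <- conv_block(tape, h, pn$c2, pad = 1L)
  h <- conv_block(tape, h, pn$c3, pad = 1L)
  h <- conv_block(tape, h, pn$c4, pad = 1L)
  h <- op_upsample2(tape, h)
  h <- conv_block(tape, h, pn$c5, pad = 1L)
  op_sigmoid(tape, conv_block(tape, h, pn$out, pad = 0L, relu = FALSE))
}

## standard FPN level assignment for the mask crop of a box
roi_level <- function(box, levels = 3:5) {
  area <- max(box[3L] - box[1L], 1e-6) * max(box[4L] - box[2L], 1e-6)
  k <- floor(4 + log2(sqrt(area) / 224))
  min(max(k, min(levels)), max(levels))
}

## ---- inference ----------------------------------------------------------

#' Run the network on one frame
#'
#' Full per-frame path: two-stream encoder and pyramids, classification
#' and regression subnets, box decoding (Regress-Boxes), clipping
#' (ClipBoxes), score-threshold + NMS filtering (Filter-detections),
#' RoIAlign of the best detection and the mask subnet.  The mask of the
#' highest-scoring detection is thresholded and pasted back at input
#' resolution; if no detection survives filtering, the guidance mask is
#' reused and flagged.
#'
#' @param model An `echo_net`.
#' @param main_input `H x W x 2` array (current frame + guidance mask) at
#'   the network input shape.
#' @param ref_input `H x W x 2` array (reference frame + annotation).
#' @return List of class `frame_result`: `mask` (binary, input shape),
#'   `best_score`, `fallback_used`, `detections`.
#' @export
forward_frame <- function(model, main_input, ref_input) {
  ishape <- model$config$input_shape
  stopifnot(all(dim(main_input) == c(ishape, 2L)),
            all(dim(ref_input) == c(ishape, 2L)))
  main_x <- new_node(NULL, array(main_input, c(dim(main_input), 1L)))
  ref_x <- new_node(NULL, array(ref_input, c(dim(ref_input), 1L)))
  pn <- wrap_params(NULL, model$params)
  fused <- fused_pyramid(NULL, model, main_x, ref_x, pnodes = pn)
  det <- detect_on_pyramid(model, pn, fused)
  if (length(det$scores) == 0L) {
    return(structure(list(mask = main_input[, , 2L], best_score = NA_real_,
                          fallback_used = TRUE, detections = det),
                     class = "frame_result"))
  }
  box <- det$boxes[1L, ]
  mask <- mask_from_box(model, pn, fused, box)
  structure(list(mask = mask, best_score = det$scores[1L],
                 fallback_used = FALSE, detections = det),
            class = "frame_result")
}

detect_on_pyramid <- function(model, pn, fused) {
  acfg <- model$config$anchors
  ishape <- model$config$input_shape
  anch <- generate_anchors(acfg, ishape)
  all_boxes <- NULL; all_scores <- numeric(0); all_level <- integer(0)
  start <- 0L
  for (li in seq_along(fused)) {
    cls <- head_forward(NULL, pn$cls, fused[[li]], sigmoid = TRUE)
    reg <- head_forward(NULL, pn$reg, fused[[li]])
    nA <- length(cls$val)
    probs <- as.vector(cls$val)
    deltas <- matrix(as.vector(reg$val), nA, 4L)
    a_boxes <- anch$boxes[anch$level == acfg$pyramid_levels[li], ,
                          drop = FALSE]
    boxes <- clip_boxes(decode_boxes(a_boxes, deltas, acfg$delta_norm),
                        ishape)
    all_boxes <- rbind(all_boxes, boxes)
    all_scores <- c(all_scores, probs)
    all_level <- c(all_level, rep(acfg$pyramid_levels[li], nA))
  }
  filter_detections(all_boxes, all_scores, acfg, level = all_level)
}

## crop the fused pyramid at `box`, run the mask subnet, paste the
## thresholded probability map back into the input-resolution canvas
mask_from_box <- function(model, pn, fused, box) {
  ishape <- model$config$input_shape
  lv <- roi_level(box)
  li <- match(lv, model$config$anchors$pyramid_levels)
  stride <- model$config$anchors$strides[li]
  crop <- op_roi_align(NULL, fused[[li]], matrix(box, 1L),
                       model$config$roi_output_size, 1 / stride)
  probs <- mask_head_forward(NULL, pn$mask, crop)$val[, , 1L, 1L]
  canvas <- matrix(0, ishape[1L], ishape[2L])
  x1 <- max(floor(box[1L]) + 1L, 1L); y1 <- max(floor(box[2L]) + 1L, 1L)
  x2 <- min(ceiling(box[3L]), ishape[2L]); y2 <- min(ceiling(box[4L]), ishape[1L])
  if (x2 >= x1 && y2 >= y1) {
    pr <- resize_mat(probs, y2 - y1 + 1L, x2 - x1 + 1L, method = "bilinear")
    canvas[y1:y2, x1:x2] <- (pr >= model$config$mask_threshold) * 1
  }
  canvas
}

#' Segment a whole sequence by reference-guided mask propagation
#'
#' Semi-supervised inference: the user-annotated first frame enters the
#' reference stream; every later frame enters the main stream guided by
#' the previous frame's predicted mask (the first propagated frame is
#' guided by the annotation itself).  The first output mask is the
#' annotation, returned verbatim.
#'
#' @param model An `echo_net`.
#' @param sequence An `echo_sequence`, `phantom_sequence`, or plain list
#'   of grayscale frame matrices (all at the same original resolution).
#' @param ref_annotation Binary mask of the first frame at the original
#'   resolution.
#' @return Object of class `mask_sequence`: `masks` (binary matrices at
#'   original resolution), `scores`, `fallback` flags.
#' @export
segment_sequence <- function(model, sequence, ref_annotation) {
  frames <- if (is.list(sequence) && !is.null(sequence$frames))
    sequence$frames else sequence
  if (length(frames) < 2L)
    stop("sequence must have at least 2 frames")
  ishape <- model$config$input_shape
  oshape <- dim(frames[[1L]])
  ref_ann <- binarize_mask(ref_annotation)
  pre <- lapply(frames, preprocess_frame,
                height = ishape[1L], width = ishape[2L])
  guidance <- binarize_mask(ref_annotation, height = ishape[1L],
                            width = ishape[2L])
  ref_input <- build_stream_input(pre[[1L]], guidance)
  n <- length(frames)
  masks <- vector("list", n)
  scores <- rep(NA_real_, n)
  fallback <- logical(n)
  masks[[1L]] <- ref_ann
  for (t in 2:n) {
    fr <- forward_frame(model, build_stream_input(pre[[t]], guidance),
                        ref_input)
    guidance <- fr$mask
    masks[[t]] <- resize_mat(fr$mask, oshape[1L], oshape[2L],
                             method = "nearest")
    scores[t] <- fr$best_score
    fallback[t] <- fr$fallback_used
  }
  structure(list(masks = masks, scores = scores, fallback = fallback),
            class = "mask_sequence")
}

#' @export
print.mask_sequence <- function(x, ...) {
  cat(sprintf(
    "mask_sequence: %d frames, %d fallback frame(s), median score %.3f\n",
    length(x$masks), sum(x$fallback),
    stats::median(x$scores, na.rm = TRUE)))
  invisible(x)
}

#' @rdname segment_sequence
#' @param object An `echo_net`.
#' @param ... Unused.
#' @export
predict.echo_net <- function(object, sequence, ref_annotation, ...) {
  segment_sequence(object, sequence, ref_annotation)
}
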