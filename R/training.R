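## End-to-end training: per iteration one sequence is sampled, its first
## frame feeds the reference stream, the remaining frames form the main-
## stream batch (guided, under teacher forcing, by the previous frame's
## ground-truth mask), and stochastic gradient descent minimises
## focal + smooth-L1 + mask cross-entropy.

#' Training configuration
#'
#' @param learning_rate SGD step size (> 0; 0 is allowed and leaves the
#'   weights untouched, useful for testing).
#' @param iterations Number of SGD iterations (one sequence each).
#' @param seed Seed controlling sequence sampling.
#' @param loss_weights Length-3 weights of (classification, regression,
#'   mask) losses.
#' @param focal A [focal_params()].
#' @param smooth A [smooth_l1_params()].
#' @param teacher_forcing If `TRUE` (default) the main-stream guidance
#'   mask is the previous frame's ground truth; if `FALSE` the model's
#'   own propagated prediction (recomputed each iteration) is used.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, iterations = 100L,
                         seed = 1L, loss_weights = c(1, 1, 1),
                         focal = focal_params(), smooth = smooth_l1_params(),
                         teacher_forcing = TRUE) {
  stopifnot(learning_rate >= 0, iterations >= 1L)
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 loss_weights = loss_weights, focal = focal, smooth = smooth,
                 teacher_forcing = teacher_forcing), class = "train_config")
}

## Pre-digest one fully annotated sequence for training: network-grid
## frames/masks, stream inputs, per-frame ground-truth boxes, anchor
## assignments per pyramid level, and 2x-RoI-grid mask targets.
prepare_train_sequence <- function(model, frames, masks,
                                   guidance_masks = NULL) {
  cfg <- model$config
  ishape <- cfg$input_shape
  acfg <- cfg$anchors
  pre_f <- lapply(frames, preprocess_frame, height = ishape[1L],
                  width = ishape[2L])
  pre_m <- lapply(masks, binarize_mask, height = ishape[1L],
                  width = ishape[2L])
  guid <- if (is.null(guidance_masks)) pre_m
    else lapply(guidance_masks, binarize_mask, height = ishape[1L],
                width = ishape[2L])
  n <- length(frames)
  stopifnot(n >= 2L, length(masks) == n)
  use <- integer(0); boxes <- NULL
  for (t in 2:n) {
    bb <- mask_bbox(pre_m[[t]])
    if (!is.null(bb)) { use <- c(use, t); boxes <- rbind(boxes, bb) }
  }
  if (length(use) == 0L) stop("sequence has no non-empty target masks")
  N <- length(use)
  main_x <- array(0, c(ishape, 2L, N))
  for (j in seq_len(N)) {
    t <- use[j]
    main_x[, , , j] <- build_stream_input(pre_f[[t]], guid[[t - 1L]])
  }
  ref_x <- array(build_stream_input(pre_f[[1L]], pre_m[[1L]]),
                 c(ishape, 2L, 1L))
  anch <- generate_anchors(acfg, ishape)
  levels <- acfg$pyramid_levels
  assign_lv <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    a_boxes <- anch$boxes[anch$level == levels[li], , drop = FALSE]
    nA <- nrow(a_boxes)
    lab <- matrix(0, nA, N)
    pos_idx <- vector("list", N); pos_tgt <- vector("list", N)
    for (j in seq_len(N)) {
      asg <- assign_anchors(a_boxes, matrix(boxes[j, ], 1L), acfg)
      l <- ifelse(asg$label == "positive", 1,
                  ifelse(asg$label == "background", 0, NA))
      lab[, j] <- l
      p <- which(asg$label == "positive")
      pos_idx[[j]] <- p
      pos_tgt[[j]] <- asg$deltas[p, , drop = FALSE]
    }
    assign_lv[[li]] <- list(labels = lab, pos_idx = pos_idx,
                            pos_tgt = pos_tgt, nA = nA)
  }
  mcs <- cfg$mask_crop_size
  mask_tgt <- array(0, c(mcs, mcs, 1L, N))
  roi_lv <- integer(N)
  for (j in seq_len(N)) {
    b <- boxes[j, ]
    m <- pre_m[[use[j]]]
    crop <- m[(b[2L] + 1L):b[4L], (b[1L] + 1L):b[3L], drop = FALSE]
    mask_tgt[, , 1L, j] <- resize_mat(crop, mcs, mcs, method = "nearest")
    roi_lv[j] <- roi_level(b)
  }
  list(main_x = main_x, ref_x = ref_x, boxes = boxes, use = use,
       assign = assign_lv, mask_tgt = mask_tgt, roi_lv = roi_lv)
}

## One forward pass + the three losses on a prepared sequence.
sequence_loss <- function(model, prep, tcfg, tape = NULL, pnodes = NULL) {
  cfg <- model$config
  acfg <- cfg$anchors
  pn <- pnodes %||% wrap_params(tape, model$params)
  main_x <- new_node(tape, prep$main_x)
  ref_x <- new_node(tape, prep$ref_x)
  fused <- fused_pyramid(tape, model, main_x, ref_x, pnodes = pn)
  N <- dim(prep$main_x)[4L]
  cls_nodes <- list(); cls_labels <- numeric(0)
  reg_nodes <- list(); reg_targets <- numeric(0)
  for (li in seq_along(fused)) {
    asg <- prep$assign[[li]]
    cls <- head_forward(tape, pn$cls, fused[[li]], sigmoid = TRUE)
    cls_nodes[[li]] <- op_flatten(tape, cls)
    cls_labels <- c(cls_labels, as.vector(asg$labels))
    any_pos <- any(vapply(asg$pos_idx, length, integer(1L)) > 0L)
    if (any_pos) {
      reg <- op_flatten(tape, head_forward(tape, pn$reg, fused[[li]]))
      nA <- asg$nA
      idx <- integer(0); tgt <- numeric(0)
      for (j in seq_len(N)) {
        p <- asg$pos_idx[[j]]
        if (length(p) == 0L) next
        for (k in 1:4) {
          idx <- c(idx, p + nA * (k - 1L) + 4L * nA * (j - 1L))
          tgt <- c(tgt, asg$pos_tgt[[j]][, k])
        }
      }
      reg_nodes[[length(reg_nodes) + 1L]] <- op_gather(tape, reg, idx)
      reg_targets <- c(reg_targets, tgt)
    }
  }
  cls_all <- op_concat_vec(tape, cls_nodes)
  loss_cls <- op_focal(tape, cls_all, cls_labels, tcfg$focal)
  loss_reg <- if (length(reg_nodes) > 0L)
    op_smooth_l1(tape, op_concat_vec(tape, reg_nodes), reg_targets,
                 tcfg$smooth$sigma)
  else new_node(tape, 0)
  ## mask loss on ground-truth box crops, grouped by RoI pyramid level
  mask_probs <- list(); mask_y <- numeric(0)
  for (lv in sort(unique(prep$roi_lv))) {
    ns <- which(prep$roi_lv == lv)
    li <- match(lv, acfg$pyramid_levels)
    feats <- if (length(ns) == N) fused[[li]]
      else op_select_n(tape, fused[[li]], ns)
    crops <- op_roi_align(tape, feats, prep$boxes[ns, , drop = FALSE],
                          cfg$roi_output_size, 1 / acfg$strides[li])
    pm <- mask_head_forward(tape, pn$mask, crops)
    mask_probs[[length(mask_probs) + 1L]] <- op_flatten(tape, pm)
    mask_y <- c(mask_y, as.vector(prep$mask_tgt[, , , ns]))
  }
  loss_mask <- op_bce(tape, op_concat_vec(tape, mask_probs), mask_y)
  total <- op_weighted_sum(tape, list(loss_cls, loss_reg, loss_mask),
                           tcfg$loss_weights)
  list(total = total, cls = loss_cls$val, reg = loss_reg$val,
       mask = loss_mask$val, pnodes = pn)
}

#' Train the network by stochastic gradient descent
#'
#' Sequences are sampled at random; for each one the first frame feeds
#' the reference stream and the remaining frames form the main-stream
#' batch.  All three subnets train jointly through backpropagation.
#' There is no fine-tuning at inference time.
#'
#' @param model An `echo_net`.
#' @param dataset List of fully annotated sequences; each element needs
#'   `$frames` and `$masks` (lists of same-size matrices).  Phantom
#'   sequences from [generate_phantom_sequence()] qualify directly.
#' @param config A [train_config()].
#' @return Object of class `echo_net_fit`: `model` (trained weights),
#'   `losses` (per-iteration total loss), and the per-component loss
#'   trace `components`.
#' @export
train_echo_net <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "echo_net"))
  if (length(dataset) == 0L) stop("empty training dataset")
  preps <- lapply(dataset, function(s)
    prepare_train_sequence(model, s$frames, s$masks))
  nit <- config$iterations
  losses <- numeric(nit)
  comp <- matrix(0, nit, 3L,
                 dimnames = list(NULL, c("cls", "reg", "mask")))
  with_seed(config$seed, {
    for (it in seq_len(nit)) {
      si <- sample.int(length(dataset), 1L)
      prep <- preps[[si]]
      if (!config$teacher_forcing && it > 1L) {
        s <- dataset[[si]]
        pred <- segment_sequence(model, s$frames, s$masks[[1L]])
        prep <- prepare_train_sequence(model, s$frames, s$masks,
                                       guidance_masks = pred$masks)
      }
      tape <- tape_new()
      res <- sequence_loss(model, prep, config, tape = tape)
      losses[it] <- res$total$val
      comp[it, ] <- c(res$cls, res$reg, res$mask)
      if (config$learning_rate > 0) {
        backward(tape, res$total)
        grads <- collect_grads(res$pnodes)
        model$params <- sgd_step(model$params, grads,
                                 config$learning_rate)
      }
    }
  })
  structure(list(model = model, losses = losses, components = comp,
                 config = config), class = "echo_net_fit")
}

#' @export
print.echo_net_fit <- function(x, ...) {
  n <- length(x$losses)
  k <- min(10L, n)
  cat(sprintf(
    "echo_net_fit: %d SGD iterations (lr %g)\n  total loss %.4f (first-%d mean) -> %.4f (last-%d mean)\n",
    n, x$config$learning_rate, mean(x$losses[seq_len(k)]), k,
    mean(x$losses[(n - k + 1L):n]), k))
  invisible(x)
}

#' @export
plot.echo_net_fit <- function(x, ...) {
  graphics::plot(seq_along(x$losses), x$losses, type = "l",
                 xlab = "iteration", ylab = "total loss",
                 main = "training loss", ...)
  invisible(x)
}
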