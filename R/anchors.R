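## Anchor machinery of the single-stage detection path: multi-level anchor
## generation over the feature pyramid, IoU computation, anchor-to-ground-
## truth assignment with the [0,0.4) / [0.4,0.5) / [0.5,1] bands, box delta
## encoding/decoding, clipping to the image, and score-threshold + greedy
## non-maximum-suppression detection filtering.
##
## Boxes are (x1, y1, x2, y2) float pixel coordinates, origin top-left,
## x rightward (columns), y downward (rows), 0-based inclusive extents.

#' Anchor and detection-filtering configuration
#'
#' @param pyramid_levels Integer vector of pyramid levels (P3..P7).
#' @param strides Pixels per feature-map cell at each level.
#' @param base_areas Base anchor areas per level (32^2..512^2 by default).
#' @param aspect_ratios Height/width ratios of the anchor shapes.
#' @param scale_multipliers Per-level octave scale factors.
#' @param iou_positive Assignment threshold for positive anchors.
#' @param iou_background_upper Upper IoU bound of the background band;
#'   anchors with best IoU in `[iou_background_upper, iou_positive)` are
#'   ignored during training.
#' @param nms_iou IoU threshold of greedy non-maximum suppression.
#' @param score_threshold Minimum classification score kept.
#' @param top_k_per_level Candidates collected per level before NMS.
#' @param delta_norm Normalisation constants dividing (dx, dy, dw, dh).
#' @return An object of class `anchor_config`.
#' @export
anchor_config <- function(pyramid_levels = 3:7,
                          strides = c(8, 16, 32, 64, 128),
                          base_areas = c(32, 64, 128, 256, 512)^2,
                          aspect_ratios = c(0.5, 1, 2),
                          scale_multipliers = 2^(c(0, 1, 2) / 3),
                          iou_positive = 0.5,
                          iou_background_upper = 0.4,
                          nms_iou = 0.5,
                          score_threshold = 0.5,
                          top_k_per_level = 1000L,
                          delta_norm = c(0.1, 0.1, 0.2, 0.2)) {
  stopifnot(length(strides) == length(pyramid_levels),
            length(base_areas) == length(pyramid_levels),
            iou_background_upper >= 0,
            iou_background_upper < iou_positive,
            iou_positive <= 1)
  structure(list(pyramid_levels = pyramid_levels, strides = strides,
                 base_areas = base_areas, aspect_ratios = aspect_ratios,
                 scale_multipliers = scale_multipliers,
                 A = length(aspect_ratios) * length(scale_multipliers),
                 iou_positive = iou_positive,
                 iou_background_upper = iou_background_upper,
                 nms_iou = nms_iou, score_threshold = score_threshold,
                 top_k_per_level = as.integer(top_k_per_level),
                 delta_norm = delta_norm),
            class = "anchor_config")
}

## Feature-map size at a given stride (ceil division, matching the
## network's stride-2 convolution chain).
level_shape <- function(input_shape, stride) {
  c(ceiling(input_shape[1L] / stride), ceiling(input_shape[2L] / stride))
}

## The A anchor shapes (width, height) for one level.
anchor_shapes <- function(base_area, aspect_ratios, scale_multipliers) {
  ## ordering: ratio varies fastest, scale slowest
  ar <- rep(aspect_ratios, times = length(scale_multipliers))
  sc <- rep(scale_multipliers, each = length(aspect_ratios))
  s <- sqrt(base_area) * sc
  cbind(w = s / sqrt(ar), h = s * sqrt(ar))
}

#' Generate the multi-level anchor set
#'
#' For every feature-map cell of every pyramid level, places A centred
#' anchor boxes (3 aspect ratios x 3 scales by default) in input-image
#' coordinates.  Within a level, anchors are ordered with the spatial
#' location varying fastest (rows within columns) and the shape index
#' slowest, matching the layout of the network head outputs.
#'
#' @param config An [anchor_config()].
#' @param input_shape `c(height, width)` of the network input.
#' @return List with `boxes` (n x 4 matrix), `level` (level id per box)
#'   and `n_per_level`.
#' @export
generate_anchors <- function(config, input_shape) {
  boxes <- vector("list", length(config$pyramid_levels))
  lev <- integer(0)
  for (li in seq_along(config$pyramid_levels)) {
    stride <- config$strides[li]
    hw <- level_shape(input_shape, stride)
    shapes <- anchor_shapes(config$base_areas[li], config$aspect_ratios,
                            config$scale_multipliers)
    ## cell centres; rows vary fastest to match array flattening
    cy <- (rep(seq_len(hw[1L]), times = hw[2L]) - 0.5) * stride
    cx <- (rep(seq_len(hw[2L]), each = hw[1L]) - 0.5) * stride
    per <- lapply(seq_len(nrow(shapes)), function(a) {
      cbind(cx - shapes[a, "w"] / 2, cy - shapes[a, "h"] / 2,
            cx + shapes[a, "w"] / 2, cy + shapes[a, "h"] / 2)
    })
    boxes[[li]] <- do.call(rbind, per)
    lev <- c(lev, rep(config$pyramid_levels[li], nrow(boxes[[li]])))
  }
  boxes <- do.call(rbind, boxes)
  colnames(boxes) <- c("x1", "y1", "x2", "y2")
  list(boxes = boxes, level = lev,
       n_per_level = as.integer(table(factor(lev,
                                             levels = config$pyramid_levels))))
}

#' Pairwise intersection-over-union of two box sets
#'
#' @param boxes_a,boxes_b Matrices n x 4 / m x 4 of (x1, y1, x2, y2).
#' @return n x m matrix of IoU values in [0, 1]; zero-area boxes have IoU
#'   0 against everything.
#' @export
iou_matrix <- function(boxes_a, boxes_b) {
  boxes_a <- matrix(boxes_a, ncol = 4L)
  boxes_b <- matrix(boxes_b, ncol = 4L)
  n <- nrow(boxes_a); m <- nrow(boxes_b)
  ix1 <- pmax(matrix(boxes_a[, 1L], n, m), matrix(boxes_b[, 1L], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(boxes_a[, 2L], n, m), matrix(boxes_b[, 2L], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(boxes_a[, 3L], n, m), matrix(boxes_b[, 3L], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(boxes_a[, 4L], n, m), matrix(boxes_b[, 4L], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  area_a <- pmax(boxes_a[, 3L] - boxes_a[, 1L], 0) *
    pmax(boxes_a[, 4L] - boxes_a[, 2L], 0)
  area_b <- pmax(boxes_b[, 3L] - boxes_b[, 1L], 0) *
    pmax(boxes_b[, 4L] - boxes_b[, 2L], 0)
  union <- matrix(area_a, n, m) + matrix(area_b, n, m, byrow = TRUE) - inter
  out <- ifelse(union > 0, inter / union, 0)
  matrix(out, n, m)
}

box_centers <- function(b) {
  b <- matrix(b, ncol = 4L)
  cbind(cx = (b[, 1L] + b[, 3L]) / 2, cy = (b[, 2L] + b[, 4L]) / 2,
        w = b[, 3L] - b[, 1L], h = b[, 4L] - b[, 2L])
}

#' Encode box regression deltas
#'
#' Offsets from anchors to target boxes as
#' `dx = (gx - ax)/aw`, `dy = (gy - ay)/ah`, `dw = log(gw/aw)`,
#' `dh = log(gh/ah)` on centres/extents, each divided by the fixed
#' normalisation constants of the configuration.
#'
#' @param anchors,gt_boxes Matrices n x 4 (rows paired).
#' @param delta_norm Length-4 normalisation constants.
#' @return n x 4 matrix of (dx, dy, dw, dh).
#' @export
encode_deltas <- function(anchors, gt_boxes,
                          delta_norm = c(0.1, 0.1, 0.2, 0.2)) {
  a <- box_centers(anchors); g <- box_centers(gt_boxes)
  if (any(a[, "w"] <= 0) || any(a[, "h"] <= 0))
    stop("zero-extent anchor cannot be encoded against")
  d <- cbind(dx = (g[, "cx"] - a[, "cx"]) / a[, "w"],
             dy = (g[, "cy"] - a[, "cy"]) / a[, "h"],
             dw = log(g[, "w"] / a[, "w"]),
             dh = log(g[, "h"] / a[, "h"]))
  sweep(d, 2L, delta_norm, "/")
}

#' Decode box regression deltas (inverse of [encode_deltas()])
#'
#' @param anchors n x 4 anchor boxes.
#' @param deltas n x 4 normalised (dx, dy, dw, dh).
#' @param delta_norm Length-4 normalisation constants.
#' @return n x 4 matrix of decoded boxes.
#' @export
decode_boxes <- function(anchors, deltas,
                         delta_norm = c(0.1, 0.1, 0.2, 0.2)) {
  a <- box_centers(anchors)
  d <- sweep(matrix(deltas, ncol = 4L), 2L, delta_norm, "*")
  cx <- a[, "cx"] + d[, 1L] * a[, "w"]
  cy <- a[, "cy"] + d[, 2L] * a[, "h"]
  w <- a[, "w"] * exp(d[, 3L])
  h <- a[, "h"] * exp(d[, 4L])
  out <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Assign anchors to ground-truth boxes
#'
#' Per anchor, the best-IoU ground-truth box decides the label: IoU at or
#' above `iou_positive` is positive (matched to the argmax box), below
#' `iou_background_upper` is background, anything in between is ignored
#' during training.  Positives carry encoded regression deltas to their
#' matched box.  With no ground-truth boxes everything is background.
#'
#' @param anchors n x 4 anchor boxes (or a [generate_anchors()] result).
#' @param gt_boxes m x 4 ground-truth boxes (m may be 0).
#' @param config An [anchor_config()].
#' @return List with `label` (character: "positive", "background",
#'   "ignore"), `gt_index` (NA for non-positives) and `deltas` (n x 4,
#'   NA rows for non-positives).
#' @export
assign_anchors <- function(anchors, gt_boxes, config = anchor_config()) {
  if (is.list(anchors) && !is.null(anchors$boxes)) anchors <- anchors$boxes
  anchors <- matrix(anchors, ncol = 4L)
  n <- nrow(anchors)
  label <- rep("background", n)
  gt_index <- rep(NA_integer_, n)
  deltas <- matrix(NA_real_, n, 4L)
  if (!is.null(gt_boxes) && NROW(gt_boxes) > 0L) {
    gt_boxes <- matrix(gt_boxes, ncol = 4L)
    iou <- iou_matrix(anchors, gt_boxes)
    best <- max.col(iou, ties.method = "first")
    best_iou <- iou[cbind(seq_len(n), best)]
    label[best_iou >= config$iou_positive] <- "positive"
    label[best_iou >= config$iou_background_upper &
          best_iou < config$iou_positive] <- "ignore"
    pos <- label == "positive"
    if (any(pos)) {
      gt_index[pos] <- best[pos]
      deltas[pos, ] <- encode_deltas(anchors[pos, , drop = FALSE],
                                     gt_boxes[best[pos], , drop = FALSE],
                                     config$delta_norm)
    }
  }
  list(label = label, gt_index = gt_index, deltas = deltas)
}

#' Clip boxes to the image extent
#'
#' @param boxes n x 4 boxes.
#' @param input_shape `c(height, width)`.
#' @return Boxes clamped to `[0, width] x [0, height]`.
#' @export
clip_boxes <- function(boxes, input_shape) {
  boxes <- matrix(boxes, ncol = 4L)
  boxes[, c(1L, 3L)] <- pmin(pmax(boxes[, c(1L, 3L)], 0), input_shape[2L])
  boxes[, c(2L, 4L)] <- pmin(pmax(boxes[, c(2L, 4L)], 0), input_shape[1L])
  colnames(boxes) <- c("x1", "y1", "x2", "y2")
  boxes
}

## Greedy NMS on one candidate set; returns kept indices in score order.
## Ties in score are broken towards the lower box index.
greedy_nms <- function(boxes, scores, iou_thr) {
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (length(ord) > 0L) {
      iou <- iou_matrix(boxes[i, , drop = FALSE],
                        boxes[ord, , drop = FALSE])[1L, ]
      ord <- ord[iou <= iou_thr]
    }
  }
  keep
}

#' Filter raw detections into final predictions
#'
#' Per pyramid level the `top_k_per_level` highest-scoring candidates are
#' collected, the score threshold is applied, and greedy non-maximum
#' suppression (highest score first, ties to the lower index) removes
#' overlaps above `nms_iou`.  The result is sorted by descending score.
#'
#' @param boxes n x 4 candidate boxes (already regressed and clipped).
#' @param scores Classification scores in [0, 1].
#' @param config An [anchor_config()].
#' @param level Optional per-box pyramid level (single level if omitted).
#' @return List with `boxes`, `scores`, `level`; zero rows when nothing
#'   survives (the caller decides the fallback).
#' @export
filter_detections <- function(boxes, scores, config = anchor_config(),
                              level = NULL) {
  boxes <- matrix(boxes, ncol = 4L)
  if (is.null(level)) level <- rep(config$pyramid_levels[1L], nrow(boxes))
  keep <- logical(nrow(boxes))
  for (lv in unique(level)) {
    idx <- which(level == lv)
    idx <- idx[order(-scores[idx], idx)]
    idx <- idx[seq_len(min(length(idx), config$top_k_per_level))]
    keep[idx] <- TRUE
  }
  cand <- which(keep & scores >= config$score_threshold)
  if (length(cand) == 0L)
    return(list(boxes = matrix(0, 0, 4L), scores = numeric(0),
                level = integer(0)))
  kept <- cand[greedy_nms(boxes[cand, , drop = FALSE], scores[cand],
                          config$nms_iou)]
  list(boxes = boxes[kept, , drop = FALSE], scores = scores[kept],
       level = level[kept])
}
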