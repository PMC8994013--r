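## Training losses: focal classification loss, smooth-L1 box regression
## loss, average binary cross-entropy mask loss, and their weighted sum.
## The same forward formulas are reused by the autodiff training ops.

EPS_PROB <- 1e-7

#' Focal loss parameters
#' @param alpha_t Class-balance weight in (0, 1] applied to positives
#'   (background anchors receive `1 - alpha_t`).
#' @param gamma Focusing exponent, >= 0; 0 recovers plain cross-entropy.
#' @return List of class `focal_params`.
#' @export
focal_params <- function(alpha_t = 0.25, gamma = 2) {
  stopifnot(gamma >= 0, alpha_t > 0, alpha_t <= 1)
  structure(list(alpha_t = alpha_t, gamma = gamma), class = "focal_params")
}

## Per-anchor focal terms: FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t),
## with p_t = p for positives and 1 - p for background.
focal_terms <- function(labels, probs, params) {
  p <- pmin(pmax(probs, EPS_PROB), 1 - EPS_PROB)
  pt <- ifelse(labels == 1, p, 1 - p)
  at <- ifelse(labels == 1, params$alpha_t, 1 - params$alpha_t)
  fl <- -at * (1 - pt)^params$gamma * log(pt)
  fl[is.na(labels)] <- 0
  fl
}

#' Focal classification loss
#'
#' Anchor-wise focal loss, summed over positive and background anchors
#' (ignored anchors contribute zero) and normalised by the number of
#' positive anchors (at least 1).
#'
#' @param true_labels Per-anchor labels: 1 (positive), 0 (background) or
#'   `NA` (ignored).
#' @param pred_probs Predicted object probabilities, same length.
#' @param params A [focal_params()].
#' @return Scalar loss.
#' @export
focal_loss <- function(true_labels, pred_probs, params = focal_params()) {
  stopifnot(length(true_labels) == length(pred_probs))
  npos <- sum(true_labels == 1, na.rm = TRUE)
  sum(focal_terms(true_labels, pred_probs, params)) / max(npos, 1)
}

#' Smooth-L1 parameters
#' @param sigma Breakpoint between the quadratic and linear regimes, > 0.
#' @return List of class `smooth_l1_params`.
#' @export
smooth_l1_params <- function(sigma = 3) {
  stopifnot(sigma > 0)
  structure(list(sigma = sigma), class = "smooth_l1_params")
}

smooth_l1_terms <- function(x, sigma) {
  ifelse(abs(x) < sigma, 0.5 * x^2 / sigma, abs(x) - 0.5 * sigma)
}

#' Smooth-L1 regression loss
#'
#' `F(x) = 0.5 x^2 / sigma` for `|x| < sigma`, else `|x| - 0.5 sigma`
#' (quadratic near zero, linear in the tails, continuous at the
#' breakpoint), averaged over all residual components.  An empty residual
#' vector (no positive anchors) gives loss 0.
#'
#' @param residuals Predicted minus target deltas of the positive anchors.
#' @param params A [smooth_l1_params()].
#' @return Scalar loss.
#' @export
smooth_l1 <- function(residuals, params = smooth_l1_params()) {
  if (length(residuals) == 0L) return(0)
  mean(smooth_l1_terms(residuals, params$sigma))
}

#' Average binary cross-entropy mask loss
#'
#' Mean over pixels of `-(y log p + (1 - y) log(1 - p))`, with predicted
#' probabilities clipped away from 0 and 1.
#'
#' @param gt_mask Binary target, any shape.
#' @param pred_mask_probs Predicted probabilities, same shape.
#' @return Scalar loss.
#' @export
mask_bce <- function(gt_mask, pred_mask_probs) {
  if (!identical(dim(gt_mask) %||% length(gt_mask),
                 dim(pred_mask_probs) %||% length(pred_mask_probs)))
    stop("mask shapes differ")
  p <- pmin(pmax(pred_mask_probs, EPS_PROB), 1 - EPS_PROB)
  y <- as.numeric(gt_mask)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Weighted total training loss
#'
#' @param cls,reg,mask The three component losses.
#' @param weights Length-3 weights (classification, regression, mask).
#' @return Scalar weighted sum.
#' @export
total_loss <- function(cls, reg, mask, weights = c(1, 1, 1)) {
  sum(weights * c(cls, reg, mask))
}
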