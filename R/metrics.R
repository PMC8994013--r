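## Evaluation statistics: segmentation overlap scores and the paired-
## measurement agreement statistics used to compare automatic and manual
## cardiac parameters.

#' Segmentation overlap scores
#'
#' Dice, Jaccard, precision and recall between a predicted and a
#' ground-truth binary mask (`A` = prediction, `B` = ground truth):
#' DSC = 2|A n B| / (|A| + |B|), JSC = |A n B| / |A u B|,
#' precision = |A n B| / |A|, recall = |A n B| / |B|.  Two empty masks are
#' in perfect agreement by convention and score 1 on all four.
#'
#' @param pred_mask,gt_mask Same-shape binary matrices.
#' @return List of class `seg_scores` with `dsc`, `jsc`, `precision`,
#'   `recall`.
#' @export
seg_scores <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("mask shapes differ")
  a <- pred_mask > 0; b <- gt_mask > 0
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  if (na == 0 && nb == 0)
    return(structure(list(dsc = 1, jsc = 1, precision = 1, recall = 1),
                     class = "seg_scores"))
  structure(list(
    dsc = 2 * ni / (na + nb),
    jsc = ni / (na + nb - ni),
    precision = if (na > 0) ni / na else 0,
    recall = if (nb > 0) ni / nb else 0), class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("DSC %.4f | JSC %.4f | precision %.4f | recall %.4f\n",
              x$dsc, x$jsc, x$precision, x$recall))
  invisible(x)
}

#' Regression error metrics
#'
#' RMSE, MAE and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` with the true values as reference.  With
#' constant true values `R^2` is undefined and reported as `NA`.
#'
#' @param pred_values,true_values Equal-length numeric vectors, n >= 2.
#' @return List with `rmse`, `mae`, `r_squared`.
#' @export
regression_metrics <- function(pred_values, true_values) {
  stopifnot(length(pred_values) == length(true_values),
            length(true_values) >= 2L)
  err <- pred_values - true_values
  ss_tot <- sum((true_values - mean(true_values))^2)
  list(rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       r_squared = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_)
}

#' Cronbach's alpha for two paired measurement series
#'
#' Internal-consistency coefficient with k = 2 items and sample variances:
#' `alpha = 2 (1 - (var(x) + var(y)) / var(x + y))`.  Undefined (`NA`)
#' when `var(x + y)` is zero.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Scalar alpha (or `NA`).
#' @export
cronbach_alpha <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  vs <- stats::var(x + y)
  if (vs == 0) return(NA_real_)
  2 * (1 - (stats::var(x) + stats::var(y)) / vs)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x - y`; bias `mean(d)`; limits of agreement
#' `mean(d) +/- 1.96 sd(d)` (sample sd) and their width.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return List with `mean_diff`, `lower`, `upper`, `width`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("Bland-Altman needs at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       width = 2 * 1.96 * s)
}

#' Pearson correlation of two paired series
#'
#' Sample Pearson correlation; `NA` when either input is constant.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Scalar r in [-1, 1] (or `NA`).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Agreement report between predicted and reference measurements
#'
#' Bundles [regression_metrics()], [cronbach_alpha()], [bland_altman()]
#' and [pearson()] for one paired series (prediction vs reference).
#'
#' @param pred_values,true_values Equal-length numeric vectors.
#' @return Object of class `agreement_report`.
#' @export
agreement_report <- function(pred_values, true_values) {
  rm_ <- regression_metrics(pred_values, true_values)
  ba <- bland_altman(pred_values, true_values)
  structure(list(
    rmse = rm_$rmse, mae = rm_$mae, r_squared = rm_$r_squared,
    cronbach_alpha = cronbach_alpha(pred_values, true_values),
    pearson_r = pearson(pred_values, true_values),
    ba_mean_diff = ba$mean_diff, ba_lower = ba$lower,
    ba_upper = ba$upper, ba_width = ba$width,
    n = length(pred_values)), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("agreement over %d pairs:\n",
           "  RMSE %.4f | MAE %.4f | R^2 %s | Cronbach's alpha %s | r %s\n",
           "  Bland-Altman bias %.4f, limits [%.4f, %.4f], width %.4f\n"),
    x$n, x$rmse, x$mae, format(x$r_squared, digits = 4),
    format(x$cronbach_alpha, digits = 4), format(x$pearson_r, digits = 4),
    x$ba_mean_diff, x$ba_lower, x$ba_upper, x$ba_width))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x An [agreement_report()].
#' @param pred_values,true_values The paired series (re-supplied for the
#'   scatter; the report stores only the summary statistics).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, pred_values, true_values, ...) {
  m <- (pred_values + true_values) / 2
  d <- pred_values - true_values
  graphics::plot(m, d, xlab = "mean of pair", ylab = "difference",
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(x$ba_mean_diff, x$ba_lower, x$ba_upper),
                   lty = c(1, 2, 2))
  invisible(x)
}
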