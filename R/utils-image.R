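## Internal image helpers.  Package-wide convention: a grayscale image is a
## numeric matrix indexed [row, col] (height x width) with values in [0, 1];
## a binary mask is the same with values in {0, 1}.  EBImage stores images
## [x, y], so every call through EBImage transposes on the way in and out.

#' @importFrom EBImage Image resize readImage writeImage
NULL

mat_to_ebimage <- function(m) EBImage::Image(t(m))

ebimage_to_mat <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 3L) {
    ## colour frame -> luma grayscale
    a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
  }
  t(a)
}

## Resize a [row, col] matrix to height_out x width_out.
## method "bilinear" for intensity images, "nearest" for masks (keeps {0,1}).
resize_mat <- function(m, height_out, width_out,
                       method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(m) == height_out && ncol(m) == width_out) return(m)
  filt <- if (method == "nearest") "none" else "bilinear"
  out <- EBImage::resize(mat_to_ebimage(m), w = width_out, h = height_out,
                         filter = filt)
  ebimage_to_mat(out)
}

## Tight bounding box of a mask as (x1, y1, x2, y2) float pixel extents,
## origin top-left, x rightward (columns), y downward (rows), 0-based,
## inclusive float extents (x2 = rightmost column, i.e. col index).
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r <- range(idx[, 1L]); c <- range(idx[, 2L])
  c(x1 = c[1L] - 1, y1 = r[1L] - 1, x2 = c[2L], y2 = r[2L])
}

## Restore RNG state on exit; run expr under a given seed.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
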