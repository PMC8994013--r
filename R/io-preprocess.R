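## Sequence loading and the network's pre-processing: grayscale conversion,
## resizing to the fixed 128x256 input grid, min-max intensity scaling,
## mask binarization and assembly of the two-channel stream inputs.

#' Load an echocardiography sequence from a directory of image frames
#'
#' Reads an ordered PNG/TIFF stack (frames sorted by file name) and
#' converts each frame to single-channel grayscale.  If the directory
#' contains a `manifest.json` written by [write_phantom_sequence()] or the
#' command-line tools, frame paths and pixel spacing are taken from it.
#'
#' @param path Directory containing the frames (or a manifest).
#' @param spacing Pixel spacing in cm/pixel of the original frames;
#'   overrides any manifest value.  May be `NULL` (unknown).
#' @return An object of class `echo_sequence`: list with `frames` (list of
#'   [0,1] grayscale matrices in temporal order), `original_height`,
#'   `original_width`, `pixel_spacing`.
#' @export
load_sequence <- function(path, spacing = NULL) {
  if (!dir.exists(path)) stop("sequence path does not exist: ", path)
  manifest <- NULL
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    files <- file.path(path, manifest$frames)
    if (is.null(spacing)) spacing <- manifest$pixel_spacing
  } else {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
  }
  if (length(files) == 0L) stop("no readable frames found in ", path)
  frames <- lapply(files, function(f) ebimage_to_mat(EBImage::readImage(f)))
  shapes <- vapply(frames, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent frame shapes in ", path, ": ",
         paste(unique(shapes), collapse = ", "))
  structure(list(frames = frames,
                 original_height = nrow(frames[[1L]]),
                 original_width = ncol(frames[[1L]]),
                 pixel_spacing = spacing),
            class = "echo_sequence")
}

#' @export
print.echo_sequence <- function(x, ...) {
  cat(sprintf("echo_sequence: %d frames, %dx%d px, spacing %s cm/px\n",
              length(x$frames), x$original_height, x$original_width,
              if (is.null(x$pixel_spacing)) "unknown"
              else format(x$pixel_spacing)))
  invisible(x)
}

#' Pre-process one frame for the network
#'
#' Resizes to the network input grid (height 128 x width 256 by default,
#' bilinear) and applies min-max scaling so values span [0, 1].  A constant
#' frame cannot be scaled and is returned as all zeros with a warning.
#'
#' @param frame Grayscale matrix of nonnegative intensities.
#' @param height,width Target grid.
#' @return Matrix `height x width` with values in [0, 1].
#' @export
preprocess_frame <- function(frame, height = 128L, width = 256L) {
  stopifnot(is.matrix(frame))
  m <- resize_mat(frame, height, width, method = "bilinear")
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    warning("constant frame: min-max scaling undefined, returning zeros")
    return(matrix(0, height, width))
  }
  (m - lo) / (hi - lo)
}

#' Binarize an annotation mask
#'
#' Values greater than or equal to `threshold` become 1, all others 0.
#' Optionally resizes (nearest-neighbour, so the output stays binary).
#'
#' @param mask 2-D numeric matrix.
#' @param threshold Cut point; the threshold value itself maps to 1.
#' @param height,width Optional target grid; `NULL` keeps the input size.
#' @return Binary {0,1} matrix.
#' @export
binarize_mask <- function(mask, threshold = 0.5,
                          height = NULL, width = NULL) {
  stopifnot(is.matrix(mask))
  if (!is.null(height) && !is.null(width))
    mask <- resize_mat(mask, height, width, method = "nearest")
  out <- (mask >= threshold) * 1
  storage.mode(out) <- "double"
  out
}

#' Assemble a two-channel stream input
#'
#' Stacks a pre-processed grayscale frame and a guidance/annotation mask as
#' the two input channels of one network stream, in the fixed order
#' `[image, mask]`.  For the main stream the mask is the previous frame's
#' predicted mask; for the reference stream it is the user annotation of
#' the reference frame.
#'
#' @param frame Pre-processed frame matrix.
#' @param mask Binary mask matrix of the same shape.
#' @return Array `height x width x 2`.
#' @export
build_stream_input <- function(frame, mask) {
  if (!identical(dim(frame), dim(mask)))
    stop("frame and mask shapes differ: ",
         paste(dim(frame), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  out <- array(0, c(dim(frame), 2L))
  out[, , 1L] <- frame
  out[, , 2L] <- mask
  out
}
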