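## Synthetic beating-ventricle phantom: a bright-walled elliptical chamber
## contracting over one cardiac cycle, with multiplicative speckle-like
## noise, exact per-frame masks and analytically known volumes/EF.  Stands
## in for clinical four-chamber-view acquisitions in tests and examples.

#' Specify a synthetic beating-ventricle phantom
#'
#' Describes one cardiac cycle of a contracting elliptical chamber rendered
#' as a grayscale image sequence.  The chamber's long axis runs along image
#' rows (apex towards the bottom, base towards the top, the usual
#' four-chamber-view orientation).  Semi-axes follow a smooth cosine
#' trajectory from their end-diastolic (ED) size down to end-systole (ES)
#' and back, so each sequence contains exactly one ED and one ES.
#'
#' @param n_frames Number of frames in the cycle.
#' @param height,width Image size in pixels.
#' @param center Chamber centre as `c(row, col)` in pixels.
#' @param semi_axis_long_ed,semi_axis_short_ed ED ellipse semi-axes in
#'   pixels (long axis along rows).
#' @param contraction_long,contraction_short Fractional shrinkage of each
#'   semi-axis at ES, in (0, 1); e.g. 0.2 means the ES semi-axis is 80% of
#'   its ED length.
#' @param es_frame_fraction Position of ES within the cycle, in (0, 1).
#' @param wall_thickness Myocardial wall ring thickness in pixels.
#' @param wall_intensity,cavity_intensity,background_intensity Gray levels
#'   in [0, 1] of the wall ring, blood pool and background.
#' @param speckle_strength Amplitude of multiplicative uniform speckle-like
#'   noise (0 disables it).
#' @param pixel_spacing Physical pixel size in cm/pixel.
#' @param seed Integer seed for the speckle generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_frames = 26L,
                         height = 320L, width = 384L,
                         center = c(160, 192),
                         semi_axis_long_ed = 100,
                         semi_axis_short_ed = 55,
                         contraction_long = 0.2,
                         contraction_short = 0.28,
                         es_frame_fraction = 0.4,
                         wall_thickness = 8,
                         wall_intensity = 0.85,
                         cavity_intensity = 0.15,
                         background_intensity = 0.35,
                         speckle_strength = 0.3,
                         pixel_spacing = 0.04,
                         seed = 1L) {
  spec <- structure(list(
    n_frames = as.integer(n_frames), height = as.integer(height),
    width = as.integer(width), center = as.numeric(center),
    semi_axis_long_ed = semi_axis_long_ed,
    semi_axis_short_ed = semi_axis_short_ed,
    contraction_long = contraction_long,
    contraction_short = contraction_short,
    es_frame_fraction = es_frame_fraction,
    wall_thickness = wall_thickness,
    wall_intensity = wall_intensity,
    cavity_intensity = cavity_intensity,
    background_intensity = background_intensity,
    speckle_strength = speckle_strength,
    pixel_spacing = pixel_spacing,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_frames < 2L) stop("phantom needs at least 2 frames")
    if (!(es_frame_fraction > 0 && es_frame_fraction < 1))
      stop("es_frame_fraction must lie strictly in (0, 1)")
    if (!(contraction_long > 0 && contraction_long < 1 &&
          contraction_short > 0 && contraction_short < 1))
      stop("contraction fractions must lie strictly in (0, 1)")
    if (semi_axis_long_ed <= 0 || semi_axis_short_ed <= 0)
      stop("semi-axes must be strictly positive")
    outer_a <- semi_axis_long_ed + wall_thickness
    outer_b <- semi_axis_short_ed + wall_thickness
    if (center[1L] - outer_a < 1 || center[1L] + outer_a > height ||
        center[2L] - outer_b < 1 || center[2L] + outer_b > width)
      stop("ellipse (at ED size, including wall) does not fit inside the ",
           "image bounds")
    if (speckle_strength < 0) stop("speckle_strength must be >= 0")
    if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  })
  invisible(spec)
}

## Per-frame semi-axes: cosine interpolation ED -> ES -> ED over one cycle.
## Returns a matrix with columns a (long) and b (short), one row per frame.
## Per-frame contraction phase s(t) in [0, 1]: cosine limbs ED -> ES -> ED.
## Two choices keep the ED/ES frames of the rendered sequence unambiguous
## (the truth labels must have a margin larger than rasterisation noise):
## end-systole is snapped to the nearest frame (the trough sits ON a
## frame, not between two), and the relaxation limb is parameterised to
## reach ED again 15% beyond the last frame, the way a clinical clip
## rarely ends exactly at end-diastole -- so the final frames stay clearly
## smaller than the ED frame.
phantom_axes <- function(spec) {
  n <- spec$n_frames
  t_es <- max(1, round(spec$es_frame_fraction * n))
  t_end <- 1.05 * n
  tt <- seq_len(n) - 1
  s <- ifelse(tt <= t_es,
              (1 - cos(pi * tt / t_es)) / 2,
              (1 + cos(pi * (tt - t_es) / (t_end - t_es))) / 2)
  a <- spec$semi_axis_long_ed * (1 - spec$contraction_long * s)
  b <- spec$semi_axis_short_ed * (1 - spec$contraction_short * s)
  cbind(a = a, b = b)
}

ellipse_mask <- function(height, width, center, a, b) {
  r <- seq_len(height) - center[1L]
  c <- seq_len(width) - center[2L]
  m <- outer((r / a)^2, (c / b)^2, "+") <= 1
  storage.mode(m) <- "double"
  m
}

## Single-plane area-length chamber volume from analytic ellipse axes.
phantom_frame_volume <- function(a, b, spacing) {
  s_area <- pi * a * b * spacing^2
  len <- 2 * a * spacing
  simpson_volume(s_area, len)
}

#' Analytic cycle truth for a phantom
#'
#' ED/ES frame indices and the ejection fraction implied by the phantom's
#' analytic semi-axis trajectory, using the single-plane area-length volume
#' model (V = 8 S^2 / (3 pi L)) on the exact ellipse area and length.
#'
#' @param spec A [phantom_spec()].
#' @return List with `true_ed_index`, `true_es_index` (1-based frame
#'   indices) and `true_ef` (percent).
#' @export
analytic_cycle_truth <- function(spec) {
  validate_phantom_spec(spec)
  ax <- phantom_axes(spec)
  v <- phantom_frame_volume(ax[, "a"], ax[, "b"], spec$pixel_spacing)
  ed <- which.max(v); es <- which.min(v)
  list(true_ed_index = ed, true_es_index = es,
       true_ef = 100 * (v[ed] - v[es]) / v[ed])
}

#' Generate a synthetic beating-ventricle sequence
#'
#' Renders the phantom described by `spec`: per frame, a filled-ellipse
#' chamber mask, and a grayscale image with a dark blood pool, a bright
#' wall ring and mid-gray background, multiplied by `1 + speckle * u` with
#' `u ~ Uniform(-1, 1)` drawn from the seeded generator and clipped to
#' [0, 1].
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_sequence`: list with `frames`
#'   (list of [0,1] matrices), `masks` (list of {0,1} matrices),
#'   `true_axes` (per-frame analytic semi-axes, px), `true_volumes` (mL,
#'   from the analytic axes), `true_ed_index`, `true_es_index`, `true_ef`
#'   (percent), `pixel_spacing` and `spec`.
#' @export
generate_phantom_sequence <- function(spec) {
  validate_phantom_spec(spec)
  ax <- phantom_axes(spec)
  truth <- analytic_cycle_truth(spec)
  n <- spec$n_frames
  frames <- vector("list", n)
  masks <- vector("list", n)
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      a <- ax[i, "a"]; b <- ax[i, "b"]
      cavity <- ellipse_mask(spec$height, spec$width, spec$center, a, b)
      outer_e <- ellipse_mask(spec$height, spec$width, spec$center,
                              a + spec$wall_thickness,
                              b + spec$wall_thickness)
      wall <- outer_e * (1 - cavity)
      img <- spec$background_intensity * (1 - outer_e) +
        spec$wall_intensity * wall + spec$cavity_intensity * cavity
      if (spec$speckle_strength > 0) {
        noise <- matrix(stats::runif(length(img), -1, 1), nrow(img))
        img <- img * (1 + spec$speckle_strength * noise)
      }
      frames[[i]] <- pmin(pmax(img, 0), 1)
      masks[[i]] <- cavity
    }
  })
  structure(list(
    frames = frames, masks = masks,
    true_axes = ax,
    true_volumes = as.numeric(
      phantom_frame_volume(ax[, "a"], ax[, "b"], spec$pixel_spacing)),
    true_ed_index = truth$true_ed_index,
    true_es_index = truth$true_es_index,
    true_ef = truth$true_ef,
    pixel_spacing = spec$pixel_spacing,
    spec = spec), class = "phantom_sequence")
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cat(sprintf(
    "phantom_sequence: %d frames %dx%d, ED frame %d, ES frame %d, EF %.1f%%\n",
    length(x$frames), x$spec$height, x$spec$width,
    x$true_ed_index, x$true_es_index, x$true_ef))
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %d frames %dx%d, ED axes (%.1f, %.1f) px, contraction (%.2f, %.2f), ES at %.2f, speckle %.2f, spacing %.3f cm/px, seed %d\n",
    x$n_frames, x$height, x$width, x$semi_axis_long_ed,
    x$semi_axis_short_ed, x$contraction_long, x$contraction_short,
    x$es_frame_fraction, x$speckle_strength, x$pixel_spacing, x$seed))
  invisible(x)
}

#' Write a phantom sequence to disk
#'
#' Writes `frame_%03d.png` and `mask_%03d.png` stacks plus a
#' `manifest.json` recording paths, pixel spacing, seed and the analytic
#' truth values, so the sequence can be re-loaded with [load_sequence()].
#'
#' @param seq_obj A [generate_phantom_sequence()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_sequence <- function(seq_obj, dir) {
  stopifnot(inherits(seq_obj, "phantom_sequence"))
  frame_dir <- file.path(dir, "frames")
  mask_dir <- file.path(dir, "masks")
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(seq_obj$frames)
  fp <- file.path(frame_dir, sprintf("frame_%03d.png", seq_len(n)))
  mp <- file.path(mask_dir, sprintf("mask_%03d.png", seq_len(n)))
  for (i in seq_len(n)) {
    EBImage::writeImage(mat_to_ebimage(seq_obj$frames[[i]]), fp[i])
    EBImage::writeImage(mat_to_ebimage(seq_obj$masks[[i]]), mp[i])
  }
  manifest <- list(
    frames = file.path("frames", basename(fp)),
    masks = file.path("masks", basename(mp)),
    pixel_spacing = seq_obj$pixel_spacing,
    seed = seq_obj$spec$seed,
    true_ed_index = seq_obj$true_ed_index,
    true_es_index = seq_obj$true_es_index,
    true_ef = seq_obj$true_ef,
    true_volumes = seq_obj$true_volumes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
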