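#' Image geometry of an AS-OCT B-scan
#'
#' Describes the pixel grid of a B-scan and its physical calibration.
#' Conventions used throughout the package: pixel indices are 0-based with
#' pixel centers at integer coordinates, `x` runs along the scan (lateral)
#' and `y` increases downward, into the tissue.  Physical coordinates are in
#' micrometers: column `c` sits at `x = c * pitch_h`, row `r` at
#' `y = r * pitch_v`.
#'
#' The default geometry is the resized scan grid used for isotropic
#' measurement: 2648 x 640 pixels covering 8 mm x 1.933 mm, so each pixel
#' spans roughly 3 um in both directions.
#'
#' @param width_px,height_px grid dimensions in pixels.
#' @param pitch_h,pitch_v lateral / axial pixel pitch in um per pixel.
#' @return An object of class `image_geometry`.
#' @examples
#' g <- image_geometry()
#' g$pitch_v * g$height_px  # 1933 um axial extent
#' @export
image_geometry <- function(width_px = 2648L, height_px = 640L,
                           pitch_h = 8000 / 2648, pitch_v = 1933 / 640) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (width_px <= 0L || height_px <= 0L)
    stop("grid dimensions must be strictly positive")
  if (!is.finite(pitch_h) || !is.finite(pitch_v) || pitch_h <= 0 || pitch_v <= 0)
    stop("pixel pitches must be strictly positive")
  structure(
    list(width_px = width_px, height_px = height_px,
         pitch_h = pitch_h, pitch_v = pitch_v),
    class = "image_geometry"
  )
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d px, pitch %.3f x %.3f um/px (%.2f x %.3f mm)\n",
              x$width_px, x$height_px, x$pitch_h, x$pitch_v,
              x$width_px * x$pitch_h / 1000, x$height_px * x$pitch_v / 1000))
  invisible(x)
}

# physical x positions (um) of all pixel-column centers
column_x_um <- function(geometry) {
  (seq_len(geometry$width_px) - 1L) * geometry$pitch_h
}

# physical x (um) of the central column (scans are pupil-fixated, so this is
# where the reference point lives)
central_x_um <- function(geometry) {
  (geometry$width_px - 1L) / 2 * geometry$pitch_h
}

#' Keratoconus stage labels
#'
#' The five cohort groups in increasing disease severity, coded as ordinals
#' 0 (normal) through 4 (scarring).  Stage labels are study inputs (graded
#' clinically from corneal curvature); they are never computed here.
#'
#' @param x stage names (character) or ordinals (integers 0-4).
#' @return For `stage_factor`, an ordered factor over the five stages; for
#'   `stage_ordinal`, integer ordinals 0-4.
#' @examples
#' stage_ordinal(c("normal", "severe"))  # 0 3
#' @export
stage_levels <- function() c("normal", "mild", "moderate", "severe", "scarring")

#' @rdname stage_levels
#' @export
stage_factor <- function(x) {
  if (is.numeric(x)) x <- stage_levels()[as.integer(x) + 1L]
  if (any(!x %in% stage_levels()))
    stop("unknown stage name: ", paste(setdiff(x, stage_levels()), collapse = ", "))
  factor(x, levels = stage_levels(), ordered = TRUE)
}

#' @rdname stage_levels
#' @export
stage_ordinal <- function(x) {
  as.integer(stage_factor(x)) - 1L
}
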