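# File interchange: label masks as single-channel PNG (pixel values 0/1/2)
# with a JSON sidecar carrying the geometry and scan metadata; grayscale
# renders as 8-bit PNG; profiles as CSV.

#' Write / read a label mask as PNG + JSON sidecar
#'
#' The PNG stores raw labels 0 (background), 1 (epithelium), 2 (stroma) in
#' a single 8-bit channel; `<path>.json` carries the pixel geometry, stage,
#' laterality, meridian and seed.
#'
#' @param mask a `label_mask`.
#' @param path output PNG path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a `label_mask`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(mask$labels / 255, target = path)
  g <- mask$geometry
  side <- list(width_px = g$width_px, height_px = g$height_px,
               pitch_h = g$pitch_h, pitch_v = g$pitch_v)
  jsonlite::write_json(c(side, mask$meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  lab <- round(raw * 255)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- image_geometry(meta$width_px, meta$height_px, meta$pitch_h, meta$pitch_v)
  label_mask(lab, g,
             meta = meta[setdiff(names(meta),
                                 c("width_px", "height_px", "pitch_h", "pitch_v"))])
}

#' Write a grayscale render as 8-bit PNG
#'
#' @param render a `bscan_render` (or numeric matrix in [0, 255]).
#' @param path output PNG path.
#' @export
write_render_png <- function(render, path) {
  img <- if (inherits(render, "bscan_render")) render$image else render
  png::writePNG(pmin(pmax(img / 255, 0), 1), target = path)
  invisible(path)
}

#' Write / read cohort profiles as CSV
#'
#' Long-form CSV with columns eye_id, stage, laterality, meridian, tissue,
#' position_mm, thickness_um.
#'
#' @param profiles data.frame from [measure_cohort()].
#' @param path CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
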