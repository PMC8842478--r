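# Segmentation-quality metrics: pixel-overlap measures (Dice, IoU,
# sensitivity, specificity) and the indirect thickness-error metric that
# compares measured profiles between a candidate and a reference
# segmentation.

target_class_pixels <- function(mask, target) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  switch(target,
         epithelium = lab == 1L,
         cornea = lab == 1L | lab == 2L,
         stop("target class must be 'epithelium' or 'cornea'"))
}

#' Pixel-overlap segmentation metrics
#'
#' Dice, IoU, sensitivity and specificity of a candidate segmentation
#' against a reference, for one target class ("epithelium" = epithelium
#' pixels, "cornea" = epithelium and stroma).  Negatives are all remaining
#' pixels of the grid.
#'
#' @param candidate,reference `label_mask`s (or bare label matrices) on the
#'   same grid.
#' @param target `"epithelium"` or `"cornea"`.
#' @return A list: dice, iou, sensitivity, specificity.
#' @export
overlap_metrics <- function(candidate, reference, target = c("cornea", "epithelium")) {
  target <- match.arg(target)
  A <- target_class_pixels(candidate, target)
  B <- target_class_pixels(reference, target)
  if (!all(dim(A) == dim(B))) stop("mask grids differ in shape")
  nB <- sum(B); nA <- sum(A)
  if (nB == 0) stop("undefined metrics: reference contains no target pixels")
  tp <- sum(A & B); fp <- nA - tp; fn <- nB - tp
  tn <- length(A) - tp - fp - fn
  dice <- 2 * tp / (nA + nB)
  list(dice = dice,
       iou = tp / (nA + nB - tp),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Indirect thickness-error metric
#'
#' Mean absolute difference (um) between candidate and reference thickness
#' profiles measured at the same 40 sample positions.
#'
#' @param candidate,reference `thickness_profile`s, or lists of them
#'   (matched element-wise).
#' @return Mean absolute thickness difference in um.
#' @export
thickness_error <- function(candidate, reference) {
  if (inherits(candidate, "thickness_profile")) candidate <- list(candidate)
  if (inherits(reference, "thickness_profile")) reference <- list(reference)
  if (length(candidate) != length(reference))
    stop("candidate and reference profile lists differ in length")
  diffs <- unlist(Map(function(a, b) {
    stopifnot(inherits(a, "thickness_profile"), inherits(b, "thickness_profile"))
    if (max(abs(a$positions - b$positions)) > 1e-9)
      stop("profile position grids differ")
    abs(a$values - b$values)
  }, candidate, reference))
  mean(diffs)
}

# reconstruct a label mask from extracted boundary traces (used to score
# the image path with pixel-overlap metrics)
mask_from_bset <- function(bset) {
  g <- bset$geometry
  cols <- column_x_um(g)
  ya <- stats::approx(bset$anterior$x, bset$anterior$y, xout = cols, rule = 1)$y
  yi <- stats::approx(bset$epithelial_interface$x, bset$epithelial_interface$y,
                      xout = cols, rule = 1)$y
  yp <- stats::approx(bset$posterior$x, bset$posterior$y, xout = cols, rule = 1)$y
  y <- (seq_len(g$height_px) - 1L) * g$pitch_v
  Y <- matrix(y, g$height_px, g$width_px)
  A <- matrix(ya, g$height_px, g$width_px, byrow = TRUE)
  I <- matrix(yi, g$height_px, g$width_px, byrow = TRUE)
  P <- matrix(yp, g$height_px, g$width_px, byrow = TRUE)
  lab <- matrix(0L, g$height_px, g$width_px)
  lab[!is.na(A) & Y >= A & Y < I] <- 1L
  lab[!is.na(A) & Y >= I & Y < P] <- 2L
  label_mask(lab, g, meta = bset$meta)
}

#' Evaluate a boundary extractor against phantom references
#'
#' Runs the chosen extraction path on every scan of a phantom cohort and
#' scores it against the rasterized reference masks and reference
#' (mask-path) thickness profiles: per-scan overlap metrics averaged per
#' group and tissue, plus the mean absolute thickness error.
#'
#' @param cohort a `phantom_cohort` (keep it small: every scan is
#'   rasterized at the given geometry).
#' @param mode `"mask"` (trace the reference mask itself; the exact path)
#'   or `"image"` (render with speckle, then gradient extraction).
#' @param geometry an `image_geometry`.
#' @param noise_params passed to [render_bscan()] in image mode.
#' @param group_by `"kc"` collapses stages into normal vs KC (the reported
#'   layout); `"stage"` keeps all five groups.
#' @return A data.frame: group, tissue, n_scans, dice, iou, sensitivity,
#'   specificity, t_error_um.
#' @export
evaluate_extractor <- function(cohort, mode = c("mask", "image"),
                               geometry = image_geometry(),
                               noise_params = list(),
                               group_by = c("kc", "stage")) {
  mode <- match.arg(mode)
  group_by <- match.arg(group_by)
  if (length(cohort) == 0) stop("empty cohort")
  rows <- list()
  for (eye in cohort) {
    for (mer in c("h", "v")) {
      spec <- eye[[paste0("spec_", mer)]]
      truth <- boundaries_from_spec(spec)
      ref_mask <- rasterize_masks(truth, geometry)
      ref_bset <- trace_from_mask(ref_mask)
      ref_prof <- measure_profile(ref_bset, eye_id = eye$eye_id, stage = eye$stage)
      cand_bset <- if (mode == "mask") {
        trace_from_mask(ref_mask)
      } else {
        trace_from_image(render_bscan(truth, geometry, noise_params,
                                      seed = spec$seed),
                         laterality = spec$laterality, meridian = spec$meridian)
      }
      cand_mask <- if (mode == "mask") ref_mask else mask_from_bset(cand_bset)
      cand_prof <- measure_profile(cand_bset, eye_id = eye$eye_id, stage = eye$stage)
      for (tis in c("epithelium", "cornea")) {
        om <- overlap_metrics(cand_mask, ref_mask, tis)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = eye$stage, tissue = tis,
          dice = om$dice, iou = om$iou,
          sensitivity = om$sensitivity, specificity = om$specificity,
          t_error_um = thickness_error(cand_prof[[tis]], ref_prof[[tis]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  df$group <- if (group_by == "kc")
    ifelse(df$stage == "normal", "normal", "KC") else df$stage
  agg <- stats::aggregate(
    df[, c("dice", "iou", "sensitivity", "specificity", "t_error_um")],
    by = list(group = df$group, tissue = df$tissue), FUN = mean)
  n <- stats::aggregate(list(n_scans = df$dice),
                        by = list(group = df$group, tissue = df$tissue),
                        FUN = length)
  out <- merge(n, agg, by = c("group", "tissue"))
  out[order(out$tissue, out$group), ]
}
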