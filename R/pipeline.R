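# Cohort-scale pipeline: specs -> boundaries -> profiles -> zones ->
# group statistics -> ectasia indices -> stage screening.  These drivers
# glue the per-scan operations together; every scientific step lives in
# its own module.

#' Measure thickness profiles for a whole cohort
#'
#' Runs the per-scan measurement over every scan of a phantom cohort and
#' returns the profiles in long form, mirrored to the common left-eye
#' orientation.  The `"truth"` path samples the analytic boundary curves at
#' pixel columns (exact boundaries, the default at cohort scale); the
#' `"mask"` path rasterizes each scan and re-traces the label mask
#' (discretized boundaries, about one pixel of quantization).
#'
#' @param cohort a `phantom_cohort`.
#' @param geometry an `image_geometry`.
#' @param path `"truth"` or `"mask"`.
#' @return A data.frame: eye_id, stage, laterality, meridian, tissue,
#'   position_mm (common orientation), thickness_um.
#' @export
measure_cohort <- function(cohort, geometry = image_geometry(),
                           path = c("truth", "mask")) {
  path <- match.arg(path)
  stopifnot(inherits(cohort, "phantom_cohort"))
  pos <- sample_positions()
  rows <- vector("list", length(cohort) * 4L)
  k <- 0L
  for (eye in cohort) {
    for (mer in c("h", "v")) {
      spec <- eye[[paste0("spec_", mer)]]
      truth <- boundaries_from_spec(spec)
      bset <- if (path == "truth") trace_from_truth(truth, geometry)
              else trace_from_mask(rasterize_masks(truth, geometry))
      prof <- measure_profile(bset, eye_id = eye$eye_id, stage = eye$stage)
      for (tis in c("epithelium", "cornea")) {
        p <- mirror_to_common_orientation(prof[[tis]])
        k <- k + 1L
        rows[[k]] <- data.frame(
          eye_id = eye$eye_id, stage = eye$stage,
          laterality = eye$laterality, meridian = p$meridian, tissue = tis,
          position_mm = pos, thickness_um = p$values,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Zone table of a cohort profile data.frame
#'
#' Collapses 40-point profiles to the 20-zone representation (zone j =
#' mean of samples 2j-1, 2j; zone 1 most temporal/inferior).
#'
#' @param profiles data.frame from [measure_cohort()].
#' @return A data.frame: eye_id, stage, meridian, tissue, zone, value.
#' @export
zone_table <- function(profiles) {
  needed <- c("eye_id", "stage", "meridian", "tissue", "position_mm", "thickness_um")
  stopifnot(all(needed %in% names(profiles)))
  profiles <- profiles[order(profiles$eye_id, profiles$meridian,
                             profiles$tissue, profiles$position_mm), ]
  idx <- stats::ave(profiles$thickness_um,
                    profiles$eye_id, profiles$meridian, profiles$tissue,
                    FUN = seq_along)
  profiles$zone <- (as.integer(idx) + 1L) %/% 2L
  agg <- stats::aggregate(
    list(value = profiles$thickness_um),
    by = profiles[, c("eye_id", "stage", "meridian", "tissue", "zone")],
    FUN = mean)
  agg[order(agg$eye_id, agg$meridian, agg$tissue, agg$zone), ]
}

#' Zone-level group statistics for a cohort
#'
#' For every meridian x tissue x zone: per-group mean and 95% CI, the
#' one-way ANOVA across stage groups, and the OLS thickness-vs-stage
#' trend.
#'
#' @param zones data.frame from [zone_table()].
#' @return A list of data.frames: `summaries` (zone, meridian, tissue,
#'   stage, n, mean, ci_low, ci_high), `anova` (zone, meridian, tissue, F,
#'   p), `trends` (zone, meridian, tissue, slope, intercept, p).
#' @export
cohort_zone_stats <- function(zones) {
  cells <- unique(zones[, c("meridian", "tissue", "zone")])
  summaries <- list(); anovas <- list(); trends <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- zones[zones$meridian == cell$meridian & zones$tissue == cell$tissue &
                   zones$zone == cell$zone, ]
    groups <- split(sub$value, factor(sub$stage, levels = stage_levels()))
    groups <- groups[vapply(groups, length, 0L) > 0L]
    for (st in names(groups)) {
      zs <- zone_group_summary(groups[[st]])
      summaries[[length(summaries) + 1L]] <- data.frame(
        cell, stage = st, n = zs$n, mean = zs$mean,
        ci_low = zs$ci_low, ci_high = zs$ci_high)
    }
    av <- anova_by_zone(groups)
    anovas[[length(anovas) + 1L]] <- data.frame(cell, F = av$F, p = av$p)
    tr <- zone_trend(sub$value, stage_ordinal(sub$stage))
    trends[[length(trends) + 1L]] <- data.frame(
      cell, slope = tr$slope, intercept = tr$intercept, p = tr$p)
  }
  list(summaries = do.call(rbind, summaries),
       anova = do.call(rbind, anovas),
       trends = do.call(rbind, trends))
}

#' Per-eye ectasia-index features
#'
#' Computes the four thickness ectasia indices for every eye of a cohort
#' profile data.frame (requires all four profiles per eye).
#'
#' @param profiles data.frame from [measure_cohort()].
#' @return A data.frame: eye_id, stage, EEI_H, EEI_V, CEI_H, CEI_V.
#' @export
cohort_features <- function(profiles) {
  build <- function(sub) {
    sub <- sub[order(sub$position_mm), ]
    thickness_profile(sub$meridian[1], sub$tissue[1], sub$position_mm,
                      sub$thickness_um, sub$eye_id[1], sub$stage[1])
  }
  out <- list()
  for (sub_eye in split(profiles, profiles$eye_id)) {
    pr <- split(sub_eye, paste(sub_eye$tissue, sub_eye$meridian, sep = "_"))
    if (!all(c("epithelium_H", "epithelium_V", "cornea_H", "cornea_V") %in% names(pr)))
      stop("eye ", sub_eye$eye_id[1], " is missing a meridian or tissue")
    idx <- ectasia_indices(build(pr$epithelium_H), build(pr$epithelium_V),
                           build(pr$cornea_H), build(pr$cornea_V))
    out[[length(out) + 1L]] <- data.frame(
      eye_id = sub_eye$eye_id[1], stage = sub_eye$stage[1],
      t(idx), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
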