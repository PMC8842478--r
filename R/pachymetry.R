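# Normal-line pachymetry: reference point at the scan center (pupil-fixated
# acquisition), a 6 mm ROI, 40 sample points every 0.15 mm of arc along the
# anterior surface, and epithelial / corneal thickness measured along the
# local inward surface normal.

ROI_HALFWIDTH_MM <- 3
SAMPLE_SPACING_MM <- 0.15
N_SAMPLES <- 40L

#' Thickness profile of one scan
#'
#' Bundles the 40 sampled thickness values of one tissue along one meridian.
#' Positions are signed mm from the reference point: negative is temporal
#' (horizontal meridian, common left-eye orientation) or inferior (vertical
#' meridian).
#'
#' @param meridian `"H"` or `"V"`.
#' @param tissue `"epithelium"` or `"cornea"`.
#' @param positions 40 strictly increasing positions (mm), spaced 0.15 mm,
#'   symmetric about 0.
#' @param values 40 positive thickness values (um).
#' @param eye_id,stage,laterality scan metadata.
#' @return An object of class `thickness_profile`.
#' @export
thickness_profile <- function(meridian, tissue, positions, values,
                              eye_id = NA_character_, stage = NA_character_,
                              laterality = "OS") {
  if (length(positions) != N_SAMPLES || length(values) != N_SAMPLES)
    stop("a thickness profile has exactly 40 positions and values")
  if (any(diff(positions) <= 0) ||
      max(abs(diff(positions) - SAMPLE_SPACING_MM)) > 1e-9 ||
      abs(sum(positions)) > 1e-9)
    stop("positions must increase by 0.15 mm and be symmetric about 0")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("thickness values must be positive and finite")
  structure(
    list(meridian = meridian, tissue = tissue,
         positions = as.numeric(positions), values = as.numeric(values),
         eye_id = eye_id, stage = stage, laterality = laterality),
    class = "thickness_profile"
  )
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("<thickness_profile> %s %s/%s (%s): %.1f-%.1f um, min %.1f @ %+.3f mm\n",
              x$tissue, x$laterality, x$meridian,
              ifelse(is.na(x$eye_id), "?", x$eye_id),
              min(x$values), max(x$values),
              min(x$values), x$positions[which.min(x$values)]))
  invisible(x)
}

#' Locate the measurement reference point
#'
#' Scans are pupil-fixated, so the pupil center projects to the central
#' image column; the reference point is the anterior-surface point there,
#' with `y` linearly interpolated between neighboring columns.
#'
#' @param bset a `boundary_set`.
#' @return A list `(x, y)` in um on the anterior trace.
#' @export
locate_reference <- function(bset) {
  stopifnot(inherits(bset, "boundary_set"))
  xc <- central_x_um(bset$geometry)
  y <- stats::approx(bset$anterior$x, bset$anterior$y, xout = xc, rule = 1)$y
  if (is.na(y))
    stop("anterior trace does not span the central column")
  list(x = xc, y = y)
}

#' The 40 sampling positions of the 6 mm ROI
#'
#' Forty signed positions in mm: the centers of 40 contiguous 0.15 mm bins
#' spanning [-3, +3] mm of arc around the reference point, i.e. -2.925,
#' -2.775, ..., +2.925.
#'
#' @param bset optional `boundary_set`; when given, the anterior trace must
#'   cover 3 mm of arc on both sides of the reference point.
#' @return Numeric vector of 40 positions (mm).
#' @export
sample_positions <- function(bset = NULL) {
  pos <- seq(-(ROI_HALFWIDTH_MM - SAMPLE_SPACING_MM / 2),
             ROI_HALFWIDTH_MM - SAMPLE_SPACING_MM / 2,
             by = SAMPLE_SPACING_MM)
  if (!is.null(bset)) {
    arc <- anterior_arc_coords(bset)
    if (arc$s_ref - 1000 * ROI_HALFWIDTH_MM < 0 ||
        arc$s_ref + 1000 * ROI_HALFWIDTH_MM > max(arc$s))
      stop("anterior trace does not cover the 6 mm ROI")
  }
  pos
}

# cumulative arc length (um) along the anterior trace and the reference
# point's arc coordinate
anterior_arc_coords <- function(bset) {
  a <- bset$anterior
  seg <- sqrt(diff(a$x)^2 + diff(a$y)^2)
  s <- c(0, cumsum(seg))
  ref <- locate_reference(bset)
  s_ref <- stats::approx(a$x, s, xout = ref$x)$y
  list(s = s, s_ref = s_ref, x = a$x, y = a$y)
}

#' Inward surface normal of a boundary trace
#'
#' Fits a local quadratic to `y(x)` over `x0 +/- fit_halfwidth` and returns
#' the inward (toward the posterior, +y) unit normal at `x0`.
#'
#' @param trace a `boundary_trace`.
#' @param x0 lateral position (um) inside the trace.
#' @param fit_halfwidth half-width of the fit window (um), default 300.
#' @return Unit vector `c(nx, ny)` with `ny > 0`.
#' @export
surface_normal <- function(trace, x0, fit_halfwidth = 300) {
  stopifnot(inherits(trace, "boundary_trace"))
  i <- which(trace$x >= x0 - fit_halfwidth & trace$x <= x0 + fit_halfwidth)
  if (length(i) < 5)
    stop("too few trace points in the normal-fit window")
  dx <- trace$x[i] - x0
  X <- cbind(1, dx, dx^2)
  beta <- qr.coef(qr(X), trace$y[i])
  slope <- beta[2]
  n <- c(-slope, 1) / sqrt(1 + slope^2)
  unname(n)
}

# linear interpolation of a trace's y at arbitrary x (NA outside)
trace_y_at <- function(trace, x) {
  stats::approx(trace$x, trace$y, xout = x, rule = 1)$y
}

#' Thickness along a surface normal
#'
#' Marches from an anterior-surface point along the inward normal in 0.5 um
#' steps until the ray first crosses the target trace, then refines the
#' crossing by bisection to better than 0.1 um.  The first crossing along
#' the ray is used.
#'
#' @param p anterior point `c(x, y)` in um.
#' @param n inward unit direction `c(nx, ny)` with `ny > 0`.
#' @param target a `boundary_trace` (epithelium-stroma interface or
#'   posterior surface).
#' @param step marching step (um).
#' @param max_range give up beyond this distance (um).
#' @param tol bisection tolerance (um).
#' @return Thickness in um (distance to the first intersection).
#' @export
thickness_along_normal <- function(p, n, target, step = 0.5,
                                   max_range = 2000, tol = 0.1) {
  stopifnot(inherits(target, "boundary_trace"))
  if (n[2] <= 0) stop("normal must point into the tissue (+y)")
  t_grid <- seq(0, max_range, by = step)
  g <- (p[2] + t_grid * n[2]) - trace_y_at(target, p[1] + t_grid * n[1])
  cross <- which(!is.na(g[-1]) & !is.na(g[-length(g)]) &
                   g[-length(g)] < 0 & g[-1] >= 0)
  if (length(cross) == 0)
    stop("no intersection with the target trace within the marching range")
  lo <- t_grid[cross[1]]; hi <- t_grid[cross[1] + 1L]
  gfun <- function(t) (p[2] + t * n[2]) - trace_y_at(target, p[1] + t * n[1])
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gfun(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Measure epithelial and corneal thickness profiles
#'
#' The full per-scan measurement: validates the boundary set, places the 40
#' ROI sample points by arc length along the anterior surface, and measures
#' thickness to the epithelium-stroma interface (epithelial) and to the
#' posterior surface (corneal) along the local inward normal at each point.
#'
#' @param bset a `boundary_set`.
#' @param eye_id,stage optional metadata overriding the boundary set's.
#' @return A list with `thickness_profile` elements `epithelium` and
#'   `cornea`.
#' @export
measure_profile <- function(bset, eye_id = NULL, stage = NULL) {
  v <- validate_boundaries(bset, ROI_HALFWIDTH_MM)
  if (!v$passed)
    stop("boundary set fails validation: ",
         if (!v$ordering_ok) "ordering violated " else "",
         if (!v$coverage_ok) "ROI not covered" else "")
  pos <- sample_positions(bset)
  arc <- anterior_arc_coords(bset)
  s_t <- arc$s_ref + pos * 1000
  x0 <- stats::approx(arc$s, arc$x, xout = s_t)$y
  y0 <- stats::approx(arc$x, arc$y, xout = x0)$y

  epi <- numeric(N_SAMPLES); cor <- numeric(N_SAMPLES)
  for (k in seq_len(N_SAMPLES)) {
    nrm <- surface_normal(bset$anterior, x0[k])
    p <- c(x0[k], y0[k])
    epi[k] <- tryCatch(
      thickness_along_normal(p, nrm, bset$epithelial_interface),
      error = function(e) stop(sprintf("position %+.3f mm (epithelium): %s",
                                       pos[k], conditionMessage(e))))
    cor[k] <- tryCatch(
      thickness_along_normal(p, nrm, bset$posterior),
      error = function(e) stop(sprintf("position %+.3f mm (cornea): %s",
                                       pos[k], conditionMessage(e))))
  }
  if (any(epi >= cor))
    stop("epithelial thickness >= corneal thickness at some sample")
  id <- if (!is.null(eye_id)) eye_id else
    if (!is.null(bset$meta$eye_id)) bset$meta$eye_id else NA_character_
  st <- if (!is.null(stage)) stage else
    if (!is.null(bset$meta$stage)) bset$meta$stage else NA_character_
  list(
    epithelium = thickness_profile(bset$meridian, "epithelium", pos, epi,
                                   id, st, bset$laterality),
    cornea = thickness_profile(bset$meridian, "cornea", pos, cor,
                               id, st, bset$laterality)
  )
}

#' Mirror a profile to the common left-eye orientation
#'
#' Horizontal scans of right eyes view the cornea mirror-imaged; for
#' between-eye comparison they are mirrored onto the left-eye frame by
#' negating positions (equivalently, reversing the value sequence on the
#' fixed symmetric grid).  Left-eye and all vertical profiles are returned
#' unchanged.  The operation is an involution.
#'
#' @param profile a `thickness_profile`.
#' @param laterality defaults to the profile's own laterality.
#' @return A `thickness_profile` in the common orientation.
#' @export
mirror_to_common_orientation <- function(profile, laterality = NULL) {
  stopifnot(inherits(profile, "thickness_profile"))
  if (is.null(laterality)) laterality <- profile$laterality
  if (profile$meridian == "H" && identical(laterality, "OD")) {
    profile$values <- rev(profile$values)
  }
  profile
}
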