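# Synthetic corneal-phantom generator.
#
# Each phantom is a 1-D cross-section (one B-scan) of a cornea: a circular
# anterior surface plus analytic epithelial and corneal thickness functions
# of arc position, from which the epithelium-stroma interface and posterior
# surface are constructed by stepping along the inward anterior normal.
# Because the deeper boundaries are built by normal offset, normal-line
# pachymetry recovers the thickness functions exactly -- the phantom is its
# own measurement oracle.

# run expr with a private RNG stream; the caller's RNG state is untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Per-stage generator defaults
#'
#' Central (cone-apex) corneal and epithelial thickness per stage, the
#' between-eye spreads, and the cone width.  The central values are the
#' midpoints of the published per-group 95% confidence intervals for the
#' thinnest-zone thickness; spreads are chosen so that simulated confidence
#' intervals at the study group sizes have comparable width.  Cone width
#' shrinks with severity so the focal thinning sharpens as keratoconus
#' progresses.
#'
#' @return A data.frame with one row per stage: apex corneal / epithelial
#'   thickness means and between-eye standard deviations (um), and the
#'   default cone width sigma (mm).
#' @export
stage_defaults <- function() {
  data.frame(
    stage   = stage_levels(),
    ct_apex = c(504.5, 496.0, 475.7, 455.3, 376.1),
    ct_sd   = c(39.5, 33.9, 37.2, 49.5, 55.0),
    et_apex = c(48.9, 48.2, 43.7, 40.3, 46.9),
    et_sd   = c(5.7, 6.0, 6.6, 7.1, 12.0),
    sigma   = c(1.4, 1.2, 1.0, 0.8, 0.8),
    stringsAsFactors = FALSE
  )
}

# peripheral defaults (no published values; typical human cornea)
.PERIPH_CT <- 620   # um, normal-stage peripheral corneal thickness
.PERIPH_ET <- 52    # um, peripheral epithelial thickness
.ANTERIOR_R <- 7800 # um, anterior radius of curvature
.APEX_DEPTH <- 60   # um, depth of the anterior apex below the image top

#' Draw a phantom specification for one scan
#'
#' Samples the generative parameters of a single synthetic B-scan around the
#' stage's defaults.  Deterministic given `(stage, laterality, meridian,
#' seed)`.  The cone center offset is stored in the common (left-eye)
#' orientation: negative means temporal for horizontal scans and inferior
#' for vertical scans.  Every eye receives a small irregular epithelial
#' undulation (about 1.5 um); scarring-stage specs set `scar = TRUE` and a
#' much larger fluctuation amplitude (about 6 um).
#'
#' @param stage stage name, one of `stage_levels()`.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param meridian `"H"` or `"V"`.
#' @param seed integer RNG seed for this scan.
#' @return An object of class `phantom_spec`.
#' @examples
#' make_phantom_spec("severe", "OS", "H", seed = 7)
#' @export
make_phantom_spec <- function(stage, laterality = "OS", meridian = "H", seed = 1L) {
  stage <- as.character(stage_factor(stage))
  laterality <- match.arg(laterality, c("OD", "OS"))
  meridian <- match.arg(meridian, c("H", "V"))
  d <- stage_defaults()
  d <- d[d$stage == stage, ]
  scar <- stage == "scarring"

  with_local_seed(seed, {
    apex_ct <- stats::rnorm(1, d$ct_apex, d$ct_sd)
    apex_et <- rnorm_trunc(1, d$et_apex, d$et_sd, lo = 20)
    # peripheral thickness tracks the apex with a stage-independent mean gap
    # (whole-cornea thinning accompanies apical thinning) plus its own
    # between-eye variation, so the center-to-periphery ratio varies
    # realistically between eyes
    periph_ct <- apex_ct + (.PERIPH_CT - 504.5) + stats::rnorm(1, 0, 40)
    periph_ct <- max(periph_ct, apex_ct + 30)
    periph_et <- apex_et + (.PERIPH_ET - d$et_apex) + stats::rnorm(1, 0, 2.5)
    if (!scar) periph_et <- max(periph_et, apex_et + 0.5)
    spec <- structure(
      list(
        stage = stage,
        anterior_radius = rnorm_trunc(1, .ANTERIOR_R, 100, 7200, 8400),
        apex_corneal_thickness = apex_ct,
        peripheral_corneal_thickness = periph_ct,
        apex_epithelial_thickness = apex_et,
        peripheral_epithelial_thickness = periph_et,
        cone_center_offset = rnorm_trunc(1, -0.45, 0.10, -0.75, -0.15),
        cone_sigma = rnorm_trunc(1, d$sigma, 0.06, lo = 0.4),
        # every epithelium undulates a little; scarring much more
        epithelial_fluctuation_amp = if (scar) rnorm_trunc(1, 6, 1, lo = 3)
                                     else rnorm_trunc(1, 1.5, 0.4, lo = 0.5),
        scar = scar,
        laterality = laterality,
        meridian = meridian,
        seed = as.integer(seed)
      ),
      class = "phantom_spec"
    )
    validate_phantom_spec(spec)
    spec
  })
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$cone_sigma <= 0) stop("cone_sigma must be positive")
  if (spec$apex_corneal_thickness <= 0)
    stop("apex corneal thickness must be positive")
  if (!spec$scar &&
      spec$apex_corneal_thickness > spec$peripheral_corneal_thickness)
    stop("apex corneal thickness exceeds peripheral in a non-scarring spec")
  if (spec$apex_epithelial_thickness >= spec$peripheral_corneal_thickness)
    stop("apex epithelial thickness must be below peripheral corneal thickness")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s %s/%s seed=%d | CT %.1f->%.1f um, ET %.1f->%.1f um, cone %.2f mm @ %.2f mm%s\n",
    x$stage, x$laterality, x$meridian, x$seed,
    x$apex_corneal_thickness, x$peripheral_corneal_thickness,
    x$apex_epithelial_thickness, x$peripheral_epithelial_thickness,
    x$cone_sigma, x$cone_center_offset,
    if (x$scar) sprintf(", scar (fluct %.1f um)", x$epithelial_fluctuation_amp) else ""
  ))
  invisible(x)
}

# smooth zero-mean fluctuation of given amplitude (sd, um) and ~0.5 mm
# correlation length, as a function of arc position s (um)
make_fluctuation <- function(seed, amplitude, extent_um, corr_um = 500) {
  knots <- seq(-extent_um - 2 * corr_um, extent_um + 2 * corr_um, by = corr_um / 2)
  raw <- with_local_seed(seed + 104729L, stats::rnorm(length(knots)))
  # gaussian smoothing over the knot values
  w <- stats::dnorm(seq(-3, 3, by = 0.5))
  sm <- stats::filter(raw, w / sum(w), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- sm - mean(sm)
  s_ <- stats::sd(sm)
  if (s_ > 0) sm <- sm / s_ * amplitude
  f <- stats::splinefun(knots, sm, method = "natural")
  f
}

#' Analytic boundary geometry of a phantom
#'
#' Realizes a `phantom_spec` as continuous boundary curves.  The anterior
#' surface is a circular arc; corneal thickness along the surface is
#' `T(s) = peripheral - (peripheral - apex) * exp(-(s - s0)^2 / (2 sigma^2))`
#' with `s` the arc position (mm from the apex / scan center), and the
#' epithelial thickness `E(s)` is analogous.  For scarring phantoms a
#' smooth seeded zero-mean fluctuation is added to `E(s)`.  The interface
#' and posterior curves are constructed by stepping `E(s)` and `T(s)` along
#' the inward anterior normal, so normal-line measurement recovers both
#' exactly.
#'
#' The cone offset is stored in the common left-eye orientation; for a
#' right-eye horizontal scan the realized scan has it mirrored, so that
#' mirroring measured profiles back to the common orientation places the
#' cone on the temporal side.
#'
#' @param spec a `phantom_spec`.
#' @param extent_mm half-extent of the modeled arc, in mm (default covers
#'   the full default image width with margin).
#' @return An object of class `boundary_truth`: functions mapping arc
#'   position in um to points and thickness.
#' @export
boundaries_from_spec <- function(spec, extent_mm = 4.35) {
  validate_phantom_spec(spec)
  R <- spec$anterior_radius
  # scan-frame cone offset: OD horizontal scans are mirrored acquisitions
  s0 <- spec$cone_center_offset * 1000
  if (spec$meridian == "H" && spec$laterality == "OD") s0 <- -s0
  sig <- spec$cone_sigma * 1000
  pT <- spec$peripheral_corneal_thickness
  aT <- spec$apex_corneal_thickness
  pE <- spec$peripheral_epithelial_thickness
  aE <- spec$apex_epithelial_thickness
  extent_um <- extent_mm * 1000

  fluct <- if (spec$epithelial_fluctuation_amp > 0)
    make_fluctuation(spec$seed, spec$epithelial_fluctuation_amp, extent_um)
  else function(s) rep(0, length(s))

  thick_c <- function(s) pT - (pT - aT) * exp(-(s - s0)^2 / (2 * sig^2))
  thick_e <- function(s) {
    e <- pE - (pE - aE) * exp(-(s - s0)^2 / (2 * sig^2)) + fluct(s)
    pmax(e, 5)  # floor: epithelium never vanishes
  }

  anterior_point <- function(s) {
    th <- s / R
    cbind(x = R * sin(th), y = .APEX_DEPTH + R * (1 - cos(th)))
  }
  inward_normal <- function(s) {
    th <- s / R
    cbind(nx = -sin(th), ny = cos(th))
  }
  offset_point <- function(s, depth) {
    p <- anterior_point(s)
    n <- inward_normal(s)
    cbind(x = p[, 1] + depth * n[, 1], y = p[, 2] + depth * n[, 2])
  }

  # sanity: 0 < E < T over the modeled extent
  sg <- seq(-extent_um, extent_um, length.out = 801)
  if (any(thick_e(sg) >= thick_c(sg)))
    stop("phantom invariant violated: epithelial thickness >= corneal thickness")

  structure(
    list(
      spec = spec,
      extent_um = extent_um,
      anterior_point = anterior_point,
      inward_normal = inward_normal,
      interface_point = function(s) offset_point(s, thick_e(s)),
      posterior_point = function(s) offset_point(s, thick_c(s)),
      thickness_cornea = thick_c,
      thickness_epithelium = thick_e
    ),
    class = "boundary_truth"
  )
}

#' Ground-truth thickness oracle
#'
#' Evaluates the analytic epithelial or corneal thickness of a phantom at
#' arc position `s_mm` (mm from the scan center, scan frame).
#'
#' @param truth a `boundary_truth`.
#' @param s_mm arc positions in mm.
#' @param tissue `"cornea"` or `"epithelium"`.
#' @return Thickness in um.
#' @export
analytic_thickness <- function(truth, s_mm, tissue = c("cornea", "epithelium")) {
  stopifnot(inherits(truth, "boundary_truth"))
  tissue <- match.arg(tissue)
  s <- s_mm * 1000
  if (any(abs(s) > truth$extent_um))
    stop("arc position outside the modeled extent")
  if (tissue == "cornea") truth$thickness_cornea(s) else truth$thickness_epithelium(s)
}

# per-column boundary depths (um) of the three curves on a pixel grid;
# curves are parametric in s, resampled to single-valued y(x) per column
boundary_depths_on_grid <- function(truth, geometry) {
  xc <- central_x_um(geometry)
  sgrid <- seq(-truth$extent_um, truth$extent_um, by = 2)
  cols <- column_x_um(geometry)
  resample <- function(pts) {
    stats::approx(pts[, 1] + xc, pts[, 2], xout = cols, rule = 1)$y
  }
  list(
    anterior = resample(truth$anterior_point(sgrid)),
    interface = resample(truth$interface_point(sgrid)),
    posterior = resample(truth$posterior_point(sgrid))
  )
}

#' Construct a 3-class label mask
#'
#' Wraps an integer matrix of per-pixel labels (0 background, 1 epithelium,
#' 2 stroma; rows = axial, columns = lateral) with its pixel geometry.
#'
#' @param labels integer matrix with values in 0:2.
#' @param geometry an `image_geometry` matching the matrix dimensions.
#' @param meta optional list of scan metadata (stage, laterality, meridian,
#'   seed).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, geometry, meta = list()) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% 0:2)) stop("labels must be 0 (bg), 1 (epithelium) or 2 (stroma)")
  if (nrow(labels) != geometry$height_px || ncol(labels) != geometry$width_px)
    stop("label matrix dimensions do not match the geometry")
  structure(list(labels = labels, geometry = geometry, meta = meta),
            class = "label_mask")
}

#' Rasterize a phantom into a 3-class label mask
#'
#' Labels every pixel by the region its center falls in: 0 background,
#' 1 epithelium (between anterior surface and epithelium-stroma interface),
#' 2 stroma (between interface and posterior surface).
#'
#' @param truth a `boundary_truth`.
#' @param geometry an `image_geometry`; curves must fit inside the grid.
#' @return An object of class `label_mask`: integer matrix `labels`
#'   (rows = axial) plus the geometry.
#' @export
rasterize_masks <- function(truth, geometry = image_geometry()) {
  d <- boundary_depths_on_grid(truth, geometry)
  max_y <- (geometry$height_px - 0.5) * geometry$pitch_v
  ok <- !is.na(d$anterior) & !is.na(d$interface) & !is.na(d$posterior)
  ok[ok] <- d$posterior[ok] <= max_y & d$anterior[ok] >= -0.5 * geometry$pitch_v
  # columns where the cornea exits the grid are clipped to background; this
  # may only happen outside the measurement ROI (plus margin)
  xs <- column_x_um(geometry)
  roi <- abs(xs - central_x_um(geometry)) <= 3300
  if (any(!ok & roi))
    stop("phantom curves exceed the image grid extent inside the ROI")
  d$anterior[!ok] <- NA
  y <- (seq_len(geometry$height_px) - 1L) * geometry$pitch_v
  h <- geometry$height_px; w <- geometry$width_px
  Y <- matrix(y, h, w)
  A <- matrix(d$anterior, h, w, byrow = TRUE)
  I <- matrix(d$interface, h, w, byrow = TRUE)
  P <- matrix(d$posterior, h, w, byrow = TRUE)
  lab <- matrix(0L, h, w)
  lab[!is.na(A) & Y >= A & Y < I] <- 1L
  lab[!is.na(A) & Y >= I & Y < P] <- 2L
  sp <- truth$spec
  structure(list(labels = lab, geometry = geometry,
                 meta = list(stage = sp$stage, laterality = sp$laterality,
                             meridian = sp$meridian, seed = sp$seed)),
            class = "label_mask")
}

#' Render a phantom as a speckled grayscale B-scan
#'
#' Produces an 8-bit-range grayscale image from the phantom's label
#' geometry: distinct mean intensities for background, epithelium and
#' stroma, multiplicative gamma speckle, and (for scarring phantoms) a
#' hyperintense stromal patch near the cone.
#'
#' @param truth a `boundary_truth`.
#' @param geometry an `image_geometry`.
#' @param noise_params list: `bg`, `epi`, `stroma` mean intensities (0-255),
#'   `speckle` contrast (sd of the unit-mean multiplicative field; 0
#'   disables), `scar_boost` added intensity inside the scar patch.
#' @param seed RNG seed; the render is deterministic given it.
#' @return A list of class `bscan_render`: numeric `image` matrix in
#'   [0, 255], the `label_mask` used, and a logical `scar_patch` matrix.
#' @export
render_bscan <- function(truth, geometry = image_geometry(),
                         noise_params = list(), seed = 1L) {
  np <- utils::modifyList(
    list(bg = 25, epi = 95, stroma = 150, speckle = 0.25, scar_boost = 60),
    noise_params
  )
  mask <- rasterize_masks(truth, geometry)
  lab <- mask$labels
  base <- matrix(np$bg, nrow(lab), ncol(lab))
  base[lab == 1L] <- np$epi
  base[lab == 2L] <- np$stroma

  scar_patch <- matrix(FALSE, nrow(lab), ncol(lab))
  if (isTRUE(truth$spec$scar)) {
    s0 <- truth$spec$cone_center_offset * 1000
    if (truth$spec$meridian == "H" && truth$spec$laterality == "OD") s0 <- -s0
    ctr <- truth$anterior_point(s0)
    n0 <- truth$inward_normal(s0)
    depth <- (truth$thickness_epithelium(s0) + truth$thickness_cornea(s0)) / 2
    cx <- central_x_um(geometry) + ctr[1, 1] + depth * n0[1, 1]
    cy <- ctr[1, 2] + depth * n0[1, 2]
    xs <- column_x_um(geometry)
    ys <- (seq_len(geometry$height_px) - 1L) * geometry$pitch_v
    DX <- matrix((xs - cx) / 600, geometry$height_px, geometry$width_px, byrow = TRUE)
    DY <- matrix((ys - cy) / 120, geometry$height_px, geometry$width_px)
    scar_patch <- (DX^2 + DY^2 <= 1) & (lab == 2L)
    base[scar_patch] <- base[scar_patch] + np$scar_boost
  }

  img <- with_local_seed(seed, {
    if (np$speckle > 0) {
      shape <- 1 / np$speckle^2
      sp <- matrix(stats::rgamma(length(base), shape = shape, rate = shape),
                   nrow(base), ncol(base))
      base * sp
    } else base
  })
  img <- pmin(pmax(img, 0), 255)
  structure(list(image = img, mask = mask, scar_patch = scar_patch,
                 geometry = geometry, seed = as.integer(seed)),
            class = "bscan_render")
}

#' Generate a synthetic study cohort
#'
#' Draws a cohort of eyes across the five stage groups.  Each eye receives
#' one horizontal and one vertical scan specification (independent cone
#' offsets per meridian), a laterality assigned approximately 1:1, and a
#' scan seed derived deterministically from the master seed.  The default
#' group sizes reproduce the study cohort: 118 normal, 134 mild, 239
#' moderate, 153 severe and 71 scarring eyes.
#'
#' @param n_per_stage integer vector of 5 group sizes (normal, mild,
#'   moderate, severe, scarring).
#' @param seed master seed.
#' @return A list of class `phantom_cohort`: one entry per eye with
#'   `eye_id`, `stage`, `laterality`, and the two `phantom_spec`s
#'   (`spec_h`, `spec_v`).
#' @examples
#' coh <- generate_cohort(c(2, 2, 2, 2, 2), seed = 1)
#' length(coh)  # 10 eyes
#' @export
generate_cohort <- function(n_per_stage = c(118L, 134L, 239L, 153L, 71L),
                            seed = 1L) {
  if (length(n_per_stage) != 5L || any(n_per_stage < 0))
    stop("n_per_stage must be 5 non-negative counts (normal..scarring)")
  n_per_stage <- as.integer(n_per_stage)
  n_eyes <- sum(n_per_stage)
  scan_seeds <- with_local_seed(seed,
    sample.int(2147483646L, n_eyes * 2L, replace = FALSE))
  eyes <- vector("list", n_eyes)
  k <- 0L
  for (g in seq_len(5L)) {
    stage <- stage_levels()[g]
    for (i in seq_len(n_per_stage[g])) {
      k <- k + 1L
      lat <- if (i %% 2L == 1L) "OD" else "OS"
      eyes[[k]] <- list(
        eye_id = sprintf("%s_%03d", stage, i),
        stage = stage,
        laterality = lat,
        spec_h = make_phantom_spec(stage, lat, "H", scan_seeds[2L * k - 1L]),
        spec_v = make_phantom_spec(stage, lat, "V", scan_seeds[2L * k])
      )
    }
  }
  structure(eyes, class = "phantom_cohort", seed = as.integer(seed))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  st <- table(factor(vapply(x, `[[`, "", "stage"), levels = stage_levels()))
  cat(sprintf("<phantom_cohort> %d eyes (%s), %d scans\n",
              length(x),
              paste(sprintf("%s=%d", names(st), st), collapse = ", "),
              2L * length(x)))
  invisible(x)
}
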