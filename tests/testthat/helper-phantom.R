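# Shared fixtures, all built in code.

# a coarse grid for cheap rasterization tests (same 8 x 1.933 mm field)
small_geometry <- function(width_px = 662L, height_px = 160L) {
  image_geometry(width_px, height_px, 8000 / width_px, 1933 / height_px)
}

# flat-layer analytic truth: horizontal boundaries at fixed depths (um);
# thickness functions are constant, normals vertical
flat_truth <- function(anterior_um = 100, interface_um = 150,
                       posterior_um = 620, extent_um = 4500,
                       laterality = "OS", meridian = "H") {
  structure(
    list(
      spec = list(stage = "flat", laterality = laterality,
                  meridian = meridian, seed = 0L, scar = FALSE),
      extent_um = extent_um,
      anterior_point = function(s) cbind(x = s, y = rep(anterior_um, length(s))),
      inward_normal = function(s) cbind(nx = rep(0, length(s)), ny = rep(1, length(s))),
      interface_point = function(s) cbind(x = s, y = rep(interface_um, length(s))),
      posterior_point = function(s) cbind(x = s, y = rep(posterior_um, length(s))),
      thickness_cornea = function(s) rep(posterior_um - anterior_um, length(s)),
      thickness_epithelium = function(s) rep(interface_um - anterior_um, length(s))
    ),
    class = "boundary_truth"
  )
}

# spec with a degenerate cone (apex == peripheral): uniform thickness
uniform_spec <- function(ct = 520, et = 50, laterality = "OS", meridian = "H") {
  sp <- make_phantom_spec("normal", laterality, meridian, seed = 1L)
  sp$apex_corneal_thickness <- ct
  sp$peripheral_corneal_thickness <- ct
  sp$apex_epithelial_thickness <- et
  sp$peripheral_epithelial_thickness <- et
  sp$anterior_radius <- 7800
  sp$epithelial_fluctuation_amp <- 0
  sp
}

# boundary_trace of a circular arc, sampled at the given x positions
circle_trace <- function(surface, R, center_x, center_y, x) {
  new_trace <- kcpachy:::new_boundary_trace
  y <- center_y - sqrt(R^2 - (x - center_x)^2)
  new_trace(surface, x, y)
}

# flat three-layer boundary_set on a geometry (rows in pixel units)
flat_bset <- function(geometry, anterior_row, interface_row, posterior_row,
                      laterality = "OS", meridian = "H") {
  x <- kcpachy:::column_x_um(geometry)
  pv <- geometry$pitch_v
  kcpachy:::new_boundary_set(
    kcpachy:::new_boundary_trace("anterior", x, rep(anterior_row * pv, length(x))),
    kcpachy:::new_boundary_trace("epithelial_interface", x, rep(interface_row * pv, length(x))),
    kcpachy:::new_boundary_trace("posterior", x, rep(posterior_row * pv, length(x))),
    geometry, laterality, meridian
  )
}

# random soft-blob label masks for metric property tests
random_mask_pair <- function(geometry, seed) {
  set.seed(seed)
  h <- geometry$height_px; w <- geometry$width_px
  blob <- function() {
    lab <- matrix(0L, h, w)
    r0 <- sample(2:(h / 2), 1); nrow_epi <- sample(2:6, 1)
    nrow_str <- sample(4:20, 1)
    c1 <- sample(1:(w - 10), 1); c2 <- min(w, c1 + sample(5:(w / 2), 1))
    rows_e <- r0:(r0 + nrow_epi - 1)
    rows_s <- (r0 + nrow_epi):(min(h, r0 + nrow_epi + nrow_str - 1))
    lab[rows_e, c1:c2] <- 1L
    lab[rows_s, c1:c2] <- 2L
    label_mask(lab, geometry)
  }
  list(a = blob(), b = blob())
}
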