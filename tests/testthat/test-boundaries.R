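test_that("mask tracing follows the pixel-edge convention", {
  g <- image_geometry(3L, 120L, 10, 3)
  lab <- matrix(0L, 120, 3)
  lab[11:13, ] <- 1L   # epithelium rows 10-12 (0-based)
  lab[14:101, ] <- 2L  # stroma rows 13-100
  b <- trace_from_mask(label_mask(lab, g), smooth_window = 1)
  expect_equal(b$anterior$y, rep(9.5 * 3, 3))
  expect_equal(b$epithelial_interface$y, rep(12.5 * 3, 3))
  expect_equal(b$posterior$y, rep(100.5 * 3, 3))
  # an n-pixel band measures exactly n * pitch_v
  expect_equal(b$epithelial_interface$y - b$anterior$y, rep(3 * 3, 3))
})

test_that("malformed and empty masks are rejected", {
  g <- image_geometry(4L, 50L, 10, 4)
  lab <- matrix(0L, 50, 4)
  lab[11:13, ] <- 1L
  lab[14:30, ] <- 2L
  lab[10, 2] <- 2L  # stroma above epithelium in one column
  expect_error(trace_from_mask(label_mask(lab, g)), "malformed")
  expect_error(trace_from_mask(label_mask(matrix(0L, 50, 4), g)), "empty mask")
})

test_that("interior gaps are interpolated and edge gaps truncate", {
  g <- image_geometry(7L, 50L, 10, 4)
  lab <- matrix(0L, 50, 7)
  lab[11:12, 2:6] <- 1L
  lab[13:30, 2:6] <- 2L
  lab[, 4] <- 0L  # single interior defect
  b <- trace_from_mask(label_mask(lab, g), smooth_window = 1)
  expect_equal(length(b$anterior$x), 5L)               # columns 2..6 only
  expect_equal(b$anterior$x, (1:5) * 10)               # 0-based cols 1..5
  expect_equal(b$anterior$y[3], 9.5 * 4)               # interpolated defect
})

test_that("trace smoothing is identity on window 1 and on straight lines, and reduces noise", {
  x <- seq(0, 1000, by = 10)
  line <- kcpachy:::new_boundary_trace("anterior", x, 5 + 0.3 * x)
  expect_identical(smooth_trace(line, 1L), line)
  expect_equal(smooth_trace(line, 11L)$y, line$y, tolerance = 1e-10)
  expect_error(smooth_trace(line, 4), "odd")
  expect_error(smooth_trace(line, -3), "odd")

  set.seed(42)
  R <- 7800; cy <- 7900
  yc <- cy - sqrt(R^2 - (x - 500)^2)
  noisy <- kcpachy:::new_boundary_trace("anterior", x, yc + stats::rnorm(length(x), 0, 3))
  sm <- smooth_trace(noisy, 11L)
  mid <- 6:(length(x) - 5)
  expect_lt(max(abs(sm$y - yc)[mid]), max(abs(noisy$y - yc)[mid]))
})

test_that("gradient extraction recovers flat layers to sub-pixel accuracy without noise", {
  g <- image_geometry(200L, 200L, 10, 4)
  ft <- flat_truth(anterior_um = 40.5 * 4, interface_um = 55.5 * 4,
                   posterior_um = 150.5 * 4, extent_um = 2100)
  rn <- render_bscan(ft, g, noise_params = list(speckle = 0), seed = 1)
  b <- trace_from_image(rn)
  expect_lt(max(abs(b$anterior$y - 40.5 * 4)), 0.5 * 4)
  expect_lt(max(abs(b$epithelial_interface$y - 55.5 * 4)), 0.5 * 4)
  expect_lt(max(abs(b$posterior$y - 150.5 * 4)), 0.5 * 4)
})

test_that("gradient extraction stays within 2 pixels on a default speckled render", {
  g <- image_geometry()
  truth <- boundaries_from_spec(make_phantom_spec("normal", "OS", "H", 11))
  rn <- render_bscan(truth, g, seed = 3)
  b <- trace_from_image(rn, laterality = "OS", meridian = "H")
  d <- kcpachy:::boundary_depths_on_grid(truth, g)
  cols_x <- kcpachy:::column_x_um(g)
  roi <- abs(cols_x - kcpachy:::central_x_um(g)) <= 3000
  frac_ok <- function(tr, ref) {
    y <- stats::approx(tr$x, tr$y, xout = cols_x[roi])$y
    mean(abs(y - ref[roi]) <= 2 * g$pitch_v, na.rm = TRUE)
  }
  expect_gte(frac_ok(b$anterior, d$anterior), 0.95)
  expect_gte(frac_ok(b$epithelial_interface, d$interface), 0.95)
  expect_gte(frac_ok(b$posterior, d$posterior), 0.95)
  expect_error(trace_from_image(matrix(0, 100, 50), image_geometry(50L, 100L, 10, 4)),
               "extraction failed")
})

test_that("extraction error decreases as speckle vanishes", {
  g <- image_geometry()
  truth <- boundaries_from_spec(make_phantom_spec("mild", "OS", "H", 17))
  d <- kcpachy:::boundary_depths_on_grid(truth, g)
  cols_x <- kcpachy:::column_x_um(g)
  roi <- abs(cols_x - kcpachy:::central_x_um(g)) <= 3000
  err <- vapply(c(0.25, 0.1, 0), function(sp) {
    b <- trace_from_image(render_bscan(truth, g, list(speckle = sp), seed = 7))
    y <- stats::approx(b$anterior$x, b$anterior$y, xout = cols_x[roi])$y
    mean(abs(y - d$anterior[roi]), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(err) <= 0))
})

test_that("boundary validation reports ordering violations and poor coverage", {
  g <- small_geometry()
  sp <- make_phantom_spec("normal", "OS", "H", 23)
  b <- trace_from_mask(rasterize_masks(boundaries_from_spec(sp), g))
  v <- validate_boundaries(b)
  expect_true(v$passed)

  bad <- b
  k <- round(length(bad$epithelial_interface$y) / 2)
  bad$epithelial_interface$y[k] <- bad$posterior$y[k] + 50
  v2 <- validate_boundaries(bad)
  expect_false(v2$passed)
  expect_length(v2$violating_columns, 1L)

  # traces covering only 4 mm fail the 6 mm ROI requirement
  narrow <- b
  keep <- abs(narrow$anterior$x - kcpachy:::central_x_um(g)) <= 2000
  for (s in c("anterior", "epithelial_interface", "posterior")) {
    narrow[[s]]$x <- narrow[[s]]$x[keep]
    narrow[[s]]$y <- narrow[[s]]$y[keep]
  }
  v3 <- validate_boundaries(narrow)
  expect_false(v3$coverage_ok)
  expect_false(v3$passed)
})
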