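test_that("phantom specs are deterministic and obey stage rules", {
  a <- make_phantom_spec("normal", "OS", "H", seed = 1)
  b <- make_phantom_spec("normal", "OS", "H", seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_phantom_spec("normal", "OS", "H", seed = 2)))

  sc <- make_phantom_spec("scarring", "OD", "V", seed = 3)
  expect_true(sc$scar)
  expect_gt(sc$epithelial_fluctuation_amp, 0)
  ns <- make_phantom_spec("moderate", "OS", "H", seed = 3)
  expect_false(ns$scar)
  # ordinary eyes undulate a little, far less than scarring
  expect_lt(ns$epithelial_fluctuation_amp, sc$epithelial_fluctuation_amp)
  expect_lte(ns$apex_corneal_thickness, ns$peripheral_corneal_thickness)

  expect_error(make_phantom_spec("keratoglobus", "OS", "H", 1), "unknown stage")
})

test_that("sampled apex thickness matches the published group intervals and ordering", {
  mean_apex <- function(stage) {
    mean(vapply(1:200, function(i)
      make_phantom_spec(stage, "OS", "H", seed = 5000 + i)$apex_corneal_thickness, 0))
  }
  m <- vapply(stage_levels(), mean_apex, 0)
  # severe-group mean inside the published 95% CI for the thinnest zone
  expect_gt(m[["severe"]], 447.38)
  expect_lt(m[["severe"]], 463.22)
  # monotone thinning normal -> severe, scarring lowest
  expect_true(all(diff(m[c("normal", "mild", "moderate", "severe")]) < 0))
  expect_equal(unname(which.min(m)), 5L)
})

test_that("analytic thickness realizes the Gaussian cone closed form", {
  sp <- make_phantom_spec("severe", "OS", "H", seed = 11)
  truth <- boundaries_from_spec(sp)
  s0 <- sp$cone_center_offset
  expect_equal(analytic_thickness(truth, s0), sp$apex_corneal_thickness,
               tolerance = 1e-12)
  # 4 sigma out the cone has decayed to within 0.1% of the peripheral value
  far <- s0 + 4 * sp$cone_sigma
  expect_lt(abs(analytic_thickness(truth, far) - sp$peripheral_corneal_thickness),
            0.001 * sp$peripheral_corneal_thickness)
  # degenerate cone: constant thickness
  u <- boundaries_from_spec(uniform_spec(ct = 520, et = 50))
  s <- seq(-3, 3, by = 0.25)
  expect_equal(analytic_thickness(u, s), rep(520, length(s)))
  expect_equal(analytic_thickness(u, s, "epithelium"), rep(50, length(s)))
  expect_error(analytic_thickness(truth, 99), "outside")
})

test_that("right-eye horizontal scans carry the cone mirrored in the scan frame", {
  od <- make_phantom_spec("severe", "OD", "H", seed = 4)
  os <- od; os$laterality <- "OS"
  t_od <- boundaries_from_spec(od)
  t_os <- boundaries_from_spec(os)
  s0 <- od$cone_center_offset
  expect_equal(analytic_thickness(t_od, -s0), od$apex_corneal_thickness,
               tolerance = 1e-12)
  expect_equal(analytic_thickness(t_os, s0), od$apex_corneal_thickness,
               tolerance = 1e-12)
})

test_that("rasterization produces ordered label bands matching the curves", {
  g <- small_geometry()
  ft <- flat_truth(anterior_um = 20.5 * g$pitch_v, interface_um = 24.5 * g$pitch_v,
                   posterior_um = 60.5 * g$pitch_v)
  m <- rasterize_masks(ft, g)
  # pixel centers at rows 21..24 fall in the epithelium band, 25..60 stroma
  expect_true(all(m$labels[22:25, ] == 1L))
  expect_true(all(m$labels[26:61, ] == 2L))
  expect_true(all(m$labels[1:21, ] == 0L))
  expect_true(all(m$labels[62:160, ] == 0L))

  # column-ordering invariant on a curved phantom
  sp <- make_phantom_spec("moderate", "OS", "H", seed = 8)
  mk <- rasterize_masks(boundaries_from_spec(sp), g)
  lab <- mk$labels
  for (j in seq(1, ncol(lab), by = 37)) {
    col <- lab[, j]
    tis <- which(col > 0)
    if (length(tis)) {
      expect_true(all(diff(tis) == 1))          # contiguous band
      expect_true(all(diff(col[tis]) >= 0))     # epithelium above stroma
    }
  }
  expect_error(rasterize_masks(flat_truth(posterior_um = 5000), g), "grid extent")
})

test_that("boundaries recovered from the rasterized mask stay within one pixel", {
  g <- small_geometry()
  sp <- make_phantom_spec("severe", "OS", "H", seed = 13)
  truth <- boundaries_from_spec(sp)
  m <- rasterize_masks(truth, g)
  b <- trace_from_mask(m, smooth_window = 1)
  d <- kcpachy:::boundary_depths_on_grid(truth, g)
  cols_x <- kcpachy:::column_x_um(g)
  for (surf in c("anterior", "posterior")) {
    ref <- if (surf == "anterior") d$anterior else d$posterior
    tr <- b[[surf]]
    ref_at <- ref[match(round(tr$x, 6), round(cols_x, 6))]
    expect_lt(max(abs(tr$y - ref_at), na.rm = TRUE), g$pitch_v)
  }
})

test_that("renders are seeded, ordered in intensity, and scar patches are bright", {
  g <- small_geometry()
  sp <- make_phantom_spec("scarring", "OS", "H", seed = 21)
  truth <- boundaries_from_spec(sp)
  r1 <- render_bscan(truth, g, seed = 5)
  r2 <- render_bscan(truth, g, seed = 5)
  expect_identical(r1$image, r2$image)
  expect_false(identical(r1$image, render_bscan(truth, g, seed = 6)$image))
  lab <- r1$mask$labels
  expect_gt(mean(r1$image[lab == 2L]), mean(r1$image[lab == 0L]))
  expect_gt(mean(r1$image[lab == 1L]), mean(r1$image[lab == 0L]))
  expect_true(any(r1$scar_patch))
  expect_gt(mean(r1$image[r1$scar_patch]),
            mean(r1$image[lab == 2L & !r1$scar_patch]))
})

test_that("cohort generation is counted, seeded and balanced", {
  coh <- generate_cohort(c(5, 5, 5, 5, 5), seed = 9)
  expect_length(coh, 25L)
  stages <- vapply(coh, `[[`, "", "stage")
  expect_equal(unname(table(factor(stages, stage_levels()))), rep(5L, 5),
               ignore_attr = TRUE)
  # one H and one V spec per eye
  expect_true(all(vapply(coh, function(e)
    e$spec_h$meridian == "H" && e$spec_v$meridian == "V", TRUE)))
  # lateralities near 1:1
  lat <- vapply(coh, `[[`, "", "laterality")
  expect_true(abs(sum(lat == "OD") - sum(lat == "OS")) <= 5)
  expect_identical(generate_cohort(c(2, 2, 2, 2, 2), seed = 9),
                   generate_cohort(c(2, 2, 2, 2, 2), seed = 9))
  expect_error(generate_cohort(c(-1, 2, 2, 2, 2), 1), "non-negative")
  # default sizes reproduce the study group proportions
  def <- formals(generate_cohort)$n_per_stage
  expect_equal(eval(def), c(118L, 134L, 239L, 153L, 71L))
})

test_that("scarring epithelium fluctuates far more than non-scarring", {
  s <- seq(-2.9, 2.9, by = 0.05)
  roughness <- function(stage, seed) {
    sp <- make_phantom_spec(stage, "OS", "H", seed = seed)
    e <- analytic_thickness(boundaries_from_spec(sp), s, "epithelium")
    stats::sd(e - stats::fitted(stats::lm(e ~ poly(s, 4))))
  }
  r_scar <- vapply(31:35, function(i) roughness("scarring", i), 0)
  r_norm <- vapply(31:35, function(i) roughness("normal", i), 0)
  expect_gt(mean(r_scar), 2 * mean(r_norm))
  expect_gt(mean(r_scar), 2)
})
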