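pos <- sample_positions()
prof <- function(values, tissue = "cornea", meridian = "H")
  thickness_profile(meridian, tissue, pos, values)

test_that("ectasia indices are max/min ratios, scale-invariant, cone-monotone", {
  flat <- ectasia_indices(prof(rep(50, 40), "epithelium"),
                          prof(rep(50, 40), "epithelium", "V"),
                          prof(rep(520, 40)), prof(rep(520, 40), "cornea", "V"))
  expect_equal(unname(flat), c(1, 1, 1, 1))

  v <- seq(496, 620, length.out = 40)
  idx <- ectasia_indices(prof(rep(50, 40), "epithelium"),
                         prof(rep(50, 40), "epithelium", "V"),
                         prof(v), prof(rep(500, 40), "cornea", "V"))
  expect_equal(unname(idx["CEI_H"]), 1.25)
  idx2 <- ectasia_indices(prof(rep(50, 40) * 3, "epithelium"),
                          prof(rep(50, 40), "epithelium", "V"),
                          prof(v * 2), prof(rep(500, 40), "cornea", "V"))
  expect_equal(idx2[["CEI_H"]], idx[["CEI_H"]])

  # deepening the cone raises the affected meridian's corneal index
  sp <- make_phantom_spec("moderate", "OS", "H", seed = 3)
  deep <- sp; deep$apex_corneal_thickness <- sp$apex_corneal_thickness - 60
  ci <- function(s) {
    p <- measure_profile(trace_from_truth(boundaries_from_spec(s)))
    max(p$cornea$values) / min(p$cornea$values)
  }
  expect_gt(ci(deep), ci(sp))
})

test_that("Fisher LDA reproduces the 1-D hand computation and its symmetries", {
  x0 <- matrix(c(-1, 0, 1), ncol = 1)
  x1 <- matrix(c(5, 6, 7), ncol = 1)
  m <- fit_lda(x0, x1)
  expect_equal(m$weights, 6)        # pooled variance 1, mean gap 6
  expect_equal(m$offset, -18)       # midpoint of projected means at score 0
  s0 <- discriminant_score(m, x0); s1 <- discriminant_score(m, x1)
  expect_true(all(s0 < 0) && all(s1 > 0))
  expect_lt(max(s0), min(s1))       # fully separated

  swapped <- fit_lda(x1, x0)
  expect_equal(discriminant_score(swapped, rbind(x0, x1)),
               -discriminant_score(m, rbind(x0, x1)))

  expect_error(fit_lda(x0, x0), "degenerate")
})

test_that("LDA direction agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  X0 <- matrix(rnorm(200, 0, 1), ncol = 4) + matrix(rep(c(1, 1.1, 1.2, 1.3), each = 50), ncol = 4)
  X1 <- X0[1:40, ] + matrix(rep(c(0.3, 0.1, 0.5, 0.2), each = 40), ncol = 4)
  m <- fit_lda(X0, X1)
  fit <- MASS::lda(rbind(X0, X1), grouping = rep(c(0, 1), c(50, 40)))
  ref <- drop(fit$scaling)
  cosang <- sum(m$weights * ref) / sqrt(sum(m$weights^2) * sum(ref^2))
  expect_gt(abs(cosang), 0.999)
})

test_that("scores are affine in the features", {
  m <- fit_lda(matrix(rnorm(40), ncol = 4), matrix(rnorm(40) + 1, ncol = 4))
  f1 <- rnorm(4); f2 <- rnorm(4)
  lhs <- discriminant_score(m, f1 + f2)
  rhs <- discriminant_score(m, f1) + discriminant_score(m, f2) - m$offset
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(discriminant_score(m, c(1, NA, 2, 3)), "non-finite")
})

test_that("ROC/AUC matches pair counting, tie and separation conventions", {
  r <- roc_auc(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75)           # 3 of 4 pairs concordant
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))

  sep <- roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  ties <- roc_auc(rep(5, 10), rep(c(0, 1), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  # invariance under strictly monotone score transforms
  set.seed(11)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(exp(2 * sc + 1), lb)$auc, roc_auc(sc, lb)$auc)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- c(rnorm(40), rnorm(35, 0.8))
  lb <- rep(c(0, 1), c(40, 35))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("stage screening needs both classes and orders by severity on a small cohort", {
  feats <- data.frame(stage = rep("normal", 10),
                      EEI_H = rnorm(10, 1.1, 0.01), EEI_V = rnorm(10, 1.1, 0.01),
                      CEI_H = rnorm(10, 1.2, 0.01), CEI_V = rnorm(10, 1.2, 0.01))
  expect_error(stage_vs_normal_screen(feats), "at least one KC stage")
  expect_error(stage_vs_normal_screen(transform(feats, stage = "severe")),
               "normal eyes")

  set.seed(3)
  coh <- generate_cohort(c(25, 25, 25, 25, 25), seed = 31)
  pr <- measure_cohort(coh)
  scr <- stage_vs_normal_screen(cohort_features(pr))
  expect_named(scr, c("mild", "moderate", "severe", "scarring"))
  aucs <- vapply(scr, `[[`, 0, "auc")
  expect_lt(aucs[["mild"]], aucs[["severe"]])
  expect_gt(aucs[["scarring"]], 0.9)
})
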