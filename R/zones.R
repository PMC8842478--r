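# Zone-level cohort statistics: 20-zone division of the 6 mm profile,
# group means with 95% CIs, one-way ANOVA, Welch t-tests, and per-zone
# OLS thickness-vs-stage trends.  The standard fits are delegated to base
# R (oneway.test, t.test, lm); this module owns the zone bookkeeping.

N_ZONES <- 20L

#' Aggregate a 40-point profile into 20 zones
#'
#' Zone `j` averages samples `2j - 1` and `2j` of a profile that has been
#' mirrored to the common orientation; zone 1 is the most temporal
#' (horizontal) or inferior (vertical) zone.  Zone 9 covers positions
#' -0.525 and -0.375 mm, i.e. about 0.45 mm temporal/inferior of the
#' reference point.
#'
#' @param profile a `thickness_profile` (mirrored to common orientation).
#' @return A data.frame with 20 rows: eye_id, stage, meridian, tissue,
#'   zone, value (um).
#' @export
assign_zones <- function(profile) {
  stopifnot(inherits(profile, "thickness_profile"))
  if (length(profile$values) != 40L)
    stop("profile must have exactly 40 values")
  zone <- rep(seq_len(N_ZONES), each = 2L)
  data.frame(
    eye_id = profile$eye_id, stage = profile$stage,
    meridian = profile$meridian, tissue = profile$tissue,
    zone = seq_len(N_ZONES),
    value = as.numeric(tapply(profile$values, zone, mean)),
    stringsAsFactors = FALSE
  )
}

# position range (mm) covered by one zone's two samples
zone_positions <- function(zone) {
  pos <- sample_positions()
  pos[c(2L * zone - 1L, 2L * zone)]
}

#' Group mean with t-based confidence interval
#'
#' @param values numeric vector of per-eye zone values (um), n >= 2.
#' @param confidence confidence level, default 0.95.
#' @return A list: n, mean, ci_low, ci_high.
#' @export
zone_group_summary <- function(values, confidence = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("insufficient data: need at least 2 values for a CI")
  m <- mean(values)
  half <- stats::qt(1 - (1 - confidence) / 2, n - 1) * stats::sd(values) / sqrt(n)
  list(n = n, mean = m, ci_low = m - half, ci_high = m + half)
}

#' One-way ANOVA across stage groups
#'
#' Standard fixed-effects one-way ANOVA (equal-variance F test) over the
#' per-eye zone values of each group.
#'
#' @param groups list of numeric vectors, one per group; at least two
#'   groups with n >= 2.
#' @return A list: F, p, df (numerator, denominator).
#' @export
anova_by_zone <- function(groups) {
  groups <- lapply(groups, function(v) v[is.finite(v)])
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  if (length(groups) < 2L)
    stop("need at least two groups with n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  within_ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (within_ss == 0) {
    means <- vapply(groups, mean, 0)
    if (max(means) - min(means) == 0)
      stop("degenerate data: zero variance within and between groups")
    return(list(F = Inf, p = 0, df = c(length(groups) - 1L, length(y) - length(groups))))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Welch two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test between two groups' zone
#' values.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return A list: t, p, df.
#' @export
pairwise_ttest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  fit <- stats::t.test(a, b)
  list(t = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' OLS thickness-versus-stage trend for one zone
#'
#' Ordinary least-squares regression of per-eye zone thickness on the stage
#' ordinal (0 = normal ... 4 = scarring).  A negative slope means the zone
#' thins as keratoconus progresses.
#'
#' @param values numeric vector of zone values (um).
#' @param ordinals stage ordinals (0-4), same length; at least two distinct
#'   ordinals must be present.
#' @return A list: slope (um per stage), intercept (um), p (slope test).
#' @export
zone_trend <- function(values, ordinals) {
  keep <- is.finite(values) & is.finite(ordinals)
  values <- values[keep]; ordinals <- as.numeric(ordinals[keep])
  if (length(unique(ordinals)) < 2L)
    stop("need at least two distinct stage ordinals")
  fit <- stats::lm(values ~ ordinals)
  # degenerate (perfect-fit) inputs are legal; the slope p is NaN then
  cf <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(cf["ordinals", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p = unname(cf["ordinals", "Pr(>|t|)"]))
}
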