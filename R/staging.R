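# Stage discrimination from thickness ectasia indices: max/min thickness
# ratios per tissue and meridian, Fisher two-class linear discriminants of
# each keratoconus stage against normal, and ROC/AUC evaluation.

FEATURE_NAMES <- c("EEI_H", "EEI_V", "CEI_H", "CEI_V")

#' Thickness ectasia indices of one eye
#'
#' The ectasia index of a profile is the ratio of its maximum to its
#' minimum thickness over the 40 ROI samples; it is 1 for a perfectly
#' uniform profile and grows with focal thinning.  One eye yields four
#' indices: epithelial and corneal, horizontal and vertical.
#'
#' @param epithelium_h,epithelium_v,cornea_h,cornea_v the four
#'   `thickness_profile`s of one eye.
#' @return Named numeric vector `(EEI_H, EEI_V, CEI_H, CEI_V)`.
#' @export
ectasia_indices <- function(epithelium_h, epithelium_v, cornea_h, cornea_v) {
  profs <- list(EEI_H = epithelium_h, EEI_V = epithelium_v,
                CEI_H = cornea_h, CEI_V = cornea_v)
  vapply(profs, function(p) {
    if (is.null(p)) stop("all four profiles of the eye are required")
    stopifnot(inherits(p, "thickness_profile"))
    if (any(p$values <= 0)) stop("nonpositive thickness values")
    max(p$values) / min(p$values)
  }, 0)
}

#' Fit a two-class Fisher linear discriminant
#'
#' Fisher LDA of a keratoconus stage against normal on the four ectasia
#' indices (or any feature matrix): weights proportional to
#' `pooled_Sigma^{-1} (mu_stage - mu_normal)`, with the offset centering
#' the score at the midpoint of the projected class means, so normal-like
#' feature vectors score negative and stage-like vectors positive.  A small
#' ridge (`1e-6 * tr(Sigma)/d` on the diagonal) is added if the pooled
#' covariance is near-singular.
#'
#' @param normal_features matrix (rows = eyes) of the normal class.
#' @param stage_features matrix of the positive (KC stage) class.
#' @param positive_class label stored on the model.
#' @return An object of class `discriminant_model`: weights, offset,
#'   positive_class.
#' @export
fit_lda <- function(normal_features, stage_features, positive_class = "KC") {
  X0 <- as.matrix(normal_features); X1 <- as.matrix(stage_features)
  if (ncol(X0) != ncol(X1)) stop("feature dimensions differ between classes")
  n0 <- nrow(X0); n1 <- nrow(X1)
  if (n0 < 2 || n1 < 2) stop("each class needs at least 2 observations")
  d <- ncol(X0)
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  dmu <- mu1 - mu0
  if (sqrt(sum(dmu^2)) < 1e-12)
    stop("degenerate model: class means coincide")
  S <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) / (n0 + n1 - 2)
  if (d == 1) S <- matrix(S, 1, 1)
  w <- tryCatch(solve(S, dmu), error = function(e) NULL)
  if (is.null(w) || rcond(S) < 1e-10) {
    S <- S + diag(1e-6 * sum(diag(S)) / d, d)
    w <- tryCatch(solve(S, dmu),
                  error = function(e) stop("singular pooled covariance after regularization"))
  }
  offset <- -sum(w * (mu0 + mu1) / 2)
  structure(list(weights = as.numeric(w), offset = as.numeric(offset),
                 feature_names = colnames(X0), positive_class = positive_class,
                 n = c(normal = n0, positive = n1)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s vs normal (n=%d/%d): score = %s %+0.3f\n",
              x$positive_class, x$n["normal"], x$n["positive"],
              paste(sprintf("%+.3f*f%d", x$weights, seq_along(x$weights)),
                    collapse = " "),
              x$offset))
  invisible(x)
}

#' Discriminant score
#'
#' Affine score `weights . features + offset`; positive means more
#' KC-like than the midpoint between the training class means.
#'
#' @param model a `discriminant_model`.
#' @param features numeric vector, or matrix with one row per eye.
#' @return Numeric score(s).
#' @export
discriminant_score <- function(model, features) {
  stopifnot(inherits(model, "discriminant_model"))
  X <- if (is.matrix(features) || is.data.frame(features))
    as.matrix(features) else matrix(features, nrow = 1)
  if (ncol(X) != length(model$weights)) stop("feature dimension mismatch")
  if (any(!is.finite(X))) stop("non-finite features")
  drop(X %*% model$weights + model$offset)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= threshold`), producing the staircase of (FPR, TPR) points from
#' (0, 0) to (1, 1).  The AUC is the trapezoidal area, identical to the
#' Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels binary labels (logical, or 0/1), both classes present.
#' @return An object of class `roc_result`: data.frame `points` (fpr, tpr)
#'   and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(is.na(scores)) || any(is.na(labels))) stop("missing values")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  points <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n = c(neg = n0, pos = n1)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (n = %d vs %d)\n",
              x$auc, x$n["neg"], x$n["pos"]))
  invisible(x)
}

#' Screen each keratoconus stage against normal
#'
#' Fits one two-class discriminant per KC stage present in the cohort
#' (mild, moderate, severe, scarring, each versus normal) on the four
#' ectasia indices and evaluates it in-sample with ROC/AUC, mirroring the
#' study design.
#'
#' @param features data.frame with columns `stage` and the four index
#'   columns `EEI_H, EEI_V, CEI_H, CEI_V` (one row per eye); must contain
#'   normal eyes and at least one KC stage.
#' @return Named list (one entry per KC stage): `model`, `roc`, `auc`.
#' @export
stage_vs_normal_screen <- function(features) {
  stopifnot(is.data.frame(features), all(c("stage", FEATURE_NAMES) %in% names(features)))
  if (!any(features$stage == "normal"))
    stop("cohort must contain normal eyes")
  kc_stages <- intersect(stage_levels()[-1], unique(features$stage))
  if (length(kc_stages) == 0)
    stop("cohort must contain at least one KC stage")
  X <- as.matrix(features[, FEATURE_NAMES])
  out <- list()
  for (st in kc_stages) {
    i0 <- features$stage == "normal"
    i1 <- features$stage == st
    model <- fit_lda(X[i0, , drop = FALSE], X[i1, , drop = FALSE],
                     positive_class = st)
    idx <- i0 | i1
    scores <- discriminant_score(model, X[idx, , drop = FALSE])
    roc <- roc_auc(scores, features$stage[idx] == st)
    out[[st]] <- list(model = model, roc = roc, auc = roc$auc)
  }
  out
}
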