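# Diagnostic accuracy of a continuous marker: empirical ROC with DeLong
# inference, precision-recall curves with nonlinear (TP/FP-space)
# interpolation and logit-method intervals, Youden-index cutoffs with
# bootstrap confidence intervals, prevalence-standardized predictive
# values, and AUC-based sample-size calculation.

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    positive <- positive %||% if ("FTD" %in% labels) "FTD" else sort(unique(labels))[1]
    return(labels == positive)
  }
  positive <- positive %||% 1
  labels == positive
}

validate_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    abort("scores and labels must have the same length", "validation_error")
  if (anyNA(scores) || any(!is.finite(scores)))
    abort("scores must be finite", "validation_error")
  if (!any(labels) || all(labels))
    abort("both classes must be present", "validation_error")
}

# DeLong structural components for oriented scores.
delong_components <- function(x, y) {
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi), m = m, n = n)
}

#' Empirical ROC AUC with DeLong inference
#'
#' AUC by the Mann-Whitney kernel (ties count one half), standard error
#' from the DeLong structural components, 95 percent CI as
#' `auc +/- 1.96 se` clipped to \[0, 1\]. The marker is auto-oriented so
#' the AUC is at least 0.5; the orientation is recorded.
#'
#' @param scores Numeric marker values.
#' @param labels Class labels; `TRUE`/`"FTD"`/`positive` marks the
#'   positive (diseased) class.
#' @param positive Value of `labels` defining the positive class.
#' @return Object of class `roc_result`: auc, se, ci95, orientation,
#'   curve (data frame fpr, tpr), counts.
#' @export
roc_auc_delong <- function(scores, labels, positive = NULL) {
  lab <- as_binary_labels(labels, positive)
  validate_scores_labels(scores, lab)
  orientation <- "greater-is-positive"
  s <- as.numeric(scores)
  cmp <- delong_components(s[lab], s[!lab])
  if (cmp$auc < 0.5) {
    orientation <- "less-is-positive"
    s <- -s
    cmp <- delong_components(s[lab], s[!lab])
  }
  se <- sqrt(stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n)
  ci <- pmin(1, pmax(0, cmp$auc + c(-1, 1) * stats::qnorm(0.975) * se))
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(thr, function(t) mean(s[!lab] >= t), 0),
    tpr = vapply(thr, function(t) mean(s[lab] >= t), 0))
  structure(list(auc = cmp$auc, se = se, ci95 = ci, orientation = orientation,
                 curve = curve, n_pos = cmp$m, n_neg = cmp$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f), %s, %d pos / %d neg\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two paired ROC AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects, using
#' the covariance of the DeLong structural components. Each marker is
#' auto-oriented so its AUC is at least 0.5 before the comparison.
#'
#' @param scores_a,scores_b Marker values on the same subjects.
#' @inheritParams roc_auc_delong
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, positive = NULL) {
  lab <- as_binary_labels(labels, positive)
  if (length(scores_a) != length(scores_b))
    abort("paired markers must have the same length", "validation_error")
  validate_scores_labels(scores_a, lab)
  validate_scores_labels(scores_b, lab)
  orient <- function(s) {
    cmp <- delong_components(s[lab], s[!lab])
    if (cmp$auc < 0.5) delong_components(-s[lab], -s[!lab]) else cmp
  }
  ca <- orient(as.numeric(scores_a)); cb <- orient(as.numeric(scores_b))
  v10 <- cbind(ca$v10, cb$v10); v01 <- cbind(ca$v01, cb$v01)
  s10 <- stats::cov(v10); s01 <- stats::cov(v01)
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (vd <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(vd); p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p)
}

# Area under one PR segment from (TPa, FPa) to (TPb, FPb), in recall
# units of a positive count P: TP is linear in the path parameter and FP
# linear in TP, which makes precision a hyperbolic arc (the nonlinear
# interpolation of achievable PR points).
pr_segment_area <- function(tpa, fpa, tpb, fpb, P) {
  dtp <- tpb - tpa
  if (dtp <= 0) return(0)
  u <- 1 + (fpb - fpa) / dtp
  c0 <- tpa + fpa
  if (c0 == 0)  # path leaves the origin: constant precision 1/u
    return(dtp / u / P)
  val <- function(k) k / u + (tpa - c0 / u) * log(c0 + u * k) / u
  (val(dtp) - val(0)) / P
}

#' Precision-recall curve with nonlinear interpolation
#'
#' Achievable (recall, precision) points at every score threshold;
#' between achievable points the curve follows the path induced by
#' linear interpolation in (TP, FP) space, and the area is the exact
#' integral of precision over recall along that path. The marker is
#' auto-oriented like in [roc_auc_delong()].
#'
#' @inheritParams roc_auc_delong
#' @param ci_level Level of the logit-method CI attached to the area.
#' @return Object of class `pr_result`: auc, ci95 (logit method), curve
#'   (data frame recall, precision along the interpolated path),
#'   achievable points, orientation.
#' @export
pr_curve <- function(scores, labels, positive = NULL, ci_level = 0.95) {
  lab <- as_binary_labels(labels, positive)
  validate_scores_labels(scores, lab)
  s <- as.numeric(scores)
  orientation <- "greater-is-positive"
  if (delong_components(s[lab], s[!lab])$auc < 0.5) {
    orientation <- "less-is-positive"; s <- -s
  }
  P <- sum(lab); N <- sum(!lab)
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(s[lab] >= t), 0L)
  fp <- vapply(thr, function(t) sum(s[!lab] >= t), 0L)
  tp <- c(0L, tp); fp <- c(0L, fp)
  auc <- 0
  grid <- list(data.frame(recall = 0, precision = NA_real_))
  for (k in seq_len(length(tp) - 1L)) {
    auc <- auc + pr_segment_area(tp[k], fp[k], tp[k + 1], fp[k + 1], P)
    if (tp[k + 1] > tp[k]) {
      kk <- seq(0, tp[k + 1] - tp[k], length.out = 8)
      slope <- (fp[k + 1] - fp[k]) / (tp[k + 1] - tp[k])
      tpk <- tp[k] + kk; fpk <- fp[k] + kk * slope
      grid[[length(grid) + 1L]] <-
        data.frame(recall = tpk / P, precision = tpk / (tpk + fpk))
    }
  }
  curve <- unique(do.call(rbind, grid))
  curve$precision[1] <- curve$precision[2]  # limit at recall -> 0
  ci <- pr_auc_logit_ci(auc, P, N, level = ci_level)
  structure(list(auc = auc, ci95 = c(ci$lower, ci$upper),
                 ci_degenerate = ci$degenerate, curve = curve,
                 achievable = data.frame(recall = tp / P,
                                         precision = ifelse(tp + fp > 0, tp / (tp + fp), NA)),
                 orientation = orientation, n_pos = P, n_neg = N),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> PR-AUC %.3f (95%% CI %.3f-%.3f, logit method), %s, %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}

#' Logit-method confidence interval for a PR AUC
#'
#' Interval on the logit scale with standard error
#' `1 / sqrt(n_pos * auc * (1 - auc))`, back-transformed, so the interval
#' stays inside (0, 1).
#'
#' @param pr_auc Point estimate in (0, 1).
#' @param n_pos Number of positives (the PR curve's effective sample size).
#' @param n_neg Number of negatives (kept for the call signature; the
#'   standard error uses the positive count).
#' @param level Confidence level.
#' @return List with `lower`, `upper`, `degenerate`.
#' @export
pr_auc_logit_ci <- function(pr_auc, n_pos, n_neg = NULL, level = 0.95) {
  stopifnot_scalar_number(pr_auc, "pr_auc", 0, 1)
  stopifnot_scalar_number(n_pos, "n_pos", 1)
  if (pr_auc <= 0 || pr_auc >= 1)
    return(list(lower = pr_auc, upper = pr_auc, degenerate = TRUE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  eta <- stats::qlogis(pr_auc)
  tau <- 1 / sqrt(n_pos * pr_auc * (1 - pr_auc))
  list(lower = stats::plogis(eta - z * tau),
       upper = stats::plogis(eta + z * tau), degenerate = FALSE)
}

#' Prevalence-standardized predictive values
#'
#' `PPV = se pi / (se pi + (1 - sp)(1 - pi))` and
#' `NPV = sp (1 - pi) / (sp (1 - pi) + (1 - se) pi)`.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @param prevalence Standardized disease prevalence (default 0.5).
#' @return List with `ppv` and `npv` (fractions).
#' @export
predictive_values <- function(sensitivity, specificity, prevalence = 0.5) {
  se <- sensitivity; sp <- specificity; pi <- prevalence
  ppv_den <- se * pi + (1 - sp) * (1 - pi)
  npv_den <- sp * (1 - pi) + (1 - se) * pi
  list(ppv = if (ppv_den > 0) se * pi / ppv_den else NA_real_,
       npv = if (npv_den > 0) sp * (1 - pi) / npv_den else NA_real_)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` (fractions).
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (k < 0 || k > n || n < 1) abort("need 0 <= k <= n, n >= 1", "validation_error")
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

# Fast Youden maximization on oriented scores: candidate cutoffs are
# midpoints between adjacent distinct observed values (plus one beyond
# each extreme); positive call is score > cutoff. Ties in J resolve to
# the highest-specificity cutoff.
youden_max <- function(x, y) {
  v <- sort(unique(c(x, y)))
  thr <- if (length(v) == 1L) c(v - 1, v + 1)
         else c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
  xs <- sort(x); ys <- sort(y)
  sens <- 1 - findInterval(thr, xs) / length(x)
  spec <- findInterval(thr, ys) / length(y)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(spec[best])]
  list(cutoff = thr[pick], j = j[pick], sensitivity = sens[pick],
       specificity = spec[pick])
}

#' Optimal cutoff by Youden's index
#'
#' Maximizes `J = sensitivity + specificity - 1` over cutoffs placed at
#' midpoints between adjacent distinct observed marker values, with the
#' marker auto-oriented so that AUC is at least 0.5. Ties in J resolve
#' toward higher specificity. Sensitivity and specificity carry exact
#' binomial (Clopper-Pearson) intervals; PPV and NPV at the standardized
#' prevalence carry intervals obtained by propagating the binomial limits
#' through the predictive-value formulas.
#'
#' @inheritParams roc_auc_delong
#' @param prevalence Standardized prevalence for PPV/NPV.
#' @return Object of class `cutoff_report` with cutoff, direction (`">"`
#'   or `"<="` on the original marker scale), sensitivity, specificity,
#'   youden_j, ppv, npv (rates in percent with `ci` fields), prevalence.
#' @export
youden_cutoff <- function(scores, labels, positive = NULL, prevalence = 0.5) {
  lab <- as_binary_labels(labels, positive)
  validate_scores_labels(scores, lab)
  s <- as.numeric(scores)
  orientation <- "greater-is-positive"
  if (delong_components(s[lab], s[!lab])$auc < 0.5) {
    orientation <- "less-is-positive"; s <- -s
  }
  ym <- youden_max(s[lab], s[!lab])
  m <- sum(lab); n <- sum(!lab)
  tp <- round(ym$sensitivity * m); tn <- round(ym$specificity * n)
  sens_ci <- exact_binomial_ci(tp, m)
  spec_ci <- exact_binomial_ci(tn, n)
  pv <- predictive_values(ym$sensitivity, ym$specificity, prevalence)
  pv_lo <- predictive_values(sens_ci[1], spec_ci[1], prevalence)
  pv_hi <- predictive_values(sens_ci[2], spec_ci[2], prevalence)
  cutoff <- if (orientation == "less-is-positive") -ym$cutoff else ym$cutoff
  structure(list(
    cutoff = cutoff,
    direction = if (orientation == "less-is-positive") "<=" else ">",
    orientation = orientation,
    sensitivity = 100 * ym$sensitivity, sensitivity_ci = 100 * sens_ci,
    specificity = 100 * ym$specificity, specificity_ci = 100 * spec_ci,
    youden_j = ym$j,
    ppv = 100 * pv$ppv, ppv_ci = 100 * c(pv_lo$ppv, pv_hi$ppv),
    npv = 100 * pv$npv, npv_ci = 100 * c(pv_lo$npv, pv_hi$npv),
    prevalence = prevalence, n_pos = m, n_neg = n,
    cutoff_ci = c(NA_real_, NA_real_), youden_j_ci = c(NA_real_, NA_real_)),
    class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("<cutoff_report> cutoff %s%.3g, J = %.3f", x$direction, x$cutoff, x$youden_j))
  if (!anyNA(x$youden_j_ci)) cat(sprintf(" (%.3f-%.3f)", x$youden_j_ci[1], x$youden_j_ci[2]))
  cat(sprintf("\n  sensitivity %.1f%% (%.1f-%.1f), specificity %.1f%% (%.1f-%.1f)\n",
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  cat(sprintf("  PPV %.1f%% (%.1f-%.1f), NPV %.1f%% (%.1f-%.1f) at prevalence %.0f%%\n",
              x$ppv, x$ppv_ci[1], x$ppv_ci[2], x$npv, x$npv_ci[1], x$npv_ci[2],
              100 * x$prevalence))
  invisible(x)
}

#' Bootstrap confidence intervals for the Youden cutoff and maximum J
#'
#' Stratified (within-class) resampling with percentile 2.5/97.5
#' intervals; deterministic under a fixed seed.
#'
#' @inheritParams roc_auc_delong
#' @param iterations Bootstrap iterations.
#' @param seed RNG seed.
#' @return List with `cutoff_ci`, `youden_j_ci`, `iterations`, `seed`,
#'   and `unstable` (TRUE when iterations < 100).
#' @export
bootstrap_cutoff_ci <- function(scores, labels, positive = NULL,
                                iterations = 5000, seed = 978) {
  lab <- as_binary_labels(labels, positive)
  validate_scores_labels(scores, lab)
  if (iterations < 1) abort("iterations must be >= 1", "validation_error")
  unstable <- iterations < 100
  if (unstable) warning("fewer than 100 bootstrap iterations; intervals are unstable",
                        call. = FALSE)
  s <- as.numeric(scores)
  flip <- delong_components(s[lab], s[!lab])$auc < 0.5
  if (flip) s <- -s
  x <- s[lab]; y <- s[!lab]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cuts <- numeric(iterations); js <- numeric(iterations)
  for (b in seq_len(iterations)) {
    ym <- youden_max(sample(x, replace = TRUE), sample(y, replace = TRUE))
    cuts[b] <- ym$cutoff; js[b] <- ym$j
  }
  if (flip) cuts <- -cuts
  list(cutoff_ci = unname(stats::quantile(cuts, c(0.025, 0.975))),
       youden_j_ci = unname(stats::quantile(js, c(0.025, 0.975))),
       iterations = iterations, seed = seed, unstable = unstable)
}

# Hanley-McNeil standard error of an empirical AUC.
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Sample size for detecting an AUC above a null value
#'
#' Smallest per-group size n such that
#' `z_{alpha/2} SE0(n) + z_beta SE1(n) <= auc_alt - auc_null`, with the
#' Hanley-McNeil standard error under the null and alternative AUCs
#' (two-sided alpha).
#'
#' @param alpha Two-sided type-1 error.
#' @param power Desired power (1 - beta).
#' @param auc_alt Alternative-hypothesis AUC.
#' @param auc_null Null-hypothesis AUC.
#' @param ratio Ratio of negatives to positives (1 = equal groups).
#' @return List with `n_pos`, `n_neg`, `n_total`.
#' @export
auc_sample_size <- function(alpha = 0.01, power = 0.8, auc_alt = 0.8,
                            auc_null = 0.5, ratio = 1) {
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1))
    abort("need 0.5 <= auc_null < auc_alt < 1", "validation_error")
  if (!(alpha > 0 && alpha < 1 && power > 0 && power < 1))
    abort("alpha and power must lie in (0, 1)", "validation_error")
  za <- stats::qnorm(1 - alpha / 2); zb <- stats::qnorm(power)
  delta <- auc_alt - auc_null
  for (n in 2:1000000) {
    nn <- ceiling(ratio * n)
    lhs <- za * hanley_mcneil_se(auc_null, n, nn) +
           zb * hanley_mcneil_se(auc_alt, n, nn)
    if (lhs <= delta)
      return(list(n_pos = n, n_neg = nn, n_total = n + nn))
  }
  abort("no feasible sample size below 1e6", "validation_error")
}
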