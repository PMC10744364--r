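# Dense-grid oracle: area under the PR path induced by linear
# interpolation in (TP, FP) space.
pr_path_area <- function(tp, fp, P, pts = 100001) {
  area <- 0
  for (k in seq_len(length(tp) - 1)) {
    dtp <- tp[k + 1] - tp[k]
    if (dtp == 0) next
    s <- (fp[k + 1] - fp[k]) / dtp
    kk <- seq(0, dtp, length.out = pts)
    tpk <- tp[k] + kk; fpk <- fp[k] + kk * s
    prec <- ifelse(tpk + fpk > 0, tpk / (tpk + fpk), 1 / (1 + s))
    area <- area + sum((prec[-1] + prec[-pts]) / 2 * diff(kk)) / P
  }
  area
}

test_that("ROC AUC and DeLong inference match brute-force pair counting and pROC", {
  r <- roc_auc_delong(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)
  r2 <- roc_auc_delong(c(1, 4, 2, 3), c(0, 1, 1, 0))  # one discordant-ish pair
  expect_equal(r2$auc, 0.75)

  skip_if_not_installed("pROC")
  set.seed(201)
  for (rep in 1:5) {
    n <- 40
    lab <- rep(c(0, 1), each = n / 2)
    sc <- rnorm(n) + lab
    mine <- roc_auc_delong(sc, lab)
    ref <- pROC::roc(lab, sc, direction = "<", quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(mine$se^2, as.numeric(pROC::var(ref)), tolerance = 1e-10)
  }
})

test_that("the empirical AUC is invariant under strictly monotone transforms", {
  set.seed(202)
  lab <- rep(c(0, 1), 25)
  sc <- rnorm(50) + 0.8 * lab
  a1 <- roc_auc_delong(sc, lab)$auc
  expect_equal(roc_auc_delong(exp(sc), lab)$auc, a1)
  expect_equal(roc_auc_delong(stats::qlogis(stats::plogis(sc)), lab)$auc, a1)
  # decreasing transform flips the recorded orientation, not the AUC
  r <- roc_auc_delong(-sc, lab)
  expect_equal(r$auc, a1)
  expect_equal(r$orientation, "less-is-positive")
})

test_that("a randomly labeled marker has AUC near one half", {
  set.seed(203)
  sc <- rnorm(400)
  lab <- sample(rep(c(0, 1), 200))
  r <- roc_auc_delong(sc, lab)
  expect_lt(abs(r$auc - 0.5), 3 * r$se + 1e-12)
  expect_error_class(roc_auc_delong(sc, rep(1, 400)), "validation_error")
})

test_that("the paired DeLong test matches pROC and respects rank invariance", {
  set.seed(204)
  lab <- rep(c(0, 1), each = 30)
  a <- rnorm(60) + lab
  b <- rnorm(60) + 0.5 * lab
  expect_equal(delong_paired_test(a, a, lab)$p, 1)
  expect_equal(delong_paired_test(a, exp(a), lab)$z, 0)  # monotone transform
  mine <- delong_paired_test(a, b, lab)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lab, a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, b, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(mine$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-10)
  expect_error_class(delong_paired_test(a, b[-1], lab), "validation_error")
})

test_that("PR curves follow the nonlinear TP/FP-space interpolation exactly", {
  # perfect and uninformative markers
  expect_equal(pr_curve(1:6, c(0, 0, 0, 1, 1, 1))$auc, 1)
  pr0 <- pr_curve(rep(1, 30), rep(c(1, 0, 0), 10))
  expect_equal(pr0$auc, 1 / 3, tolerance = 1e-12)

  # printed 6-subject example against the dense-grid path oracle
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c(1, 0, 1, 1, 0, 0)
  pr <- pr_curve(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- c(0, vapply(thr, function(t) sum(scores[labels == 1] >= t), 0))
  fp <- c(0, vapply(thr, function(t) sum(scores[labels == 0] >= t), 0))
  expect_equal(pr$auc, pr_path_area(tp, fp, 3), tolerance = 1e-9)

  # random markers: closed-form segment areas equal the dense oracle
  set.seed(205)
  for (rep in 1:5) {
    lab <- sample(c(rep(1, 8), rep(0, 12)))
    sc <- round(rnorm(20), 1)  # force ties
    pr <- pr_curve(sc, lab)
    s_or <- if (pr$orientation == "less-is-positive") -sc else sc
    thr <- sort(unique(s_or), decreasing = TRUE)
    tp <- c(0, vapply(thr, function(t) sum(s_or[lab == 1] >= t), 0))
    fp <- c(0, vapply(thr, function(t) sum(s_or[lab == 0] >= t), 0))
    expect_equal(pr$auc, pr_path_area(tp, fp, 8), tolerance = 1e-8)
  }
  expect_error_class(pr_curve(1:4, rep(0, 4)), "validation_error")
})

test_that("logit-method PR intervals are symmetric on the logit scale and shrink with n", {
  ci <- pr_auc_logit_ci(0.5, 40)
  expect_equal(stats::qlogis(ci$lower), -stats::qlogis(ci$upper), tolerance = 1e-12)
  wider <- pr_auc_logit_ci(0.7, 20)
  narrower <- pr_auc_logit_ci(0.7, 80)
  expect_lt(narrower$upper - narrower$lower, wider$upper - wider$lower)
  expect_true(pr_auc_logit_ci(1, 20)$degenerate)
  expect_true(all(unlist(pr_auc_logit_ci(0.9, 10)[1:2]) > 0 &
                  unlist(pr_auc_logit_ci(0.9, 10)[1:2]) < 1))
})

test_that("predictive values reproduce the published arithmetic", {
  # sens 69.6 / spec 79.3 at 50% prevalence
  pv <- predictive_values(0.696, 0.793, 0.5)
  expect_equal(round(100 * pv$ppv, 1), 77.1)
  # sens 69.6 / spec 86.2
  pv2 <- predictive_values(0.696, 0.862, 0.5)
  expect_equal(round(100 * pv2$npv, 1), 73.9)
  expect_equal(round(0.696 + 0.793 - 1, 3), 0.489)
  pv3 <- predictive_values(1, 1, 0.5)
  expect_equal(c(pv3$ppv, pv3$npv), c(1, 1))
})

test_that("Clopper-Pearson intervals hit the published bounds and boundaries", {
  ci <- exact_binomial_ci(16, 23)
  expect_equal(round(100 * ci[["lower"]], 1), 47.1)
  expect_equal(round(100 * ci[["upper"]], 1), 86.8)
  expect_equal(exact_binomial_ci(10, 10)[["upper"]], 1)
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  expect_error_class(exact_binomial_ci(5, 3), "validation_error")
})

test_that("Youden cutoffs maximize J with specificity-favoring ties", {
  yc <- youden_cutoff(c(1, 2, 3, 4, 10), c(0, 0, 1, 1, 1))
  expect_equal(yc$youden_j, 1)
  expect_equal(yc$cutoff, 2.5)
  expect_equal(yc$direction, ">")
  # report arithmetic: J = se + sp - 1 and the predictive-value formulas
  set.seed(206)
  for (rep in 1:10) {
    lab <- sample(rep(c(0, 1), c(12, 9)))
    sc <- round(rnorm(21), 1)
    r <- youden_cutoff(sc, lab)
    expect_equal(r$youden_j, (r$sensitivity + r$specificity) / 100 - 1, tolerance = 1e-12)
    pv <- predictive_values(r$sensitivity / 100, r$specificity / 100, r$prevalence)
    expect_equal(r$ppv, 100 * pv$ppv, tolerance = 1e-12)
    expect_equal(r$npv, 100 * pv$npv, tolerance = 1e-12)
  }
})

test_that("the Youden rule is invariant under strictly monotone transforms", {
  set.seed(207)
  lab <- rep(c(0, 1), each = 20)
  sc <- rnorm(40) + lab
  r1 <- youden_cutoff(sc, lab)
  r2 <- youden_cutoff(exp(sc), lab)
  expect_equal(r2$sensitivity, r1$sensitivity)
  expect_equal(r2$specificity, r1$specificity)
  # the transformed cutoff classifies identically
  expect_equal(exp(sc) > r2$cutoff, sc > r1$cutoff)
})

test_that("bootstrap cutoff intervals are deterministic and consistent", {
  set.seed(208)
  lab <- rep(c(0, 1), each = 25)
  sc <- rnorm(50) + 1.2 * lab
  b1 <- bootstrap_cutoff_ci(sc, lab, iterations = 400, seed = 978)
  b2 <- bootstrap_cutoff_ci(sc, lab, iterations = 400, seed = 978)
  expect_identical(b1, b2)
  # duplicating every subject tightens the J interval
  b10 <- bootstrap_cutoff_ci(rep(sc, 10), rep(lab, 10), iterations = 400, seed = 978)
  expect_lt(diff(b10$youden_j_ci), diff(b1$youden_j_ci))
  expect_warning(bootstrap_cutoff_ci(sc, lab, iterations = 50, seed = 1), "unstable")
})

test_that("AUC sample size reproduces the published calculation and monotonicities", {
  expect_equal(auc_sample_size(0.01, 0.8, 0.8, 0.5)$n_pos, 20)
  expect_lt(auc_sample_size(0.01, 0.8, 0.9, 0.5)$n_pos, 20)
  expect_lt(auc_sample_size(0.05, 0.8, 0.8, 0.5)$n_pos, 20)
  expect_gt(auc_sample_size(0.01, 0.9, 0.8, 0.5)$n_pos, 20)
  expect_error_class(auc_sample_size(0.01, 0.8, 0.5, 0.8), "validation_error")
})
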