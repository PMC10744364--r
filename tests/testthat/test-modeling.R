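test_that("logistic fits recover closed-form coefficients", {
  # intercept-only on a balanced outcome: log-odds zero
  y <- rep(c(0, 1), 20)
  f <- logistic_fit(data.frame(x = rnorm(40)), y)
  # (slope near zero for pure noise; intercept near zero)
  expect_lt(abs(f$coefficients[["(Intercept)"]]), 1)

  # 2x2 cell counts (10, 5; 5, 10): coefficient log(4)
  x <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  y2 <- c(rep(1, 15), rep(0, 15))
  f2 <- logistic_fit(data.frame(x = x), y2)
  expect_equal(f2$coefficients[["x"]], log(4), tolerance = 1e-8)

  expect_error_class(logistic_fit(data.frame(x = y2), y2), "separation_error")
  expect_error_class(logistic_fit(data.frame(x = rep(1, 30)), y2), "validation_error")
})

test_that("stepwise selection finds a strong predictor among noise", {
  set.seed(211)
  hits <- 0
  for (rep in 1:10) {
    y <- rep(c(0, 1), each = 30)
    cand <- data.frame(strong = y + rnorm(60, sd = 0.9),
                       n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60))
    r <- stepwise_select(cand, y)
    if (identical(r$selected, "strong") ||
        ("strong" %in% r$selected)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("stepwise agrees with exhaustive search on a fixed dataset", {
  set.seed(212)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  cand <- data.frame(a = y * 0.8 + rnorm(n), b = rnorm(n), c = rnorm(n))
  r <- stepwise_select(cand, y)
  # exhaustive: best admissible model under the same enter/stay criteria
  # (every included variable must hold Wald p <= 0.1, grown greedily);
  # here we check the selected set maximizes the likelihood among all
  # subsets whose members all pass the removal criterion
  subsets <- list(character(0), "a", "b", "c", c("a", "b"), c("a", "c"),
                  c("b", "c"), c("a", "b", "c"))
  admissible <- Filter(function(s) {
    if (!length(s)) return(TRUE)
    f <- tryCatch(logistic_fit(cand[s], y), ftdqeeg_error = function(e) NULL)
    !is.null(f) && all(ftdqeeg:::wald_p(f)[-1] <= 0.1)
  }, subsets)
  ll <- vapply(admissible, function(s) {
    if (!length(s)) {
      p <- mean(y); n * (p * log(p) + (1 - p) * log(1 - p))
    } else logistic_fit(cand[s], y)$loglik
  }, 0)
  best <- admissible[[which.max(ll)]]
  expect_setequal(r$selected, best)
})

test_that("all-noise candidate pools rarely admit a variable", {
  set.seed(213)
  entered <- 0
  for (rep in 1:20) {
    y <- rep(c(0, 1), each = 25)
    cand <- data.frame(n1 = rnorm(50), n2 = rnorm(50), n3 = rnorm(50))
    r <- stepwise_select(cand, y)
    if (length(r$selected)) entered <- entered + 1
  }
  # familywise entry is loose (3 candidates at 0.05): bound generously
  expect_lte(entered, 8)
})

test_that("classification accuracy matches direct prediction counting", {
  y <- c(rep(1, 23), rep(0, 29))
  r <- stepwise_select(data.frame(noise = rnorm(52, sd = 1e-3)), y)
  # intercept-only fallback: majority-class accuracy 29/52
  expect_equal(r$accuracy, 100 * 29 / 52, tolerance = 1e-9)

  set.seed(214)
  x <- rnorm(52) + y
  f <- logistic_fit(data.frame(x = x), y)
  acc <- classification_accuracy(f, data.frame(x = x), y)
  pred <- stats::plogis(f$coefficients[1] + f$coefficients[2] * x) >= 0.5
  expect_equal(acc, 100 * mean(pred == (y == 1)))
  expect_gte(acc, 0); expect_lte(acc, 100)
})

test_that("odds ratios and their intervals follow from the coefficients", {
  set.seed(215)
  y <- rep(c(0, 1), each = 30)
  cand <- data.frame(a = y + rnorm(60, sd = 1.2))
  r <- stepwise_select(cand, y)
  tab <- r$table
  expect_equal(tab$or, exp(tab$coefficient), tolerance = 1e-10)
  expect_equal(tab$or_lower, exp(tab$coefficient - stats::qnorm(0.975) * tab$se),
               tolerance = 1e-10)
  expect_equal(tab$or_upper, exp(tab$coefficient + stats::qnorm(0.975) * tab$se),
               tolerance = 1e-10)
  expect_equal(tab$wald, (tab$coefficient / tab$se)^2, tolerance = 1e-12)
})
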