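# Stepwise multiple logistic regression for disease status on candidate
# markers plus demographic covariates: forward entry by likelihood-ratio
# p-value, backward removal by Wald p-value.

#' Maximum-likelihood logistic fit
#'
#' Binomial GLM fit by iteratively reweighted least squares
#' ([stats::glm()]) with a tight convergence tolerance; covariance from
#' the inverse observed information. Predictors are standardized
#' internally for numerical stability and coefficients back-transformed
#' to the original scale. Complete or quasi-complete separation
#' (diverging coefficients / fitted probabilities at the boundary) raises
#' a `separation_error`.
#'
#' @param design Data frame or matrix of predictors (no intercept column).
#' @param outcome Binary outcome (logical, 0/1, or labels with `positive`).
#' @param positive Level of `outcome` treated as 1.
#' @return List with `coefficients`, `se`, `vcov`, `fit` (the glm object
#'   on the standardized scale), `loglik`, `converged`.
#' @export
logistic_fit <- function(design, outcome, positive = NULL) {
  y <- as_binary_labels(outcome, positive)
  design <- as.data.frame(design)
  if (nrow(design) != length(y))
    abort("design and outcome sizes differ", "validation_error")
  if (nrow(design) <= ncol(design) + 1L)
    abort("need more observations than predictors plus one", "validation_error")
  centers <- rep(0, ncol(design)); scales <- rep(1, ncol(design))
  X <- design
  for (j in seq_along(design)) {
    v <- design[[j]]
    if (!is.numeric(v)) abort("predictors must be numeric (code factors first)",
                              "validation_error")
    if (stats::sd(v) < 1e-12)
      abort(sprintf("predictor '%s' is constant", names(design)[j]), "validation_error")
    centers[j] <- mean(v); scales[j] <- stats::sd(v)
    X[[j]] <- (v - centers[j]) / scales[j]
  }
  dat <- cbind(X, .y = as.integer(y))
  fit <- suppressWarnings(stats::glm(
    .y ~ ., data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  if (!fit$converged || anyNA(stats::coef(fit)) ||
      max(abs(stats::coef(fit))) > 15)
    abort("separation detected: coefficients diverge, fit halted", "separation_error")
  beta_std <- stats::coef(fit)
  V_std <- stats::vcov(fit)
  # back-transform to original predictor scale
  k <- length(scales)
  Tm <- diag(c(1, 1 / scales))
  Tm[1, -1] <- -centers / scales
  beta <- as.vector(Tm %*% beta_std)
  V <- Tm %*% V_std %*% t(Tm)
  nm <- c("(Intercept)", names(design))
  names(beta) <- nm; dimnames(V) <- list(nm, nm)
  list(coefficients = beta, se = sqrt(diag(V)), vcov = V, fit = fit,
       loglik = as.numeric(stats::logLik(fit)), converged = fit$converged)
}

wald_p <- function(fit_obj) {
  w <- (fit_obj$coefficients / fit_obj$se)^2
  stats::pchisq(w, df = 1, lower.tail = FALSE)
}

#' Stepwise logistic variable selection
#'
#' Forward entry of the candidate with the smallest likelihood-ratio
#' p-value below `p_enter`, then backward removal of any included
#' variable whose Wald p-value exceeds `p_remove`, iterated to stability.
#' Candidates that trigger separation are skipped with a note.
#'
#' @param candidates Data frame of candidate predictors (markers plus
#'   covariates such as age and sex, all numeric).
#' @param outcome Binary outcome.
#' @param positive Level of `outcome` treated as 1.
#' @param p_enter Entry threshold (LRT p-value).
#' @param p_remove Removal threshold (Wald p-value).
#' @return Object of class `logistic_report`: selected variable names,
#'   per-variable coefficient/SE/Wald chi-square/odds ratio with 95
#'   percent CI, classification accuracy (percent, at probability 0.5 on
#'   the fitting sample), `n`, and the final `fit`.
#' @export
stepwise_select <- function(candidates, outcome, positive = NULL,
                            p_enter = 0.05, p_remove = 0.1) {
  candidates <- as.data.frame(candidates)
  if (!ncol(candidates)) abort("candidate set is empty", "validation_error")
  y <- as_binary_labels(outcome, positive)
  if (!any(y) || all(y)) abort("both outcome classes must be present", "validation_error")
  selected <- character(0)
  note <- NULL
  loglik_for <- function(vars) {
    if (!length(vars)) {
      p <- mean(y)
      sum(y * log(p) + (1 - y) * log(1 - p))
    } else logistic_fit(candidates[vars], y)$loglik
  }
  seen <- character(0)  # guard against enter/remove cycling
  repeat {
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen) break
    seen <- c(seen, state)
    changed <- FALSE
    # forward step
    pool <- setdiff(names(candidates), selected)
    if (length(pool)) {
      ll0 <- loglik_for(selected)
      ps <- vapply(pool, function(v) {
        ll1 <- tryCatch(loglik_for(c(selected, v)), ftdqeeg_error = function(e) NA_real_)
        if (is.na(ll1)) NA_real_
        else stats::pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
      }, 0)
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_enter) {
        selected <- c(selected, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward step; a removal that would recreate an already-visited
    # state signals enter/remove cycling (for instance the Hauck-Donner
    # collapse of the Wald statistic near separation) and ends selection
    if (length(selected)) {
      f <- logistic_fit(candidates[selected], y)
      wp <- wald_p(f)[-1]  # drop intercept
      if (max(wp) > p_remove) {
        reduced <- setdiff(selected, selected[which.max(wp)])
        if (paste(sort(reduced), collapse = "|") %in% seen) break
        selected <- reduced
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(selected)) {
    note <- "no candidate entered; intercept-only model"
    p <- mean(y)
    acc <- 100 * max(p, 1 - p)
    out <- list(selected = character(0), table = NULL, accuracy = acc,
                n = length(y), note = note, fit = NULL)
    class(out) <- "logistic_report"
    return(out)
  }
  f <- logistic_fit(candidates[selected], y)
  wp <- wald_p(f)
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    variable = names(f$coefficients),
    coefficient = unname(f$coefficients),
    se = unname(f$se),
    wald = unname((f$coefficients / f$se)^2),
    p = unname(wp),
    or = exp(unname(f$coefficients)),
    or_lower = exp(unname(f$coefficients - z * f$se)),
    or_upper = exp(unname(f$coefficients + z * f$se)),
    stringsAsFactors = FALSE)
  acc <- classification_accuracy(f, candidates[selected], y)
  out <- list(selected = selected, table = tab, accuracy = acc,
              n = length(y), note = note, fit = f)
  class(out) <- "logistic_report"
  out
}

#' @export
print.logistic_report <- function(x, ...) {
  if (!length(x$selected)) {
    cat("<logistic_report>", x$note, sprintf("(accuracy %.2f%%)\n", x$accuracy))
    return(invisible(x))
  }
  cat(sprintf("<logistic_report> selected: %s (n = %d, accuracy %.2f%%)\n",
              paste(x$selected, collapse = ", "), x$n, x$accuracy))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classification accuracy of a fitted logistic model
#'
#' Percent of subjects whose predicted probability at threshold 0.5
#' matches the outcome, on the fitting sample.
#'
#' @param fit_obj A [logistic_fit()] result.
#' @param design The predictor table the model was fitted on.
#' @param outcome Binary outcome.
#' @param positive Level of `outcome` treated as 1.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(fit_obj, design, outcome, positive = NULL) {
  y <- as_binary_labels(outcome, positive)
  X <- cbind(1, as.matrix(as.data.frame(design)))
  eta <- as.vector(X %*% fit_obj$coefficients)
  pred <- stats::plogis(eta) >= 0.5
  100 * mean(pred == y)
}
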