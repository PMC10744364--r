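# Group screening: Mann-Whitney U per feature, Benjamini-Hochberg
# correction across the feature family, demographic comparisons.

#' Mann-Whitney U test
#'
#' U counts pairs with `x > y` (plus half the ties). The p-value is by
#' exact enumeration when the combined sample size is at most 20 and tie
#' free, otherwise by the tie-corrected normal approximation with
#' continuity correction (this is the behaviour of
#' [stats::wilcox.test()], which does the computation).
#'
#' @param x,y Numeric samples (x is the group whose larger values push U up).
#' @param exact_max Combined size at or below which the exact distribution
#'   is used (tie-free samples only).
#' @return List with `U`, `p`, `n_x`, `n_y`, `degenerate` (TRUE when all
#'   values across both samples are identical, in which case `p = 1`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    abort("both samples must be nonempty and finite", "validation_error")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1, n_x = length(x),
                n_y = length(y), degenerate = TRUE))
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y), degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input-order
#' preservation and range validation.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    abort("p-values must lie in [0, 1]", "validation_error")
  stats::p.adjust(pvals, method = "BH")
}

#' Chi-square test for two proportions
#'
#' Pearson chi-square on the 2x2 table, without continuity correction,
#' 1 degree of freedom. Degenerate tables (a zero margin) return p = 1
#' with a flag.
#'
#' @param a_events,a_n,b_events,b_n Event counts and totals per group.
#' @return List with `chisq`, `p`, `degenerate`.
#' @export
chi_square_proportion <- function(a_events, a_n, b_events, b_n) {
  counts <- c(a_events, a_n, b_events, b_n)
  if (any(counts < 0) || a_events > a_n || b_events > b_n)
    abort("need 0 <= events <= n for both groups", "validation_error")
  tab <- matrix(c(a_events, a_n - a_events, b_events, b_n - b_events), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chisq = 0, p = 1, degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p = ct$p.value, degenerate = FALSE)
}

#' Screen all features for FTD versus CTL differences
#'
#' One Mann-Whitney U test per feature (the 65 power ratios plus the 10
#' lobar band powers when both tables are given), with Benjamini-Hochberg
#' adjustment across the whole family. The direction is the sign of the
#' FTD minus CTL median difference.
#'
#' @param ratios A [power_ratios()] table (or NULL).
#' @param powers A [band_power_table()] (or NULL).
#' @param subjects Subject table with `subject_id` and `group` columns
#'   (`"FTD"` / `"CTL"`).
#' @return Data frame of class `screening_result`: feature, U, p, p_adj,
#'   direction, median_ftd, median_ctl, n_ftd, n_ctl, sorted as given
#'   (ratios then powers).
#' @export
screen_features <- function(ratios, powers, subjects) {
  tabs <- list()
  if (!is.null(ratios)) tabs <- c(tabs, list(ratios))
  if (!is.null(powers)) tabs <- c(tabs, list(powers))
  if (!length(tabs)) abort("need at least one feature table", "validation_error")
  if (!all(c("subject_id", "group") %in% names(subjects)))
    abort("subjects needs subject_id and group columns", "validation_error")
  if (length(unique(subjects$group[subjects$group %in% c("FTD", "CTL")])) < 2L ||
      min(table(factor(subjects$group, c("FTD", "CTL")))) < 2L)
    abort("need at least 2 subjects in each of FTD and CTL", "validation_error")
  rows <- list()
  for (tab in tabs) {
    idx <- match(tab$subject_id, subjects$subject_id)
    if (anyNA(idx)) abort("feature table has subjects missing from the subject table",
                          "validation_error")
    grp <- subjects$group[idx]
    for (feat in setdiff(names(tab), "subject_id")) {
      v <- tab[[feat]]
      ok <- !is.na(v)
      x <- v[ok & grp == "FTD"]; y <- v[ok & grp == "CTL"]
      mw <- mann_whitney_u(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, U = mw$U, p = mw$p,
        direction = if (stats::median(x) >= stats::median(y)) "FTD>CTL" else "FTD<CTL",
        median_ftd = stats::median(x), median_ctl = stats::median(y),
        n_ftd = length(x), n_ctl = length(y), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[, c("feature", "U", "p", "p_adj", "direction",
                 "median_ftd", "median_ctl", "n_ftd", "n_ctl")]
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Demographic comparison table
#'
#' Age and MMSE by rank-sum (Mann-Whitney) test, sex by chi-square on the
#' female proportion.
#'
#' @param subjects Subject table (subject_id, group, age, sex, mmse).
#' @return Data frame with variable, summary per group, p.
#' @export
compare_demographics <- function(subjects) {
  ftd <- subjects[subjects$group == "FTD", ]
  ctl <- subjects[subjects$group == "CTL", ]
  num_row <- function(name, x, y) {
    mw <- mann_whitney_u(x, y)
    data.frame(variable = name,
               ftd = sprintf("%.2f (%.2f)", mean(x), stats::sd(x)),
               ctl = sprintf("%.2f (%.2f)", mean(y), stats::sd(y)),
               p = mw$p, stringsAsFactors = FALSE)
  }
  sex <- chi_square_proportion(sum(ftd$sex == "F"), nrow(ftd),
                               sum(ctl$sex == "F"), nrow(ctl))
  rbind(num_row("MMSE", ftd$mmse, ctl$mmse),
        num_row("Age", ftd$age, ctl$age),
        data.frame(variable = "Sex (female prop.)",
                   ftd = sprintf("%.2f", mean(ftd$sex == "F")),
                   ctl = sprintf("%.2f", mean(ctl$sex == "F")),
                   p = sex$p, stringsAsFactors = FALSE))
}
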