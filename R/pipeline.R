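# Orchestration: run the whole analysis over every (FFT parameterization
# x reference) configuration and collate the cross-configuration
# consistency of screened features.

#' Analysis configuration
#'
#' @param configurations Data frame with columns `window_s`,
#'   `steps_per_hz`, `reference` (one row per configuration). The default
#'   is the four-configuration consistency design: 2 s/10, 2 s/5 and
#'   1 s/10 under the average reference, plus 2 s/10 under REST.
#' @param scheme A [band_scheme()].
#' @param lobes A [lobe_map()].
#' @param prevalence Standardized prevalence for predictive values.
#' @param bootstrap List with `iterations` and `seed` for the Youden
#'   cutoff bootstrap.
#' @param tiers Significance tiers for the consistency report.
#' @param headline_markers Ratio names taken to the diagnostic and
#'   modeling stages.
#' @param model_covariates Subject-table columns offered to the stepwise
#'   model alongside the headline markers.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(configurations = data.frame(
                              window_s = c(2, 2, 1, 2),
                              steps_per_hz = c(10, 5, 10, 10),
                              reference = c("average", "average", "average", "REST")),
                            scheme = band_scheme(), lobes = lobe_map(),
                            prevalence = 0.5,
                            bootstrap = list(iterations = 5000, seed = 978),
                            tiers = c(0.05, 0.01),
                            headline_markers = c("F-theta/T-alpha", "F-alpha/T-theta",
                                                 "F-theta/F-alpha", "T-beta/T-gamma"),
                            model_covariates = c("age", "sex")) {
  configurations <- as.data.frame(configurations)
  if (!nrow(configurations))
    abort("at least one configuration required", "validation_error")
  if (!all(c("window_s", "steps_per_hz", "reference") %in% names(configurations)))
    abort("configurations need window_s, steps_per_hz, reference columns", "validation_error")
  bad <- setdiff(configurations$reference, c("average", "REST"))
  if (length(bad))
    abort(sprintf("unknown reference '%s' (use 'average' or 'REST')", bad[1]),
          "validation_error")
  configurations$name <- sprintf("%gs%g-%s", configurations$window_s,
                                 configurations$steps_per_hz, configurations$reference)
  if (is.unsorted(rev(tiers)))
    abort("tiers must be ordered from loose to strict", "validation_error")
  structure(list(configurations = configurations, scheme = scheme, lobes = lobes,
                 prevalence = prevalence, bootstrap = bootstrap, tiers = tiers,
                 headline_markers = headline_markers,
                 model_covariates = model_covariates),
            class = "analysis_config")
}

reference_recordings <- function(recordings, reference) {
  if (reference == "average")
    return(lapply(recordings, average_reference))
  model <- build_head_model(recordings[[1]]$labels)
  lapply(recordings, function(r) rest_reference(r, model))
}

#' Run the full spectral power-ratio analysis
#'
#' For each configuration: re-reference, compute lobar band powers and
#' the 65 ratios, screen all 75 features (Mann-Whitney with
#' Benjamini-Hochberg across the family), compute ROC (DeLong), PR
#' (logit-method CI), and Youden cutoff reports (with bootstrap CIs) for
#' the headline markers, and fit the stepwise logistic model on the
#' headline markers plus covariates. Finishes with the
#' cross-configuration consistency matrix. A failure inside one
#' configuration is recorded and the remaining configurations still run.
#'
#' @param cohort A [cohort_spec()], a directory path (see
#'   [read_cohort()]), or a list with `recordings` and `subjects`.
#' @param config An [analysis_config()].
#' @return Object of class `ftdqeeg_analysis`: per-configuration results,
#'   consistency matrix, demographics table, subjects.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  if (!inherits(config, "analysis_config"))
    abort("`config` must be an analysis_config", "validation_error")
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  subjects <- cohort$subjects
  if (min(table(factor(subjects$group, c("FTD", "CTL")))) < 2L)
    abort("need at least 2 subjects per group", "validation_error")
  is_ftd <- subjects$group == "FTD"
  per_config <- list()
  errors <- list()
  for (i in seq_len(nrow(config$configurations))) {
    cfg <- config$configurations[i, ]
    res <- tryCatch({
      recs <- reference_recordings(cohort$recordings, cfg$reference)
      params <- spectral_params(cfg$window_s, cfg$steps_per_hz,
                                fs = recs[[1]]$fs)
      powers <- band_power_table(recs, subjects$subject_id, params,
                                 lobes = config$lobes, scheme = config$scheme)
      ratios <- power_ratios(powers, scheme = config$scheme)
      screening <- screen_features(ratios, powers, subjects)
      diag <- list()
      for (mk in intersect(config$headline_markers, names(ratios))) {
        sc <- ratios[[mk]]
        ok <- !is.na(sc)
        roc <- roc_auc_delong(sc[ok], is_ftd[ok])
        pr <- pr_curve(sc[ok], is_ftd[ok])
        cut <- youden_cutoff(sc[ok], is_ftd[ok], prevalence = config$prevalence)
        bs <- bootstrap_cutoff_ci(sc[ok], is_ftd[ok],
                                  iterations = config$bootstrap$iterations,
                                  seed = config$bootstrap$seed)
        cut$cutoff_ci <- bs$cutoff_ci
        cut$youden_j_ci <- bs$youden_j_ci
        diag[[mk]] <- list(roc = roc, pr = pr, cutoff = cut)
      }
      cand <- ratios[intersect(config$headline_markers, names(ratios))]
      for (cv in config$model_covariates) {
        v <- subjects[[cv]]
        cand[[cv]] <- if (is.numeric(v)) v else as.numeric(factor(v)) - 1
      }
      model <- stepwise_select(cand, is_ftd)
      list(name = cfg$name, params = params, reference = cfg$reference,
           powers = powers, ratios = ratios, screening = screening,
           diagnostics = diag, model = model)
    }, ftdqeeg_error = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) {
      errors[[cfg$name]] <- conditionMessage(res)
      warning(sprintf("configuration %s failed: %s", cfg$name,
                      conditionMessage(res)), call. = FALSE)
    } else per_config[[cfg$name]] <- res
  }
  consistency <- if (length(per_config) >= 2L)
    consistency_report(lapply(per_config, `[[`, "screening"), config$tiers)
  else NULL
  structure(list(per_config = per_config, consistency = consistency,
                 demographics = compare_demographics(subjects),
                 subjects = subjects, config = config, errors = errors),
            class = "ftdqeeg_analysis")
}

#' Cross-configuration consistency of screened features
#'
#' A feature is tier-consistent when its BH-adjusted p-value is below the
#' tier with the same group direction in every configuration.
#'
#' @param screenings List (one per configuration) of
#'   [screen_features()] results.
#' @param tiers Significance tiers.
#' @return Data frame: feature, direction, worst (largest) `p_adj` across
#'   configurations, and one logical column per tier.
#' @export
consistency_report <- function(screenings, tiers = c(0.05, 0.01)) {
  if (length(screenings) < 2L)
    abort("need at least 2 configurations for a consistency report", "validation_error")
  feats <- Reduce(intersect, lapply(screenings, function(s) s$feature))
  if (!length(feats)) abort("configurations share no features", "validation_error")
  if (!all(vapply(screenings, function(s) length(s$feature), 0L) == length(feats)))
    warning("configurations have differing feature sets; using the intersection",
            call. = FALSE)
  p_adj <- vapply(screenings, function(s) s$p_adj[match(feats, s$feature)],
                  numeric(length(feats)))
  dirs <- vapply(screenings, function(s) s$direction[match(feats, s$feature)],
                 character(length(feats)))
  same_dir <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  worst <- apply(p_adj, 1L, max)
  out <- data.frame(feature = feats,
                    direction = ifelse(same_dir, dirs[, 1], "inconsistent"),
                    worst_p_adj = worst, stringsAsFactors = FALSE)
  for (t in tiers)
    out[[sprintf("consistent_%g", t)]] <- same_dir & worst < t
  class(out) <- c("consistency_report", "data.frame")
  out
}

#' @export
print.ftdqeeg_analysis <- function(x, ...) {
  cat(sprintf("<ftdqeeg_analysis> %d configuration(s): %s\n",
              length(x$per_config), paste(names(x$per_config), collapse = ", ")))
  cat(sprintf("  %d FTD / %d CTL subjects\n", sum(x$subjects$group == "FTD"),
              sum(x$subjects$group == "CTL")))
  if (!is.null(x$consistency)) {
    for (t in x$config$tiers) {
      col <- sprintf("consistent_%g", t)
      n <- sum(x$consistency[[col]])
      cat(sprintf("  features consistent at p_adj < %g in all configurations: %d\n", t, n))
    }
    strict <- x$consistency[[sprintf("consistent_%g", min(x$config$tiers))]]
    if (any(strict))
      cat("   ", paste(x$consistency$feature[strict], collapse = ", "), "\n")
  }
  if (length(x$errors))
    cat("  failed configurations:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' TSV tables per configuration (band powers, ratios, screening, cutoff
#' reports, logistic model) plus the consistency matrix and a
#' machine-readable JSON summary.
#'
#' @param analysis A [run_analysis()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(analysis$demographics, "demographics.tsv")
  wt(analysis$subjects, "participants.tsv")
  summary <- list()
  for (nm in names(analysis$per_config)) {
    pc <- analysis$per_config[[nm]]
    wt(pc$powers, sprintf("%s_band_powers.tsv", nm))
    wt(pc$ratios, sprintf("%s_ratios.tsv", nm))
    wt(pc$screening, sprintf("%s_screening.tsv", nm))
    cuts <- do.call(rbind, lapply(names(pc$diagnostics), function(mk) {
      d <- pc$diagnostics[[mk]]
      data.frame(marker = mk,
                 auc = d$roc$auc, auc_se = d$roc$se,
                 auc_lo = d$roc$ci95[1], auc_hi = d$roc$ci95[2],
                 pr_auc = d$pr$auc, pr_lo = d$pr$ci95[1], pr_hi = d$pr$ci95[2],
                 cutoff = d$cutoff$cutoff, direction = d$cutoff$direction,
                 cutoff_lo = d$cutoff$cutoff_ci[1], cutoff_hi = d$cutoff$cutoff_ci[2],
                 sensitivity = d$cutoff$sensitivity,
                 sens_lo = d$cutoff$sensitivity_ci[1], sens_hi = d$cutoff$sensitivity_ci[2],
                 specificity = d$cutoff$specificity,
                 spec_lo = d$cutoff$specificity_ci[1], spec_hi = d$cutoff$specificity_ci[2],
                 youden_j = d$cutoff$youden_j,
                 j_lo = d$cutoff$youden_j_ci[1], j_hi = d$cutoff$youden_j_ci[2],
                 ppv = d$cutoff$ppv, ppv_lo = d$cutoff$ppv_ci[1], ppv_hi = d$cutoff$ppv_ci[2],
                 npv = d$cutoff$npv, npv_lo = d$cutoff$npv_ci[1], npv_hi = d$cutoff$npv_ci[2],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(cuts)) wt(cuts, sprintf("%s_diagnostics.tsv", nm))
    for (mk in names(pc$diagnostics)) {
      safe <- gsub("/", "_over_", mk, fixed = TRUE)
      wt(pc$diagnostics[[mk]]$roc$curve, sprintf("%s_roc_%s.tsv", nm, safe))
      wt(pc$diagnostics[[mk]]$pr$curve, sprintf("%s_pr_%s.tsv", nm, safe))
    }
    if (!is.null(pc$model$table)) wt(pc$model$table, sprintf("%s_model.tsv", nm))
    summary[[nm]] <- list(
      reference = pc$reference,
      window_s = pc$params$window_s, steps_per_hz = pc$params$steps_per_hz,
      n_significant_05 = sum(pc$screening$p_adj < 0.05),
      n_significant_01 = sum(pc$screening$p_adj < 0.01),
      model_selected = pc$model$selected, model_accuracy = pc$model$accuracy,
      markers = lapply(pc$diagnostics, function(d)
        list(auc = d$roc$auc, pr_auc = d$pr$auc, youden_j = d$cutoff$youden_j,
             cutoff = d$cutoff$cutoff)))
  }
  if (!is.null(analysis$consistency)) wt(analysis$consistency, "consistency.tsv")
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Screening bar chart
#'
#' Figure-style overview of the screening: minus log10 adjusted p per
#' feature with rule lines at the significance tiers. Requires ggplot2.
#'
#' @param screening A [screen_features()] result.
#' @param tiers Significance tiers drawn as rule lines.
#' @param top_n Show only the `top_n` smallest adjusted p-values.
#' @return A ggplot object.
#' @export
plot_screening <- function(screening, tiers = c(0.05, 0.01), top_n = 30) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort("ggplot2 is required for plotting", "validation_error")
  d <- screening[order(screening$p_adj), ]
  d <- utils::head(d, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = -log10(.data$p_adj),
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(tiers), linetype = "dashed",
                        colour = c("darkgreen", "red")[seq_along(tiers)]) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10]~adjusted~italic(p)),
                  fill = "Direction") +
    ggplot2::theme_minimal()
}
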