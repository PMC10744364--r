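# Synthetic resting-state EEG cohorts with configurable lobe-by-band
# spectral group effects. Signals are sums of unit-RMS band-limited noise
# carriers scaled by per-(lobe, band) amplitudes plus a 1/f^beta broadband
# floor; FTD subjects get multiplicative amplitude effects.

default_base_amplitude <- function(scheme = band_scheme()) {
  # microvolt RMS per band, eyes-closed resting baseline (CTL)
  amps <- c(delta = 10, theta = 8, alpha = 12, beta = 5, gamma = 2)
  m <- matrix(rep(amps[scheme$band], each = 3L), nrow = 3L,
              dimnames = list(c("F", "T", "other"), scheme$band))
  m
}

default_ftd_multipliers <- function(scheme = band_scheme()) {
  m <- matrix(1, nrow = 2L, ncol = nrow(scheme),
              dimnames = list(c("F", "T"), scheme$band))
  if (all(c("theta", "alpha", "gamma") %in% scheme$band)) {
    m["F", "theta"] <- 1.3
    m["F", "alpha"] <- 0.75
    m["T", "alpha"] <- 0.7
    m["T", "gamma"] <- 1.25
  }
  m
}

#' Specification of a synthetic EEG cohort
#'
#' Generative parameters for a two-group (FTD/CTL) resting-state cohort:
#' group sizes, montage, per-(lobe, band) microvolt-RMS amplitudes for the
#' CTL baseline, multiplicative FTD group effects, between-subject
#' log-normal amplitude spread, a 1/f^beta background floor, and
#' demographic covariate models. The defaults emulate a 19-channel 10-20
#' montage at 500 Hz with lower frontal/temporal alpha and higher frontal
#' theta and temporal gamma in FTD, which raises F-theta/T-alpha and
#' F-theta/F-alpha and lowers F-alpha/T-theta and T-beta/T-gamma.
#'
#' @param n_ftd,n_ctl Group sizes.
#' @param fs Sampling rate (Hz).
#' @param duration Recording length (seconds).
#' @param channels Ordered channel labels (10-20 names).
#' @param base_amplitude 3 x bands matrix (rows `F`, `T`, `other`) of CTL
#'   band amplitudes, microvolt RMS.
#' @param ftd_multipliers 2 x bands matrix (rows `F`, `T`) of
#'   multiplicative FTD amplitude effects; non-frontal/temporal channels
#'   always use the CTL baseline.
#' @param subject_sd Log-normal sigma of the per-(subject, lobe, band)
#'   amplitude factor.
#' @param background_exponent Spectral slope beta of the 1/f^beta floor.
#' @param background_scale Microvolt RMS of the floor; default 0.1 times
#'   the mean base amplitude.
#' @param covariates Per-group demographic models: list with elements
#'   `FTD` and `CTL`, each `list(age_mean, age_sd, female_p, mmse_mean,
#'   mmse_sd)`.
#' @param scheme A [band_scheme()].
#' @param lobes A [lobe_map()].
#' @param seed Integer seed; identical spec + seed reproduces the cohort
#'   bit-identically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ftd = 23, n_ctl = 29, fs = 500, duration = 600,
                        channels = channels_1020(),
                        base_amplitude = default_base_amplitude(scheme),
                        ftd_multipliers = default_ftd_multipliers(scheme),
                        subject_sd = 0.2,
                        background_exponent = 1,
                        background_scale = 0.1 * mean(base_amplitude),
                        covariates = list(
                          FTD = list(age_mean = 63.6, age_sd = 8.2, female_p = 0.39,
                                     mmse_mean = 22.17, mmse_sd = 8.22),
                          CTL = list(age_mean = 67.9, age_sd = 5.4, female_p = 0.38,
                                     mmse_mean = 30, mmse_sd = 0)),
                        scheme = band_scheme(), lobes = lobe_map(), seed = 1L) {
  stopifnot_scalar_number(n_ftd, "n_ftd", lower = 1)
  stopifnot_scalar_number(n_ctl, "n_ctl", lower = 1)
  stopifnot_scalar_number(fs, "fs", lower = 2 * max(scheme$high) + 1e-9)
  stopifnot_scalar_number(duration, "duration", lower = 2)
  stopifnot_scalar_number(subject_sd, "subject_sd", lower = 0)
  stopifnot_scalar_number(background_scale, "background_scale", lower = 0)
  channels <- normalize_labels(channels)
  base_amplitude <- as.matrix(base_amplitude)
  ftd_multipliers <- as.matrix(ftd_multipliers)
  if (!all(c("F", "T", "other") %in% rownames(base_amplitude)) ||
      !identical(colnames(base_amplitude), scheme$band))
    abort("base_amplitude needs rows F, T, other and one column per band", "validation_error")
  if (!all(c("F", "T") %in% rownames(ftd_multipliers)) ||
      !identical(colnames(ftd_multipliers), scheme$band))
    abort("ftd_multipliers needs rows F, T and one column per band", "validation_error")
  if (any(base_amplitude < 0) || any(ftd_multipliers < 0))
    abort("amplitudes and multipliers must be nonnegative", "validation_error")
  structure(list(n_ftd = as.integer(n_ftd), n_ctl = as.integer(n_ctl),
                 fs = fs, duration = duration, channels = channels,
                 base_amplitude = base_amplitude, ftd_multipliers = ftd_multipliers,
                 subject_sd = subject_sd,
                 background_exponent = background_exponent,
                 background_scale = background_scale,
                 covariates = covariates, scheme = scheme, lobes = lobes,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d FTD + %d CTL, %d channels @ %g Hz, %g s, seed %d\n",
              x$n_ftd, x$n_ctl, length(x$channels), x$fs, x$duration, x$seed))
  invisible(x)
}

#' Unit-RMS band-limited Gaussian noise
#'
#' Constructed in the frequency domain: i.i.d. complex Gaussian
#' coefficients on the grid frequencies inside `[low, high]`, zero
#' outside, inverse transformed and rescaled to unit RMS, so the band
#' confinement is exact.
#'
#' @param low,high Band edges (Hz); must satisfy `0 < low < high < fs/2`.
#' @param fs Sampling rate (Hz).
#' @param n Number of samples.
#' @return Numeric vector of length `n` with RMS exactly 1.
#' @export
band_limited_noise <- function(low, high, fs, n) {
  if (!(low > 0 && high > low && high < fs / 2))
    abort(sprintf("band (%g, %g) must lie strictly inside (0, Nyquist = %g)",
                  low, high, fs / 2), "invalid_band_error")
  n <- as.integer(n)
  if (n < 10 * fs / low)
    warning(sprintf("signal of %d samples is short for a %g Hz lower edge; spectral leakage grows",
                    n, low), call. = FALSE)
  f <- (seq_len(n %/% 2L)) * fs / n           # positive-frequency bins
  sel <- which(f >= low & f <= high)
  if (!length(sel)) abort("no frequency bins inside the band at this length", "invalid_band_error")
  coef <- complex(real = stats::rnorm(length(sel)),
                  imaginary = stats::rnorm(length(sel)))
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[1L + sel] <- coef
  spec[n + 1L - sel] <- Conj(coef)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Unit-RMS 1/f^beta noise confined to [low, high] Hz.
one_over_f_noise <- function(beta, fs, n, low = 0.5, high = 45) {
  n <- as.integer(n)
  high <- min(high, fs / 2 * 0.999)
  f <- (seq_len(n %/% 2L)) * fs / n
  sel <- which(f >= low & f <= high)
  coef <- complex(real = stats::rnorm(length(sel)),
                  imaginary = stats::rnorm(length(sel))) * f[sel]^(-beta / 2)
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[1L + sel] <- coef
  spec[n + 1L - sel] <- Conj(coef)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

channel_lobe <- function(channels, lobes) {
  ifelse(channels %in% lobes$F, "F", ifelse(channels %in% lobes$T, "T", "other"))
}

# Per-(lobe, band) amplitudes for one subject. subject_factors is a
# 3 x bands matrix of log-normal draws (rows F, T, other).
subject_amplitudes <- function(spec, group, subject_factors) {
  a <- spec$base_amplitude
  if (group == "FTD") {
    a["F", ] <- a["F", ] * spec$ftd_multipliers["F", ]
    a["T", ] <- a["T", ] * spec$ftd_multipliers["T", ]
  }
  a * subject_factors
}

#' Generate one subject's multichannel recording
#'
#' Each channel is the sum over bands of the subject's (lobe, band)
#' amplitude times an independent unit-RMS band-limited noise carrier,
#' plus the 1/f^beta background floor. Channels outside the frontal and
#' temporal sets use the CTL baseline profile in both groups. Draws from
#' the current R RNG state; seed management is done by [generate_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param group `"FTD"` or `"CTL"`.
#' @param subject_factors Optional 3 x bands matrix of per-(lobe, band)
#'   log-normal factors; drawn internally when omitted.
#' @return An [eeg_recording()], reference state `"average"`-agnostic
#'   (`"as-recorded"`).
#' @export
generate_subject_signal <- function(spec, group = c("CTL", "FTD"), subject_factors = NULL) {
  group <- match.arg(group)
  if (is.null(subject_factors))
    subject_factors <- draw_subject_factors(spec)
  amps <- subject_amplitudes(spec, group, subject_factors)
  n <- as.integer(round(spec$duration * spec$fs))
  half <- n %/% 2L
  f <- seq_len(half) * spec$fs / n
  sels <- lapply(seq_len(nrow(spec$scheme)), function(b)
    which(f >= spec$scheme$low[b] & f <= spec$scheme$high[b]))
  bg_sel <- which(f >= 0.5 & f <= min(45, spec$fs / 2 * 0.999))
  bg_w <- f[bg_sel]^(-spec$background_exponent / 2)
  lobe_of <- channel_lobe(spec$channels, spec$lobes)
  nch <- length(spec$channels)
  # all carriers synthesized in one frequency-domain pass per channel:
  # complex Gaussian coefficients inside each band, normalized to the
  # band's exact (Parseval) unit RMS, then scaled by the (lobe, band)
  # amplitude; plus the 1/f^beta floor. One inverse FFT per channel.
  spec_mat <- matrix(0i, n, nch)
  for (ch in seq_len(nch)) {
    pos <- complex(real = rep(0, half), imaginary = rep(0, half))
    for (b in seq_len(nrow(spec$scheme))) {
      a <- amps[lobe_of[ch], spec$scheme$band[b]]
      sel <- sels[[b]]
      if (a > 0 && length(sel)) {
        cf <- complex(real = stats::rnorm(length(sel)),
                      imaginary = stats::rnorm(length(sel)))
        cf <- cf * (a / sqrt(2 / n^2 * sum(Mod(cf)^2)))
        pos[sel] <- pos[sel] + cf
      }
    }
    if (spec$background_scale > 0 && length(bg_sel)) {
      cf <- complex(real = stats::rnorm(length(bg_sel)),
                    imaginary = stats::rnorm(length(bg_sel))) * bg_w
      cf <- cf * (spec$background_scale / sqrt(2 / n^2 * sum(Mod(cf)^2)))
      pos[bg_sel] <- pos[bg_sel] + cf
    }
    spec_mat[1L + seq_len(half), ch] <- pos
    spec_mat[n + 1L - seq_len(half), ch] <- Conj(pos)
  }
  data <- t(Re(stats::mvfft(spec_mat, inverse = TRUE)) / n)
  eeg_recording(data, spec$fs, spec$channels, reference = "as-recorded")
}

draw_subject_factors <- function(spec) {
  m <- matrix(stats::rlnorm(3L * nrow(spec$scheme), 0, spec$subject_sd),
              nrow = 3L, dimnames = list(c("F", "T", "other"), spec$scheme$band))
  m
}

draw_covariates <- function(spec, group) {
  cv <- spec$covariates[[group]]
  age <- round(stats::rnorm(1, cv$age_mean, cv$age_sd), 1)
  sex <- if (stats::runif(1) < cv$female_p) "F" else "M"
  mmse <- if (cv$mmse_sd <= 0) round(cv$mmse_mean)
          else round(stats::rnorm(1, cv$mmse_mean, cv$mmse_sd))
  mmse <- max(0L, min(30L, as.integer(mmse)))
  list(age = age, sex = sex, mmse = mmse)
}

#' Generate a synthetic cohort
#'
#' Draws `n_ftd + n_ctl` recordings and a subject table under the spec's
#' seed. FTD subjects come first; subject ids are `sub-001`, `sub-002`,
#' and so on. Identical spec and seed reproduce the cohort bit-identically.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of [eeg_recording()]) and
#'   `subjects` (data frame: subject_id, group, age, sex, mmse).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec", "validation_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  groups <- c(rep("FTD", spec$n_ftd), rep("CTL", spec$n_ctl))
  ids <- sprintf("sub-%03d", seq_along(groups))
  recordings <- vector("list", length(groups))
  subjects <- data.frame(subject_id = ids, group = groups,
                         age = NA_real_, sex = NA_character_, mmse = NA_integer_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    cv <- draw_covariates(spec, groups[i])
    subjects$age[i] <- cv$age; subjects$sex[i] <- cv$sex; subjects$mmse[i] <- cv$mmse
    factors <- draw_subject_factors(spec)
    recordings[[i]] <- generate_subject_signal(spec, groups[i], factors)
  }
  list(recordings = recordings, subjects = subjects)
}

#' Write a cohort to disk
#'
#' EDF files plus a tab-separated subject table. `layout = "flat"` writes
#' `<id>.edf` files next to `participants.tsv`; `layout = "bids"` writes a
#' BIDS-EEG style tree `sub-*/eeg/sub-*_task-rest_eeg.edf`.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param layout `"flat"` or `"bids"`.
#' @return Invisibly, the paths of the written EDF files.
#' @export
write_cohort <- function(cohort, dir, layout = c("flat", "bids")) {
  layout <- match.arg(layout)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_subject_table(cohort$subjects, file.path(dir, "participants.tsv"))
  paths <- character(nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    paths[i] <- if (layout == "bids") {
      d <- file.path(dir, id, "eeg"); dir.create(d, recursive = TRUE, showWarnings = FALSE)
      file.path(d, sprintf("%s_task-rest_eeg.edf", id))
    } else file.path(dir, paste0(id, ".edf"))
    write_edf(cohort$recordings[[i]], paths[i])
  }
  invisible(paths)
}
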