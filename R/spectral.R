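#' Welch/FFT parameterization
#'
#' A parameterization is written "window/steps" (seconds / frequency-grid
#' points per Hz). The FFT length is `steps_per_hz * fs` samples, so the
#' spectral grid has spacing `1/steps_per_hz` Hz; segments overlap by the
#' given fraction. At 500 Hz the three parameterizations used for the
#' consistency analysis decompose as window/FFT/overlap sample counts
#' 1000/5000/500 (2 s/10), 1000/2500/500 (2 s/5) and 500/5000/250 (1 s/10).
#'
#' @param window_s Segment length in seconds.
#' @param steps_per_hz Frequency-grid points per Hz (FFT zero-padding factor).
#' @param fs Sampling rate (Hz).
#' @param overlap Overlap fraction between consecutive segments.
#' @param taper Taper applied per segment: `"hamming"`, `"hann"` or `"rect"`.
#' @param detrend Remove the per-segment mean before tapering?
#' @return An object of class `spectral_params` with derived integer fields
#'   `window_n`, `nfft`, `overlap_n`, `step_n`.
#' @examples
#' p <- spectral_params(2, 10, fs = 500)
#' c(p$window_n, p$nfft, p$overlap_n)  # 1000 5000 500
#' @export
spectral_params <- function(window_s, steps_per_hz, fs = 500, overlap = 0.5,
                            taper = c("hamming", "hann", "rect"), detrend = TRUE) {
  taper <- match.arg(taper)
  stopifnot_scalar_number(window_s, "window_s", lower = 1e-9)
  stopifnot_scalar_number(steps_per_hz, "steps_per_hz", lower = 1e-9)
  stopifnot_scalar_number(fs, "fs", lower = 1e-9)
  stopifnot_scalar_number(overlap, "overlap", lower = 0, upper = 0.99)
  window_n <- as.integer(round(window_s * fs))
  nfft <- as.integer(round(steps_per_hz * fs))
  if (nfft < window_n)
    abort("FFT length (steps_per_hz * fs) shorter than the window; increase steps_per_hz",
          "validation_error")
  overlap_n <- as.integer(round(window_n * overlap))
  structure(list(window_s = window_s, steps_per_hz = steps_per_hz, fs = fs,
                 overlap = overlap, taper = taper, detrend = detrend,
                 window_n = window_n, nfft = nfft, overlap_n = overlap_n,
                 step_n = window_n - overlap_n),
            class = "spectral_params")
}

#' @export
print.spectral_params <- function(x, ...) {
  cat(sprintf("<spectral_params> %g s / %g steps per Hz @ %g Hz: window/FFT/overlap = %d/%d/%d samples, %s taper\n",
              x$window_s, x$steps_per_hz, x$fs, x$window_n, x$nfft, x$overlap_n, x$taper))
  invisible(x)
}

taper_window <- function(n, type) {
  switch(type,
         hamming = 0.54 - 0.46 * cos(2 * pi * seq_len(n) / (n + 1)),
         hann    = 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))),
         rect    = rep(1, n))
}

# Segment a signal into a window_n x nseg matrix of overlapping segments.
segment_matrix <- function(x, window_n, step_n) {
  n <- length(x)
  nseg <- 1L + (n - window_n) %/% step_n
  starts <- (seq_len(nseg) - 1L) * step_n
  matrix(x[rep(starts, each = window_n) + seq_len(window_n)], nrow = window_n)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: overlapping segments are (optionally)
#' mean-detrended, tapered, zero-padded to the FFT length and averaged.
#' One-sided density scaling is Parseval-consistent: the sum of the
#' spectrum times the grid spacing over (0, Nyquist\] equals the tapered
#' signal's mean power.
#'
#' @param signal Numeric vector (one channel, microvolts).
#' @param params A [spectral_params()].
#' @return An object of class `psd`: list with `freq` (Hz) and `power`
#'   (microvolts squared per Hz), plus the params used.
#' @export
welch_psd <- function(signal, params) {
  if (!inherits(params, "spectral_params")) abort("`params` must be spectral_params", "validation_error")
  if (length(signal) < params$window_n)
    abort(sprintf("signal (%d samples) shorter than one window (%d samples)",
                  length(signal), params$window_n), "invalid_input_error")
  p <- welch_psd_matrix(matrix(as.numeric(signal), nrow = 1), params)
  structure(list(freq = attr(p, "freq"), power = p[1, ], params = params), class = "psd")
}

# Multi-channel Welch kernel: rows are channels, returns channels x nfreq
# power matrix with the frequency grid in attr "freq".
welch_psd_matrix <- function(data, params) {
  w <- taper_window(params$window_n, params$taper)
  scale <- 2 / (params$fs * sum(w^2))
  nfreq <- params$nfft %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * params$fs / params$nfft
  out <- matrix(0, nrow(data), nfreq)
  pad <- matrix(0, params$nfft - params$window_n, 0)
  for (ch in seq_len(nrow(data))) {
    seg <- segment_matrix(data[ch, ], params$window_n, params$step_n)
    if (params$detrend) seg <- sweep(seg, 2L, colMeans(seg))
    seg <- seg * w
    if (params$nfft > params$window_n)
      seg <- rbind(seg, matrix(0, params$nfft - params$window_n, ncol(seg)))
    spec <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    pw <- rowMeans(Mod(spec)^2) * scale
    # DC and (even-nfft) Nyquist bins are not mirrored: halve them back
    pw[1L] <- pw[1L] / 2
    if (params$nfft %% 2L == 0L) pw[nfreq] <- pw[nfreq] / 2
    out[ch, ] <- pw
  }
  attr(out, "freq") <- freq
  out
}

#' Absolute average band power
#'
#' Mean of the spectral density over the grid points inside a band. The
#' band interval is half-open `(low, high]` unless `include_low = TRUE`
#' (used for the lowest band, delta).
#'
#' @param spectrum A `psd` object from [welch_psd()].
#' @param low,high Band edges (Hz).
#' @param include_low Include the lower edge itself?
#' @return Scalar band power (microvolts squared per Hz, averaged over the
#'   band's grid points).
#' @export
band_power <- function(spectrum, low, high, include_low = FALSE) {
  if (!inherits(spectrum, "psd")) abort("`spectrum` must be a psd object", "validation_error")
  if (low >= high) abort("band low edge must be below high edge", "invalid_band_error")
  if (low > max(spectrum$freq) || high > max(spectrum$freq) + 1e-9)
    abort(sprintf("band (%g, %g] outside spectrum range (0, %g]", low, high,
                  max(spectrum$freq)), "invalid_band_error")
  sel <- if (include_low) spectrum$freq >= low & spectrum$freq <= high
         else spectrum$freq > low & spectrum$freq <= high
  if (!any(sel)) abort("no spectral grid points inside the band", "invalid_band_error")
  mean(spectrum$power[sel])
}

# ---- fast band-power engine ------------------------------------------------
# Identical estimator to welch_psd + band mean, computed without the
# zero-padded FFT: the band mean over the fine grid is a linear
# functional of the segment-averaged autocorrelation,
#   sum_{k in K} |X_k|^2 = r(0) |K| + 2 sum_{d>=1} r(d) c_K(d),
#   c_K(d) = sum_{k in K} cos(2 pi k d / nfft),
# where r(d) is the autocorrelation of the detrended, tapered segment.
# Autocorrelations come from power-of-two FFTs with two segments packed
# per complex column (|A_k|^2 + |B_k|^2 = (|Y_k|^2 + |Y_{-k}|^2) / 2).

# Per-band grid index sets on the nfft grid, same edge convention as
# band_powers_matrix.
band_bin_sets <- function(params, scheme) {
  nfreq <- params$nfft %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * params$fs / params$nfft
  lapply(seq_len(nrow(scheme)), function(i) {
    sel <- if (i == 1L) freq >= scheme$low[i] & freq <= scheme$high[i]
           else freq > scheme$low[i] & freq <= scheme$high[i]
    which(sel) - 1L  # 0-based grid index k
  })
}

# Autocorrelation-to-band-mean weight matrix, window_n x nbands:
# column b maps r(0..L-1) to the band-mean power including the Welch
# scale 2 / (fs sum w^2).
band_weight_matrix <- function(params, scheme) {
  bins <- band_bin_sets(params, scheme)
  if (any(vapply(bins, length, 0L) == 0L))
    abort("spectral grid misses a band entirely", "invalid_band_error")
  w <- taper_window(params$window_n, params$taper)
  scale <- 2 / (params$fs * sum(w^2))
  d <- 0:(params$window_n - 1L)
  out <- matrix(0, params$window_n, length(bins),
                dimnames = list(NULL, scheme$band))
  for (b in seq_along(bins)) {
    k <- bins[[b]]
    cb <- cos(outer(d, k) * (2 * pi / params$nfft)) %*% rep(1, length(k))
    cb <- as.vector(cb)
    cb[-1L] <- 2 * cb[-1L]
    out[, b] <- cb * scale / length(k)
  }
  out
}

# channels x nbands band-power matrix, equal to
# band_powers_matrix(welch_psd_matrix(data, params), ...) up to float
# rounding, but much faster.
fast_band_power_matrix <- function(data, params, scheme,
                                   weights = band_weight_matrix(params, scheme)) {
  L <- params$window_n
  Q <- 2L^ceiling(log2(2L * L))
  w <- taper_window(L, params$taper)
  nch <- nrow(data)
  cols <- list(); owner <- integer(0)
  nseg <- NA_integer_
  for (ch in seq_len(nch)) {
    seg <- segment_matrix(data[ch, ], L, params$step_n)
    nseg <- ncol(seg)
    if (params$detrend) seg <- sweep(seg, 2L, colMeans(seg))
    seg <- seg * w
    odd <- seq(1L, nseg, by = 2L)
    even <- odd + 1L
    has_even <- even <= nseg
    z <- matrix(0i, Q, length(odd))
    z[seq_len(L), ] <- seg[, odd, drop = FALSE] * (1 + 0i)
    if (any(has_even))
      z[seq_len(L), has_even] <- z[seq_len(L), has_even] +
        1i * seg[, even[has_even], drop = FALSE]
    cols[[ch]] <- z
    owner <- c(owner, rep(ch, length(odd)))
  }
  Z <- do.call(cbind, cols)
  Y <- stats::mvfft(Z)
  P <- Mod(Y)^2
  P <- (P + P[c(1L, Q:2L), , drop = FALSE]) / 2   # per-column pair sum
  # per-channel sums of segment spectra
  S <- t(rowsum(t(P), owner))                      # Q x nch
  r <- Re(stats::mvfft(S, inverse = TRUE)) / Q     # autocorrelation sums
  rbar <- r[seq_len(L), , drop = FALSE] / nseg
  bp <- t(rbar) %*% weights
  rownames(bp) <- rownames(data)
  bp
}

# Band powers for all bands of a scheme from a channels x nfreq power
# matrix; returns channels x nbands.
band_powers_matrix <- function(pw, freq, scheme) {
  out <- matrix(NA_real_, nrow(pw), nrow(scheme),
                dimnames = list(NULL, scheme$band))
  for (i in seq_len(nrow(scheme))) {
    sel <- if (i == 1L) freq >= scheme$low[i] & freq <= scheme$high[i]
           else freq > scheme$low[i] & freq <= scheme$high[i]
    if (!any(sel)) abort("spectral grid misses a band entirely", "invalid_band_error")
    out[, i] <- rowMeans(pw[, sel, drop = FALSE])
  }
  out
}

#' Lobar band powers for one recording
#'
#' Per (lobe, band): each lobe electrode's band power, averaged across the
#' lobe's electrodes.
#'
#' @param rec An [eeg_recording()].
#' @param params A [spectral_params()].
#' @param lobes A [lobe_map()].
#' @param scheme A [band_scheme()].
#' @param weights Precomputed autocorrelation weight matrix (internal
#'   reuse across a cohort); leave as default.
#' @return Named numeric vector of length lobes x bands, names like
#'   `"F-theta"`, `"T-alpha"`.
#' @export
lobar_band_power <- function(rec, params, lobes = lobe_map(), scheme = band_scheme(),
                             weights = band_weight_matrix(params, scheme)) {
  wanted <- c(lobes$F, lobes$T)
  missing <- setdiff(wanted, rec$labels)
  if (length(missing))
    abort(sprintf("recording is missing lobe electrode(s): %s",
                  paste(missing, collapse = ", ")), "missing_channel_error")
  bp <- fast_band_power_matrix(rec$data[wanted, , drop = FALSE], params, scheme,
                               weights = weights)
  out <- c(colMeans(bp[lobes$F, , drop = FALSE]),
           colMeans(bp[lobes$T, , drop = FALSE]))
  names(out) <- c(paste0("F-", scheme$band), paste0("T-", scheme$band))
  out
}

#' Band-power table for a cohort
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param subject_ids Character vector of subject identifiers.
#' @inheritParams lobar_band_power
#' @return A data frame of class `band_power_table`: `subject_id` plus the
#'   10 lobar band-power columns.
#' @export
band_power_table <- function(recordings, subject_ids, params,
                             lobes = lobe_map(), scheme = band_scheme()) {
  if (length(recordings) != length(subject_ids))
    abort("one subject id per recording required", "validation_error")
  weights <- band_weight_matrix(params, scheme)
  rows <- t(vapply(recordings, lobar_band_power,
                   numeric(2L * nrow(scheme)),
                   params = params, lobes = lobes, scheme = scheme,
                   weights = weights))
  out <- data.frame(subject_id = as.character(subject_ids), rows,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Names of the 65 lobar power ratios
#'
#' 25 inter-lobar F/T ratios plus 20 intra-frontal and 20 intra-temporal
#' ratios between distinct bands, named like `"F-theta/T-alpha"`.
#'
#' @param scheme A [band_scheme()].
#' @return Character vector of ratio names (65 for the 5-band scheme).
#' @export
ratio_names <- function(scheme = band_scheme()) {
  b <- scheme$band
  inter <- as.vector(t(outer(b, b, function(i, j) paste0("F-", i, "/T-", j))))
  intra <- function(l) {
    g <- expand.grid(i = b, j = b, stringsAsFactors = FALSE)
    g <- g[g$i != g$j, ]
    # row-major in numerator order
    g <- g[order(match(g$i, b), match(g$j, b)), ]
    paste0(l, "-", g$i, "/", l, "-", g$j)
  }
  c(inter, intra("F"), intra("T"))
}

#' All inter- and intra-lobar power ratios
#'
#' Every F-band/T-band combination plus every within-lobe ratio between
#' distinct bands: 65 ratios for the 5-band scheme. A zero denominator
#' yields NA for that cell with a warning; downstream tests drop NA cells.
#'
#' @param bpt A [band_power_table()].
#' @param scheme A [band_scheme()].
#' @return A data frame of class `ratio_table`: `subject_id` plus 65 ratio
#'   columns.
#' @export
power_ratios <- function(bpt, scheme = band_scheme()) {
  if (!inherits(bpt, "band_power_table")) abort("`bpt` must be a band_power_table", "validation_error")
  rn <- ratio_names(scheme)
  parts <- strsplit(rn, "/", fixed = TRUE)
  out <- data.frame(subject_id = bpt$subject_id, stringsAsFactors = FALSE)
  n_zero <- 0L
  for (k in seq_along(rn)) {
    num <- bpt[[parts[[k]][1]]]; den <- bpt[[parts[[k]][2]]]
    v <- num / den
    bad <- !is.finite(v)
    if (any(bad)) { v[bad] <- NA_real_; n_zero <- n_zero + sum(bad) }
    out[[rn[k]]] <- v
  }
  if (n_zero > 0L)
    warning(sprintf("%d ratio cells had zero/invalid denominators and were set to NA", n_zero),
            call. = FALSE)
  class(out) <- c("ratio_table", "data.frame")
  out
}
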