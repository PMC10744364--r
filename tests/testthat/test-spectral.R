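test_that("the three parameterizations reproduce the printed sample counts", {
  p1 <- spectral_params(2, 10, fs = 500)
  expect_equal(c(p1$window_n, p1$nfft, p1$overlap_n), c(1000, 5000, 500))
  p2 <- spectral_params(2, 5, fs = 500)
  expect_equal(c(p2$window_n, p2$nfft, p2$overlap_n), c(1000, 2500, 500))
  p3 <- spectral_params(1, 10, fs = 500)
  expect_equal(c(p3$window_n, p3$nfft, p3$overlap_n), c(500, 5000, 250))
  # grid spacing is 1/steps_per_hz
  expect_equal(diff(welch_psd(rnorm(2000), p1)$freq)[1], 0.1)
  expect_error_class(spectral_params(2, 1, fs = 500), "validation_error")
})

test_that("a pure sinusoid concentrates its power at its frequency", {
  t <- seq_len(500 * 20) / 500
  x <- sin(2 * pi * 10 * t)
  for (p in list(spectral_params(2, 10, 500), spectral_params(2, 5, 500),
                 spectral_params(1, 10, 500))) {
    ps <- welch_psd(x, p)
    # >= 99% of power inside the Hamming mainlobe (half-width 2/T Hz)
    halfwidth <- 2 / p$window_s
    frac <- sum(ps$power[abs(ps$freq - 10) <= halfwidth]) / sum(ps$power)
    expect_gte(frac, 0.99)
    # alpha band dominates every other band by >= 100x
    bp <- vapply(seq_len(5), function(i) {
      sc <- band_scheme()
      band_power(ps, sc$low[i], sc$high[i], include_low = i == 1)
    }, 0)
    expect_true(all(bp[3] >= 100 * bp[-3]))
  }
})

test_that("white-noise spectra are flat and Parseval-consistent", {
  set.seed(81)
  x <- rnorm(500 * 120)
  p <- spectral_params(2, 10, 500)
  ps <- welch_psd(x, p)
  sel <- ps$freq > 0
  # flatness in 5 Hz bins
  bins <- cut(ps$freq[sel], seq(0, 250, by = 5))
  bm <- tapply(ps$power[sel], bins, mean)
  expect_lte(max(bm) / min(bm), 1.2)
  # sum of spectrum x grid spacing ~ variance
  tot <- sum(ps$power[sel]) * (ps$freq[2] - ps$freq[1])
  expect_equal(tot, stats::var(x), tolerance = 0.05)
})

test_that("degenerate spectra and invalid bands are handled", {
  p <- spectral_params(2, 10, 500)
  ps <- welch_psd(rep(0, 3000), p)
  expect_equal(max(ps$power), 0)
  expect_error_class(welch_psd(rnorm(500), p), "invalid_input_error")
  ps2 <- welch_psd(rnorm(3000), p)
  # on a spectrum restricted to the 0-45 Hz analysis range, a 50-60 Hz
  # band has no grid support
  ps45 <- ps2
  keep <- ps45$freq <= 45
  ps45$freq <- ps45$freq[keep]; ps45$power <- ps45$power[keep]
  expect_error_class(band_power(ps45, 50, 60), "invalid_band_error")
  expect_error_class(band_power(ps2, 300, 400), "invalid_band_error")
  # constant spectrum: band power equals the constant in every band
  ps2$power[] <- 3.5
  sc <- band_scheme()
  for (i in seq_len(nrow(sc)))
    expect_equal(band_power(ps2, sc$low[i], sc$high[i], include_low = i == 1), 3.5)
})

test_that("the autocorrelation band-power engine equals the direct Welch path", {
  set.seed(82)
  x <- matrix(rnorm(3 * 8000), 3, 8000)
  for (p in list(spectral_params(2, 10, 500), spectral_params(2, 5, 500),
                 spectral_params(1, 10, 500))) {
    pw <- ftdqeeg:::welch_psd_matrix(x, p)
    naive <- ftdqeeg:::band_powers_matrix(pw, attr(pw, "freq"), band_scheme())
    fast <- ftdqeeg:::fast_band_power_matrix(x, p, band_scheme())
    expect_equal(fast, naive, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("lobar band powers respect symmetry and report missing channels", {
  rec <- sinusoid_recording(10)
  p <- spectral_params(2, 10, 500)
  bp <- lobar_band_power(rec, p)
  expect_length(bp, 10)
  # identical signals on all channels: F equals T per band
  expect_equal(bp[paste0("F-", band_scheme()$band)],
               bp[paste0("T-", band_scheme()$band)], ignore_attr = TRUE)
  miss <- eeg_recording(rec$data[-14, ], rec$fs, rec$labels[-14])   # drop T3
  cond <- expect_error(lobar_band_power(miss, p), class = "missing_channel_error")
  expect_match(conditionMessage(cond), "T3")
})

test_that("frontal amplitude doubling quadruples frontal power", {
  base <- default_base_amplitude()
  base["F", "theta"] <- 2 * base["T", "theta"]
  spec <- cohort_spec(n_ftd = 1, n_ctl = 1, duration = 20, base_amplitude = base,
                      background_scale = 0.02, subject_sd = 0, seed = 83)
  set.seed(83)
  rec <- generate_subject_signal(spec, "CTL")
  bp <- lobar_band_power(rec, spectral_params(2, 10, 500))
  expect_equal(bp[["F-theta"]] / bp[["T-theta"]], 4, tolerance = 0.15)
})

test_that("scaling a recording scales powers by c^2 and leaves ratios unchanged", {
  sc <- small_cohort()
  rec <- sc$cohort$recordings[[1]]
  p <- spectral_params(2, 10, 500)
  bp1 <- lobar_band_power(rec, p)
  rec3 <- eeg_recording(3 * rec$data, rec$fs, rec$labels)
  bp3 <- lobar_band_power(rec3, p)
  expect_equal(bp3, 9 * bp1, tolerance = 1e-10)
  mk <- function(bp) {
    tab <- data.frame(subject_id = "s1", t(bp), check.names = FALSE)
    class(tab) <- c("band_power_table", "data.frame")
    power_ratios(tab)
  }
  r1 <- mk(bp1); r3 <- mk(bp3)
  expect_equal(as.numeric(r3[-1]), as.numeric(r1[-1]), tolerance = 1e-10)
})

test_that("the ratio table has the 65 named columns with exact arithmetic", {
  rn <- ratio_names()
  expect_length(rn, 65)
  expect_length(grep("^F-.+/T-", rn), 25)
  expect_length(grep("^F-.+/F-", rn), 20)
  expect_length(grep("^T-.+/T-", rn), 20)
  expect_true("F-theta/T-alpha" %in% rn)

  vals <- stats::setNames(rep(1, 10), c(paste0("F-", band_scheme()$band),
                                        paste0("T-", band_scheme()$band)))
  tab <- data.frame(subject_id = "s1", t(vals), check.names = FALSE)
  class(tab) <- c("band_power_table", "data.frame")
  rt <- power_ratios(tab)
  expect_equal(unique(as.numeric(rt[-1])), 1)

  vals["F-theta"] <- 2; vals["T-alpha"] <- 0.5
  tab2 <- data.frame(subject_id = "s1", t(vals), check.names = FALSE)
  class(tab2) <- c("band_power_table", "data.frame")
  rt2 <- power_ratios(tab2)
  expect_equal(rt2[["F-theta/T-alpha"]], 4)
  expect_equal(rt2[["F-theta/F-alpha"]] * rt2[["F-alpha/F-theta"]], 1)

  vals["T-gamma"] <- 0
  tab3 <- data.frame(subject_id = "s1", t(vals), check.names = FALSE)
  class(tab3) <- c("band_power_table", "data.frame")
  expect_warning(rt3 <- power_ratios(tab3), "denominator")
  expect_true(is.na(rt3[["T-beta/T-gamma"]]))
})
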