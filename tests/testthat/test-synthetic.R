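test_that("band-limited noise is unit-RMS and spectrally confined", {
  set.seed(101)
  x <- band_limited_noise(8, 13, fs = 500, n = 300000)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 0.02)
  # periodogram fraction inside the band
  pg <- Mod(stats::fft(x))^2
  f <- (seq_along(pg) - 1) * 500 / length(pg)
  inside <- f >= 8 & f <= 13 | f >= 500 - 13 & f <= 500 - 8
  expect_gte(sum(pg[inside]) / sum(pg), 0.95)

  y <- band_limited_noise(4, 8, fs = 500, n = 300000)
  expect_gte(stats::var(y), 0.96)
  expect_lte(stats::var(y), 1.04)
})

test_that("bands outside the Nyquist range are rejected", {
  expect_error_class(band_limited_noise(30, 45, fs = 60, n = 1000), "invalid_band_error")
  expect_error_class(band_limited_noise(-1, 10, fs = 500, n = 1000), "invalid_band_error")
  expect_error_class(band_limited_noise(13, 8, fs = 500, n = 1000), "invalid_band_error")
})

test_that("zero amplitudes and zero background give an all-zero recording", {
  spec <- cohort_spec(n_ftd = 1, n_ctl = 1, duration = 4,
                      base_amplitude = 0 * default_base_amplitude(),
                      background_scale = 0, seed = 1)
  set.seed(1)
  rec <- generate_subject_signal(spec, "CTL")
  expect_equal(max(abs(rec$data)), 0)
})

test_that("cohorts reproduce the configured group structure deterministically", {
  spec <- cohort_spec(n_ftd = 23, n_ctl = 29, duration = 2, seed = 3)
  co <- generate_cohort(spec)
  expect_length(co$recordings, 52)
  expect_equal(sum(co$subjects$group == "FTD"), 23)
  expect_equal(sum(co$subjects$group == "CTL"), 29)
  co2 <- generate_cohort(spec)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$recordings[[7]]$data, co2$recordings[[7]]$data)
})

test_that("covariate draws track the configured generative means", {
  spec <- cohort_spec(n_ftd = 60, n_ctl = 60, duration = 2, seed = 5)
  co <- generate_cohort(spec)
  ftd <- co$subjects[co$subjects$group == "FTD", ]
  ctl <- co$subjects[co$subjects$group == "CTL", ]
  # MMSE: FTD drawn around 22.17 (sd 8.22, truncated to [0, 30]); CTL fixed 30
  expect_equal(unique(ctl$mmse), 30)
  se <- 8.22 / sqrt(nrow(ftd))
  expect_lt(abs(mean(ftd$mmse) - 22.17), 2 * se + 1.5)  # truncation shifts slightly
  expect_lt(abs(mean(ftd$age) - 63.6), 3 * 8.2 / sqrt(nrow(ftd)))
  expect_lt(abs(mean(ctl$age) - 67.9), 3 * 5.4 / sqrt(nrow(ctl)))
  expect_true(all(co$subjects$mmse >= 0 & co$subjects$mmse <= 30))
})

test_that("downstream band power scales as amplitude squared", {
  # spectral fidelity: regression of log power on log amplitude has slope 2
  amps <- c(4, 8, 16, 32)
  params <- spectral_params(2, 10, fs = 500)
  pw <- vapply(seq_along(amps), function(i) {
    base <- default_base_amplitude()
    base["F", "alpha"] <- amps[i]
    spec <- cohort_spec(n_ftd = 1, n_ctl = 1, duration = 20, base_amplitude = base,
                        background_scale = 0.05, subject_sd = 0, seed = 21)
    set.seed(40 + i)
    rec <- generate_subject_signal(spec, "CTL")
    lobar_band_power(rec, params)[["F-alpha"]]
  }, 0)
  slope <- stats::coef(stats::lm(log(pw) ~ log(amps)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)
})

test_that("default FTD effects raise F-theta/F-alpha at the cohort level", {
  spec <- cohort_spec(n_ftd = 25, n_ctl = 25, duration = 20, seed = 31)
  co <- generate_cohort(spec)
  params <- spectral_params(2, 10, fs = 500)
  bpt <- band_power_table(lapply(co$recordings, average_reference),
                          co$subjects$subject_id, params)
  rt <- power_ratios(bpt)
  grp <- co$subjects$group
  expect_gt(stats::median(rt[["F-theta/F-alpha"]][grp == "FTD"]),
            stats::median(rt[["F-theta/F-alpha"]][grp == "CTL"]))
  expect_lt(stats::median(rt[["T-beta/T-gamma"]][grp == "FTD"]),
            stats::median(rt[["T-beta/T-gamma"]][grp == "CTL"]))
})

test_that("cohort spec validates amplitudes, rates and durations", {
  expect_error_class(cohort_spec(n_ftd = 0), "validation_error")
  expect_error_class(cohort_spec(fs = 80), "validation_error")   # below 2 x 45 Hz
  expect_error_class(cohort_spec(duration = 1), "validation_error")
  bad <- default_base_amplitude(); bad["F", "alpha"] <- -1
  expect_error_class(cohort_spec(base_amplitude = bad), "validation_error")
})
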