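# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic cohort with the default FTD effects: 6/6 subjects,
# 20 s recordings. Cached because several files use it.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- cohort_spec(n_ftd = 6, n_ctl = 6, duration = 20, seed = 11)
    .fixture_env$small <- list(spec = spec, cohort = generate_cohort(spec))
  }
  .fixture_env$small
}

# Cohort-free recording with known content: channels are pure
# sinusoids plus a small offset of deterministic noise.
sinusoid_recording <- function(freq = 10, fs = 500, seconds = 20,
                               labels = channels_1020()) {
  t <- seq_len(fs * seconds) / fs
  data <- matrix(rep(sin(2 * pi * freq * t), length(labels)),
                 nrow = length(labels), byrow = TRUE)
  eeg_recording(data, fs, labels)
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# Brute-force oracle: exact two-sided Mann-Whitney p by enumerating all
# group labelings.
mwu_enum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(i) {
    xs <- pooled[i]; ys <- pooled[-i]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
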