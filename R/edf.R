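# Minimal EDF (European Data Format) codec: 16-bit continuous recordings,
# one-second data records, identical sampling rate on every signal. This
# covers what the synthetic cohorts and the study layout need.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-aligned, space-padded
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records; the per-channel physical range
#' is taken from the data, so amplitudes are preserved to the 16-bit
#' quantization step (range / 2^15). Samples beyond a whole number of
#' one-second records are dropped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording", "validation_error")
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    abort("EDF writer requires an integer sampling rate", "format_error")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) abort("recording shorter than one EDF data record (1 s)", "format_error")
  if (n_rec * fs < ncol(rec$data))
    warning(sprintf("dropping %d trailing samples (not a whole 1 s record)",
                    ncol(rec$data) - n_rec * fs), call. = FALSE)
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("ftdqeeg synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax), edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round(sweep(sweep(x[, idx, drop = FALSE], 1, pmin), 1, scale, `*`)) + dmin
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @param normalize Normalize channel labels to canonical 10-20 names?
#' @return An [eeg_recording()] with reference state `"as-recorded"`.
#' @export
read_edf <- function(path, normalize = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "format_error")
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256)
    abort(sprintf("%s: truncated EDF header", path), "format_error")
  fld <- function(s, from, len) substr(s, from, from + len - 1)
  n_rec <- suppressWarnings(as.integer(fld(hdr, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(hdr, 245, 8)))
  ns <- suppressWarnings(as.integer(fld(hdr, 253, 4)))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(ns) || ns < 1L || rec_dur <= 0)
    abort(sprintf("%s: unparseable EDF header (records/duration/signals)", path),
          "format_error")
  shdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(shdr, type = "bytes") < 256 * ns)
    abort(sprintf("%s: truncated EDF signal header", path), "format_error")
  labels <- vapply(seq_len(ns), function(i)
    trimws(substr(shdr, (i - 1) * 16 + 1, i * 16)), "")
  num_at <- function(byte_offset, width = 8) {
    v <- suppressWarnings(as.numeric(vapply(seq_len(ns), function(i)
      substr(shdr, byte_offset + (i - 1) * width + 1, byte_offset + i * width), "")))
    if (anyNA(v)) abort(sprintf("%s: unparseable EDF signal-header numeric field", path),
                        "format_error")
    v
  }
  pmin <- num_at(ns * (16 + 80 + 8))
  pmax <- num_at(ns * (16 + 80 + 8 + 8))
  dmin <- num_at(ns * (16 + 80 + 8 + 8 + 8))
  dmax <- num_at(ns * (16 + 80 + 8 + 8 + 8 + 8))
  nspr <- as.integer(num_at(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  if (length(unique(nspr / rec_dur)) != 1L)
    abort(sprintf("%s: signals have differing sampling rates", path), "format_error")
  fs <- nspr[1] / rec_dur
  total <- sum(nspr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2L, endian = "little")
  if (length(raw) < total)
    abort(sprintf("%s: truncated EDF data section", path), "format_error")
  data <- matrix(0, ns, nspr[1] * n_rec)
  per_rec <- sum(nspr)
  offs <- c(0L, cumsum(nspr))
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * per_rec
    for (i in seq_len(ns)) {
      seg <- raw[(base + offs[i] + 1L):(base + offs[i + 1L])]
      data[i, ((r - 1L) * nspr[i] + 1L):(r * nspr[i])] <-
        (seg - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  eeg_recording(data, fs, labels, reference = "as-recorded", normalize = normalize)
}
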