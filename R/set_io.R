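# EEGLAB SET reading/writing for continuous (non-epoched) recordings.
# A SET file is a MAT-file with an EEG struct; data are either embedded
# or in a float32 .fdt sidecar named by EEG.data.

#' Read an EEGLAB SET recording
#'
#' Supports continuous data only (`trials` absent or 1); epoched files
#' are rejected. Data may be embedded in the MAT structure or stored in
#' a float32 `.fdt` sidecar next to the SET file. Channel labels come
#' from `chanlocs.labels` and are normalized to canonical 10-20 names.
#'
#' @param path SET file path.
#' @param normalize Normalize channel labels?
#' @return An [eeg_recording()] with reference state `"as-recorded"`.
#' @export
read_set <- function(path, normalize = TRUE) {
  vars <- read_mat5(path)
  eeg <- vars$EEG %||% (if (length(vars) == 1L) vars[[1]] else NULL)
  if (is.null(eeg) || !is.list(eeg) || is.null(eeg$srate))
    abort(sprintf("%s: no EEG struct with an srate field found", path), "format_error")
  trials <- eeg$trials %||% 1
  if (length(trials) && trials > 1)
    abort(sprintf("%s: epoched SET files (trials = %d) are not supported", path, trials),
          "format_error")
  fs <- as.numeric(eeg$srate)
  nbchan <- as.integer(eeg$nbchan %||% NA)
  dat <- eeg$data
  if (is.character(dat)) {  # .fdt sidecar
    fdt <- file.path(dirname(path), basename(dat))
    if (!file.exists(fdt))
      abort(sprintf("%s: data sidecar '%s' not found", path, dat), "format_error")
    if (is.na(nbchan)) abort(sprintf("%s: nbchan needed to read .fdt sidecar", path),
                             "format_error")
    v <- readBin(fdt, numeric(), n = file.size(fdt) / 4L, size = 4L, endian = "little")
    if (length(v) %% nbchan != 0L)
      abort(sprintf("%s: sidecar size is not a multiple of nbchan", path), "format_error")
    dat <- matrix(v, nrow = nbchan)
  }
  if (!is.matrix(dat))
    abort(sprintf("%s: EEG.data missing or not a matrix", path), "format_error")
  chanlocs <- eeg$chanlocs
  if (is.null(chanlocs))
    abort(sprintf("%s: chanlocs with channel labels required", path), "labeling_error")
  if (!is.null(names(chanlocs))) chanlocs <- list(chanlocs)  # single channel
  labels <- vapply(chanlocs, function(cl) as.character(cl$labels %||% NA_character_), "")
  if (anyNA(labels) || length(labels) != nrow(dat))
    abort(sprintf("%s: chanlocs labels missing or inconsistent with data rows", path),
          "labeling_error")
  eeg_recording(dat, fs, labels, reference = "as-recorded", normalize = normalize)
}

#' Write a recording as an EEGLAB SET file
#'
#' Continuous single-trial SET (MAT level 5) with embedded double data
#' and minimal `chanlocs`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_set <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording", "validation_error")
  eeg <- list(
    setname = "ftdqeeg export",
    nbchan = nrow(rec$data),
    pnts = ncol(rec$data),
    trials = 1,
    srate = rec$fs,
    xmin = 0,
    data = rec$data,
    chanlocs = lapply(rec$labels, function(l) list(labels = l))
  )
  write_mat5(list(EEG = eeg), path)
  invisible(path)
}
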