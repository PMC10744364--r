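#' EEG recording container
#'
#' A channels-by-samples amplitude matrix (microvolts) with sampling rate,
#' channel labels and the referencing state of the data.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of channel labels, one per row of `data`.
#'   Normalized with [normalize_labels()] unless `normalize = FALSE`.
#' @param reference Referencing state: one of `"as-recorded"`,
#'   `"linked-mastoid"`, `"average"`, `"REST"`.
#' @param normalize Normalize channel labels on construction?
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels,
                          reference = c("as-recorded", "linked-mastoid", "average", "REST"),
                          normalize = TRUE) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot_scalar_number(fs, "fs", lower = .Machine$double.eps)
  labels <- if (normalize) normalize_labels(labels) else as.character(labels)
  if (nrow(data) != length(labels))
    abort(sprintf("data has %d rows but %d labels given", nrow(data), length(labels)),
          "validation_error")
  if (anyDuplicated(labels))
    abort("channel labels must be unique", "labeling_error")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
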