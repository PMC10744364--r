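#' Canonical frequency bands
#'
#' The five-band scheme used throughout the package: delta \[0.5, 4\],
#' theta (4, 8\], alpha (8, 13\], beta (13, 30\] and gamma (30, 45\] Hz.
#' All intervals except delta are half-open on the left so that a grid
#' frequency is never counted in two bands; delta is closed at 0.5 Hz
#' because recordings are assumed high-pass filtered there.
#'
#' @param edges Named numeric vector of band upper edges in Hz. The lower
#'   edge of the first band is given by `lowest`.
#' @param lowest Lower edge of the first band (Hz).
#' @return An object of class `band_scheme`: a data frame with columns
#'   `band`, `low`, `high`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(edges = c(delta = 4, theta = 8, alpha = 13, beta = 30, gamma = 45),
                        lowest = 0.5) {
  if (is.null(names(edges)) || anyNA(names(edges)) || any(names(edges) == ""))
    abort("band edges must be named", "validation_error")
  if (any(diff(c(lowest, edges)) <= 0))
    abort("band edges must be strictly increasing and above `lowest`", "validation_error")
  out <- data.frame(
    band = names(edges),
    low  = unname(c(lowest, edges[-length(edges)])),
    high = unname(edges),
    stringsAsFactors = FALSE
  )
  class(out) <- c("band_scheme", "data.frame")
  out
}

#' Assign grid frequencies to bands
#'
#' Membership convention: `(low, high]` for every band except the first,
#' which is `[low, high]`.
#'
#' @param freqs Numeric vector of frequencies (Hz).
#' @param scheme A [band_scheme()].
#' @return Character vector of band names (NA outside all bands).
#' @export
band_of <- function(freqs, scheme = band_scheme()) {
  out <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(scheme))) {
    lo <- scheme$low[i]; hi <- scheme$high[i]
    sel <- if (i == 1L) freqs >= lo & freqs <= hi else freqs > lo & freqs <= hi
    out[sel] <- scheme$band[i]
  }
  out
}

#' Frontal and temporal electrode sets
#'
#' Default lobar electrode map: frontal Fp1, Fp2, F3, F4, F7, F8, Fz and
#' temporal T3, T4, T5, T6 (legacy 10-20 names; modern T7/T8/P7/P8 are
#' normalized to these on read).
#'
#' @param frontal,temporal Character vectors of channel labels.
#' @return An object of class `lobe_map`: a named list with elements
#'   `F` (frontal) and `T` (temporal).
#' @export
lobe_map <- function(frontal = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
                     temporal = c("T3", "T4", "T5", "T6")) {
  frontal <- as.character(frontal); temporal <- as.character(temporal)
  if (length(intersect(frontal, temporal)))
    abort("frontal and temporal electrode sets must be disjoint", "validation_error")
  structure(list(F = frontal, T = temporal), class = "lobe_map")
}
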