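# 10-20 electrode nomenclature and a spherical layout for the 19 scalp
# channels. Legacy temporal names (T3/T4/T5/T6) are canonical internally;
# modern 10-10 equivalents (T7/T8/P7/P8) are mapped onto them.

LEGACY_EQUIV <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6", M1 = "A1", M2 = "A2")

CANONICAL_1020 <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
                    "C3", "C4", "Cz", "P3", "P4", "Pz",
                    "T3", "T4", "T5", "T6", "O1", "O2",
                    "Fpz", "Oz", "A1", "A2")

#' Default 19-channel 10-20 montage
#' @return Character vector of the 19 scalp channel labels in standard order.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
    "P3", "P4", "Pz", "T3", "T4", "T5", "T6", "O1", "O2")
}

#' Normalize channel labels to canonical 10-20 names
#'
#' Case-insensitive matching against the canonical 10-20 set, with modern
#' 10-10 temporal-chain names mapped to the legacy names used internally
#' (T7 to T3, T8 to T4, P7 to T5, P8 to T6; M1/M2 to A1/A2). Labels that
#' match nothing are passed through unchanged with a warning.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of normalized labels, same length.
#' @examples
#' normalize_labels(c("FP1", "t7", "Cz"))
#' @export
normalize_labels <- function(labels) {
  labels <- as.character(labels)
  lut <- c(CANONICAL_1020, names(LEGACY_EQUIV))
  names(lut) <- toupper(c(CANONICAL_1020, names(LEGACY_EQUIV)))
  out <- character(length(labels))
  for (i in seq_along(labels)) {
    key <- toupper(trimws(labels[i]))
    if (key %in% names(lut)) {
      hit <- lut[[key]]
      out[i] <- if (hit %in% names(LEGACY_EQUIV)) LEGACY_EQUIV[[hit]] else hit
    } else {
      warning(sprintf("unknown channel label '%s' passed through", labels[i]),
              call. = FALSE)
      out[i] <- labels[i]
    }
  }
  if (anyDuplicated(out))
    abort(sprintf("duplicate channel labels after normalization: %s",
                  paste(unique(out[duplicated(out)]), collapse = ", ")),
          "labeling_error")
  out
}

# Unit-sphere electrode positions (x right, y anterior, z up). Midline and
# ring electrodes follow the 10-20 arc rules (outer ring at 72 deg
# inclination in 18 deg azimuth steps); F3/F4 and P3/P4 are great-circle
# midpoints of (Fz, F7), (Fz, F8), (Pz, T5), (Pz, T6).
electrode_positions <- function(labels) {
  sph <- function(inc, az) {  # degrees; az from anterior midline, + to the right
    i <- inc * pi / 180; a <- az * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  mid <- function(p, q) { m <- p + q; m / sqrt(sum(m^2)) }
  pos <- list(
    Cz = sph(0, 0),
    Fz = sph(36, 0),   Pz = sph(36, 180),
    Fpz = sph(72, 0),  Oz = sph(72, 180),
    Fp1 = sph(72, -18), Fp2 = sph(72, 18),
    F7 = sph(72, -54),  F8 = sph(72, 54),
    T3 = sph(72, -90),  T4 = sph(72, 90),
    T5 = sph(72, -126), T6 = sph(72, 126),
    O1 = sph(72, -162), O2 = sph(72, 162),
    C3 = sph(36, -90),  C4 = sph(36, 90),
    A1 = sph(108, -95), A2 = sph(108, 95)
  )
  pos$F3 <- mid(pos$Fz, pos$F7); pos$F4 <- mid(pos$Fz, pos$F8)
  pos$P3 <- mid(pos$Pz, pos$T5); pos$P4 <- mid(pos$Pz, pos$T6)
  labels <- as.character(labels)
  unknown <- setdiff(labels, names(pos))
  if (length(unknown))
    abort(sprintf("no spherical position for electrode(s): %s",
                  paste(unknown, collapse = ", ")), "labeling_error")
  out <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}
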