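# Re-referencing: average reference, linked mastoids, and the REST
# (reference electrode standardization technique) infinity reference via
# an analytic three-concentric-sphere volume-conductor model.

#' Average reference
#'
#' Subtracts the instantaneous mean across channels, so each sample's
#' channel mean becomes zero.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return The re-referenced [eeg_recording()], reference `"average"`.
#' @export
average_reference <- function(rec) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording", "validation_error")
  if (nrow(rec$data) < 2L)
    abort("average reference needs at least 2 channels", "invalid_input_error")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

#' Linked-mastoid reference
#'
#' Subtracts the mean of the two mastoid channels (A1, A2). Provided as a
#' utility; the analysis path uses average and REST referencing.
#'
#' @param rec An [eeg_recording()] containing channels A1 and A2.
#' @param mastoids Labels of the two mastoid channels.
#' @param drop Drop the mastoid channels from the output?
#' @return The re-referenced [eeg_recording()].
#' @export
linked_mastoid_reference <- function(rec, mastoids = c("A1", "A2"), drop = TRUE) {
  if (!all(mastoids %in% rec$labels))
    abort(sprintf("mastoid channel(s) missing: %s",
                  paste(setdiff(mastoids, rec$labels), collapse = ", ")),
          "labeling_error")
  ref <- colMeans(rec$data[mastoids, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref)
  if (drop) {
    keep <- !(rec$labels %in% mastoids)
    rec$data <- rec$data[keep, , drop = FALSE]
    rec$labels <- rec$labels[keep]
  }
  rec$reference <- "linked-mastoid"
  rec
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Radial transfer coefficients for a three-shell concentric sphere.
# For each harmonic degree n, solves the boundary-value problem for a
# source term c_n r^-(n+1) in the innermost medium and returns the scalp
# surface factor U_n such that the scalp potential harmonic is U_n * c_n.
# Shells: brain (sigma1, r < r1), skull (sigma2, r1-r2), scalp (sigma3,
# r2-r3) with an insulating boundary at r3.
sphere_transfer_coeffs <- function(n_max, radii, cond) {
  r1 <- radii[1]; r2 <- radii[2]; r3 <- radii[3]
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  U <- numeric(n_max)
  for (n in seq_len(n_max)) {
    # unknowns: A1, A2, B2, A3, B3
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # continuity of V at r1:  A1 r1^n - A2 r1^n - B2 r1^-(n+1) = -c r1^-(n+1)
    M[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    rhs[1] <- -r1^(-(n + 1))
    # continuity of sigma dV/dr at r1
    M[2, ] <- c(s1 * n * r1^(n - 1),
                -s2 * n * r1^(n - 1), s2 * (n + 1) * r1^(-(n + 2)), 0, 0)
    rhs[2] <- s1 * (n + 1) * r1^(-(n + 2))
    # continuity of V at r2
    M[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    # continuity of sigma dV/dr at r2
    M[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-(n + 2)),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-(n + 2)))
    # insulating scalp surface at r3
    M[5, ] <- c(0, 0, 0, n * r3^(n - 1), -(n + 1) * r3^(-(n + 2)))
    sol <- solve(M, rhs)
    U[n] <- sol[4] * r3^n + sol[5] * r3^(-(n + 1))
  }
  U
}

# Sum_n w_n P_n(x) for a matrix x of cos(angle) values, by upward
# Legendre recursion.
legendre_series <- function(w, x) {
  out <- array(0, dim = dim(x))
  p_prev <- array(1, dim = dim(x))  # P_0
  p_cur <- x                        # P_1
  for (n in seq_along(w)) {
    out <- out + w[n] * p_cur
    p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur; p_cur <- p_next
  }
  out
}

#' Three-sphere head model with analytic lead field
#'
#' Concentric-sphere volume conductor (brain, skull, scalp) with a layer
#' of radial dipoles on an inner sphere, and the analytic forward
#' solution (Legendre series with per-degree transfer coefficients across
#' the shells) evaluated at the 10-20 electrode positions. Potentials are
#' referenced to infinity (zero-mean spherical harmonics), which is what
#' REST requires.
#'
#' @param labels Electrode labels (resolvable to 10-20 positions).
#' @param radii Outer radii of brain, skull, scalp shells (scalp = 1).
#' @param conductivities Relative conductivities of the three shells.
#' @param n_sources Number of radial dipoles on the source layer.
#' @param source_radius Radius of the dipole layer (inside the brain shell).
#' @param n_max Truncation degree of the Legendre series.
#' @return An object of class `head_model` with the electrodes x sources
#'   lead-field matrix in `$leadfield`.
#' @export
build_head_model <- function(labels,
                             radii = c(brain = 0.87, skull = 0.92, scalp = 1.0),
                             conductivities = c(1, 0.0125, 1),
                             n_sources = 300, source_radius = 0.86, n_max = 80) {
  labels <- normalize_labels(labels)
  if (anyDuplicated(labels)) abort("duplicate electrode labels", "labeling_error")
  if (any(diff(radii) <= 0)) abort("radii must increase brain < skull < scalp", "validation_error")
  if (any(conductivities <= 0)) abort("conductivities must be positive", "validation_error")
  if (source_radius >= radii[1])
    abort("source layer must lie inside the brain shell", "validation_error")
  elec <- electrode_positions(labels)
  src_dir <- fibonacci_sphere(n_sources)
  U <- sphere_transfer_coeffs(n_max, radii, conductivities)
  b <- source_radius
  n <- seq_len(n_max)
  # radial unit dipole at radius b: source harmonic coefficient
  # c_n = n b^(n-1) / (4 pi sigma1)
  w <- U * n * b^(n - 1) / (4 * pi * conductivities[1])
  cosang <- elec %*% t(src_dir)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  G <- legendre_series(w, cosang)
  dimnames(G) <- list(labels, NULL)
  structure(list(labels = labels, electrodes = elec, sources = src_dir * b,
                 source_radius = b, radii = radii,
                 conductivities = conductivities, n_max = n_max,
                 leadfield = G),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> 3-sphere (r = %s; sigma = %s), %d electrodes, %d radial sources at r = %g\n",
              paste(x$radii, collapse = "/"), paste(x$conductivities, collapse = "/"),
              nrow(x$leadfield), ncol(x$leadfield), x$source_radius))
  invisible(x)
}

# Moore-Penrose pseudoinverse by truncated SVD with a relative singular
# value threshold.
pinv <- function(A, rel_tol = 1e-6) {
  s <- svd(A)
  keep <- s$d > rel_tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' REST (infinity) reference
#'
#' Reference electrode standardization technique: the average-referenced
#' data are mapped to an approximate infinity reference through the head
#' model's lead field, `V_rest = G pinv(G_avg) V_avg`, where `G` is the
#' infinity-referenced lead field and `G_avg` its average-referenced
#' counterpart. The input is converted to average reference first if it
#' is not already.
#'
#' @param rec An [eeg_recording()].
#' @param model A [build_head_model()] whose electrodes match `rec`.
#' @param rel_tol Relative singular-value threshold of the pseudoinverse.
#' @return The re-referenced [eeg_recording()], reference `"REST"`.
#' @export
rest_reference <- function(rec, model = build_head_model(rec$labels), rel_tol = 1e-6) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording", "validation_error")
  if (!setequal(rec$labels, model$labels))
    abort("head model electrodes do not match recording channels", "labeling_error")
  G <- model$leadfield[rec$labels, , drop = FALSE]
  G_avg <- sweep(G, 2L, colMeans(G))
  sv <- svd(G_avg, nu = 0, nv = 0)$d
  if (sum(sv > rel_tol * sv[1]) < nrow(G) - 1L)
    abort("average-referenced lead field is rank-deficient beyond tolerance",
          "conditioning_error")
  if (rec$reference != "average") rec <- average_reference(rec)
  R <- G %*% pinv(G_avg, rel_tol)
  rec$data <- R %*% rec$data
  rownames(rec$data) <- rec$labels
  rec$reference <- "REST"
  rec
}

#' Forward-simulate infinity-referenced scalp potentials
#'
#' Maps source-layer activity through the head model's lead field,
#' `V_inf = G J`. Useful for validating the REST transform.
#'
#' @param model A [build_head_model()].
#' @param source_activity Sources x samples matrix of radial dipole
#'   moments.
#' @return Electrodes x samples matrix of infinity-referenced potentials.
#' @export
forward_potentials <- function(model, source_activity) {
  source_activity <- as.matrix(source_activity)
  if (nrow(source_activity) != ncol(model$leadfield))
    abort("source_activity must have one row per model source", "validation_error")
  model$leadfield %*% source_activity
}
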