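test_that("average reference removes the common mode and is idempotent", {
  rec <- eeg_recording(matrix(5, 4, 10), 100, c("Fp1", "Fp2", "F3", "F4"))
  out <- average_reference(rec)
  expect_equal(max(abs(out$data)), 0)
  expect_equal(out$reference, "average")

  set.seed(71)
  rec2 <- eeg_recording(matrix(rnorm(40), 4, 10), 100, c("Fp1", "Fp2", "F3", "F4"))
  once <- average_reference(rec2)
  expect_equal(max(abs(colMeans(once$data))), 0, tolerance = 1e-12)
  expect_equal(average_reference(once)$data, once$data)

  # two-channel closed form: [a, b] -> [(a-b)/2, (b-a)/2]
  rec3 <- eeg_recording(matrix(c(3, 1), 2, 5), 100, c("Fp1", "Fp2"))
  out3 <- average_reference(rec3)
  expect_equal(out3$data[1, ], rep(1, 5))
  expect_equal(out3$data[2, ], rep(-1, 5))

  expect_error_class(
    average_reference(eeg_recording(matrix(1, 1, 5), 100, "Cz")),
    "invalid_input_error")
})

test_that("three-sphere transfer coefficients match the homogeneous closed form", {
  # equal conductivities collapse the shells: U_n = (2n+1)/n at scalp radius 1
  U <- ftdqeeg:::sphere_transfer_coeffs(30, c(0.87, 0.92, 1.0), c(1, 1, 1))
  n <- 1:30
  expect_equal(U, (2 * n + 1) / n, tolerance = 1e-12)
})

test_that("head model lead field has the right shape and peaks under the dipole", {
  m <- build_head_model(channels_1020())
  expect_equal(dim(m$leadfield), c(19, 300))
  # radial dipole closest to Cz: the column peak is at Cz
  czi <- which.max(m$sources[, 3])
  expect_equal(rownames(m$leadfield)[which.max(abs(m$leadfield[, czi]))], "Cz")
  # same for a temporal source near T3
  t3 <- ftdqeeg:::electrode_positions("T3")
  near <- which.max(m$sources %*% t(t3))
  expect_equal(rownames(m$leadfield)[which.max(abs(m$leadfield[, near]))], "T3")
  expect_error_class(build_head_model(c("Cz", "Cz")), "labeling_error")
  expect_error_class(build_head_model("Cz", radii = c(1, 0.9, 0.8)), "validation_error")
})

test_that("REST recovers forward-simulated infinity potentials and is linear", {
  m <- build_head_model(channels_1020())
  G <- m$leadfield
  set.seed(72)
  # montage-visible source activity (row space of the average-referenced
  # lead field): recovery should be essentially exact
  Gavg <- sweep(G, 2, colMeans(G))
  J <- t(Gavg) %*% matrix(rnorm(19 * 50), 19, 50)
  Vinf <- forward_potentials(m, J)
  rec <- eeg_recording(sweep(Vinf, 2, colMeans(Vinf)), 500, channels_1020(),
                       reference = "average")
  out <- rest_reference(rec, m)
  expect_equal(out$reference, "REST")
  relerr <- sqrt(sum((out$data - Vinf)^2) / sum(Vinf^2))
  expect_lt(relerr, 0.05)

  # zero in, zero out; homogeneity
  zero <- eeg_recording(matrix(0, 19, 10), 500, channels_1020(), reference = "average")
  expect_equal(max(abs(rest_reference(zero, m)$data)), 0)
  rec3 <- eeg_recording(3 * rec$data, 500, channels_1020(), reference = "average")
  expect_equal(rest_reference(rec3, m)$data, 3 * out$data, tolerance = 1e-12)

  # additivity on random inputs
  a <- eeg_recording(matrix(rnorm(190), 19, 10), 500, channels_1020(), reference = "average")
  b <- eeg_recording(matrix(rnorm(190), 19, 10), 500, channels_1020(), reference = "average")
  ab <- eeg_recording(a$data + b$data, 500, channels_1020(), reference = "average")
  expect_equal(rest_reference(ab, m)$data,
               rest_reference(a, m)$data + rest_reference(b, m)$data,
               tolerance = 1e-10)

  bad <- eeg_recording(matrix(0, 4, 10), 500, c("Fp1", "Fp2", "F3", "F4"))
  expect_error_class(rest_reference(bad, m), "labeling_error")
})

test_that("linked-mastoid utility subtracts the mastoid mean", {
  rec <- eeg_recording(rbind(matrix(2, 2, 5), matrix(c(1, 3), 2, 5)), 100,
                       c("Fp1", "Fp2", "A1", "A2"))
  out <- linked_mastoid_reference(rec)
  expect_equal(out$labels, c("Fp1", "Fp2"))
  expect_equal(unique(as.vector(out$data)), 0)
  expect_error_class(linked_mastoid_reference(out), "labeling_error")
})
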