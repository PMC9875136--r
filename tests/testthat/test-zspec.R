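test_that("normalization divides by the reference image and prunes dead voxels", {
  offs <- c(39.1, -1, 0, 1)
  raw <- array(2, c(4, 4, 4, 1))
  ds <- normalize_zspectra(raw, offs, b1_list = 3)
  expect_true(all(ds$signal == 1))
  raw2 <- raw
  raw2[2, 2, 1, 1] <- 0                     # dead reference voxel
  expect_message(ds2 <- normalize_zspectra(raw2, offs, 3), "dropped")
  expect_false(ds2$mask[2, 2])
  expect_error(normalize_zspectra(raw, c(10, -1, 0, 1), 3), "reference")
  expect_error(suppressMessages(normalize_zspectra(raw * 0, offs, 3)),
               "normalization failed")
})

test_that("on-resonance signal in a simulated phantom is nearly saturated", {
  z <- bm_zspectrum(default_pools(), 3, c(39.1, 0), t_sat = 1.5)
  expect_lt(z[2], 0.1)
})

test_that("translation registration recovers known shifts", {
  set.seed(4)
  img <- matrix(rnorm(32 * 32), 32)
  for (i in 1:3) {
    img <- (img + rbind(img[-1, ], img[1, ]) + cbind(img[, -1], img[, 1])) / 3
  }
  same <- register_translation(img, img)
  expect_equal(same$shift, c(0, 0), tolerance = 1e-6)
  moved <- img[c(31:32, 1:30), c(2:32, 1)]   # roll by (+2, -1) with wraparound
  reg <- register_translation(moved, img)
  expect_equal(reg$shift, c(2, -1), tolerance = 0.05)
  expect_lt(max(abs(reg$registered - img)), 1e-6)
  # pure noise: bounded shift, flagged
  rn <- register_translation(matrix(rnorm(1024), 32), matrix(rnorm(1024), 32))
  expect_lte(max(abs(rn$shift)), 8.5)
  expect_true(rn$low_confidence)
})

test_that("series registration undoes accumulated drift", {
  set.seed(9)
  img <- matrix(rnorm(32 * 32), 32)
  for (i in 1:3) {
    img <- (img + rbind(img[-1, ], img[1, ]) + cbind(img[, -1], img[, 1])) / 3
  }
  stack <- array(0, c(32, 32, 4))
  shifts <- rbind(c(0, 0), c(1, 0), c(2, 1), c(3, 1))
  for (i in 1:4) {
    stack[, , i] <- img[(seq_len(32) - 1 - shifts[i, 1]) %% 32 + 1,
                        (seq_len(32) - 1 - shifts[i, 2]) %% 32 + 1]
  }
  reg <- register_series(stack)
  expect_equal(reg$shifts, shifts, tolerance = 0.05)
  for (i in 2:4) expect_lt(max(abs(reg$stack[, , i] - img)), 1e-5)
})

test_that("an exact two-Lorentzian spectrum is recovered to high precision", {
  off <- default_offsets()
  z <- 1 - (lor_curve(off, 0.9, 0.1, 2.0) + lor_curve(off, 0.05, 1.5, 3.0))
  f <- fit_two_lorentzian(z, off)
  truth <- c(aw = 0.9, dw = 0.1, ww = 2.0, ar = 0.05, dr = 1.5, wr = 3.0)
  got <- unlist(f[names(truth)])
  expect_true(f$converged)
  expect_lt(max(abs(got - truth) / truth), 1e-4)
})

test_that("a water-only spectrum yields a vanishing composite component", {
  off <- default_offsets()
  z <- 1 - lor_curve(off, 0.9, 0.1, 2.0)
  f <- fit_two_lorentzian(z, off)
  expect_lte(f$ar, 1e-3)
})

test_that("the fitted water centre tracks a bulk B0 shift", {
  off <- default_offsets()
  z <- 1 - (lor_curve(off, 0.9, 0.3, 2.0) + lor_curve(off, 0.05, 1.8, 3.0))
  expect_equal(fit_two_lorentzian(z, off)$dw, 0.3, tolerance = 0.01)
})

test_that("degenerate spectra are rejected or flagged", {
  off <- default_offsets()
  expect_error(fit_two_lorentzian(rep(NA_real_, length(off)), off), "all-NaN")
  expect_error(fit_two_lorentzian(rep(1, 5), c(39.1, -6, 0, 3, 6)),
               ">= 10 finite offsets")
})

test_that("water removal annihilates a pure-water spectrum", {
  off <- default_offsets()
  z <- 1 - lor_curve(off, 0.9, 0.1, 2.0)
  f <- fit_two_lorentzian(z, off)
  expect_lt(abs(water_removed_residual(z, off, f,
                                       spillover_correction = FALSE)), 1e-6)
})

test_that("a known labile peak survives water removal at its amplitude", {
  off <- default_offsets()
  z <- 1 - (lor_curve(off, 0.9, 0, 2.0) + lor_curve(off, 0.02, 3.5, 3.0))
  f <- fit_two_lorentzian(z, off)
  r <- water_removed_residual(z, off, f, spillover_correction = FALSE,
                              readout_window = 0)
  expect_lt(abs(r - 0.02), 1e-3)
  # the default windowed readout stays within the peak's own sampling blur
  rw <- water_removed_residual(z, off, f, spillover_correction = FALSE)
  expect_lt(abs(rw - 0.02), 0.1 * 0.02)
})

test_that("the residual is invariant to spectrum-wide B0 shifts", {
  acq <- acq_config()
  pools <- default_pools(kex_amide = 700)
  base <- chain_residuals(pools, acq)
  shifted <- vapply(acq$b1_list, function(b1) {
    z <- bm_zspectrum(pools, b1, acq$offsets, t_sat = 1.5, b0_shift = 0.25)
    fit <- fit_two_lorentzian(z, acq$offsets)
    water_removed_residual(z, acq$offsets, fit)
  }, numeric(1))
  expect_lt(max(abs(shifted - base) / base), 0.02)
  # the corrected readout offset follows the fitted centre
  z <- bm_zspectrum(pools, 3, acq$offsets, t_sat = 1.5, b0_shift = 0.25)
  expect_equal(fit_two_lorentzian(z, acq$offsets)$dw, 0.25, tolerance = 0.02)
})

test_that("residual extraction refuses targets outside the sampled range", {
  off <- default_offsets()
  z <- 1 - lor_curve(off, 0.9, 0, 2.0)
  f <- fit_two_lorentzian(z, off)
  expect_error(water_removed_residual(z, off, f, target_offset = 11),
               "outside the sampled range")
  f$converged <- FALSE
  expect_error(water_removed_residual(z, off, f), "did not converge")
})

test_that("fit quality does not degrade when noise decreases", {
  off <- default_offsets()
  clean <- 1 - (lor_curve(off, 0.9, 0, 3.0) + lor_curve(off, 0.05, 1.5, 3.0))
  set.seed(21)
  noise <- rnorm(length(off))
  rss <- vapply(c(0.01, 0.004, 0), function(s) {
    fit_two_lorentzian(clean + s * noise, off)$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-12))
})
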