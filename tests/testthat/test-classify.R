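roi_masks <- function() {
  lesion <- matrix(FALSE, 12, 12); lesion[3:6, 3:6] <- TRUE
  nawm <- matrix(FALSE, 12, 12); nawm[8:11, 8:11] <- TRUE
  list(lesion = lesion, nawm = nawm)
}

test_that("ROI elevation is the difference of the two mask means", {
  m <- roi_masks()
  map <- matrix(100, 12, 12)
  map[m$lesion] <- 255
  d <- roi_delta(map, m$lesion, m$nawm)
  expect_equal(d$delta, 155)
  expect_true(d$evaluable)
  # identical values in both masks
  expect_equal(roi_delta(matrix(7, 12, 12), m$lesion, m$nawm)$delta, 0)
})

test_that("sentinel voxels are excluded and sparse ROIs flagged", {
  m <- roi_masks()
  map <- matrix(100, 12, 12)
  map[m$lesion][1:3] <- NaN
  d <- roi_delta(map, m$lesion, m$nawm)
  expect_equal(d$n_excluded, 3)
  expect_equal(d$n_lesion, 13)
  map2 <- matrix(100, 12, 12)
  map2[m$lesion] <- NaN
  map2[3, 3] <- 100                      # only 1 valid lesion voxel
  d2 <- roi_delta(map2, m$lesion, m$nawm)
  expect_false(d2$evaluable)
  expect_true(is.na(d2$delta))
  expect_error(roi_delta(map, m$lesion, m$lesion), "disjoint")
})

test_that("positivity follows the sign rule with optional contrast floor", {
  expect_true(positivity(28.19))           # a positive elevation is positive
  expect_false(positivity(0))              # strict inequality at zero
  expect_false(positivity(-12))
  expect_false(positivity(50, nawm_sd = 30, z_min = 2))   # 50 < 60
  expect_true(positivity(70, nawm_sd = 30, z_min = 2))
  expect_equal(positivity(c(1, -1, 0)), c(TRUE, FALSE, FALSE))
})

test_that("shape classification separates rings from nodules", {
  n <- 21
  ax <- seq_len(n) - 11
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  mask <- rr <= 6
  ring_map <- matrix(10, n, n); ring_map[mask & rr > 4] <- 60
  expect_equal(shape_classify(ring_map, mask)$shape, "ring")
  flat_map <- matrix(10, n, n); flat_map[mask] <- 60
  expect_equal(shape_classify(flat_map, mask)$shape, "nodular")
  # tie-break: exactly at the ratio counts as ring; build the tie with the
  # classifier's own rim/core split
  n_iter <- max(1L, round(0.3 * sqrt(sum(mask) / pi)))
  core <- kexqsm:::erode_mask(mask, n_iter)
  tie_map <- matrix(0, n, n)
  tie_map[core] <- 10
  tie_map[mask & !core] <- 1.2 * 10
  sc2 <- shape_classify(tie_map, mask, ring_ratio = 1.2)
  expect_equal(sc2$shape, "ring")
  # mask too small to erode -> nodular, flagged
  tiny <- matrix(FALSE, n, n); tiny[10:11, 10] <- TRUE
  out <- shape_classify(flat_map, tiny)
  expect_equal(out$shape, "nodular")
  expect_true(out$flagged)
})

test_that("pattern assignment is total and matches the published scheme", {
  grid <- expand.grid(gd = c(TRUE, FALSE), kex = c(TRUE, FALSE),
                      qsm = c(TRUE, FALSE))
  pat <- assign_pattern(grid$gd, grid$kex, grid$qsm)
  expect_false(any(is.na(pat)))                       # total on the flag cube
  expect_true(all(pat[grid$gd] == "GdPlus"))          # one enhancing category
  expect_equal(as.character(assign_pattern(FALSE, TRUE, TRUE)), "I")
  expect_equal(as.character(assign_pattern(FALSE, TRUE, FALSE)), "IIa")
  expect_equal(as.character(assign_pattern(FALSE, FALSE, TRUE)), "IIb")
  expect_equal(as.character(assign_pattern(FALSE, FALSE, FALSE)), "III")
  expect_equal(as.character(assign_pattern(TRUE, FALSE, FALSE)), "GdPlus")
})

test_that("classification of the fixture reproduces the pattern percentages", {
  fx <- classify_lesions(lesion_fixture())
  # one pseudo-patient: aggregate over the whole table
  fx$patient_id <- 1L
  ps <- patient_summary(fx)
  expect_equal(ps$n_gd_neg, 169)
  expect_equal(ps$n_I, 114)
  expect_equal(round(ps$pct_I, 1), 67.5)
  expect_equal(round(ps$pct_II, 1), 27.8)
  expect_equal(round(ps$pct_III, 1), 4.7)
  expect_equal(ps$pct_I + ps$pct_II + ps$pct_III, 100, tolerance = 1e-9)
  expect_equal(ps$n_IIa + ps$n_IIb + ps$n_I + ps$n_III, ps$n_gd_neg)
})

test_that("patients without enhancing-negative lesions are flagged", {
  rec <- classify_lesions(tibble::tibble(
    patient_id = c(1, 1, 2),
    gd_positive = c(FALSE, FALSE, TRUE),
    kex_positive = c(FALSE, FALSE, TRUE),
    qsm_positive = c(FALSE, FALSE, TRUE)))
  ps <- patient_summary(rec)
  expect_equal(ps$pct_I[ps$patient_id == 1], 0)     # all Pattern III
  expect_true(ps$no_gd_neg[ps$patient_id == 2])
  expect_true(is.na(ps$pct_I[ps$patient_id == 2]))
})

test_that("flags are derived from elevations when absent", {
  rec <- classify_lesions(tibble::tibble(
    patient_id = 1, gd_positive = FALSE,
    delta_kex = c(155, -20), delta_chi = c(28, 9)))
  expect_equal(as.character(rec$pattern), c("I", "IIb"))
  expect_equal(as.character(rec$pattern_merged), c("I", "II"))
})

test_that("lesion measurement applies the eligibility filter", {
  m <- roi_masks()
  kmap <- matrix(100, 12, 12); kmap[m$lesion] <- 300
  qmap <- matrix(0, 12, 12); qmap[m$lesion] <- 25
  roi <- list(lesion_id = 1L, patient_id = 1L, mask = m$lesion,
              nawm_mask = m$nawm, gd_positive = FALSE, gd_shape = "none")
  rec <- measure_lesions(kmap, qmap, list(roi), voxel_mm = 1.875)
  expect_true(rec$eligible)
  expect_equal(as.character(rec$pattern), "I")
  expect_equal(rec$delta_kex, 200)
  expect_equal(rec$delta_chi, 25)
  # at a coarse enough nominal resolution the lesion falls below 3 mm
  rec2 <- measure_lesions(kmap, qmap, list(roi), voxel_mm = 0.5)
  expect_false(rec2$eligible)
  expect_true(is.na(rec2$pattern))
})
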