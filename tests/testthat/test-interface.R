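test_that("Z-spectral datasets round-trip through NIfTI + sidecar", {
  dir <- withr::local_tempdir()
  set.seed(1)
  ds <- zspectral_dataset(array(runif(4 * 4 * 5 * 2), c(4, 4, 5, 2)),
                          offsets = c(39.1, -2, 0, 2, 3.5), b1_list = c(2, 4))
  write_zspectra(ds, dir)
  back <- read_zspectra(dir)
  expect_equal(back$offsets, ds$offsets)
  expect_equal(back$signal, ds$signal, tolerance = 1e-6)   # float32 storage
  # a second round trip is lossless
  dir2 <- withr::local_tempdir()
  write_zspectra(back, dir2)
  expect_identical(as.vector(read_zspectra(dir2)$signal),
                   as.vector(back$signal))
})

test_that("sidecar inconsistencies are rejected", {
  dir <- withr::local_tempdir()
  ds <- zspectral_dataset(array(1, c(4, 4, 3, 1)),
                          offsets = c(39.1, 0, 3.5), b1_list = 3)
  write_zspectra(ds, dir)
  meta <- jsonlite::read_json(file.path(dir, "zspec.json"),
                              simplifyVector = TRUE)
  meta$offsets <- rev(meta$offsets)       # permuted against the data order
  jsonlite::write_json(meta, file.path(dir, "zspec.json"), auto_unbox = TRUE)
  expect_error(read_zspectra(dir), "does not match data order")
  expect_error(read_zspectra(withr::local_tempdir()), "missing sidecar")
})

test_that("maps and phase stacks round-trip with their metadata", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(64), 8)
  p <- file.path(dir, "map.nii.gz")
  write_map(m, p)
  expect_equal(read_map(p), m, tolerance = 1e-6)
  te <- (4.3 + 4.8 * 0:3) / 1000
  ph <- array(rnorm(8 * 8 * 4, sd = 0.1), c(8, 8, 4))
  pp <- file.path(dir, "phase.nii.gz")
  write_phase(ph, te, pp)
  back <- read_phase(pp)
  expect_equal(back$te_list, te)
  expect_equal(back$phase, ph, tolerance = 1e-6)
  expect_error(write_phase(ph, te[1:3], pp), "does not match te_list")
})

test_that("run configuration validates its schema", {
  cfg <- run_config(list(seed = 9))
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$acquisition$b1_list, c(2, 3, 4))
  expect_error(run_config(list(seeds = 1)), "unknown config keys")
  expect_error(run_config(list(processing = list(taus = 1))),
               "unknown keys in 'processing'")
})

test_that("the full pipeline runs, classifies and is reproducible", {
  cfg <- run_config(list(
    seed = 11,
    phantom = list(grid = c(24, 24), n_lesions = 2, lesion_radius = 3,
                   noise_sd = 0.002, delta_kex = 400, delta_chi = 30)))
  dir1 <- withr::local_tempdir()
  out1 <- suppressMessages(run_pipeline(cfg, dir1))
  expect_true(all(file.exists(file.path(
    dir1, c("kex_map.nii.gz", "qsm.nii.gz", "lesions.csv", "patients.csv",
            "stats.json", "manifest.json", "config.yaml")))))
  expect_equal(nrow(out1$records), 2)
  expect_true(all(out1$records$evaluable))
  # injected elevations recovered with correct sign, pattern doubly positive
  expect_true(all(out1$records$delta_kex > 0))
  expect_true(all(out1$records$delta_chi > 0))
  expect_true(all(out1$records$pattern == "I"))
  # lesion exchange-rate elevation within the end-to-end accuracy band
  nodular <- out1$records$delta_kex[1]
  expect_lt(abs(nodular - 400) / 400, 0.5)

  dir2 <- withr::local_tempdir()
  out2 <- suppressMessages(run_pipeline(cfg, dir2))
  expect_identical(readLines(file.path(dir1, "lesions.csv")),
                   readLines(file.path(dir2, "lesions.csv")))
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_true(all(c("config_hash", "files") %in% names(man)))
})

test_that("the fixture-only report reproduces the printed counts", {
  dir <- withr::local_tempdir()
  rep_tbl <- fixture_report(dir)
  expect_true(file.exists(file.path(dir, "fixture_patterns.csv")))
  expect_equal(rep_tbl$n[rep_tbl$pattern == "GdPlus"], 153)
  expect_equal(rep_tbl$n[rep_tbl$pattern == "I"], 114)
  expect_equal(rep_tbl$pct_of_gdneg[rep_tbl$pattern == "I"], 67.5)
})

test_that("tidiers and plots expose results as tibbles and ggplots", {
  r <- ideal_residual(0.001, 700, 1, c(2, 3, 4))
  of <- omega_fit(r, c(2, 3, 4))
  expect_equal(glance(of)$kex, 700, tolerance = 1e-6)
  expect_equal(nrow(tidy(of)), 2)
  spec <- phantom_spec(grid = c(8, 8), lesions = list(), b0_amp = 0,
                       seed = 1)
  sim <- generate_phantom(spec)
  km <- kex_map(sim$dataset)
  td <- tidy(km)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 64)
  expect_s3_class(autoplot(km), "ggplot")
  expect_s3_class(autoplot(sim$dataset), "ggplot")
  expect_s3_class(plot_omega(r, c(2, 3, 4)), "ggplot")
  expect_output(print(km), "kex_map")
})
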