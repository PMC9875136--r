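# Shared builders for synthetic inputs. Everything is generated in code at
# test time; nothing is read from disk.

lor_curve <- function(x, A, d, w) A * (w / 2)^2 / ((w / 2)^2 + (x - d)^2)

# water + amide pool set with white-matter water, fixed amide fraction
wm_pools <- function(k, f = 0.0009) {
  list(water = pool("water", 1, 0, 1.0, 14, 0),
       amide = pool("amide", f, k, 1, 30, 3.5))
}

# residual at +3.5 ppm per saturation power for a pool set, full chain
chain_residuals <- function(pools, acq = acq_config()) {
  vapply(acq$b1_list, function(b1) {
    z <- bm_zspectrum(pools, b1, acq$offsets, t_sat = acq$t_sat)
    fit <- fit_two_lorentzian(z, acq$offsets)
    water_removed_residual(z, acq$offsets, fit)
  }, numeric(1))
}

# voxelized sphere of susceptibility in a cubic grid
sphere_chi <- function(n, radius, dchi) {
  ax <- seq_len(n) - (n / 2 + 0.5)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  chi <- array(0, c(n, n, n))
  chi[r2 <= radius^2] <- dchi
  list(chi = chi, r2 = r2)
}

# small lesion phantom spec shared by pipeline-level tests
small_lesion_spec <- function(seed = 1, noise_sd = 0, delta_kex = 400,
                              delta_chi = 30) {
  phantom_spec(
    grid = c(24, 24),
    lesions = list(
      list(center = c(7, 7), radius = 3, profile = "nodular",
           delta_kex = delta_kex, delta_chi = delta_chi, gd_positive = FALSE),
      list(center = c(17, 17), radius = 3, profile = "ring",
           delta_kex = delta_kex, delta_chi = delta_chi, gd_positive = FALSE)
    ),
    noise_sd = noise_sd, seed = seed
  )
}
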