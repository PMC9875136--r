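#' Define an exchanging proton pool
#'
#' A pool is characterised by its proton fraction relative to water, its
#' exchange rate to water, longitudinal and transverse relaxation rates, and
#' its chemical shift from the water resonance.
#'
#' @param name Label, e.g. `"water"`, `"amide"`.
#' @param f Proton fraction relative to the water pool (water = 1).
#' @param k Exchange rate to water, s^-1 (0 for water itself).
#' @param R1 Longitudinal relaxation rate, s^-1.
#' @param R2 Transverse relaxation rate, s^-1.
#' @param delta Chemical shift from water, ppm.
#'
#' @return A `pool_params` object (named list).
#' @export
#' @examples
#' pool("amide", f = 0.0009, k = 700, R1 = 1, R2 = 30, delta = 3.5)
pool <- function(name, f, k, R1, R2, delta) {
  vals <- c(f = f, k = k, R1 = R1, R2 = R2, delta = delta)
  stop_if(!all(is.finite(vals)), sprintf("pool '%s': all parameters must be finite", name))
  stop_if(f < 0 || k < 0, sprintf("pool '%s': f and k must be >= 0", name))
  stop_if(R1 <= 0 || R2 <= 0, sprintf("pool '%s': R1 and R2 must be > 0", name))
  structure(list(name = name, f = f, k = k, R1 = R1, R2 = R2, delta = delta),
            class = "pool_params")
}

#' Default white-matter pool set
#'
#' Water plus an amide pool at +3.5 ppm (the labile-proton pool whose exchange
#' rate is the quantity of interest) and a weak broad composite pool centred
#' at +1.5 ppm standing in for the sum of the remaining saturation-transfer
#' mechanisms (NOE, MT, other CEST). An optional broad MT pool can be added.
#' Water relaxation defaults to white-matter-typical values at 3 T
#' (T1 = 1 s, T2 = 71 ms); with those, 1.5 s of saturation is close enough
#' to steady state that the direct-saturation line is near-Lorentzian and
#' removable by the two-component decomposition.
#'
#' @param kex_amide Amide exchange rate, s^-1.
#' @param f_amide Amide proton fraction.
#' @param include_mt Add a broad semisolid MT pool.
#'
#' @return List of [pool()] objects, water first.
#' @export
default_pools <- function(kex_amide = 500, f_amide = 0.0009, include_mt = FALSE) {
  pools <- list(
    water = pool("water", f = 1, k = 0, R1 = 1.0, R2 = 14, delta = 0),
    amide = pool("amide", f = f_amide, k = kex_amide, R1 = 1, R2 = 30, delta = 3.5),
    composite = pool("composite", f = 0.002, k = 20, R1 = 1, R2 = 200, delta = 1.5)
  )
  if (include_mt) {
    pools$mt <- pool("mt", f = 0.05, k = 25, R1 = 1, R2 = 1e5, delta = -2.4)
  }
  pools
}

#' Default saturation-offset list
#'
#' Reference offsets at +39.1 and +15.6 ppm, shoulder points at +/-6, +/-5 and
#' +/-4.5 ppm, and a dense grid from -4 to +4 ppm in 0.25 ppm steps.
#'
#' @return Numeric vector of offsets, ppm, reference first.
#' @export
default_offsets <- function() {
  c(39.1, 15.6, -6, -5, -4.5, seq(-4, 4, by = 0.25), 4.5, 5, 6)
}

#' Acquisition configuration for Z-spectral imaging
#'
#' @param field_strength Static field, tesla.
#' @param b1_list Saturation amplitudes, uT; at least two distinct values are
#'   needed downstream for the omega plot.
#' @param t_sat Saturation duration, s.
#' @param offsets Saturation frequency offsets, ppm; must contain the
#'   normalization reference offset.
#' @param reference_offset Offset of the normalization image, ppm.
#'
#' @return An `acq_config` object; `larmor` (MHz) and `gamma`
#'   (rad s^-1 uT^-1) are derived fields.
#' @export
#' @examples
#' acq <- acq_config()
#' acq$larmor   # 127.731 MHz at 3 T
acq_config <- function(field_strength = 3,
                       b1_list = c(2, 3, 4),
                       t_sat = 1.5,
                       offsets = default_offsets(),
                       reference_offset = 39.1) {
  stop_if(!is_number(field_strength) || field_strength <= 0,
          "field_strength must be a positive number")
  stop_if(any(b1_list <= 0), "b1_list must be strictly positive")
  stop_if(length(unique(b1_list)) < 2,
          "b1_list needs >= 2 distinct values (omega plot needs >= 2 points)")
  stop_if(!reference_offset %in% offsets,
          "offsets must include the normalization reference offset")
  stop_if(!is_number(t_sat) || t_sat <= 0, "t_sat must be positive")
  structure(list(
    field_strength = field_strength,
    larmor = LARMOR_MHZ_PER_T * field_strength,
    b1_list = as.numeric(b1_list),
    t_sat = t_sat,
    offsets = as.numeric(offsets),
    reference_offset = reference_offset,
    gamma = GAMMA_H
  ), class = "acq_config")
}
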