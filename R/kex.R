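#' Omega-plot exchange-rate fit
#'
#' Linear omega-plot inversion of water-peak-removed CEST residuals acquired
#' at two or more saturation powers. Under the labeling-efficiency model
#' `R = (f k / R1w) * w1^2 / (w1^2 + k^2)`, the inverse residual is linear in
#' the inverse squared saturation amplitude,
#' `1/R = (R1w/(f k)) * (1 + k^2 / w1^2)`, so an ordinary least-squares line
#' of `1/R` against `1/w1^2` yields `k_ex = sqrt(slope / intercept)`; the
#' proton fraction and water relaxation cancel in the ratio.
#'
#' @param residuals Residual signal per saturation power.
#' @param b1_list Saturation amplitudes, uT.
#' @param gamma Gyromagnetic ratio, rad s^-1 uT^-1.
#'
#' @return An `omega_fit` object: `slope`, `intercept`, `r2` (of the line),
#'   `kex` (s^-1, `NaN` when invalid), `valid`.
#' @export
#' @examples
#' r <- ideal_residual(0.001, 700, 0.33, b1 = c(2, 3, 4))
#' omega_fit(r, c(2, 3, 4))$kex  # 700
omega_fit <- function(residuals, b1_list, gamma = GAMMA_H) {
  out <- structure(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                        kex = NaN, valid = FALSE), class = "omega_fit")
  ok <- is.finite(residuals)
  if (sum(ok) < 2L) return(out)
  x <- 1 / (gamma * b1_list[ok])^2
  stop_if(length(unique(x)) < 2L, "all saturation powers identical: omega plot degenerate")
  if (any(residuals[ok] <= 0)) return(out)
  y <- 1 / residuals[ok]
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  syy <- sum((y - ym)^2)
  r2 <- if (syy > 0) slope^2 * sxx / syy else 1
  out$slope <- slope; out$intercept <- intercept; out$r2 <- r2
  if (slope < 0 || intercept <= 0) return(out)
  out$kex <- sqrt(slope / intercept)
  out$valid <- TRUE
  out
}

#' Per-voxel exchange-rate map from a Z-spectral dataset
#'
#' Runs the full quantification chain for every masked voxel: two-Lorentzian
#' decomposition of each saturation power's spectrum, water-peak removal at
#' the B0-corrected labile-proton offset, and the omega-plot inversion across
#' powers. Voxels with a failed fit or non-positive residual carry `NaN`
#' sentinels (kept, not clipped: lesion elevations may legitimately be
#' negative in necrotic tissue) and are excluded from downstream ROI
#' statistics.
#'
#' @param dataset A [zspectral_dataset()] with at least two saturation powers.
#' @param target_offset Labile-proton offset, ppm.
#' @param min_r2 Omega-plot line quality floor; voxels below it are invalid.
#'
#' @return A `kex_map` object: matrices `kex` (s^-1), `r2`, logical
#'   `valid_mask`, and a `qc` list (`fraction_valid`, `median_r2`).
#' @export
kex_map <- function(dataset, target_offset = 3.5, min_r2 = 0) {
  stop_if(!inherits(dataset, "zspectral_dataset"), "dataset must be a zspectral_dataset")
  nb1 <- length(dataset$b1_list)
  stop_if(nb1 < 2L, "need >= 2 saturation powers")
  d <- dim(dataset$signal)
  kex <- matrix(NaN, d[1], d[2])
  r2 <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])

  # identical spectra (homogeneous regions of noiseless phantoms) are
  # processed once
  cache <- new.env(parent = emptyenv())
  voxel_residual <- function(spec_b, dw_fix) {
    key <- paste(signif(c(spec_b, dw_fix), 10), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- fit_two_lorentzian(spec_b, dataset$offsets, dw_fix = dw_fix)
    val <- if (!fit$converged) c(NA_real_, NA_real_) else c(
      tryCatch(
        water_removed_residual(spec_b, dataset$offsets, fit, target_offset),
        error = function(e) NA_real_),
      fit$dw)
    cache[[key]] <- val
    val
  }

  # the B0 shift is a voxel property, not a power property: estimate it on
  # the sharpest (lowest-power) spectrum and share it across powers
  b_order <- order(dataset$b1_list)

  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!dataset$mask[i, j]) next
      res <- rep(NA_real_, nb1)
      dw_shared <- NULL
      for (b in b_order) {
        out <- voxel_residual(dataset$signal[i, j, , b], dw_shared)
        res[b] <- out[1]
        if (!is.finite(res[b])) break
        if (is.null(dw_shared)) dw_shared <- out[2]
      }
      if (!all(is.finite(res))) next
      of <- omega_fit(res, dataset$b1_list)
      r2[i, j] <- of$r2
      if (of$valid && (is.na(of$r2) || of$r2 >= min_r2)) {
        kex[i, j] <- of$kex
        valid[i, j] <- TRUE
      }
    }
  }
  n_mask <- sum(dataset$mask)
  structure(list(
    kex = kex, r2 = r2, valid_mask = valid,
    qc = list(fraction_valid = sum(valid) / max(1L, n_mask),
              median_r2 = median(r2[valid], na.rm = TRUE))
  ), class = "kex_map")
}
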