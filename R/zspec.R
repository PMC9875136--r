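#' Z-spectral dataset container
#'
#' Holds the normalized Z-spectral stack for one slice: per-voxel signal over
#' saturation offsets and saturation powers, plus the processable-voxel mask.
#' Offsets are stored sorted ascending.
#'
#' @param signal Numeric array `x * y * n_offsets * n_b1`, normalized signal.
#' @param offsets Saturation offsets, ppm (length `n_offsets`).
#' @param b1_list Saturation amplitudes, uT (length `n_b1`).
#' @param reference_offset Normalization reference offset, ppm.
#' @param mask Logical matrix of processable voxels (default all).
#' @param larmor Larmor frequency, MHz.
#'
#' @return A `zspectral_dataset` object.
#' @export
zspectral_dataset <- function(signal, offsets, b1_list, reference_offset = 39.1,
                              mask = NULL, larmor = 127.731) {
  stop_if(length(dim(signal)) != 4L, "signal must be x * y * n_offsets * n_b1")
  stop_if(dim(signal)[3] != length(offsets), "offset count mismatch")
  stop_if(dim(signal)[4] != length(b1_list), "b1 count mismatch")
  ord <- order(offsets)
  structure(list(
    signal = signal[, , ord, , drop = FALSE],
    offsets = as.numeric(offsets[ord]),
    b1_list = as.numeric(b1_list),
    reference_offset = reference_offset,
    mask = if (is.null(mask)) matrix(TRUE, dim(signal)[1], dim(signal)[2]) else mask,
    larmor = larmor
  ), class = "zspectral_dataset")
}

#' Normalize a raw Z-spectral stack
#'
#' Divides every offset image by the reference-offset image of its own
#' saturation power. Voxels whose reference signal is at or below the noise
#' floor are excluded from the processing mask.
#'
#' @param raw Raw signal array `x * y * n_offsets * n_b1`.
#' @param offsets Offsets, ppm, matching dim 3 of `raw`.
#' @param b1_list Saturation amplitudes, uT, matching dim 4.
#' @param reference_offset Offset of the normalization image, ppm; must be
#'   present in `offsets`.
#' @param noise_floor Reference-signal floor below which a voxel is dropped.
#'
#' @return A [zspectral_dataset()].
#' @export
normalize_zspectra <- function(raw, offsets, b1_list, reference_offset = 39.1,
                               noise_floor = 0) {
  stop_if(length(dim(raw)) != 4L, "raw must be x * y * n_offsets * n_b1")
  iref <- which(offsets == reference_offset)
  stop_if(length(iref) != 1L, "reference offset missing from data")

  nb1 <- length(b1_list)
  signal <- raw
  mask <- matrix(TRUE, dim(raw)[1], dim(raw)[2])
  for (j in seq_len(nb1)) {
    ref <- raw[, , iref, j]
    mask <- mask & (ref > noise_floor)
    refsafe <- ifelse(ref > noise_floor, ref, NA_real_)
    signal[, , , j] <- sweep(raw[, , , j, drop = FALSE][, , , 1],
                             c(1, 2), refsafe, "/")
  }
  dropped <- sum(!mask)
  if (dropped > 0) {
    message(sprintf("normalize_zspectra: %d voxel(s) dropped (reference <= noise floor)",
                    dropped))
  }
  stop_if(!any(mask), "normalization failed: no voxel has reference signal above the noise floor")
  zspectral_dataset(signal, offsets, b1_list, reference_offset, mask)
}

#' Estimate and apply a translational shift between two images
#'
#' Finds the shift maximizing the circular normalized cross-correlation
#' (computed via FFT), refines it to subvoxel precision by parabolic peak
#' interpolation, and applies it with a Fourier phase shift (wraparound
#' boundary). A correlation peak at the search bound is clamped and flagged.
#'
#' @param moving,fixed Same-size numeric matrices.
#' @param max_shift Search bound, voxels.
#' @param subvoxel Refine the integer peak by parabolic interpolation.
#'
#' @return List: `shift` (c(dx, dy), voxels), `registered` (shifted moving
#'   image), `confidence` (peak normalized correlation), `low_confidence`
#'   flag.
#' @export
register_translation <- function(moving, fixed, max_shift = 8, subvoxel = TRUE) {
  stop_if(!identical(dim(moving), dim(fixed)), "images must share a grid")
  d <- dim(fixed)
  a <- moving - mean(moving)
  b <- fixed - mean(fixed)
  denom <- sqrt(sum(a^2) * sum(b^2))
  low <- FALSE
  if (denom <= 0) {
    return(list(shift = c(0, 0), registered = moving, confidence = 0,
                low_confidence = TRUE))
  }
  # cc(s) = sum_x moving(x + s) fixed(x) / denom: peaks at the displacement
  # s0 for which moving(x) = fixed(x - s0)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a) / denom
  # wrap correlation lags to [-n/2, n/2)
  lag1 <- fft_freq(d[1]) * d[1]
  lag2 <- fft_freq(d[2]) * d[2]
  allowed <- outer(abs(lag1) <= max_shift, abs(lag2) <= max_shift, "&")
  cc_masked <- ifelse(allowed, cc, -Inf)
  peak <- arrayInd(which.max(cc_masked), d)
  sh <- c(lag1[peak[1]], lag2[peak[2]])
  conf <- cc[peak[1], peak[2]]
  if (any(abs(sh) >= max_shift)) {
    warn("register_translation: correlation peak at search bound; shift clamped")
    sh <- pmin(pmax(sh, -max_shift), max_shift)
    low <- TRUE
  }
  if (subvoxel) {
    sh <- sh + c(parabolic_offset(cc, peak, 1L), parabolic_offset(cc, peak, 2L))
  }
  if (conf < 0.3) low <- TRUE
  list(shift = sh, registered = shift_image(moving, -sh), confidence = conf,
       low_confidence = low)
}

parabolic_offset <- function(cc, peak, axis) {
  d <- dim(cc)
  i <- peak[axis]
  im <- (i - 2L) %% d[axis] + 1L
  ip <- i %% d[axis] + 1L
  pick <- function(j) if (axis == 1L) cc[j, peak[2]] else cc[peak[1], j]
  y0 <- pick(im); y1 <- pick(i); y2 <- pick(ip)
  den <- y0 - 2 * y1 + y2
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  off <- 0.5 * (y0 - y2) / den
  max(min(off, 0.5), -0.5)
}

# circular shift by a possibly fractional displacement via Fourier phase ramp
shift_image <- function(img, shift) {
  d <- dim(img)
  ph1 <- exp(-2i * pi * fft_freq(d[1]) * shift[1])
  ph2 <- exp(-2i * pi * fft_freq(d[2]) * shift[2])
  Re(fft(fft(img) * (ph1 %o% ph2), inverse = TRUE)) / length(img)
}

#' Register a Z-spectral image series by chained translations
#'
#' Registers each image to its previous adjacent image and accumulates the
#' shifts, mirroring sequential acquisition where motion drifts between
#' offsets.
#'
#' @param stack Array `x * y * n_images`.
#' @param max_shift Per-step search bound, voxels.
#'
#' @return List: `stack` (registered array), `shifts` (n x 2 matrix of
#'   cumulative applied shifts).
#' @export
register_series <- function(stack, max_shift = 8) {
  n <- dim(stack)[3]
  shifts <- matrix(0, n, 2)
  out <- stack
  cum <- c(0, 0)
  for (i in seq_len(n)[-1]) {
    reg <- register_translation(stack[, , i], stack[, , i - 1], max_shift = max_shift)
    cum <- cum + reg$shift
    shifts[i, ] <- cum
    out[, , i] <- shift_image(stack[, , i], -cum)
  }
  list(stack = out, shifts = shifts)
}

lorentz <- function(x, A, delta, w) {
  A * (w / 2)^2 / ((w / 2)^2 + (x - delta)^2)
}

#' Two-Lorentzian decomposition of a Z-spectrum
#'
#' Fits the flipped spectrum `1 - Z` as the sum of a bulk-water Lorentzian
#' (centred near 0 ppm; its centre doubles as the voxel's B0 shift) and a
#' composite Lorentzian (centred near +1.5 ppm) standing for the summed
#' remaining saturation-transfer effects, by bounded Levenberg-Marquardt
#' least squares.
#'
#' @param signal Normalized Z values over `offsets`.
#' @param offsets Offsets, ppm.
#' @param exclude Offsets excluded from the fit (the reference points).
#' @param lower,upper Named bounds for `aw, dw, ww, ar, dr, wr` (water and
#'   composite amplitude / centre ppm / FWHM ppm). The water-width ceiling
#'   accommodates the direct-saturation linewidth at the default powers:
#'   in steady state the lineshape is Lorentzian with
#'   `FWHM = 2 sqrt(R2^2 + w1^2 R2 / R1)`, 7-15 ppm at 2-4 uT for white
#'   matter water.
#' @param readout_offset Centre of the wing-fit weighting, ppm: the water
#'   subtraction is made most accurate at the mirrored labile-proton offset,
#'   where the residual is later read out.
#' @param dw_fix Optional externally supplied water centre (B0 shift), ppm:
#'   the static-field shift is a property of the voxel, not of the
#'   saturation power, so multi-power processing estimates it once on the
#'   sharpest (lowest-power) line and shares it across powers.
#'
#' @return A `lorentzian_fit` object: fields `aw, dw, ww, ar, dr, wr`,
#'   `rss`, `converged`.
#' @export
fit_two_lorentzian <- function(signal, offsets,
                               exclude = c(39.1, 15.6),
                               lower = c(aw = 0.2, dw = -1, ww = 0.5,
                                         ar = 0,  dr = 0.5, wr = 1),
                               upper = c(aw = 1.2, dw = 1, ww = 20,
                                         ar = 0.5, dr = 2.5, wr = 12),
                               readout_offset = 3.5, dw_fix = NULL) {
  keep <- !(offsets %in% exclude) & is.finite(signal)
  stop_if(!any(is.finite(signal)), "spectrum is all-NaN")
  stop_if(sum(keep & abs(offsets) <= 6) < 10,
          "need >= 10 finite offsets within +/-6 ppm")
  x <- offsets[keep]
  y <- 1 - signal[keep]

  failed <- structure(list(aw = NA_real_, dw = NA_real_, ww = NA_real_,
                           ar = NA_real_, dr = NA_real_, wr = NA_real_,
                           rss = NA_real_, converged = FALSE),
                      class = "lorentzian_fit")
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100)
  # snap near-zero starts to exact zero: the LM implementation scales each
  # parameter by its starting magnitude, so a ~1e-15 start yields a
  # numerically singular Jacobian column
  clamp <- function(v, nm) {
    v <- max(min(unname(v), upper[nm] - 1e-3), lower[nm] + 1e-4)
    if (abs(v) < 1e-8) 0 else v
  }

  # A simultaneous 6-parameter fit is degenerate whenever the measured line
  # deviates from an exact Lorentzian sum (as a saturated water line does):
  # the optimizer splits the water peak between the two components, which
  # destroys the decomposition the water subtraction relies on. The fit is
  # therefore staged without feedback: (1) the water centre from the
  # symmetric core of the line, (2) water amplitude/width from the negative
  # wing only (the labile pools sit at positive offsets), weighted toward
  # the mirrored readout offset so the subtraction is most accurate where
  # the residual is read, (3) the composite on the water-subtracted
  # remainder. A joint refinement of all six parameters is then attempted
  # and kept only when it attains an essentially exact fit (RSS < 1e-12),
  # i.e. when the spectrum truly is a sum of two Lorentzians and the joint
  # problem is well posed.

  # (1) water centre: parabolic vertex through the peak, refined by a
  # wider least-squares parabola over the core (or supplied externally)
  if (!is.null(dw_fix)) {
    dw0 <- clamp(dw_fix, "dw")
  } else {
    dw0 <- x[which.max(y)]
    sel <- which.max(y) + (-1:1)
    if (all(sel >= 1 & sel <= length(x))) {
      pf <- tryCatch(coef(lm(y[sel] ~ poly(x[sel], 2, raw = TRUE))),
                     error = function(e) NULL)
      if (!is.null(pf) && is.finite(pf[3]) && pf[3] < 0) {
        dw0 <- -pf[2] / (2 * pf[3])
      }
    }
    dw0 <- clamp(dw0, "dw")
    core <- which(abs(x - dw0) <= 0.6)
    if (length(core) >= 5) {
      pf <- tryCatch(coef(lm(y[core] ~ poly(x[core], 2, raw = TRUE))),
                     error = function(e) NULL)
      if (!is.null(pf) && is.finite(pf[3]) && pf[3] < 0) {
        dw0 <- clamp(-pf[2] / (2 * pf[3]), "dw")
      }
    }
  }

  # (2) water amplitude and width from the negative wing, centre frozen
  wing <- (x - dw0) <= -1 & (x - dw0) >= -6.5
  if (sum(wing) < 5) wing <- x <= dw0 + 0.5
  if (sum(wing) < 4) wing <- rep(TRUE, length(x))
  xg <- x[wing]; yg <- y[wing]
  wt <- exp(-(abs(xg - dw0) - readout_offset)^2 / 2)
  ww_grid <- seq(max(1, lower["ww"]), upper["ww"], by = 0.5)
  init <- vapply(ww_grid, function(w) {
    L <- lorentz(xg, 1, dw0, w)
    a <- sum(wt * L * yg) / sum(wt * L^2)
    c(a, sum(wt * (yg - a * L)^2))
  }, numeric(2))
  best <- which.min(init[2, ])
  dwfix <- dw0
  wfit <- tryCatch(
    minpack.lm::nlsLM(yg ~ lorentz(xg, aw, dwfix, ww),
                      start = list(aw = clamp(init[1, best], "aw"),
                                   ww = ww_grid[best]),
                      lower = lower[c("aw", "ww")],
                      upper = upper[c("aw", "ww")],
                      weights = wt, control = ctrl),
    error = function(e) NULL)
  if (is.null(wfit)) return(failed)
  p <- list(aw = coef(wfit)[["aw"]], dw = dw0, ww = coef(wfit)[["ww"]])

  # (3) composite on the water-subtracted remainder; when the remainder has
  # no appreciable peak the composite is recorded as (near-)zero directly --
  # an LM fit with a vanishing amplitude has a rank-deficient Jacobian in
  # its centre and width
  yr <- y - lorentz(x, p$aw, p$dw, p$ww)
  if (max(yr) < 0.01) {
    p <- c(p, list(ar = max(0, max(yr)), dr = 1.5, wr = 4))
  } else {
    rfit <- tryCatch(
      minpack.lm::nlsLM(yr ~ lorentz(x, ar, dr, wr),
                        start = list(ar = clamp(max(0.05, min(max(yr), 0.2)),
                                                "ar"),
                                     dr = 1.5, wr = 4),
                        lower = lower[c("ar", "dr", "wr")],
                        upper = upper[c("ar", "dr", "wr")], control = ctrl),
      error = function(e) NULL)
    if (is.null(rfit)) {
      p <- c(p, list(ar = max(0, max(yr)), dr = 1.5, wr = 4))
    } else {
      p <- c(p, as.list(coef(rfit)))
    }
  }

  # joint refinement, kept only if essentially exact
  ord <- c("aw", "dw", "ww", "ar", "dr", "wr")
  jfit <- tryCatch(
    minpack.lm::nlsLM(y ~ lorentz(x, aw, dw, ww) + lorentz(x, ar, dr, wr),
                      start = lapply(setNames(ord, ord),
                                     function(nm) clamp(p[[nm]], nm)),
                      lower = lower[ord], upper = upper[ord], control = ctrl),
    error = function(e) NULL)
  if (!is.null(jfit) && sum(residuals(jfit)^2) < 1e-12) {
    p <- as.list(coef(jfit))
  }
  rss <- sum((y - lorentz(x, p$aw, p$dw, p$ww) -
                lorentz(x, p$ar, p$dr, p$wr))^2)
  structure(c(p, list(rss = rss, converged = TRUE)),
            class = "lorentzian_fit")
}




#' Water-peak-removed residual at a target offset
#'
#' Subtracts the fitted bulk-water Lorentzian from the flipped spectrum and
#' evaluates the remainder at the B0-corrected target offset
#' `target + dw` (the fitted water centre is the voxel's B0 shift). The
#' measured spectrum is interpolated with a cubic spline where the corrected
#' offset falls between samples. Only the water peak is removed; the
#' composite peak's tail at the target deliberately remains, since the
#' tissue exchange rate is a weighted average of all exchange mechanisms.
#'
#' With `spillover_correction` (the default) the subtraction residual is
#' rescaled by the measured Z and the fitted water line at the target,
#' `residual / (Z * (1 - L_w))`: the exchange-transfer dip rides on the
#' water magnetization left over after direct saturation, which shrinks as
#' the power grows, and in the steady-state weak-pool limit the raw
#' subtraction equals `(R_ex/R1w) * Z * Z_water`. Undoing that scaling makes
#' the residual proportional to the labeling efficiency across powers —
#' without it the residual is not monotone in B1 and the omega-plot slope
#' can turn negative. Set `FALSE` for the plain subtraction.
#'
#' @param signal Normalized Z values over `offsets`.
#' @param offsets Offsets, ppm.
#' @param fit A converged [fit_two_lorentzian()] result.
#' @param target_offset Labile-proton offset, ppm (default +3.5, amide).
#' @param window Interpolation restricted to `|offset| <= window` ppm.
#' @param spillover_correction Rescale the subtraction residual by the
#'   direct-saturation factors (see Details).
#' @param readout_window Half-width of the symmetric readout window, ppm
#'   (0 reads the single interpolated point).
#'
#' @return Residual signal (dimensionless scalar).
#' @export
water_removed_residual <- function(signal, offsets, fit, target_offset = 3.5,
                                   window = 8, spillover_correction = TRUE,
                                   readout_window = 0.25) {
  stop_if(!isTRUE(fit$converged), "Lorentzian fit did not converge")
  target <- target_offset + fit$dw
  keep <- abs(offsets) <= window & is.finite(signal)
  x <- offsets[keep]
  stop_if(target < min(x) || target > max(x),
          "B0-corrected target offset outside the sampled range")
  yfun <- splinefun(x, 1 - signal[keep], method = "natural")
  # the residual spectrum is averaged over a small symmetric window around
  # the corrected target: exact where it is flat or symmetric, and it
  # suppresses single-sample noise at the readout
  pts <- target + c(-readout_window, 0, readout_window)
  pts <- pts[pts >= min(x) & pts <= max(x)]
  res <- mean(yfun(pts) - lorentz(pts, fit$aw, fit$dw, fit$ww))
  if (spillover_correction) {
    lw <- lorentz(target, fit$aw, fit$dw, fit$ww)
    z_meas <- 1 - yfun(target)
    z_water <- 1 - lw
    if (z_meas > 0.01 && z_water > 0.01) res <- res / (z_meas * z_water)
  }
  res
}
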