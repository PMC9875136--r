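#' Bloch-McConnell Z-spectrum
#'
#' Propagates the coupled Bloch-McConnell equations for a set of exchanging
#' proton pools under continuous-wave saturation and returns the normalized
#' water Z-spectrum. The coupled linear system (3 magnetization components
#' per pool plus the relaxation recovery term) is solved by matrix
#' exponentiation over the saturation duration, one offset at a time, reading
#' the water longitudinal magnetization at `t_sat`.
#'
#' @param pools List of [pool()] objects; the first must be the water pool
#'   (`delta = 0`, `f = 1`) and at least one non-water pool is required.
#' @param b1 Saturation amplitude, uT (> 0).
#' @param offsets Saturation offsets, ppm.
#' @param t_sat Saturation duration, s.
#' @param b0_shift Static-field inhomogeneity expressed as a frequency shift
#'   of the water resonance, ppm. The effective offset seen by the spins is
#'   `offsets - b0_shift`.
#' @param larmor Larmor frequency, MHz (127.731 at 3 T).
#' @param reference_offset Offset of the normalization image, ppm, or `NULL`
#'   to return the raw water magnetization fraction.
#'
#' @return Numeric vector, one value of Z per offset, in (0, 1] up to
#'   normalization.
#' @export
#' @examples
#' z <- bm_zspectrum(default_pools(kex_amide = 700), b1 = 3,
#'                   offsets = c(-3.5, 0, 3.5))
#' z[3] < z[1]  # CEST asymmetry: amide pool saturates the +3.5 ppm side
bm_zspectrum <- function(pools, b1, offsets, t_sat = 1.5, b0_shift = 0,
                         larmor = 127.731, reference_offset = 39.1) {
  check_pools(pools)
  stop_if(length(pools) < 2, "need >= 1 non-water pool")
  stop_if(!is_number(b1) || b1 <= 0, "b1 must be a positive number")
  stop_if(!is_number(t_sat) || t_sat <= 0, "t_sat must be positive")
  stop_if(!all(is.finite(offsets)), "offsets must be finite")

  z <- vapply(offsets, function(off) {
    bm_water_mz(pools, b1, off - b0_shift, t_sat, larmor)
  }, numeric(1))
  if (!is.null(reference_offset)) {
    zref <- bm_water_mz(pools, b1, reference_offset - b0_shift, t_sat, larmor)
    z <- z / zref
  }
  z
}

check_pools <- function(pools) {
  stop_if(length(pools) < 1 || !all(vapply(pools, inherits, logical(1), "pool_params")),
          "pools must be a non-empty list of pool() objects")
  w <- pools[[1]]
  stop_if(w$delta != 0 || w$f != 1,
          "first pool must be water (delta = 0, f = 1)")
  invisible(NULL)
}

# Water Mz/M0 after t seconds of CW saturation at a single offset (ppm).
bm_water_mz <- function(pools, b1, offset_ppm, t, larmor) {
  n <- length(pools)
  ppm2rad <- 2 * pi * larmor          # rad/s per ppm
  w1 <- GAMMA_H * b1                  # rad/s

  f  <- vapply(pools, `[[`, numeric(1), "f")
  k  <- vapply(pools, `[[`, numeric(1), "k")
  r1 <- vapply(pools, `[[`, numeric(1), "R1")
  r2 <- vapply(pools, `[[`, numeric(1), "R2")
  dl <- vapply(pools, `[[`, numeric(1), "delta")

  dim <- 3L * n + 1L
  A <- matrix(0, dim, dim)
  idx <- function(i) 3L * (i - 1L)    # block offset for pool i

  for (i in seq_len(n)) {
    o <- idx(i)
    th <- (dl[i] - offset_ppm) * ppm2rad  # pool resonance offset in sat frame
    A[o + 1L, o + 1L] <- -r2[i];  A[o + 1L, o + 2L] <- -th
    A[o + 2L, o + 1L] <-  th;     A[o + 2L, o + 2L] <- -r2[i]
    A[o + 2L, o + 3L] <- -w1
    A[o + 3L, o + 2L] <-  w1;     A[o + 3L, o + 3L] <- -r1[i]
    A[o + 3L, dim] <- r1[i] * f[i]      # recovery toward M0_i = f_i
    if (i > 1L) {
      # exchange pool i <-> water (pool 1), detailed balance k_wi = f_i k_i
      for (c in 1:3) {
        A[o + c, o + c] <- A[o + c, o + c] - k[i]
        A[o + c, c]     <- A[o + c, c] + f[i] * k[i]
        A[c, o + c]     <- A[c, o + c] + k[i]
        A[c, c]         <- A[c, c] - f[i] * k[i]
      }
    }
  }

  x0 <- numeric(dim)
  x0[3L * seq_len(n)] <- f            # thermal equilibrium Mz
  x0[dim] <- 1

  xt <- tryCatch(expm_apply(A, t, x0),
                 error = function(e) abort(sprintf(
                   "Bloch-McConnell solve failed at offset %.3g ppm: %s",
                   offset_ppm, conditionMessage(e))))
  xt[3L]                               # water Mz (M0_w = 1)
}

# exp(A t) %*% x via eigendecomposition, falling back to scaling-and-squaring
expm_apply <- function(A, t, x) {
  eg <- eigen(A)
  y <- tryCatch({
    co <- solve(eg$vectors, x)
    Re(eg$vectors %*% (exp(eg$values * t) * co))
  }, error = function(e) NULL)
  if (!is.null(y) && all(is.finite(y))) return(drop(y))
  # fallback: scaling and squaring with a Taylor kernel
  s <- max(0L, ceiling(log2(max(1e-16, norm(A, "F") * t))))
  B <- A * (t / 2^s)
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (j in 1:16) {
    term <- term %*% B / j
    E <- E + term
  }
  for (j in seq_len(s)) E <- E %*% E
  drop(E %*% x)
}

#' Idealized water-peak-removed CEST residual
#'
#' Closed-form residual signal of a dilute labile pool under CW saturation in
#' the linear (weak-saturation) regime:
#' `R = (f k / R1w) * w1^2 / (w1^2 + k^2)` with `w1 = gamma * b1`. This is
#' the generative model that the omega-plot line inverts, and serves as the
#' exact oracle for the estimator.
#'
#' @param f Labile proton fraction.
#' @param k Exchange rate, s^-1.
#' @param r1w Water longitudinal relaxation rate, s^-1 (> 0).
#' @param b1 Saturation amplitude, uT.
#' @param gamma Gyromagnetic ratio, rad s^-1 uT^-1.
#'
#' @return Dimensionless residual signal.
#' @export
#' @examples
#' ideal_residual(f = 0.001, k = 1000, r1w = 0.33, b1 = 3)
ideal_residual <- function(f, k, r1w, b1, gamma = GAMMA_H) {
  stop_if(any(c(f, k, b1) < 0), "f, k and b1 must be >= 0")
  stop_if(!is_number(r1w) || r1w <= 0, "r1w must be > 0")
  w1 <- gamma * b1
  if (k == 0) return(0 * w1)
  (f * k / r1w) * w1^2 / (w1^2 + k^2)
}
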