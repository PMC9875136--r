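#' Fit a field map from multi-echo phase images
#'
#' Per-voxel least-squares slope of phase against echo time gives the local
#' off-resonance frequency, converted to ppm of the Larmor frequency. Phase
#' is assumed unwrapped; voxels whose phase jumps by more than pi between
#' adjacent echoes are flagged unreliable (reliability 0) since wrapping
#' cannot be excluded there.
#'
#' @param phase Array of phase images, radians: `x * y * n_echo` (or
#'   `x * y * 1 * n_echo` as written by the NIfTI writer).
#' @param te_list Echo times, seconds; at least 3.
#' @param larmor Larmor frequency, MHz.
#'
#' @return A `field_map` object: matrices `field` (ppm) and `reliability`
#'   (`1 / (1 + rms residual)`, 0 where wrapped).
#' @export
echo_fit <- function(phase, te_list, larmor = 127.731) {
  if (length(dim(phase)) == 4L && dim(phase)[3] == 1L) {
    phase <- array(phase, dim(phase)[c(1, 2, 4)])
  }
  stop_if(length(dim(phase)) != 3L, "phase must be x * y * n_echo")
  ne <- length(te_list)
  stop_if(ne < 3L, "need >= 3 echoes")
  stop_if(dim(phase)[3] != ne, "echo count does not match te_list")

  d <- dim(phase)
  P <- matrix(phase, nrow = d[1] * d[2], ncol = ne)
  tc <- te_list - mean(te_list)
  w <- tc / sum(tc^2)
  slope <- drop(P %*% w)                          # rad/s
  inter <- rowMeans(P) - slope * mean(te_list)
  fitted <- outer(slope, te_list) + inter
  rms <- sqrt(rowMeans((P - fitted)^2))
  wrapped <- apply(abs(P[, -1, drop = FALSE] - P[, -ne, drop = FALSE]), 1, max) > pi

  reliability <- 1 / (1 + rms)
  reliability[wrapped] <- 0
  field <- slope / (2 * pi) / larmor              # Hz -> ppm of larmor MHz

  structure(list(
    field = matrix(field, d[1], d[2]),
    reliability = matrix(reliability, d[1], d[2]),
    larmor = larmor
  ), class = "field_map")
}

#' Reference a susceptibility map to a region
#'
#' Subtracts the mean susceptibility over a reference region (typically
#' normal-appearing white matter) so that reported values are elevations
#' relative to that internal reference. Idempotent.
#'
#' @param chi Susceptibility map, ppb (matrix or 3D array), or a
#'   `susceptibility_map` object.
#' @param reference_mask Logical mask of the reference region, same shape.
#'
#' @return A `susceptibility_map` object: `chi` (ppb, mean zero over the
#'   reference region) and `reference_mask`.
#' @export
reference_map <- function(chi, reference_mask) {
  if (inherits(chi, "susceptibility_map")) chi <- chi$chi
  stop_if(!any(reference_mask), "reference mask is empty")
  stop_if(!identical(dim(chi), dim(reference_mask)),
          "chi and reference_mask shapes differ")
  structure(list(
    chi = chi - mean(chi[reference_mask]),
    reference_mask = reference_mask
  ), class = "susceptibility_map")
}
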