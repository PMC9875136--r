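# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data :=
#' @importFrom ggplot2 autoplot
#' @importFrom stats coef fft lm median na.omit pchisq pnorm pt qlogis
#'   plogis quantile residuals rnorm rlnorm runif rpois sd setNames spline
#'   splinefun var
#' @importFrom utils combn head tail
NULL

# gyromagnetic ratio of 1H, rad s^-1 uT^-1
GAMMA_H <- 267.522

# Larmor frequency per tesla, MHz
LARMOR_MHZ_PER_T <- 42.577

stop_if <- function(cond, msg, class = "kexqsm_error") {
  if (isTRUE(cond)) abort(msg, class = class)
  invisible(NULL)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# quantize to a step, used to memoize Bloch-McConnell solves across voxels
quantize <- function(x, step) round(x / step) * step

# 4-neighbour binary erosion of a logical matrix, n iterations
erode_mask <- function(mask, n = 1L) {
  m <- mask
  if (n < 1L) return(m)
  for (i in seq_len(n)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m & up & dn & lf & rt
  }
  m
}

# deterministic integer sub-seed derived from a master seed and a stream tag
# (double arithmetic: the product overflows 32-bit integers)
sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(tag) * 97) %% 2147483647)
}
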