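# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Turn a result object into a tidy tibble
#'
#' @param x Object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x Object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.omega_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.omega_fit <- function(x, ...) {
  tibble::tibble(kex = x$kex, r2 = x$r2, valid = x$valid)
}

#' @export
tidy.lorentzian_fit <- function(x, ...) {
  tibble::tibble(
    component = rep(c("water", "composite"), each = 3),
    term = rep(c("amplitude", "center_ppm", "fwhm_ppm"), 2),
    estimate = c(x$aw, x$dw, x$ww, x$ar, x$dr, x$wr))
}

#' @export
glance.lorentzian_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged)
}

map_tidy <- function(m, value_name) {
  d <- dim(m)
  tibble::tibble(x = rep(seq_len(d[1]), d[2]),
                 y = rep(seq_len(d[2]), each = d[1]),
                 "{value_name}" := as.vector(m))
}

#' @export
tidy.kex_map <- function(x, ...) {
  out <- map_tidy(x$kex, "kex")
  out$r2 <- as.vector(x$r2)
  out$valid <- as.vector(x$valid_mask)
  out
}

#' @export
glance.kex_map <- function(x, ...) {
  tibble::tibble(fraction_valid = x$qc$fraction_valid,
                 median_r2 = x$qc$median_r2,
                 mean_kex = mean(x$kex[x$valid_mask]))
}

#' @export
tidy.susceptibility_map <- function(x, ...) map_tidy(x$chi, "chi")

#' @export
tidy.field_map <- function(x, ...) {
  out <- map_tidy(x$field, "field")
  out$reliability <- as.vector(x$reliability)
  out
}

#' @export
tidy.zspectral_dataset <- function(x, ...) {
  d <- dim(x$signal)
  tidyr::expand_grid(b1 = x$b1_list, offset = x$offsets) |>
    dplyr::mutate(signal = purrr::map2_dbl(.data$b1, .data$offset, function(b, o) {
      mean(x$signal[, , which(x$offsets == o), which(x$b1_list == b)][x$mask],
           na.rm = TRUE)
    }))
}

map_autoplot <- function(m, value_name, unit) {
  df <- map_tidy(m, "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = sprintf("%s (%s)", value_name, unit)) +
    ggplot2::theme_minimal()
}

#' Plot a quantitative map
#'
#' @param object Map object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kex_map <- function(object, ...) {
  map_autoplot(object$kex, "k_ex", "s^-1")
}

#' @rdname autoplot.kex_map
#' @export
autoplot.susceptibility_map <- function(object, ...) {
  map_autoplot(object$chi, "chi", "ppb")
}

#' @rdname autoplot.kex_map
#' @export
autoplot.field_map <- function(object, ...) {
  map_autoplot(object$field, "field", "ppm")
}

#' Mask-averaged Z-spectra per saturation power
#'
#' @param object A [zspectral_dataset()].
#' @param max_offset Restrict the x axis to `|offset| <=` this, ppm.
#' @param ... Unused.
#' @return A ggplot (Z against offset, reversed axis by convention).
#' @export
autoplot.zspectral_dataset <- function(object, max_offset = 6, ...) {
  df <- tidy(object) |> dplyr::filter(abs(.data$offset) <= max_offset)
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$signal,
                                   colour = factor(.data$b1))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "offset (ppm)", y = "Z", colour = "B1 (uT)") +
    ggplot2::theme_minimal()
}

#' Omega plot for one voxel or ROI
#'
#' Inverse residual against inverse squared saturation amplitude with the
#' fitted line; the exchange rate is the square root of slope over
#' intercept.
#'
#' @param residuals Residual per saturation power.
#' @param b1_list Saturation amplitudes, uT.
#' @return A ggplot.
#' @export
plot_omega <- function(residuals, b1_list) {
  fit <- omega_fit(residuals, b1_list)
  df <- tibble::tibble(x = 1 / (GAMMA_H * b1_list)^2, y = 1 / residuals)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         linetype = 2) +
    ggplot2::labs(x = "1 / omega1^2 (s^2 rad^-2)", y = "1 / residual",
                  subtitle = sprintf("k_ex = %.0f s^-1", fit$kex)) +
    ggplot2::theme_minimal()
}

#' @export
print.kex_map <- function(x, ...) {
  cat(sprintf("<kex_map> %d x %d voxels; %.1f%% valid; mean k_ex %.1f s^-1\n",
              nrow(x$kex), ncol(x$kex), 100 * x$qc$fraction_valid,
              mean(x$kex[x$valid_mask])))
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d grid, %d lesion(s), noise %.3g, seed %d\n",
              x$grid[1], x$grid[2], length(x$lesions), x$noise_sd, x$seed))
  invisible(x)
}
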