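# ggplot2 quick-look graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scan fit: data against the fitted model spectrum
#'
#' Log-log magnitude and phase of the cell-covered scan with the fitted
#' cell-electrode model overlaid, plus the cell-free scan with its
#' calibrated interface model.
#'
#' @param object An `ecis_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecis_fit
#' @export
autoplot.ecis_fit <- function(object, ...) {
  f <- object$data$covered$frequency_hz
  z_obs_c <- complex(real = object$data$covered$z_real_ohm,
                     imaginary = object$data$covered$z_imag_ohm)
  z_obs_f <- complex(real = object$data$free$z_real_ohm,
                     imaginary = object$data$free$z_imag_ohm)
  z_fit_c <- well_impedance(f, object$electrode, object$params, coverage = 1)
  z_fit_f <- well_impedance(f, object$electrode)
  df <- dplyr::bind_rows(
    tibble::tibble(frequency_hz = f, mag = Mod(z_obs_c),
                   phase = Arg(z_obs_c), state = "cell_covered", kind = "data"),
    tibble::tibble(frequency_hz = f, mag = Mod(z_fit_c),
                   phase = Arg(z_fit_c), state = "cell_covered", kind = "model"),
    tibble::tibble(frequency_hz = f, mag = Mod(z_obs_f),
                   phase = Arg(z_obs_f), state = "cell_free", kind = "data"),
    tibble::tibble(frequency_hz = f, mag = Mod(z_fit_f),
                   phase = Arg(z_fit_f), state = "cell_free", kind = "model")
  ) |>
    tidyr::pivot_longer(c("mag", "phase"), names_to = "channel")
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_hz, .data$value,
                                   colour = .data$state,
                                   linetype = .data$kind)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "model")) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$kind == "data"),
                        size = 1) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "|Z| (ohm) / phase (rad)",
                  title = sprintf("Rb=%.3g ohm cm2, h=%.3g nm, Cm=%.3g uF/cm2",
                                  object$params$rb_ohm_cm2,
                                  object$params$h_nm,
                                  object$params$cm_uf_cm2)) +
    ggplot2::theme_minimal()
}

#' Plot an adhesion-stage segmentation
#'
#' The trace with the per-stage fitted lines and the stage boundaries.
#'
#' @param object An `ecis_stages`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecis_stages
#' @export
autoplot.ecis_stages <- function(object, ...) {
  seg <- object$stages
  lines <- purrr::map_dfr(seq_len(nrow(seg)), function(k) {
    idx <- seg$start_idx[k]:seg$end_idx[k]
    tibble::tibble(stage = seg$stage[k],
                   time_h = object$data$time_h[idx],
                   fit = seg$intercept[k] + seg$slope[k] * object$data$time_h[idx])
  })
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(y = .data$fit, colour = .data$stage),
                       linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = object$breakpoints_h, linetype = 3) +
    ggplot2::labs(x = "time (h)", y = "value", colour = "stage") +
    ggplot2::theme_minimal()
}

#' Plot simulated or imported time series by substrate
#'
#' @param timeseries A time-series tibble (long dialect with a `substrate`
#'   column, as produced by [simulate_experiment()]).
#' @return A ggplot faceted by channel.
#' @export
plot_traces <- function(timeseries) {
  ggplot2::ggplot(timeseries,
                  ggplot2::aes(.data$time_h, .data$value,
                               colour = .data$substrate,
                               group = .data$well)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL, colour = "substrate") +
    ggplot2::theme_minimal()
}
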