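# ggplot2 visualization of spectra, band schemes and coherence profiles.

#' Plot a power spectrum
#'
#' One line per channel (log10 power). Supply a band scheme to shade the
#' individualized bands and mark the TF/IAF anchors.
#'
#' @param object A `psd_tbl` from [welch_psd()] (or a single-channel
#'   `freq`/`power` tibble).
#' @param scheme Optional [build_band_scheme()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psd_tbl <- function(object, scheme = NULL, ...) {
  df <- if ("channel" %in% names(object)) object
        else dplyr::mutate(object, channel = "avg")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                        group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
  if (!is.null(scheme)) {
    sch <- tibble::as_tibble(scheme)
    p <- p +
      ggplot2::geom_rect(
        data = sch, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$lo, xmax = .data$hi, fill = .data$band),
        ymin = -Inf, ymax = Inf, alpha = 0.15
      ) +
      ggplot2::geom_vline(xintercept = c(attr(scheme, "tf"),
                                         attr(scheme, "iaf")),
                          linetype = "dashed") +
      ggplot2::labs(fill = "band")
  }
  p
}

#' Plot a spectrum with its band scheme
#'
#' Convenience wrapper: electrode-averaged spectrum with shaded
#' individualized bands.
#'
#' @param ps A `psd_tbl` from [welch_psd()].
#' @param scheme A [build_band_scheme()] result.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(ps, scheme = NULL) {
  avg <- grand_average_spectrum(ps)
  class(avg) <- c("psd_tbl", class(avg))
  autoplot(avg, scheme = scheme)
}

#' Heatmap of a coherence profile
#'
#' Pair-by-band tile plot of band coherence, faceted by pair set.
#'
#' @param profile A [coherence_profile()] tibble (may hold several
#'   subjects; values are averaged).
#' @return A ggplot object.
#' @export
plot_coherence_profile <- function(profile) {
  df <- profile |>
    dplyr::group_by(.data$set, .data$pair, .data$band) |>
    dplyr::summarise(coherence = mean(.data$coherence), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$band, .data$pair,
                                   fill = .data$coherence)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~set, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "coherence")
}
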