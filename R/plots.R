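# ggplot2 displays for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wavelet-coherence result
#'
#' Time-period raster of squared coherence with the cone of influence
#' overlaid; cells inside the cone are faded. The y axis shows the
#' equivalent Fourier period on a log2 scale, long periods at the
#' bottom.
#'
#' @param object a `wtc_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.wtc_result <- function(object, ...) {
  df <- tidy(object)
  coi_df <- tibble::tibble(time_s = object$times,
                           period_s = pmin(object$coi, max(object$periods)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$period_s)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$coherence,
                                      alpha = ifelse(.data$in_coi, 0.35, 1))) +
    ggplot2::geom_line(data = coi_df, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_y_continuous(trans = c("log2", "reverse")) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "R²") +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = "Time (s)", y = "Period (s)") +
    ggplot2::theme_minimal()
}

#' Plot a time-averaged coherence profile
#'
#' @param object a `tac_profile`.
#' @param ... unused.
#' @return a ggplot of TAC against frequency (log10 x axis).
#' @export
autoplot.tac_profile <- function(object, ...) {
  df <- object[is.finite(object$tac), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$tac,
                                   colour = .data$quadrant)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Time-averaged coherence") +
    ggplot2::theme_minimal()
}

#' Plot a protocol schedule
#'
#' @param object a `protocol_schedule`.
#' @param ... unused.
#' @return a ggplot timeline of epochs.
#' @export
autoplot.protocol_schedule <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$onset_s,
                                    xmax = .data$onset_s + .data$duration_s,
                                    ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot axial slices of a CVR slope map
#'
#' @param maps a `cvr_maps` object.
#' @param what `"slope"`, `"tstat"` or `"p"`.
#' @param outline_significant draw significant voxels at full alpha and
#'   the rest faded (requires an attached `sig_mask`).
#' @return a ggplot faceted by slice.
#' @export
plot_cvr_slices <- function(maps, what = c("slope", "tstat", "p"),
                            outline_significant = TRUE) {
  what <- match.arg(what)
  df <- tidy(maps)
  df <- df[df$in_mask, ]
  fade <- if (outline_significant && !is.null(maps$sig_mask)) {
    ifelse(df$significant, 1, 0.35)
  } else 1
  df$alpha <- fade
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data[[what]],
                                   alpha = .data$alpha)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
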