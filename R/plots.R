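raster_df <- function(m, value_name = "value") {
  df <- data.frame(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  names(df)[3] <- value_name
  df
}

#' Plot a BOM map
#'
#' Raster view of a superpixel (or pixel-wise) BOM field; higher BOM means
#' higher resistivity.
#'
#' @param object An `lsfg_bom_map` from [superpixel_bom_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lsfg_bom_map <- function(object, ...) {
  df <- raster_df(object$map, "bom")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$bom)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "BOM", option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Superpixel BOM map") +
    ggplot2::theme_minimal()
}

#' Plot a superpixel labeling
#'
#' Shows superpixel boundaries over the label field.
#'
#' @param object An `lsfg_labeling` from [slic_segment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lsfg_labeling <- function(object, ...) {
  lab <- object$labels
  H <- nrow(lab)
  W <- ncol(lab)
  edge <- matrix(FALSE, H, W)
  edge[-H, ] <- edge[-H, ] | (lab[-H, ] != lab[-1, ])
  edge[, -W] <- edge[, -W] | (lab[, -W] != lab[, -1])
  df <- raster_df(lab, "label")
  df$edge <- as.vector(edge)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$label %% 7)),
                         show.legend = FALSE) +
    ggplot2::geom_point(data = df[df$edge, ], size = 0.1, colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d superpixels", object$n_labels)) +
    ggplot2::theme_minimal()
}

#' Plot a waveform power spectrum
#'
#' Spectral magnitude against frequency, with the cardiac band shaded when
#' the spectrum comes from a [bom()] result.
#'
#' @param object An `lsfg_spectrum` or `lsfg_waveform`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lsfg_spectrum <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$p)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$freq_hz, yend = 0)) +
    ggplot2::labs(x = "frequency (Hz)", y = "P(f)",
                  title = "Waveform power spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lsfg_spectrum
#' @export
autoplot.lsfg_waveform <- function(object, ...) {
  autoplot.lsfg_spectrum(object$spectrum) +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "red") +
    ggplot2::labs(subtitle = sprintf("BOM = %.3f (peak %.2f Hz)",
                                     object$bom, object$peak_freq_hz))
}

#' Plot a bias experiment
#'
#' Scatter of superpixel-method against rubber-band BOM per replicate, with
#' the identity line; points above the line show the superpixel bias.
#'
#' @param object An `lsfg_bias_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lsfg_bias_experiment <- function(object, ...) {
  df <- object$replicates
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bom_rb, y = .data$bom_sp)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "BOM (rubber band)", y = "BOM (superpixel)",
                  title = sprintf("mean bias %.4f, sign-test p = %.2g",
                                  object$mean_diff, object$p_value)) +
    ggplot2::theme_minimal()
}
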