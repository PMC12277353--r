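#' Plot spectra coloured by potassium content
#'
#' @param object A [spectra_set()].
#' @param max_samples Cap on the number of spectra drawn (default 50),
#'   sampled evenly across the potassium range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.spectra_set <- function(object, max_samples = 50, ...) {
  idx <- if (nrow(object) > max_samples) {
    order(object$potassium)[round(seq(1, nrow(object), length.out = max_samples))]
  } else {
    seq_len(nrow(object))
  }
  long <- as_tibble(object[idx, ]) |>
    tidyr::pivot_longer(-c("sample_id", "potassium"),
                        names_to = "wavelength", values_to = "reflectance") |>
    mutate(wavelength = as.numeric(.data$wavelength))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
                                     group = .data$sample_id,
                                     colour = .data$potassium)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "K (10 g/kg)") +
    ggplot2::labs(
      x = "wavelength (nm)",
      y = if (spectra_order(object) == 0) "reflectance"
          else sprintf("order-%g fractional derivative", spectra_order(object))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation surface
#'
#' Absolute band-potassium correlation per (differentiation order, band).
#'
#' @param object A `correlation_surface` from [correlation_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_surface <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$wavelength, .data$order,
                               fill = .data$abs_r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|r|", na.value = "grey80") +
    ggplot2::labs(x = "wavelength (nm)", y = "differentiation order") +
    ggplot2::theme_minimal()
}

#' Training/validation accuracy across differentiation orders
#'
#' @param object A `comparison_tbl` from [run_experiment()].
#' @param metric Metric column to draw (default `"r2"`).
#' @param ... Unused.
#' @return A ggplot object, faceted by model.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_tbl <- function(object, metric = "r2", ...) {
  ggplot2::ggplot(filter(object, is.na(.data$error)),
                  ggplot2::aes(.data$order, .data[[metric]],
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "differentiation order", y = metric) +
    ggplot2::theme_minimal()
}
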