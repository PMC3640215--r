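#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decomposition into one row per component
#'
#' @param x an [hft_decomposition][fastica_temporal].
#' @param ... unused.
#' @return tibble with `component`, `variance_explained` (share of the
#'   retained-subspace variance carried by the component's map) and
#'   `map_skewness`.
#' @export
tidy.hft_decomposition <- function(x, ...) {
  ve <- rowSums(x$spatial_maps^2)
  tibble::tibble(component = seq_len(x$n_ics),
                 variance_explained = ve / sum(x$singular_values^2 /
                                                 (nrow(x$ic_timecourses) - 1)),
                 map_skewness = apply(x$spatial_maps, 1, .skewness))
}

#' @rdname tidy.hft_decomposition
#' @export
glance.hft_decomposition <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs, n_ics = x$n_ics,
                 n_timepoints = nrow(x$ic_timecourses),
                 n_voxels = ncol(x$spatial_maps),
                 iterations = x$convergence$iterations,
                 contrast = x$convergence$contrast)
}

#' Tidy a component spectrum
#'
#' @param x an [hft_spectrum][component_spectrum].
#' @param ... unused.
#' @return the frequency/power grid as a tibble.
#' @export
tidy.hft_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freq, power = x$power)
}

#' Plot a component power spectrum
#'
#' Line plot of the segment-averaged periodogram with the band edges marked.
#'
#' @param object an [hft_spectrum][component_spectrum].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hft_spectrum <- function(object, ...) {
  df <- tidy.hft_spectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$band_edges, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = sprintf("peak at %.3f Hz", object$peak_freq)) +
    ggplot2::theme_minimal()
}

#' Plot the band-fraction fingerprint of all components
#'
#' Scatter of the lowest high-frequency band fraction (0.25-0.5 Hz) against
#' the 0.75-1.0 Hz fraction, the two axes that separate RSN-like components
#' and technical artifacts from the rest, coloured by assigned label.
#'
#' @param object an [hft_characterization][characterize] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hft_characterization <- function(object, ...) {
  fr_cols <- grep("^frac_", names(object), value = TRUE)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[fr_cols[1]]],
                               y = .data[[fr_cols[3]]],
                               colour = .data$label,
                               shape = .data$keep)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "fraction 0.25-0.5 Hz", y = "fraction 0.75-1.0 Hz") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a component spatial map
#'
#' @param d an [hft_decomposition][fastica_temporal].
#' @param component component number.
#' @param slice slice index along the third axis.
#' @param voxel_index V x 3 voxel coordinates for the map columns.
#' @return a ggplot raster.
#' @export
plot_component_map <- function(d, component, slice, voxel_index) {
  stopifnot(inherits(d, "hft_decomposition"))
  w <- d$spatial_maps[component, ]
  sel <- voxel_index[, 3] == slice
  df <- tibble::tibble(x = voxel_index[sel, 1], y = voxel_index[sel, 2],
                       weight = w[sel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("IC %d, slice %d", component, slice)) +
    ggplot2::theme_minimal()
}
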