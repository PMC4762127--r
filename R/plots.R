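#' Plot a free-energy landscape
#'
#' Tile plot of bin free energies over (native, non-native) base-pair
#' counts, with local minima marked.
#'
#' @param object A `kf_landscape` from [landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kf_landscape <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$native, y = .data$nonnative)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$free_energy)) +
    ggplot2::geom_point(data = object[object$minimum, ],
                        shape = 4, size = 3, stroke = 1.2) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)",
                                  direction = -1) +
    ggplot2::labs(x = "native base pairs (N)",
                  y = "non-native base pairs (NN)") +
    ggplot2::theme_minimal()
}

#' Plot a melting profile
#'
#' Bound fraction and species populations against temperature.
#'
#' @param object A `kf_melting` from [melting_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kf_melting <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("bound_fraction", "p_kissing", "p_extended_duplex",
              "p_unbound"),
    names_to = "series", values_to = "population")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$temperature - 273.15,
                                     y = .data$population,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)", y = "population",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the coil-entropy fit
#'
#' ln(conformation count) against chain length with the fitted line and
#' the linear coil model for comparison.
#'
#' @param n_range Chain lengths to enumerate (kept small; exhaustive).
#' @return A ggplot object.
#' @export
plot_coil_fit <- function(n_range = 4:10) {
  tab <- enumerate_free_coil(max(n_range))
  tab <- tab[tab$n_nt %in% n_range, ]
  fit <- coil_slope(n_range)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_nt, y = .data$ln_omega)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::geom_abline(slope = 2.05, intercept = 0.1, linetype = 2) +
    ggplot2::labs(x = "chain length (nt)", y = "ln ω") +
    ggplot2::theme_minimal()
}
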