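#' Plot a Morse fit over its scan points
#'
#' @param object A [fit_morse()] result.
#' @param ... Unused.
#' @return A ggplot: scan energies as points, fitted Morse curve as a line.
#' @method autoplot morse_fit
#' @export
autoplot.morse_fit <- function(object, ...) {
  grid <- seq(min(object$data$distance), max(object$data$distance),
              length.out = 400)
  fit_df <- tibble(distance = grid, energy = predict(object, grid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$distance, .data$energy)) +
    ggplot2::geom_point(colour = "firebrick", size = 1.4) +
    ggplot2::geom_line(data = fit_df, colour = "black") +
    ggplot2::labs(x = "r [Å]", y = expression(Delta * E ~ "[kJ/mol]"),
                  title = "Electronic dissociation energy and Morse fit") +
    ggplot2::theme_minimal()
}

#' Plot a descriptor fit over its normalized values
#'
#' @param object A [fit_descriptor()] result.
#' @param ... Unused.
#' @return A ggplot of the normalized descriptor and its exponential fit.
#' @method autoplot descriptor_fit
#' @export
autoplot.descriptor_fit <- function(object, ...) {
  grid <- seq(object$r_min, object$r_max, length.out = 400)
  fit_df <- tibble(distance = grid, value = predict(object, grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$distance, .data$normalized_value)) +
    ggplot2::geom_point(colour = "steelblue", size = 1.4) +
    ggplot2::geom_line(data = fit_df,
                       ggplot2::aes(.data$distance, .data$value),
                       colour = "black") +
    ggplot2::labs(x = "r [Å]", y = "normalized descriptor",
                  title = sprintf("Descriptor decay fit (%s)", object$name)) +
    ggplot2::theme_minimal()
}

#' Plot an assembled free-energy curve
#'
#' Shows the Gibbs curve with its Morse and sigmoid components, the cleavage
#' distance and, when present, the transition state.
#'
#' @param object A `free_energy_result`.
#' @param components Overlay the Morse and entropy components (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot free_energy_result
#' @export
autoplot.free_energy_result <- function(object, components = TRUE, ...) {
  cv <- object$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(.data$r, .data$delta_g)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$sigmoid$r_cleave,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "r [Å]", y = expression(Delta * G ~ "[kJ/mol]"),
                  title = "Assembled Gibbs free-energy curve") +
    ggplot2::theme_minimal()
  if (components) {
    comp <- tibble(
      r = rep(cv$r, 2),
      value = c(predict(object$morse, cv$r),
                entropy_sigmoid(cv$r, object$sigmoid) - object$offset),
      component = rep(c("Morse (electronic)", "-T dS (sigmoid)"),
                      each = nrow(cv))
    )
    p <- p + ggplot2::geom_line(data = comp,
                                ggplot2::aes(.data$r, .data$value,
                                             colour = .data$component),
                                linetype = "dashed", linewidth = 0.5) +
      ggplot2::scale_colour_manual(
        values = c("Morse (electronic)" = "firebrick",
                   "-T dS (sigmoid)" = "forestgreen"), name = NULL)
  }
  if (!isTRUE(object$no_barrier) && !is.na(object$r_ts)) {
    ts_df <- tibble(r = object$r_ts, delta_g = .eval_curve(object, object$r_ts))
    p <- p + ggplot2::geom_point(data = ts_df, shape = 18, size = 3,
                                 colour = "darkorange")
  }
  p
}

#' @importFrom rlang .data
NULL
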