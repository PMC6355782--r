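#' Plot methods
#'
#' Each result type has an `autoplot()` method returning a ggplot:
#' density profiles, pair distributions, free-energy profiles,
#' entropy/enthalpy decompositions and MSD curves.
#'
#' @param object A memlens result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name memlens-plots
NULL

#' @rdname memlens-plots
#' @export
autoplot.membrane_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z relative to bilayer center (nm)",
                  y = expression(density ~ (amu / nm^3)), colour = "group")
}

#' @rdname memlens-plots
#' @export
autoplot.pair_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "g(r)",
                  subtitle = paste0("mode: ", attr(object, "mode")))
}

#' @rdname memlens-plots
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(object[object$defined, ],
                  ggplot2::aes(x = .data$r, y = .data$dG)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = expression(Delta * G ~ (kJ / mol)),
                  subtitle = attr(object, "reference"))
}

#' @rdname memlens-plots
#' @export
autoplot.thermo_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(object[object$defined, c("r", "dG", "minus_TdS", "dH")],
                              -"r", names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "kJ/mol", colour = NULL)
}

#' @rdname memlens-plots
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$msd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$msd - .data$se,
                                      ymax = .data$msd + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tau ~ (ns)), y = expression(MSD ~ (nm^2)),
                  subtitle = paste0("axes: ", paste(attr(object, "axes"),
                                                    collapse = "")))
}

#' @rdname memlens-plots
#' @export
autoplot.pair_axis_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$density,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial coordinate (nm)", y = "linear density (1/nm)",
                  colour = NULL)
}
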