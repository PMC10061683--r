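# ggplot2 views of trajectories, FFS results, fits, and the model surfaces.

#' @export
autoplot.fh_trajectory <- function(object, cv = "x", ...) {
  sn <- object$snapshots
  sn$cv <- cv_of(cv_weights(cv), sn)
  sn$state <- factor(sn$active_state)
  ggplot2::ggplot(sn, ggplot2::aes(x = .data$time, y = .data$cv,
                                   colour = .data$state, group = 1)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = "time (reduced units)",
                  y = if (is.character(cv)) cv else "collective variable",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fh_ffs <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$lambda)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$P), fill = "steelblue",
                      width = diff(range(s$lambda)) / (2 * nrow(s))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_product /
                                      max(.data$cum_product))) +
    ggplot2::labs(x = "interface position", y = "crossing probability",
                  subtitle = sprintf("k_AB = %.3g +/- %.2g", object$k_AB,
                                     object$dk_AB)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fh_fit <- function(object, ...) {
  d <- object$data
  if (object$tag == "landau-zener") {
    xs <- seq(0, max(d$gap) * 1.05, length.out = 200)
    curve <- tibble(x = xs, y = landau_zener_rate(object, xs))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gap, y = .data$rate))
    xl <- "adiabatic gap g"
  } else {
    xs <- seq(min(1 / d$temperature), max(1 / d$temperature),
              length.out = 100)
    est <- setNames(object$params$estimate, object$params$term)
    Ea <- if ("E_a_eff" %in% names(est)) est[["E_a_eff"]] else
      attr(object, "activation_energy") %||% NA_real_
    curve <- tibble(x = xs, y = est[["nu"]] * exp(-Ea * xs))
    d$gap <- NULL
    p <- ggplot2::ggplot(d, ggplot2::aes(x = 1 / .data$temperature,
                                         y = .data$rate))
    xl <- "1 / T"
  }
  p +
    ggplot2::geom_point() +
    { if ("rate_err" %in% names(d))
        ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data$rate - 2 * .data$rate_err,
          ymax = .data$rate + 2 * .data$rate_err), width = 0) } +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xl, y = "rate constant") +
    ggplot2::theme_minimal()
}

#' Plot the adiabatic surfaces of a model
#'
#' The avoided-crossing model is drawn as energy curves along x; the
#' conical-intersection model as a filled contour map of the lower
#' adiabatic surface over (x, y).
#'
#' @param model A `fh_model`.
#' @param xlim,ylim Plot ranges.
#' @param n Grid resolution.
#' @return A ggplot object.
#' @export
plot_surface <- function(model, xlim = NULL, ylim = NULL, n = 151) {
  if (model$type == 0L) {
    xlim <- xlim %||% c(-2.2, 2.2)
    xs <- seq(xlim[1], xlim[2], length.out = n)
    ad <- cpp_eval_model(as_cpp_model(model), cbind(xs, 0, 0))
    d <- tibble(x = rep(xs, 2),
                energy = c(ad$adiabatic[, 1], ad$adiabatic[, 2]),
                state = rep(c("lower", "upper"), each = n))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$energy,
                                    colour = .data$state)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "adiabatic energy") +
      ggplot2::theme_minimal()
  } else {
    xlim <- xlim %||% c(-4.5, 4.5); ylim <- ylim %||% c(-4.5, 4.5)
    g <- expand.grid(x = seq(xlim[1], xlim[2], length.out = n),
                     y = seq(ylim[1], ylim[2], length.out = n))
    ad <- cpp_eval_model(as_cpp_model(model), cbind(g$x, g$y, 0))
    g$energy <- ad$adiabatic[, 1]
    ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y,
                                    z = .data$energy)) +
      ggplot2::geom_contour_filled(bins = 14, show.legend = FALSE) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  }
}
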