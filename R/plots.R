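#' Plot a Gaussian error profile
#'
#' Draws the normal density defined by the profile's mean and standard
#' deviation over the percent-error axis, with a rug of the individual
#' errors.
#'
#' @param object An [error_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_profile <- function(object, ...) {
  sd <- max(object$delta_std, 1e-3)
  lo <- min(object$errors, object$delta_av - 4 * sd)
  hi <- max(object$errors, object$delta_av + 4 * sd)
  grid <- tibble::tibble(error = seq(lo, hi, length.out = 400))
  grid$density <- object$density(grid$error)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$error, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_rug(data = tibble::tibble(error = object$errors),
                      ggplot2::aes(x = .data$error), inherit.aes = FALSE,
                      alpha = 0.6) +
    ggplot2::labs(
      x = if (object$signed) "signed relative error (%)" else
        "unsigned relative error (%)",
      y = "density",
      title = sprintf("Error profile: mean %.3f%%, sd %.3f%% (n = %d)",
                      object$delta_av, object$delta_std, length(object$errors))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the convergence trace of a geometry refit
#'
#' Penalty value against iteration, on a log scale. Requires the refit to
#' have been run with `trace = TRUE`.
#'
#' @param object A `refit_result` with a trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refit_result <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("refit was run without `trace = TRUE`; nothing to plot", call. = FALSE)
  }
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$penalty)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "penalty S",
                  title = "Gradient-descent convergence") +
    ggplot2::theme_minimal()
}

#' Plot a molecular geometry
#'
#' Projects the geometry onto its two largest-extent principal axes and
#' draws perceived bonds as segments, atoms as labeled points.
#'
#' @param object A [geometry()].
#' @param ... Passed to [perceive_bonds()].
#' @return A ggplot object.
#' @export
autoplot.molecular_geometry <- function(object, ...) {
  xyz <- coords_matrix(object)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  pc <- svd(xyz, nu = 0, nv = 2)$v
  uv <- xyz %*% pc
  atoms <- tibble::tibble(u = uv[, 1], v = uv[, 2], element = object$element)
  bonds <- perceive_bonds(object, ...)
  seg <- tibble::tibble(u = uv[bonds$i, 1], v = uv[bonds$i, 2],
                        uend = uv[bonds$j, 1], vend = uv[bonds$j, 2])
  ggplot2::ggplot(atoms, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$u, y = .data$v,
                                       xend = .data$uend, yend = .data$vend),
                          inherit.aes = FALSE, color = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$element),
                       nudge_y = 0.12, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "principal axis 1 (A)", y = "principal axis 2 (A)",
                  title = geometry_label(object)) +
    ggplot2::theme_minimal()
}
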