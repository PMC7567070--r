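#' @describeIn compute_rmsd RMSD-vs-time line plot.
#' @param object result object to plot.
#' @export
autoplot.rmsd_series <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$rmsd)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_value, linetype = "dashed") +
    ggplot2::labs(x = "time (ps)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' @describeIn compute_rmsf per-atom RMSF profile plot.
#' @param object result object to plot.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$resid, .data$rmsf)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' @describeIn rmsf_to_bfactor per-residue B-factor profile plot.
#' @param object result object to plot.
#' @export
autoplot.bfactor_profile <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$resid, .data$bfactor)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "residue", y = expression(B ~ (ring(A)^2)) ) +
    ggplot2::theme_minimal()
}

#' @describeIn compute_pseudo_dihedral angle-vs-time plot.
#' @param object result object to plot.
#' @export
autoplot.dihedral_series <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$angle)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "time (ps)", y = "pseudo-dihedral (deg)") +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_angles histogram with the circular mean marked.
#' @param object result object to plot.
#' @param ... unused.
#' @export
autoplot.angle_distribution <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$bin_center, .data$density)) +
    ggplot2::geom_col(width = object$bin_width, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$circular_mean, linetype = "dashed") +
    ggplot2::labs(x = "pseudo-dihedral (deg)", y = "density (1/deg)") +
    ggplot2::theme_minimal()
}

#' @describeIn cgi_estimate forward and negated-backward work densities with
#'   the estimated crossing marked (call on a [work_set()]).
#' @param object a `work_set`.
#' @param ... unused.
#' @export
autoplot.work_set <- function(object, ...) {
  d <- tibble::tibble(
    work = c(object$forward, -object$backward),
    direction = rep(c("forward", "reverse (negated)"),
                    c(length(object$forward), length(object$backward)))
  )
  g <- fit_gaussians(object)
  dg <- cgi_point(g$forward$mu, g$forward$sd, g$reverse$mu, g$reverse$sd)$dg
  ggplot2::ggplot(d, ggplot2::aes(.data$work, fill = .data$direction)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            alpha = 0.5, position = "identity", bins = 30) +
    ggplot2::geom_vline(xintercept = dg, linetype = "dashed") +
    ggplot2::labs(x = "work (kJ/mol)", y = "density") +
    ggplot2::theme_minimal()
}
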