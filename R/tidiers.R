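#' @describeIn compute_rmsd tidy the per-frame values into a tibble.
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy.rmsd_series <- function(x, ...) x$data

#' @describeIn compute_rmsd one-row summary (mean, frame count, flags).
#' @export
glance.rmsd_series <- function(x, ...) {
  tibble::tibble(mean_rmsd = x$mean_value, n_frames = nrow(x$data),
                 fitted = x$fitted, mass_weighted = x$mass_weighted,
                 window_start = x$mean_window[1], window_end = x$mean_window[2])
}

#' @describeIn compute_rmsf tidy per-atom RMSF values.
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy.rmsf_profile <- function(x, ...) x$data

#' @describeIn compute_rmsf one-row summary of the profile.
#' @export
glance.rmsf_profile <- function(x, ...) {
  tibble::tibble(n_atoms = nrow(x$data), mean_rmsf = mean(x$data$rmsf),
                 max_rmsf = max(x$data$rmsf),
                 window_start = x$window[1], window_end = x$window[2],
                 averaging_time = x$averaging_time)
}

#' @describeIn rmsf_to_bfactor tidy per-atom B-factors.
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy.bfactor_profile <- function(x, ...) x$data

#' @describeIn rmsf_to_bfactor one-row summary of the B-factor profile.
#' @export
glance.bfactor_profile <- function(x, ...) {
  tibble::tibble(n_atoms = nrow(x$data), mean_bfactor = mean(x$data$bfactor),
                 max_bfactor = max(x$data$bfactor))
}

#' @describeIn compute_pseudo_dihedral tidy the angle time series.
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy.dihedral_series <- function(x, ...) x$data

#' @describeIn compute_pseudo_dihedral one-row circular summary of the series.
#' @export
glance.dihedral_series <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$data),
                 circular_mean = circular_mean(x$data$angle),
                 circular_sd = circular_sd(x$data$angle))
}

#' @describeIn summarize_angles tidy the histogram table.
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy.angle_distribution <- function(x, ...) x$data

#' @describeIn summarize_angles one-row distribution summary.
#' @export
glance.angle_distribution <- function(x, ...) {
  tibble::tibble(n = x$n, bin_width = x$bin_width,
                 arithmetic_mean = x$arithmetic_mean,
                 circular_mean = x$circular_mean, circular_sd = x$circular_sd,
                 mode_bin_center = x$mode_bin_center,
                 window_start = x$window[1], window_end = x$window[2])
}

#' @describeIn compare_distributions one-row shift summary.
#' @param x object to summarise.
#' @param ... unused.
#' @export
glance.angle_shift <- function(x, ...) {
  tibble::tibble(delta_circular_mean = x$delta_circular_mean,
                 delta_mode = x$delta_mode, sd_ratio = x$sd_ratio,
                 overlap = x$overlap, left_shifted = x$left_shifted)
}

#' @describeIn compare_distributions alias of `glance()` for shift summaries.
#' @export
tidy.angle_shift <- function(x, ...) glance.angle_shift(x, ...)

#' @describeIn cgi_estimate one-row estimate summary.
#' @param x object to summarise.
#' @param ... unused.
#' @export
glance.free_energy_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, dg = x$dg, stderr = x$stderr,
                 ci_lo = x$ci95[1], ci_hi = x$ci95[2],
                 n_forward = x$n_forward, n_backward = x$n_backward,
                 temperature = x$temperature, overlap = x$diagnostics$overlap)
}

#' @describeIn cgi_estimate alias of `glance()`.
#' @export
tidy.free_energy_estimate <- function(x, ...) glance.free_energy_estimate(x, ...)

#' @describeIn double_difference one-row double-difference summary.
#' @param x object to summarise.
#' @param ... unused.
#' @export
glance.ddg_estimate <- function(x, ...) {
  tibble::tibble(label = x$label, ddg = x$ddg, stderr = x$stderr,
                 ci_lo = x$ci95[1], ci_hi = x$ci95[2], mode = x$mode,
                 interpretation = x$interpretation)
}

#' @describeIn double_difference alias of `glance()`.
#' @export
tidy.ddg_estimate <- function(x, ...) glance.ddg_estimate(x, ...)

#' @describeIn fit_gaussians tidy the two fitted Gaussians (one row each).
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy.gaussian_fit_pair <- function(x, ...) {
  tibble::tibble(direction = c("forward", "reverse"),
                 mu = c(x$forward$mu, x$reverse$mu),
                 sd = c(x$forward$sd, x$reverse$sd),
                 n = c(x$forward$n, x$reverse$n))
}
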