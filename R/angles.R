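#' Circular mean of angles in degrees
#' @param x angles in degrees.
#' @return circular mean in degrees, in (-180, 180].
#' @export
circular_mean <- function(x) {
  r <- deg2rad(x)
  wrap_angle(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Circular standard deviation of angles in degrees
#'
#' Computed as \eqn{\sqrt{-2 \ln \bar R}} where \eqn{\bar R} is the mean
#' resultant length, converted to degrees.
#' @param x angles in degrees.
#' @return circular standard deviation in degrees.
#' @export
circular_sd <- function(x) {
  r <- deg2rad(x)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(rbar, 1)
  rad2deg(sqrt(-2 * log(rbar)))
}

# Shortest signed angular difference a - b, in (-180, 180].
circular_diff <- function(a, b) wrap_angle(a - b)

#' Windowed distribution summary of a dihedral series
#'
#' Histograms the in-window angles on a fixed grid anchored at 0 degrees
#' (edges at integer multiples of `bin_width`), and reports the arithmetic
#' mean on the (-180, 180] branch, the circular mean, the circular standard
#' deviation, and the center of the most populated bin (ties broken toward
#' the bin nearer the circular mean).
#'
#' @param series a `dihedral_series`.
#' @param window `c(t0, t1)` in ps, or `NULL` for all frames. Typical use
#'   mirrors MD practice of summarising the equilibrated tail of a run
#'   (e.g. the last 30 ns).
#' @param bin_width histogram bin width in degrees; default 1.
#' @return an `angle_distribution`: list with `data` (tibble `bin_center`,
#'   `count`, `density` per degree), `window`, `bin_width`, `n`,
#'   `arithmetic_mean`, `circular_mean`, `circular_sd`, `mode_bin_center`.
#' @export
summarize_angles <- function(series, window = NULL, bin_width = 1) {
  stopifnot(inherits(series, "dihedral_series"))
  if (!is_scalar_number(bin_width) || bin_width <= 0)
    stopf("bin_width must be a positive number")
  times <- series$data$time
  window <- if (is.null(window)) range(times) else as.numeric(window)
  ang <- series$data$angle[times >= window[1] & times <= window[2]]
  if (length(ang) == 0L) stopf("window [%g, %g] ps contains no frames",
                               window[1], window[2])
  ang <- wrap_angle(ang)

  lo <- bin_width * floor(-180 / bin_width)
  hi <- bin_width * ceiling(180 / bin_width)
  edges <- seq(lo, hi, by = bin_width)
  # bins are (edge, edge + width]; values exactly at the lowest edge cannot
  # occur because angles live in (-180, 180] and lo <= -180
  bin <- findInterval(ang, edges, left.open = TRUE, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  centers <- edges[-length(edges)] + bin_width / 2

  cmean <- circular_mean(ang)
  top <- which(counts == max(counts))
  mode_center <- centers[top[which.min(abs(circular_diff(centers[top], cmean)))]]

  structure(list(
    data = tibble::tibble(bin_center = centers, count = counts,
                          density = counts / (length(ang) * bin_width)),
    window = window, bin_width = bin_width, n = length(ang),
    arithmetic_mean = mean(ang), circular_mean = cmean,
    circular_sd = circular_sd(ang), mode_bin_center = mode_center
  ), class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf(
    "<angle_distribution> n = %d, circular mean %.1f deg (sd %.1f), mode bin %.1f deg\n",
    x$n, x$circular_mean, x$circular_sd, x$mode_bin_center))
  invisible(x)
}

#' Compare two angle distributions
#'
#' Quantifies how the distribution `x` is displaced relative to `reference`:
#' the shortest signed difference of circular means and of mode bins, the
#' ratio of circular standard deviations, and the overlap coefficient of the
#' normalised histograms. A negative mean shift beyond `shift_tolerance`
#' raises the `left_shifted` flag (the reading used for a helix pair whose
#' torsion distribution moves to smaller angles).
#'
#' @param x the `angle_distribution` under test.
#' @param reference the reference `angle_distribution`; must share the bin
#'   grid of `x`.
#' @param shift_tolerance degrees below which a mean shift is not called a
#'   left shift; default 0.5.
#' @return an `angle_shift`: list with `delta_circular_mean`, `delta_mode`
#'   (degrees, x minus reference), `sd_ratio` (x / reference),
#'   `overlap` (in [0, 1]), `left_shifted`.
#' @export
compare_distributions <- function(x, reference, shift_tolerance = 0.5) {
  stopifnot(inherits(x, "angle_distribution"),
            inherits(reference, "angle_distribution"))
  if (x$bin_width != reference$bin_width ||
      !isTRUE(all.equal(x$data$bin_center, reference$data$bin_center)))
    stopf("distributions are on different bin grids")
  d_mean <- circular_diff(x$circular_mean, reference$circular_mean)
  structure(list(
    delta_circular_mean = d_mean,
    delta_mode = circular_diff(x$mode_bin_center, reference$mode_bin_center),
    sd_ratio = x$circular_sd / reference$circular_sd,
    overlap = sum(pmin(x$data$count / x$n, reference$data$count / reference$n)),
    left_shifted = d_mean < -shift_tolerance
  ), class = "angle_shift")
}

#' @export
print.angle_shift <- function(x, ...) {
  cat(sprintf(
    "<angle_shift> d(mean) = %+.2f deg, d(mode) = %+.2f deg, sd ratio %.2f, overlap %.3f%s\n",
    x$delta_circular_mean, x$delta_mode, x$sd_ratio, x$overlap,
    if (x$left_shifted) " [left-shifted]" else ""))
  invisible(x)
}
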