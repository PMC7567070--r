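#' Root-mean-square fluctuation profile
#'
#' Measures, for each selected atom, the deviation about its time-averaged
#' position over a window:
#' \deqn{RMSF_i = [ (1/T) \sum_{t_j} | r_i(t_j) - r_i^{ref} |^2 ]^{1/2}}
#' where the reference positions \eqn{r_i^{ref}} are the window-mean
#' coordinates. With `fit = TRUE` internal fluctuations are separated from
#' rigid-body motion by one fixed-point iteration: frames are first fitted to
#' the first in-window frame, the mean structure is computed, and frames are
#' refitted to that mean before averaging.
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms to profile; default `"calpha"`.
#' @param window `c(t0, t1)` in ps, or `NULL` for the full trajectory. The
#'   window must contain at least 2 frames.
#' @param fit remove rigid-body motion first? Default `TRUE`.
#' @param mass_weighted use mass weights in the superposition? Default `TRUE`.
#' @return an `rmsf_profile`: list with `data` (tibble `index`, `serial`,
#'   `name`, `resid`, `chain`, `rmsf`), `window` (ps), `reference_positions`
#'   (window-mean coordinates), `averaging_time` (ps).
#' @export
compute_rmsf <- function(traj, selection = "calpha", window = NULL,
                         fit = TRUE, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- resolve_selection(traj, selection)
  idx <- sel$indices
  window <- if (is.null(window)) range(traj$times) else as.numeric(window)
  frames <- which(traj$times >= window[1] & traj$times <= window[2])
  if (length(frames) == 0L) stopf("window [%g, %g] ps is outside the trajectory",
                                  window[1], window[2])
  if (length(frames) < 2L) stopf("RMSF window must contain at least 2 frames")

  m <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  x <- lapply(frames, function(k) traj_frame(traj, k)[idx, , drop = FALSE])
  if (fit) {
    x <- lapply(x, function(xk)
      apply_transform(xk, kabsch_fit(xk, x[[1]], weights = m)$transform))
    mean1 <- Reduce(`+`, x) / length(x)
    x <- lapply(x, function(xk)
      apply_transform(xk, kabsch_fit(xk, mean1, weights = m)$transform))
  }
  ref <- Reduce(`+`, x) / length(x)
  msd <- Reduce(`+`, lapply(x, function(xk) rowSums((xk - ref)^2))) / length(x)

  a <- traj$atoms[idx, , drop = FALSE]
  structure(list(
    data = tibble::tibble(index = idx, serial = a$serial, name = a$name,
                          resid = a$resid, chain = a$chain, rmsf = sqrt(msd)),
    window = window, reference_positions = ref,
    averaging_time = diff(range(traj$times[frames])),
    selection = sel, fitted = fit
  ), class = "rmsf_profile")
}

#' Convert an RMSF profile to Debye-Waller B-factors
#'
#' Applies the crystallographic identity \eqn{B_i = (8/3)\,\pi^2\,RMSF_i^2}
#' per atom. Large B-factors indicate highly flexible atoms.
#'
#' @param profile an `rmsf_profile` from [compute_rmsf()].
#' @return a `bfactor_profile`: list with `data` (the profile tibble plus a
#'   `bfactor` column, Angstrom^2) and `source` (the input profile).
#' @export
rmsf_to_bfactor <- function(profile) {
  stopifnot(inherits(profile, "rmsf_profile"))
  d <- profile$data
  d$bfactor <- (8 / 3) * pi^2 * d$rmsf^2
  structure(list(data = d, source = profile), class = "bfactor_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf_profile> %d atoms, window [%g, %g] ps, mean %.3f A\n",
              nrow(x$data), x$window[1], x$window[2], mean(x$data$rmsf)))
  invisible(x)
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat(sprintf("<bfactor_profile> %d atoms, mean B %.2f A^2\n",
              nrow(x$data), mean(x$data$bfactor)))
  invisible(x)
}
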