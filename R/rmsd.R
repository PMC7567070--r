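#' Root-mean-square deviation time series
#'
#' For every frame, optionally superposes the selected atoms onto the
#' reference with a weighted Kabsch fit, then evaluates
#' \deqn{RMSD(t) = [ (1/M) \sum_i m_i | r_i(t) - r_i^{ref} |^2 ]^{1/2}}
#' with \eqn{M = \sum_i m_i}. With `mass_weighted = FALSE` all \eqn{m_i = 1}.
#' By default the fit uses the same atom set and weights as the RMSD itself.
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms to fit and measure (expression, `atom_selection`,
#'   or indices); default `"backbone"`.
#' @param reference `"first_frame"` (the starting conformation) or an
#'   `md_structure` with the same atom count.
#' @param fit superpose each frame before measuring? Default `TRUE`.
#' @param mass_weighted weight by atomic masses? Default `TRUE`.
#' @param mean_window optional `c(t0, t1)` (ps) over which `mean_value` is
#'   reported; default the full series.
#' @return an `rmsd_series`: list with `data` (tibble `time`, `rmsd`),
#'   `selection`, `fitted`, `mass_weighted`, `mean_value`, `mean_window`.
#' @export
compute_rmsd <- function(traj, selection = "backbone",
                         reference = "first_frame",
                         fit = TRUE, mass_weighted = TRUE,
                         mean_window = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- resolve_selection(traj, selection)
  idx <- sel$indices
  ref <- reference_coords(traj, reference, idx)
  m <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  w <- m / sum(m)

  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xk <- traj_frame(traj, k)[idx, , drop = FALSE]
    if (fit) xk <- apply_transform(xk, kabsch_fit(xk, ref, weights = m)$transform)
    sqrt(sum(w * rowSums((xk - ref)^2)))
  }, numeric(1))

  window <- if (is.null(mean_window)) range(traj$times) else as.numeric(mean_window)
  in_win <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(in_win)) stopf("mean_window contains no frames")
  structure(list(
    data = tibble::tibble(time = traj$times, rmsd = vals),
    selection = sel, fitted = fit, mass_weighted = mass_weighted,
    mean_value = mean(vals[in_win]), mean_window = window
  ), class = "rmsd_series")
}

reference_coords <- function(traj, reference, idx) {
  if (identical(reference, "first_frame"))
    return(traj_frame(traj, 1)[idx, , drop = FALSE])
  if (inherits(reference, "md_structure")) {
    if (nrow(reference$coords) == length(idx)) return(reference$coords)
    if (nrow(reference$coords) == nrow(traj$atoms))
      return(reference$coords[idx, , drop = FALSE])
    stopf("reference has %d atoms; expected %d (selection) or %d (trajectory)",
          nrow(reference$coords), length(idx), nrow(traj$atoms))
  }
  stopf("reference must be \"first_frame\" or an md_structure")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %d frames, mean %.3f A (%s%s)\n",
              nrow(x$data), x$mean_value,
              if (x$fitted) "fitted" else "unfitted",
              if (x$mass_weighted) ", mass-weighted" else ""))
  invisible(x)
}
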