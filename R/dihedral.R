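#' Specify a four-atom pseudo-dihedral quadruple
#'
#' The default quadruple is the helix-orientation metric for a RAS-like
#' GTPase: Calpha atoms of residues 67 and 74 (on the alpha2 helix) and 104
#' and 87 (on the alpha3 helix), evaluated in exactly that listed order.
#' Author (PDB) residue numbering is used as-is.
#'
#' @param resid integer vector of 4 residue numbers, in torsion order.
#' @param name atom name(s), recycled to length 4; default `"CA"`.
#' @param chain optional chain id(s), recycled to length 4; `NA` matches any.
#' @return a `dihedral_quadruple`.
#' @export
dihedral_quadruple <- function(resid = c(67L, 74L, 104L, 87L),
                               name = "CA", chain = NA_character_) {
  if (length(resid) != 4L) stopf("a quadruple needs exactly 4 residues")
  structure(list(resid = as.integer(resid),
                 name = rep_len(name, 4L),
                 chain = rep_len(chain, 4L)),
            class = "dihedral_quadruple")
}

#' @export
print.dihedral_quadruple <- function(x, ...) {
  cat(sprintf("<dihedral_quadruple> %s\n",
              paste(sprintf("%d:%s", x$resid, x$name), collapse = " -> ")))
  invisible(x)
}

resolve_quadruple <- function(traj, quadruple) {
  a <- atom_table(traj)
  idx <- vapply(seq_len(4L), function(i) {
    hit <- which(a$resid == quadruple$resid[i] & a$name == quadruple$name[i] &
                 (is.na(quadruple$chain[i]) | a$chain == quadruple$chain[i]))
    if (length(hit) == 0L)
      stopf("quadruple atom %d (resid %d, name %s) not found",
            i, quadruple$resid[i], quadruple$name[i])
    if (length(hit) > 1L)
      stopf("quadruple atom %d (resid %d, name %s) is ambiguous (%d matches)",
            i, quadruple$resid[i], quadruple$name[i], length(hit))
    hit
  }, integer(1))
  if (anyDuplicated(idx)) stopf("quadruple must resolve to 4 distinct atoms")
  idx
}

# Torsion of ordered points p1..p4: signed angle between plane(p1,p2,p3) and
# plane(p2,p3,p4), IUPAC convention, degrees in (-180, 180].
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) return(NA_real_)
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  wrap_angle(rad2deg(atan2(y, x)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pseudo-dihedral time series over a trajectory
#'
#' Evaluates the torsion of the quadruple's four atoms in every frame. As a
#' pure internal coordinate it needs no superposition and is invariant under
#' rigid motion of the whole frame; mirror-imaging the coordinates negates it.
#'
#' @param traj an `md_trajectory`.
#' @param quadruple a [dihedral_quadruple()].
#' @return a `dihedral_series`: list with `data` (tibble `time`, `angle` in
#'   degrees, range (-180, 180]) and `quadruple`. Collinear geometry in any
#'   frame is an error naming the frame.
#' @export
compute_pseudo_dihedral <- function(traj, quadruple = dihedral_quadruple()) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- resolve_quadruple(traj, quadruple)
  ang <- vapply(seq_len(n_frames(traj)), function(k) {
    p <- traj_frame(traj, k)[idx, , drop = FALSE]
    torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  }, numeric(1))
  if (anyNA(ang))
    stopf("undefined torsion (collinear points) in frame %d", which(is.na(ang))[1])
  new_dihedral_series(traj$times, ang, quadruple)
}

new_dihedral_series <- function(times, angles, quadruple) {
  structure(list(data = tibble::tibble(time = times, angle = angles),
                 quadruple = quadruple),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> %d frames, circular mean %.1f deg\n",
              nrow(x$data), circular_mean(x$data$angle)))
  invisible(x)
}
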