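# Standard atomic masses (amu) for the elements that occur in protein PDB files.
ATOMIC_MASS <- setNames(
  c(1.008, 2.014, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971, 55.845,
    65.38, 24.305, 40.078, 22.990, 39.098, 35.45, 54.938, 18.998),
  c("H", "D", "C", "N", "O", "S", "P", "SE", "FE",
    "ZN", "MG", "CA", "NA", "K", "CL", "MN", "F")
)

# Infer the element symbol from a PDB atom name when columns 77-78 are blank.
# PDB atom names right-pad the element: " CA " is carbon-alpha (C), "CA  "
# in a calcium HETATM would carry the element field instead.
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    s <- sub("^[0-9']+", "", nm[i])
    first <- substr(s, 1, 1)
    out[i] <- if (first %in% c("C", "N", "O", "S", "P", "H")) first else first
  }
  out
}

mass_of <- function(element) {
  el <- toupper(trimws(element))
  m <- unname(ATOMIC_MASS[el])
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    stopf("no mass tabulated for element(s): %s", paste(bad, collapse = ", "))
  }
  m
}

new_atom_table <- function(serial, name, element, resname, resid, chain,
                           occupancy = 1, altloc = "") {
  name <- trimws(name)
  element <- toupper(trimws(element))
  stopifnot(all(nzchar(name)), all(is.finite(resid)))
  tibble::tibble(
    serial = as.integer(serial),
    name = name,
    element = element,
    resname = as.character(resname),
    resid = as.integer(resid),
    chain = as.character(chain),
    mass = mass_of(element),
    occupancy = as.numeric(occupancy),
    altloc = as.character(altloc)
  )
}

#' Construct a static structure
#'
#' A structure is an ordered atom table plus an N x 3 coordinate matrix in
#' Angstrom. It is the single-frame counterpart of [md_trajectory()].
#'
#' @param atoms atom table built with the package readers or generators
#'   (columns `serial`, `name`, `element`, `resname`, `resid`, `chain`,
#'   `mass`, `occupancy`, `altloc`).
#' @param coords numeric N x 3 matrix of coordinates (Angstrom).
#' @param meta optional named list of provenance metadata.
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms, coords, meta = list()) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stopf("coords must be a numeric N x 3 matrix")
  if (nrow(coords) != nrow(atoms))
    stopf("coords has %d rows but atom table has %d", nrow(coords), nrow(atoms))
  if (!all(is.finite(coords))) stopf("non-finite coordinates")
  if (any(atoms$mass <= 0)) stopf("atom masses must be positive")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, meta = meta),
            class = "md_structure")
}

#' Construct a trajectory
#'
#' A trajectory shares one atom table across F frames of coordinates.
#'
#' @param atoms atom table (see [md_structure()]).
#' @param coords numeric F x N x 3 array of coordinates (Angstrom).
#' @param times numeric vector of F strictly increasing time stamps (ps).
#' @param meta optional named list of provenance metadata.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords, times = NULL, meta = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stopf("coords must be an F x N x 3 array")
  f <- dim(coords)[1]; n <- dim(coords)[2]
  if (f < 1L) stopf("trajectory needs at least one frame")
  if (n != nrow(atoms))
    stopf("frames have %d atoms but atom table has %d", n, nrow(atoms))
  if (!all(is.finite(coords))) stopf("non-finite coordinates")
  if (is.null(times)) times <- seq_len(f) - 1
  times <- as.numeric(times)
  if (length(times) != f) stopf("need one time stamp per frame")
  if (f > 1L && any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = times, meta = meta),
            class = "md_trajectory")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %d atoms, %d residues\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), nrow(x$atoms), x$times[1], tail(x$times, 1)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[1]
}

#' Extract one frame of a trajectory as an N x 3 matrix
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return numeric N x 3 matrix.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"), i >= 1, i <= n_frames(traj))
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Promote a structure to a one-frame trajectory
#' @param x an `md_structure` or `md_trajectory`.
#' @return an `md_trajectory`.
#' @export
as_trajectory <- function(x) {
  if (inherits(x, "md_trajectory")) return(x)
  stopifnot(inherits(x, "md_structure"))
  md_trajectory(x$atoms, array(x$coords, c(1L, dim(x$coords))),
                times = 0, meta = x$meta)
}

atom_table <- function(x) {
  if (inherits(x, c("md_structure", "md_trajectory"))) x$atoms
  else if (is.data.frame(x)) x
  else stopf("expected an md_structure, md_trajectory or atom table")
}
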