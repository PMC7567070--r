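#' Read a (possibly multi-MODEL) PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]; on top of it this reader
#' resolves alternate locations to the highest-occupancy conformer (ties go to
#' altloc "A", then first seen), infers the element from columns 77-78 or the
#' atom name, and assigns standard atomic masses. Multi-MODEL files read with
#' `model_policy = "all"` become a trajectory with one frame per MODEL;
#' PDB has no time field, so frame times default to 0, 1, 2, ... ps unless
#' `times` is given.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` returns an `md_structure` from the first
#'   MODEL; `"all"` returns an `md_trajectory` with one frame per MODEL.
#' @param times optional numeric vector of frame times (ps) for
#'   `model_policy = "all"`.
#' @return an [md_structure()] or [md_trajectory()].
#' @export
read_pdb <- function(path, model_policy = c("first", "all"), times = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stopf("file not found: %s", path)
  check_model_atom_counts(path)
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_policy == "all",
                                     hex = TRUE, verbose = FALSE)),
    error = function(e) stopf("PDB parse error in %s: %s", path, conditionMessage(e))
  )
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stopf("no ATOM records in %s", path)
  keep <- which(p$atom$type == "ATOM")[resolve_altloc(at)]
  at <- p$atom[keep, , drop = FALSE]

  elesy <- at$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[blank] <- infer_element(at$elety[blank])
  atoms <- new_atom_table(
    serial = at$eleno, name = at$elety, element = elesy,
    resname = at$resid, resid = at$resno, chain = ifelse(is.na(at$chain), "", at$chain),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )

  xyz_cols <- bio3d::atom2xyz(keep)
  if (model_policy == "all") {
    xyz <- p$xyz[, xyz_cols, drop = FALSE]
    f <- nrow(xyz)
    coords <- array(NA_real_, c(f, nrow(atoms), 3L))
    for (k in seq_len(f)) coords[k, , ] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    if (is.null(times)) times <- seq_len(f) - 1
    md_trajectory(atoms, coords, times = times, meta = list(source = path))
  } else {
    xyz <- if (is.matrix(p$xyz)) p$xyz[1, xyz_cols] else p$xyz[xyz_cols]
    md_structure(atoms, matrix(xyz, ncol = 3, byrow = TRUE),
                 meta = list(source = path, model = 1L))
  }
}

# Validate that every MODEL block has the same number of ATOM records,
# naming the offending model (bio3d silently recycles otherwise).
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2L) return(invisible(TRUE))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stopf("unbalanced MODEL/ENDMDL records in %s", path)
  counts <- mapply(function(s, e) sum(rec[s:e] == "ATOM  "), model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stopf("MODEL %d has %d ATOM records but MODEL 1 has %d",
          bad, counts[bad], counts[1])
  }
  invisible(TRUE)
}

# Keep one conformer per atom: highest occupancy, ties to altloc "A",
# then first seen. Returns row indices into the ATOM-only table.
resolve_altloc <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (all(!nzchar(alt))) return(seq_len(nrow(at)))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, alt != "A", seq_len(nrow(at)))
  sort(ord[!duplicated(key[ord])])
}

#' Write a structure or trajectory as a (multi-MODEL) PDB file
#'
#' One MODEL block per frame. PDB coordinate fields are fixed-width (8.3), so
#' a read/write round trip preserves coordinates to 3 decimals and any
#' coordinate of magnitude >= 10^4 Angstrom is a format error.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  traj <- as_trajectory(x)
  if (max(abs(traj$coords)) >= 1e4)
    stopf("coordinate magnitude >= 10^4 Angstrom cannot be written in PDB fixed width")
  a <- traj$atoms
  f <- n_frames(traj)
  xyz <- matrix(NA_real_, f, 3L * nrow(a))
  for (k in seq_len(f)) xyz[k, ] <- as.vector(t(traj_frame(traj, k)))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
    eleno = a$serial, elety = a$name, resid = a$resname, chain = a$chain,
    resno = a$resid, o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

#' Read a plain-text trajectory table
#'
#' A diff-friendly fixture format: one row per (frame, atom) with columns
#' `frame`, optional `time` (ps), `name`, optional `resname`, `resid`,
#' optional `chain`, `x`, `y`, `z` (Angstrom). Comma- or whitespace-separated;
#' a header row is required. When the `time` column is absent, frame times
#' default to 0, 1, 2, ... ps with a warning.
#'
#' @param path path to the table.
#' @return an [md_trajectory()] (single-frame tables give F = 1).
#' @export
read_xyz_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("frame", "name", "resid", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("trajectory table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  frames <- sort(unique(d$frame))
  per <- table(d$frame)
  if (length(unique(per)) > 1L)
    stopf("ragged trajectory table: frames have differing atom counts (%s)",
          paste(unique(per), collapse = ", "))
  d <- d[order(match(d$frame, frames)), , drop = FALSE]
  n <- unname(per[1]); f <- length(frames)
  a0 <- d[d$frame == frames[1], , drop = FALSE]
  atoms <- new_atom_table(
    serial = seq_len(n), name = a0$name, element = infer_element(a0$name),
    resname = if ("resname" %in% names(d)) a0$resname else "ALA",
    resid = a0$resid, chain = if ("chain" %in% names(d)) a0$chain else "A"
  )
  coords <- array(NA_real_, c(f, n, 3L))
  for (k in seq_len(f)) {
    dk <- d[d$frame == frames[k], , drop = FALSE]
    coords[k, , ] <- cbind(dk$x, dk$y, dk$z)
  }
  if ("time" %in% names(d)) {
    times <- vapply(frames, function(fr) d$time[d$frame == fr][1], numeric(1))
  } else {
    warning("no time column; defaulting frame times to 0, 1, 2, ... ps")
    times <- seq_len(f) - 1
  }
  md_trajectory(atoms, coords, times = times, meta = list(source = path))
}
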