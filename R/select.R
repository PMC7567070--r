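#' Select atoms by a small expression grammar
#'
#' Expressions are clauses joined with `and`; each clause is one of
#' \itemize{
#'   \item a preset: `all`, `heavy`, `calpha` (Calpha atoms) or `backbone`
#'     (protein backbone N, CA, C, O) -- presets exclude hydrogens;
#'   \item `name <A> <B> ...` -- atom names;
#'   \item `resid <spec> ...` -- residue numbers, single (`67`) or ranges
#'     (`10:20` or `10-20`);
#'   \item `chain <A> <B> ...` -- chain identifiers.
#' }
#' Resolution is deterministic: indices are sorted, unique, and independent of
#' clause order.
#'
#' @param x an `md_structure`, `md_trajectory`, or atom table.
#' @param expression selection string, e.g. `"resid 67 74 87 104 and calpha"`.
#' @return an `atom_selection`: list with `expression` and sorted 1-based
#'   `indices`. Selecting zero atoms is an error (metrics must never silently
#'   run on an empty set).
#' @export
select_atoms <- function(x, expression = "all") {
  atoms <- atom_table(x)
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) keep <- keep & clause_mask(atoms, trimws(cl))
  idx <- which(keep)
  if (length(idx) == 0L)
    stopf("selection '%s' matches no atoms", expression)
  structure(list(expression = expression, indices = sort(unique(idx))),
            class = "atom_selection")
}

clause_mask <- function(atoms, clause) {
  if (!nzchar(clause)) stopf("empty selection clause")
  toks <- strsplit(clause, "\\s+")[[1]]
  key <- tolower(toks[1])
  args <- toks[-1]
  switch(key,
    all = rep(TRUE, nrow(atoms)),
    heavy = atoms$element != "H",
    calpha = atoms$name == "CA" & atoms$element != "H",
    backbone = atoms$name %in% c("N", "CA", "C", "O") & atoms$element != "H",
    name = {
      if (!length(args)) stopf("'name' clause needs at least one atom name")
      atoms$name %in% args
    },
    resid = {
      if (!length(args)) stopf("'resid' clause needs at least one residue")
      atoms$resid %in% parse_resid_spec(args)
    },
    chain = {
      if (!length(args)) stopf("'chain' clause needs at least one chain id")
      atoms$chain %in% args
    },
    stopf("unknown selection clause: '%s'", clause)
  )
}

parse_resid_spec <- function(args) {
  out <- integer(0)
  for (a in args) {
    if (grepl("^-?[0-9]+[:-][0-9]+$", a)) {
      parts <- as.integer(strsplit(a, "[:-]")[[1]])
      out <- c(out, seq(parts[1], parts[2]))
    } else if (grepl("^-?[0-9]+$", a)) {
      out <- c(out, as.integer(a))
    } else stopf("cannot parse residue spec '%s'", a)
  }
  unique(out)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

# Accept a selection object, an expression string, or raw indices.
resolve_selection <- function(x, selection) {
  if (inherits(selection, "atom_selection")) return(selection)
  if (is.character(selection)) return(select_atoms(x, selection))
  if (is.numeric(selection)) {
    n <- nrow(atom_table(x))
    idx <- sort(unique(as.integer(selection)))
    if (any(idx < 1L) || any(idx > n)) stopf("selection indices out of range")
    if (!length(idx)) stopf("empty selection")
    return(structure(list(expression = "<indices>", indices = idx),
                     class = "atom_selection"))
  }
  stopf("selection must be an atom_selection, expression string, or indices")
}
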