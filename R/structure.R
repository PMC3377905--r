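#' Multi-chain structure objects
#'
#' A `complex_structure` holds one conformation of a multi-chain protein
#' complex: an identifier plus a tidy atom table with one row per heavy atom.
#' Objects are created by [read_pdb()] and [make_synthetic_native()]; the atom
#' table is recovered with [tibble::as_tibble()].
#'
#' The atom table has columns `chain`, `resno`, `ins` (insertion code, `""`
#' when absent), `resname`, `elety` (atom name), `elesy` (element symbol),
#' `x`, `y`, `z` (Angstrom) and `occ` (occupancy).  Rows are ordered by chain
#' (order of first appearance), then residue, then atom.
#'
#' @param id Character label for the structure.
#' @param atoms Atom tibble as described above.
#'
#' @return A `complex_structure` object.
#' @keywords internal
new_complex_structure <- function(id, atoms) {
  required <- c("chain", "resno", "ins", "resname", "elety", "elesy",
                "x", "y", "z", "occ")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "fpair_validation_error")
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("atom coordinates must be finite", class = "fpair_validation_error")
  }
  structure(list(id = id, atoms = as_tibble(atoms)),
            class = "complex_structure")
}

#' @export
as_tibble.complex_structure <- function(x, ...) x$atoms

#' @export
print.complex_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("<complex_structure> ", x$id, "\n", sep = "")
  cat("  chains:  ", paste(chain_ids(x), collapse = " "), "\n", sep = "")
  cat("  residues:", nrow(res), "  atoms:", nrow(x$atoms), "\n")
  invisible(x)
}

#' Chain identifiers of a structure
#'
#' @param x A `complex_structure`.
#' @return Character vector of chain ids in structure order.
#' @export
#' @examples
#' s <- make_synthetic_native(n_chains = 3, residues_per_chain = 12)
#' chain_ids(s)
chain_ids <- function(x) {
  stopifnot(inherits(x, "complex_structure"))
  unique(x$atoms$chain)
}

#' Number of chains in a structure
#'
#' @param x A `complex_structure`.
#' @return Integer chain count.
#' @export
n_chains <- function(x) length(chain_ids(x))

# One row per residue, in atom-table order.
residue_table <- function(x) {
  dplyr::distinct(x$atoms, .data$chain, .data$resno, .data$ins, .data$resname)
}

# Atom subset for one chain (optionally one atom-name scope), as a tibble.
chain_atoms <- function(x, chain, elety = NULL) {
  out <- x$atoms[x$atoms$chain == chain, , drop = FALSE]
  if (!is.null(elety)) out <- out[out$elety %in% elety, , drop = FALSE]
  out
}

# Coordinate matrix (n x 3) from an atom tibble.
coord_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# Atom names making up a measurement scope.
scope_atoms <- function(atom_scope = c("backbone", "calpha")) {
  atom_scope <- match.arg(atom_scope)
  if (atom_scope == "backbone") c("N", "CA", "C", "O") else "CA"
}
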