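# In-code fixtures: small hand-written PDB texts and structure editors.

write_pdb_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", ins = " ", element = "C",
                          record = "ATOM  ") {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name)),
          alt, resname, chain, resno, ins, x, y, z, occ, 0, element)
}

# Rigidly translate one chain in place (no randomness) — used where a test
# needs an exactly known perturbation.
translate_chain <- function(structure, chain, shift) {
  atoms <- tibble::as_tibble(structure)
  sel <- atoms$chain == chain
  atoms$x[sel] <- atoms$x[sel] + shift[1]
  atoms$y[sel] <- atoms$y[sel] + shift[2]
  atoms$z[sel] <- atoms$z[sel] + shift[3]
  fpair:::new_complex_structure(paste0(structure$id, "_shifted"), atoms)
}

# Apply a proper rigid transform to every atom of a structure.
transform_structure <- function(structure, rotation, translation) {
  atoms <- tibble::as_tibble(structure)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  atoms[, c("x", "y", "z")] <- as.data.frame(xyz)
  fpair:::new_complex_structure(structure$id, atoms)
}

# Relabel chains of a structure (used for chain-mapping tests).
relabel_chains <- function(structure, map) {
  atoms <- tibble::as_tibble(structure)
  atoms$chain <- unname(map[atoms$chain])
  fpair:::new_complex_structure(structure$id, atoms)
}

random_rotation_matrix <- function() {
  axis <- stats::rnorm(3)
  fpair:::rotation_about_axis(axis, stats::runif(1, 0, 360))
}
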