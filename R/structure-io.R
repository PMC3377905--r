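#' Read a multi-chain structure from a PDB file
#'
#' Parses ATOM records into a [complex_structure][new_complex_structure],
#' applying the deterministic filtering rules used throughout the package:
#'
#' * HETATM records, waters and hydrogens (element H/D) are excluded;
#' * only the first MODEL of a multi-model file is read;
#' * alternate locations are resolved per atom to the highest-occupancy
#'   variant, ties broken by the lexicographically smallest altloc code;
#' * residues lacking a C-alpha atom are dropped with a warning, so truncated
#'   termini do not abort an evaluation.
#'
#' @param path Path to a PDB file.
#' @param id Structure label; defaults to the file name without extension.
#'
#' @return A `complex_structure`.  Errors if the file is unreadable, contains
#'   no parsable ATOM records, or holds fewer than two chains.
#' @export
#' @seealso [write_pdb()], [common_residues()]
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "fpair_io_error")
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))

  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) {
      abort(paste0("failed to parse ", path, ": ", conditionMessage(e)),
            class = "fpair_format_error")
    }
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) {
    abort(paste0("no ATOM records in ", path), class = "fpair_format_error")
  }

  atoms <- tibble(
    chain   = as.character(at$chain),
    resno   = as.integer(at$resno),
    ins     = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = as.character(at$resid),
    elety   = as.character(at$elety),
    alt     = ifelse(is.na(at$alt), "", as.character(at$alt)),
    elesy   = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o)
  )
  atoms$chain[is.na(atoms$chain)] <- " "

  # waters and hydrogens out; element fallback from the atom name when the
  # element column is blank (e.g. "1HB" -> H)
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD", "H2O")), ,
                 drop = FALSE]
  elem <- atoms$elesy
  blank <- elem == ""
  elem[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atoms$elety[blank])
  atoms <- atoms[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) {
    abort(paste0("no protein heavy atoms in ", path),
          class = "fpair_format_error")
  }

  # altloc: keep the highest-occupancy variant of each atom, ties broken by
  # the smallest altloc code (the empty code sorts first); file order of the
  # surviving atoms is preserved
  atoms$.row <- seq_len(nrow(atoms))
  atoms <- atoms %>%
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$elety) %>%
    dplyr::arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$.row)
  atoms$alt <- NULL

  # drop residues without a C-alpha
  keys <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  ca_keys <- unique(keys[atoms$elety == "CA"])
  n_drop <- length(unique(keys)) - length(ca_keys)
  if (n_drop > 0) {
    warn(paste0(id, ": dropped ", n_drop,
                " residue(s) lacking a C-alpha atom"))
    atoms <- atoms[keys %in% ca_keys, , drop = FALSE]
  }

  chains <- unique(atoms$chain)
  if (length(chains) < 2) {
    abort(paste0(path, ": need at least 2 chains, found ", length(chains)),
          class = "fpair_validation_error")
  }

  atoms <- atoms %>%
    dplyr::arrange(match(.data$chain, chains), .data$resno, .data$ins)
  atoms$.row <- NULL
  new_complex_structure(id, atoms)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM records (wwPDB v3.3 columns, coordinates
#' to three decimals), one TER record per chain, and a terminating END
#' record, so output round-trips through [read_pdb()].
#'
#' @param structure A `complex_structure`.
#' @param path Output file path.
#'
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "complex_structure"))
  atoms <- structure$atoms
  if (nrow(atoms) == 0) {
    abort("cannot write a structure with no atoms",
          class = "fpair_validation_error")
  }
  per_chain <- table(atoms$chain)
  if (any(per_chain == 0)) {
    abort("empty chain in structure", class = "fpair_validation_error")
  }

  # atom-name column convention: names of 1-3 characters start in column 14
  fmt_name <- function(name) {
    ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
  }
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    rec <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial + seq_len(nrow(sub)), fmt_name(sub$elety), sub$resname,
      substr(ch, 1, 1), sub$resno,
      ifelse(sub$ins == "", " ", substr(sub$ins, 1, 1)),
      sub$x, sub$y, sub$z, sub$occ, 0, sub$elesy)
    serial <- serial + nrow(sub)
    last <- sub[nrow(sub), ]
    ter <- sprintf("TER   %5d      %-3s %1s%4d%1s",
                   serial + 1L, last$resname, substr(ch, 1, 1), last$resno,
                   ifelse(last$ins == "", " ", substr(last$ins, 1, 1)))
    serial <- serial + 1L
    lines <- c(lines, rec, ter)
  }
  lines <- c(lines, "END")
  tryCatch(writeLines(lines, path),
           error = function(e) abort(paste0("cannot write ", path, ": ",
                                            conditionMessage(e)),
                                     class = "fpair_io_error"))
  invisible(path)
}

#' Residues shared by two structures
#'
#' Determines, per mapped chain pair, the residue identifiers
#' (`resno`, `ins`) present in both structures.  All downstream comparisons
#' (global RMSD, iRMSD, fnat) are restricted to this intersection so a decoy
#' with truncated termini or internal gaps is still comparable to the native.
#'
#' @param a,b `complex_structure` objects (conventionally native and decoy).
#' @param mapping Named character vector mapping chain ids of `a` to chain
#'   ids of `b`; defaults to the identity over the chains of `a`.
#'
#' @return A tibble with columns `chain_a`, `chain_b`, `resno`, `ins`,
#'   ascending within each chain pair.  Errors, naming the chains, if any
#'   mapped pair has an empty intersection.
#' @export
#' @examples
#' s <- make_synthetic_native(n_chains = 2, residues_per_chain = 12)
#' nrow(common_residues(s, s))  # every residue pairs with itself
common_residues <- function(a, b, mapping = NULL) {
  stopifnot(inherits(a, "complex_structure"), inherits(b, "complex_structure"))
  if (is.null(mapping)) {
    mapping <- setNames(chain_ids(a), chain_ids(a))
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort("mapping must be a named character vector (chains of a -> b)",
          class = "fpair_validation_error")
  }
  if (anyDuplicated(mapping) || anyDuplicated(names(mapping))) {
    abort("mapping must be bijective", class = "fpair_validation_error")
  }
  missing_a <- setdiff(names(mapping), chain_ids(a))
  missing_b <- setdiff(unname(mapping), chain_ids(b))
  if (length(missing_a) || length(missing_b)) {
    abort(paste0("mapping names chains absent from the structures: ",
                 paste(c(missing_a, missing_b), collapse = ", ")),
          class = "fpair_validation_error")
  }

  res_a <- residue_table(a)
  res_b <- residue_table(b)
  out <- purrr::map_dfr(names(mapping), function(ca) {
    cb <- unname(mapping[[ca]])
    ra <- res_a[res_a$chain == ca, c("resno", "ins")]
    rb <- res_b[res_b$chain == cb, c("resno", "ins")]
    shared <- dplyr::inner_join(ra, rb, by = c("resno", "ins"))
    if (nrow(shared) == 0) {
      abort(paste0("no shared residues between chain ", ca, " of ", a$id,
                   " and chain ", cb, " of ", b$id),
            class = "fpair_validation_error")
    }
    shared <- shared[order(shared$resno, shared$ins), , drop = FALSE]
    tibble(chain_a = ca, chain_b = cb,
           resno = shared$resno, ins = shared$ins)
  })
  out
}
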