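#' Enumerate unordered chain pairs
#'
#' All N(N-1)/2 unordered chain pairs of a complex, in deterministic
#' lexicographic order — the set P over which fpair is defined.
#'
#' @param x A `complex_structure`, or a character vector of chain ids.
#' @return A tibble with columns `chain_x`, `chain_y` (`chain_x` <
#'   `chain_y`).
#' @export
#' @examples
#' enumerate_pairs(c("A", "B", "C"))  # A-B, A-C, B-C
enumerate_pairs <- function(x) {
  ids <- if (inherits(x, "complex_structure")) chain_ids(x) else
    as.character(x)
  ids <- sort(unique(ids))
  if (length(ids) < 2) {
    abort("need at least 2 chains to form pairs",
          class = "fpair_validation_error")
  }
  cmb <- utils::combn(ids, 2)
  tibble(chain_x = cmb[1, ], chain_y = cmb[2, ])
}

#' Interface residues of a native chain pair
#'
#' The docking interface of an unordered chain pair, defined on the native
#' structure: every residue of one chain having any heavy atom within
#' `contact_cutoff` of any heavy atom of the partner chain, together with the
#' symmetric set.  10 Angstrom is the CAPRI interface convention.
#'
#' @param native A `complex_structure` (the reference).
#' @param chain_x,chain_y Chain ids of the pair (order irrelevant).
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom.
#' @return An `interface_definition`: list with `chain_x`, `chain_y`,
#'   `contact_cutoff` and `residues`, a tibble (`chain`, `resno`, `ins`).
#'   The residue tibble is empty when the chains do not approach within the
#'   cutoff anywhere.
#' @export
native_interface <- function(native, chain_x, chain_y, contact_cutoff = 10) {
  stopifnot(inherits(native, "complex_structure"))
  pr <- sort(c(chain_x, chain_y))
  missing <- setdiff(pr, chain_ids(native))
  if (length(missing) > 0) {
    abort(paste0("chain(s) not in ", native$id, ": ",
                 paste(missing, collapse = ", ")),
          class = "fpair_validation_error")
  }
  ax <- chain_atoms(native, pr[1])
  ay <- chain_atoms(native, pr[2])
  d2 <- cross_dist2(coord_matrix(ax), coord_matrix(ay))
  hit <- d2 <= contact_cutoff^2

  res <- dplyr::bind_rows(
    dplyr::distinct(ax[rowSums(hit) > 0, c("chain", "resno", "ins")]),
    dplyr::distinct(ay[colSums(hit) > 0, c("chain", "resno", "ins")])
  )
  structure(
    list(chain_x = pr[1], chain_y = pr[2],
         contact_cutoff = contact_cutoff, residues = res),
    class = "interface_definition")
}

#' @export
print.interface_definition <- function(x, ...) {
  cat("<interface_definition> ", x$chain_x, "-", x$chain_y,
      ": ", nrow(x$residues), " residue(s) at ", x$contact_cutoff,
      " A cutoff\n", sep = "")
  invisible(x)
}

#' Interface RMSD of one chain pair
#'
#' The iRMSD of a decoy chain pair against the corresponding native pair:
#' the atoms of the native interface residues (backbone N, CA, C, O by
#' default) are collected from both structures in identical order, the
#' decoy's are superposed onto the native's by least squares using only this
#' pair's atoms — chains outside the pair play no role — and the minimized
#' RMSD is reported.  A pair with iRMSD strictly below `hit_threshold`
#' (4 Angstrom, the CAPRI acceptable-prediction criterion) is a hit.
#'
#' When the native pair has no interface at the cutoff (or too few shared
#' interface atoms to superpose), the whole-pair fallback is applied: all
#' in-scope atoms of both chains are superposed instead and the result is
#' flagged `used_fallback`, so non-contacting pairs still enter the fpair
#' denominator.
#'
#' @param native,decoy `complex_structure` objects on the same chain ids
#'   (apply [resolve_chain_mapping()]/[apply_chain_mapping()] first if the
#'   decoy is labelled differently).
#' @param chain_x,chain_y Chain ids of the pair.
#' @param interface Optional precomputed [native_interface()]; computed at
#'   `interface_cutoff` when omitted.
#' @param atom_scope `"backbone"` (N, CA, C, O) or `"calpha"`.
#' @param hit_threshold Hit criterion in Angstrom (strict `<`).
#' @param interface_cutoff Cutoff used when `interface` is omitted.
#' @param common Optional precomputed [common_residues()] table; computed
#'   for the two chains when omitted.
#'
#' @return A one-row tibble: `chain_x`, `chain_y`, `irmsd`,
#'   `n_interface_residues`, `n_atoms`, `is_hit`, `used_fallback`.
#' @export
pair_irmsd <- function(native, decoy, chain_x, chain_y,
                       interface = NULL,
                       atom_scope = c("backbone", "calpha"),
                       hit_threshold = 4,
                       interface_cutoff = 10,
                       common = NULL) {
  scope <- scope_atoms(atom_scope)
  pr <- sort(c(chain_x, chain_y))
  if (is.null(interface)) {
    interface <- native_interface(native, pr[1], pr[2], interface_cutoff)
  }
  if (is.null(common)) {
    common <- common_residues(native, decoy,
                              mapping = setNames(pr, pr))
  }
  common <- common[common$chain_a %in% pr, , drop = FALSE]

  # native interface residues, restricted to residues present in both
  iface <- dplyr::semi_join(
    interface$residues,
    dplyr::rename(common[, c("chain_a", "resno", "ins")],
                  chain = "chain_a"),
    by = c("chain", "resno", "ins"))

  paired <- paired_scope_atoms(native, decoy, iface, scope)
  used_fallback <- FALSE
  n_iface_res <- nrow(iface)
  if (nrow(paired$native) < 3) {
    # whole-pair fallback: every shared residue of both chains
    whole <- tibble(chain = common$chain_a, resno = common$resno,
                    ins = common$ins)
    paired <- paired_scope_atoms(native, decoy, whole, scope)
    used_fallback <- TRUE
    n_iface_res <- 0L
    if (nrow(paired$native) < 3) {
      abort(paste0("pair ", pr[1], "-", pr[2],
                   ": too few shared atoms to compute an iRMSD"),
            class = "fpair_undefined_metric_error")
    }
  }

  fit <- kabsch_superpose(paired$decoy, paired$native)
  tibble(
    chain_x = pr[1], chain_y = pr[2],
    irmsd = fit$rmsd,
    n_interface_residues = n_iface_res,
    n_atoms = fit$n_points,
    is_hit = fit$rmsd < hit_threshold,
    used_fallback = used_fallback)
}

# In-scope atoms of the given residues, paired between native and decoy in
# one deterministic order. `residues`: tibble(chain, resno, ins).
paired_scope_atoms <- function(native, decoy, residues, scope) {
  pick <- function(s) {
    at <- s$atoms[s$atoms$elety %in% scope, , drop = FALSE]
    dplyr::semi_join(at, residues, by = c("chain", "resno", "ins"))
  }
  joined <- dplyr::inner_join(
    pick(native), pick(decoy),
    by = c("chain", "resno", "ins", "elety"),
    suffix = c("_nat", "_dec"))
  joined <- joined[order(joined$chain, joined$resno, joined$ins,
                         match(joined$elety, scope)), , drop = FALSE]
  list(
    native = as.matrix(joined[, c("x_nat", "y_nat", "z_nat")]),
    decoy  = as.matrix(joined[, c("x_dec", "y_dec", "z_dec")]))
}

#' Fraction of native contacts of one chain pair
#'
#' fnat: native contacts are residue pairs — one residue from each chain —
#' with any heavy-atom distance at or below `contact_cutoff` (5 Angstrom,
#' the CAPRI convention) in the native structure; the returned value is the
#' fraction of those contacts also present in the decoy, computed over the
#' residues shared by the two structures.
#'
#' @inheritParams pair_irmsd
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom.
#' @return A fraction in 0..1, or `NA` when the native pair has no contacts.
#' @export
pair_fnat <- function(native, decoy, chain_x, chain_y, contact_cutoff = 5,
                      common = NULL) {
  pr <- sort(c(chain_x, chain_y))
  for (s in list(native, decoy)) {
    missing <- setdiff(pr, chain_ids(s))
    if (length(missing) > 0) {
      abort(paste0("chain(s) not in ", s$id, ": ",
                   paste(missing, collapse = ", ")),
            class = "fpair_validation_error")
    }
  }
  if (is.null(common)) {
    common <- common_residues(native, decoy, mapping = setNames(pr, pr))
  }
  common <- common[common$chain_a %in% pr, , drop = FALSE]
  keep <- tibble(chain = common$chain_a, resno = common$resno,
                 ins = common$ins)

  contacts <- function(s) {
    ax <- dplyr::semi_join(chain_atoms(s, pr[1]), keep,
                           by = c("chain", "resno", "ins"))
    ay <- dplyr::semi_join(chain_atoms(s, pr[2]), keep,
                           by = c("chain", "resno", "ins"))
    d2 <- cross_dist2(coord_matrix(ax), coord_matrix(ay))
    hit <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
    unique(paste(ax$resno[hit[, 1]], ax$ins[hit[, 1]],
                 ay$resno[hit[, 2]], ay$ins[hit[, 2]], sep = "\r"))
  }
  nat <- contacts(native)
  if (length(nat) == 0) return(NA_real_)
  dec <- contacts(decoy)
  length(intersect(nat, dec)) / length(nat)
}

# Squared Euclidean cross-distance matrix between two n x 3 matrices.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}
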