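#' Build a synthetic multi-chain native complex
#'
#' Constructs an artificial native structure from compact poly-alanine
#' chains — three-segment helix-turn-helix-turn-helix bundles with ideal
#' backbone bond lengths and angles (N, CA, C, O per residue) and seeded
#' per-residue torsion variation, so every chain is conformationally
#' unique and globular rather than rod-like.  Chains are laid out so that
#' adjacent chains in the arrangement touch at exactly `inter_chain_gap`:
#'
#' * `"ring"`: chains tangent to a circle whose radius is solved so the
#'   nearest adjacent-chain atoms sit `inter_chain_gap` apart (for 3
#'   chains every pair is adjacent, so every pair has a non-empty 10
#'   Angstrom interface);
#' * `"line"`: chains head-to-tail along x, so exactly the N-1 adjacent
#'   pairs are in contact and non-adjacent pairs exercise the
#'   non-contacting-pair fallback of [pair_irmsd()].
#'
#' Chains are labelled A, B, C, ... and numbered 1..n; the randomness —
#' per-chain torsion variation and a roll about the chain's long axis —
#' varies the structure with `seed` without affecting the contact
#' guarantees.  Output is byte-stable: the same spec and seed always give
#' the identical structure.
#'
#' @param n_chains Number of chains (>= 2).
#' @param residues_per_chain Residues per chain (>= 10).
#' @param arrangement `"ring"` or `"line"`.
#' @param inter_chain_gap Nearest-approach gap between adjacent chains,
#'   Angstrom; the default 5 guarantees non-empty interfaces at the 10
#'   Angstrom cutoff.
#' @param id Structure label.
#' @param seed Integer seed for the per-chain roll.
#'
#' @return A `complex_structure`.
#' @export
#' @examples
#' nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 15)
#' n_chains(nat)
make_synthetic_native <- function(n_chains = 3,
                                  residues_per_chain = 30,
                                  arrangement = c("ring", "line"),
                                  inter_chain_gap = 5,
                                  id = "synthetic_native",
                                  seed = 1) {
  arrangement <- match.arg(arrangement)
  if (n_chains < 2 || n_chains > 26) {
    abort("n_chains must be between 2 and 26", class = "fpair_validation_error")
  }
  if (residues_per_chain < 10) {
    abort("residues_per_chain must be at least 10",
          class = "fpair_validation_error")
  }
  if (inter_chain_gap <= 0) {
    abort("inter_chain_gap must be positive", class = "fpair_validation_error")
  }

  ids <- LETTERS[seq_len(n_chains)]

  withr::local_seed(seed)
  # each chain gets its own seeded torsion variation around the bundle
  # template and a roll about its long axis: perfectly regular chains are
  # too self-similar (a thin helical rod in particular has a cheap axial
  # self-rotation) and would let whole-pair superpositions absorb large
  # rigid-body moves
  placed <- lapply(seq_len(n_chains), function(j) {
    xyz <- bundle_backbone(residues_per_chain, jitter = 10)
    xyz <- xyz %*% t(rotation_about_axis(c(1, 0, 0), runif(1, 0, 360)))
    sweep(xyz, 2, colMeans(xyz))
  })

  if (arrangement == "line" || n_chains == 2) {
    # head-to-tail along x, each chain slid until its nearest-atom
    # distance to the previous chain is exactly the gap; a 2-chain "ring"
    # degenerates to the same layout
    for (j in seq_len(n_chains)[-1]) {
      s <- min_gap_offset(placed[[j - 1]], placed[[j]], inter_chain_gap)
      placed[[j]][, 1] <- placed[[j]][, 1] + s
    }
  } else {
    # chains tangent to a circle, each at its own radial distance; the
    # radii are relaxed until every adjacent-chain nearest-atom gap is
    # close to `inter_chain_gap`, so all adjacent pairs are guaranteed to
    # contact within the 10 A interface cutoff
    angs <- 2 * pi * (seq_len(n_chains) - 1) / n_chains
    oriented <- lapply(seq_len(n_chains), function(j) {
      placed[[j]] %*% t(rotation_about_axis(c(0, 0, 1),
                                            (angs[j] + pi / 2) * 180 / pi))
    })
    place_ring <- function(radii) {
      lapply(seq_len(n_chains), function(j) {
        sweep(oriented[[j]], 2, radii[j] * c(cos(angs[j]), sin(angs[j]), 0),
              "+")
      })
    }
    pair_gap <- function(ch, j, k) sqrt(min(cross_dist2(ch[[j]], ch[[k]])))
    radii <- rep(max(vapply(placed, function(m) diff(range(m[, 1])), 0)) +
                   inter_chain_gap, n_chains)
    for (iter in 1:60) {
      ch <- place_ring(radii)
      gaps <- vapply(seq_len(n_chains), function(j) {
        pair_gap(ch, j, j %% n_chains + 1)
      }, 0)
      if (all(abs(gaps - inter_chain_gap) < 0.2)) break
      err <- gaps - inter_chain_gap                # gap to the next chain
      adjust <- (err + err[c(n_chains, seq_len(n_chains - 1))]) / 2
      radii <- pmax(radii - 0.8 * adjust, 1)
    }
    placed <- place_ring(radii)
  }

  atoms <- purrr::map_dfr(seq_len(n_chains), function(j) {
    xyz <- placed[[j]]
    n_res <- residues_per_chain
    tibble(
      chain = ids[j],
      resno = rep(seq_len(n_res), each = 4),
      ins = "",
      resname = "ALA",
      elety = rep(c("N", "CA", "C", "O"), n_res),
      elesy = rep(c("N", "C", "C", "O"), n_res),
      x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
      z = round(xyz[, 3], 3),
      occ = 1)
  })
  new_complex_structure(id, atoms)
}

# Compact three-segment bundle (helix-turn-helix-turn-helix) with seeded
# torsion jitter.  Globular rather than rod-like, so no rigid self-motion
# of a chain is cheap — a property the evaluation metrics rely on when a
# whole-pair superposition must not absorb a genuine perturbation.
bundle_backbone <- function(n_res, jitter = 10) {
  phi <- rep(-57, n_res)
  psi <- rep(-47, n_res)
  seg <- floor((n_res - 4) / 3)
  turns <- c(seg + 1, 2 * seg + 3)
  turns <- turns[turns + 1 < n_res]
  phi[turns] <- -90; psi[turns] <- 0
  phi[turns + 1] <- -135; psi[turns + 1] <- 75
  helix_backbone(n_res,
                 phi = phi + runif(n_res, -jitter, jitter),
                 psi = psi + runif(n_res, -jitter, jitter))
}

# Offset along +x placing `q` so its nearest-atom distance to `p` is
# exactly `gap` (closed form over atom pairs).
min_gap_offset <- function(p, q, gap) {
  dyz2 <- outer(p[, 2]^2 + p[, 3]^2, q[, 2]^2 + q[, 3]^2, "+") -
    2 * (p[, 2] %o% q[, 2] + p[, 3] %o% q[, 3])
  feasible <- dyz2 < gap^2
  dx <- outer(p[, 1], q[, 1], "-")
  max(dx[feasible] + sqrt(gap^2 - dyz2[feasible]))
}

# Alpha-helical backbone (N, CA, C, O per residue) with ideal bond lengths
# and angles, centered at the origin with the principal axis along +x.
# phi/psi may be vectors (one value per residue) to vary the conformation.
helix_backbone <- function(n_res, phi = -57, psi = -47) {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  omega <- 180
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8

  coords <- matrix(NA_real_, nrow = 4 * n_res, ncol = 3)
  idx <- function(res, atom) (res - 1) * 4 + atom  # 1=N 2=CA 3=C 4=O

  coords[idx(1, 1), ] <- c(0, 0, 0)
  coords[idx(1, 2), ] <- c(b_n_ca, 0, 0)
  th <- (180 - a_n_ca_c) * pi / 180
  coords[idx(1, 3), ] <- coords[idx(1, 2), ] +
    b_ca_c * c(cos(th), sin(th), 0)

  for (r in seq_len(n_res)) {
    n_i <- coords[idx(r, 1), ]; ca_i <- coords[idx(r, 2), ]
    c_i <- coords[idx(r, 3), ]
    coords[idx(r, 4), ] <- place_atom(n_i, ca_i, c_i, b_c_o, a_ca_c_o,
                                      psi[r] + 180)
    if (r == n_res) break
    n_next <- place_atom(n_i, ca_i, c_i, b_c_n, a_ca_c_n, psi[r])
    ca_next <- place_atom(ca_i, c_i, n_next, b_n_ca, a_c_n_ca, omega)
    c_next <- place_atom(c_i, n_next, ca_next, b_ca_c, a_n_ca_c, phi[r + 1])
    coords[idx(r + 1, 1), ] <- n_next
    coords[idx(r + 1, 2), ] <- ca_next
    coords[idx(r + 1, 3), ] <- c_next
  }

  centered <- sweep(coords, 2, colMeans(coords))
  pc <- prcomp(centered, center = FALSE)
  rot <- pc$rotation
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  centered %*% rot
}

# Natural extension reference frame: position of atom D given A-B-C, the
# C-D bond length, the B-C-D angle and the A-B-C-D dihedral (degrees).
place_atom <- function(a, b, c, length, angle, dihedral) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  th <- angle * pi / 180; chi <- dihedral * pi / 180
  d <- c(-length * cos(th), length * sin(th) * cos(chi),
         length * sin(th) * sin(chi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Perturb chains of a native complex into a decoy
#'
#' Applies an independent random rigid-body move — a rotation about the
#' chain centroid (axis isotropic, angle drawn from `rotation`) and a
#' translation in a uniform random direction — to each listed chain;
#' unlisted chains are copied verbatim.  Chain ids and residue numbering
#' are preserved, so the decoy evaluates against its native without any
#' chain-mapping work.  Deterministic for a given native, arguments and
#' seed.
#'
#' @param native A `complex_structure`.
#' @param chains Character vector of chain ids to move (may be empty).
#' @param translation Translation magnitude in Angstrom: a single value for
#'   an exact magnitude, or a length-2 range sampled uniformly.
#' @param rotation Rotation angle in degrees, same convention: exact value
#'   or uniform range.  Note that a pure translation of a distant chain can
#'   be partially absorbed by a pair superposition (a small whole-pair
#'   rotation sweeps a far chain a long way), so perturbations meant to
#'   decisively break a pair should include a substantial rotation.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param id Decoy label.
#' @return A `complex_structure`.
#' @export
#' @examples
#' nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 15)
#' dec <- make_decoy(nat, chains = "B", translation = 25, seed = 7)
make_decoy <- function(native, chains, translation = c(5, 25),
                       rotation = c(0, 30), seed = NULL,
                       id = paste0(native$id, "_decoy")) {
  stopifnot(inherits(native, "complex_structure"))
  unknown <- setdiff(chains, chain_ids(native))
  if (length(unknown) > 0) {
    abort(paste0("unknown chain id(s): ", paste(unknown, collapse = ", ")),
          class = "fpair_validation_error")
  }
  for (arg in list(translation, rotation)) {
    if (!length(arg) %in% c(1, 2) || any(arg < 0)) {
      abort("translation and rotation must be non-negative magnitudes or ranges",
            class = "fpair_validation_error")
    }
  }
  draw <- function(spec) {
    if (length(spec) == 2) runif(1, spec[1], spec[2]) else spec
  }
  if (!is.null(seed)) withr::local_seed(seed)

  atoms <- native$atoms
  for (ch in chains) {
    sel <- atoms$chain == ch
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    centroid <- colMeans(xyz)
    rot <- random_rotation(draw(rotation))
    mag <- draw(translation)
    dir <- rnorm(3)
    while (sum(dir^2) < 1e-12) dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    xyz <- sweep(sweep(xyz, 2, centroid) %*% t(rot), 2,
                 centroid + mag * dir, "+")
    atoms[sel, c("x", "y", "z")] <- as.data.frame(round(xyz, 3))
  }
  new_complex_structure(id, atoms)
}

#' Generate a decoy population spanning the RMSD classes
#'
#' Builds `n_decoys` decoys by cycling over a schedule of translation
#' magnitudes crossed with moved-chain counts 1..N-1 (plus one unperturbed
#' combination for magnitude 0), with the moved chains drawn at random per
#' decoy.  The default magnitudes 0, 2, 6, 12, 25 and 50 Angstrom were
#' chosen so small complexes populate all six global-RMSD classes: a single
#' chain of a 3-chain complex displaced by t shifts the superposed global
#' C-alpha RMSD by roughly 0.47 t, so 50 Angstrom reaches the 20+ class.
#' Deterministic per seed.
#'
#' @param native A `complex_structure`.
#' @param n_decoys Number of decoys (>= 1).
#' @param magnitude_schedule Translation magnitudes in Angstrom.
#' @param max_angle Rotation-angle bound for perturbed chains, degrees.
#' @param seed Integer seed.
#' @return Named list of `complex_structure` decoys
#'   (`decoy_001`, `decoy_002`, ...).
#' @export
#' @examples
#' nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 15)
#' pop <- make_decoy_population(nat, n_decoys = 6, seed = 3)
#' names(pop)
make_decoy_population <- function(native, n_decoys,
                                  magnitude_schedule = c(0, 2, 6, 12, 25, 50),
                                  max_angle = 30,
                                  seed = 1) {
  stopifnot(inherits(native, "complex_structure"))
  if (n_decoys < 1) {
    abort("n_decoys must be at least 1", class = "fpair_validation_error")
  }
  ids <- chain_ids(native)
  n <- length(ids)
  combos <- purrr::map_dfr(sort(magnitude_schedule), function(m) {
    if (m == 0) tibble(magnitude = 0, k = 0L)
    else tibble(magnitude = m, k = seq_len(n - 1))
  })

  withr::local_seed(seed)
  out <- vector("list", n_decoys)
  for (i in seq_len(n_decoys)) {
    cb <- combos[(i - 1) %% nrow(combos) + 1, ]
    did <- sprintf("decoy_%03d", i)
    if (cb$k == 0) {
      d <- new_complex_structure(did, native$atoms)
    } else {
      moved <- sort(sample(ids, cb$k))
      d <- make_decoy(native, chains = moved, translation = cb$magnitude,
                      rotation = if (cb$magnitude == 0) 0 else c(0, max_angle),
                      seed = NULL, id = did)
    }
    out[[i]] <- d
  }
  setNames(out, vapply(out, function(d) d$id, ""))
}
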