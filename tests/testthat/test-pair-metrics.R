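test_that("pair enumeration gives N(N-1)/2 lexicographic pairs", {
  p3 <- enumerate_pairs(c("C", "A", "B"))
  expect_identical(nrow(p3), 3L)
  expect_identical(p3$chain_x, c("A", "A", "B"))
  expect_identical(p3$chain_y, c("B", "C", "C"))

  expect_identical(nrow(enumerate_pairs(LETTERS[1:4])), 6L)
  expect_identical(nrow(enumerate_pairs(LETTERS[1:6])), 15L)
  s6 <- make_synthetic_native(n_chains = 6, residues_per_chain = 10)
  expect_identical(nrow(enumerate_pairs(s6)), 15L)
  expect_error(enumerate_pairs("A"), class = "fpair_validation_error")
})

test_that("the native interface matches a brute-force distance scan", {
  nat <- make_synthetic_native(n_chains = 2, residues_per_chain = 18, seed = 9)
  iface <- native_interface(nat, "A", "B", contact_cutoff = 10)
  oracle <- brute_force_interface(nat, "A", "B", cutoff = 10)
  expect_gt(nrow(iface$residues), 0)
  key <- function(d) sort(paste(d$chain, d$resno, d$ins))
  expect_identical(key(iface$residues), key(oracle))

  # order of the chain arguments is irrelevant
  iface_rev <- native_interface(nat, "B", "A", contact_cutoff = 10)
  expect_identical(key(iface_rev$residues), key(iface$residues))
})

test_that("interface edge cases: distant chains are empty, near single residues included", {
  far <- translate_chain(
    make_synthetic_native(n_chains = 2, residues_per_chain = 10),
    "B", c(500, 0, 0))
  expect_identical(nrow(native_interface(far, "A", "B")$residues), 0L)

  near <- fpair:::new_complex_structure("near", tibble::tibble(
    chain = c("A", "B"), resno = 1L, ins = "", resname = "ALA",
    elety = "CA", elesy = "C",
    x = c(0, 6), y = 0, z = 0, occ = 1))
  expect_identical(nrow(native_interface(near, "A", "B", 10)$residues), 2L)
  expect_error(native_interface(near, "A", "Z"),
               class = "fpair_validation_error")
})

test_that("iRMSD is zero for the native and for rigidly moved pairs, and matches bio3d", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 16, seed = 5)

  self <- pair_irmsd(nat, nat, "A", "B")
  expect_lt(self$irmsd, 1e-6)
  expect_true(self$is_hit)
  expect_false(self$used_fallback)

  # the whole pair moved as a rigid unit: iRMSD is internal to the pair
  withr::local_seed(21)
  rot <- random_rotation_matrix()
  moved <- transform_structure(nat, rot, c(30, -12, 7))
  expect_lt(pair_irmsd(nat, moved, "A", "B")$irmsd, 1e-6)

  # a genuinely perturbed chain: cross-check against bio3d on the same atoms
  dec <- translate_chain(nat, "B", c(6, -8, 3))
  got <- pair_irmsd(nat, dec, "A", "B")
  iface <- native_interface(nat, "A", "B")
  scope <- c("N", "CA", "C", "O")
  pick <- function(s) {
    at <- merge(tibble::as_tibble(s), iface$residues,
                by = c("chain", "resno", "ins"))
    at <- at[at$elety %in% scope, ]
    at <- at[order(at$chain, at$resno, at$ins, match(at$elety, scope)), ]
    as.matrix(at[, c("x", "y", "z")])
  }
  expect_equal(got$irmsd, bio3d_fit_rmsd(pick(dec), pick(nat)),
               tolerance = 1e-6)
  expect_identical(got$n_atoms, nrow(pick(nat)))
})

test_that("iRMSD is symmetric in chain labels and invariant to whole-decoy motion", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 14, seed = 2)
  dec <- make_decoy(nat, chains = "B", translation = 8, seed = 3)
  ab <- pair_irmsd(nat, dec, "A", "B")
  ba <- pair_irmsd(nat, dec, "B", "A")
  expect_equal(ab$irmsd, ba$irmsd, tolerance = 1e-12)
  expect_identical(ab$chain_x, "A")

  withr::local_seed(4)
  moved <- transform_structure(dec, random_rotation_matrix(), rnorm(3, sd = 15))
  expect_equal(pair_irmsd(nat, moved, "A", "B")$irmsd, ab$irmsd,
               tolerance = 1e-6)
})

test_that("non-contacting native pairs fall back to a whole-pair superposition", {
  lin <- make_synthetic_native(n_chains = 4, residues_per_chain = 12,
                               arrangement = "line", seed = 6)
  ev <- pair_irmsd(lin, lin, "A", "D")  # ends of the line: no interface
  expect_true(ev$used_fallback)
  expect_identical(ev$n_interface_residues, 0L)
  expect_lt(ev$irmsd, 1e-6)

  adj <- pair_irmsd(lin, lin, "A", "B")
  expect_false(adj$used_fallback)
  expect_gt(adj$n_interface_residues, 0L)
})

test_that("the hit criterion is a strict 4 A threshold", {
  nat <- make_synthetic_native(n_chains = 2, residues_per_chain = 15, seed = 1)
  dec <- translate_chain(nat, "B", c(5, 2, -4))
  x <- pair_irmsd(nat, dec, "A", "B")$irmsd
  expect_gt(x, 0)
  # threshold exactly at the measured value: not a hit (strict <)
  expect_false(pair_irmsd(nat, dec, "A", "B", hit_threshold = x)$is_hit)
  expect_true(pair_irmsd(nat, dec, "A", "B",
                         hit_threshold = x + 1e-9)$is_hit)
  expect_identical(pair_irmsd(nat, dec, "A", "B")$is_hit, x < 4)
})

test_that("iRMSD degrades monotonically with translation magnitude", {
  nat <- make_synthetic_native(n_chains = 2, residues_per_chain = 15, seed = 3)
  dir <- c(1, 2, -1) / sqrt(6)
  irmsds <- vapply(c(0, 1, 2, 4, 8), function(mag) {
    pair_irmsd(nat, translate_chain(nat, "B", mag * dir), "A", "B")$irmsd
  }, 0)
  expect_true(all(diff(irmsds) >= -1e-9))
  expect_lt(irmsds[1], 1e-6)
})

test_that("fnat matches a brute-force contact enumeration", {
  # chains packed closer than the default so 5 A residue contacts exist
  nat <- make_synthetic_native(n_chains = 2, residues_per_chain = 18,
                               inter_chain_gap = 3, seed = 7)
  expect_equal(pair_fnat(nat, nat, "A", "B"), 1)

  gone <- translate_chain(nat, "B", c(100, 0, 0))
  expect_equal(pair_fnat(nat, gone, "A", "B"), 0)

  # partial perturbation: compare the preserved fraction with the oracle
  dec <- translate_chain(nat, "B", c(2.0, 1.0, -1.5))
  nat_contacts <- brute_force_contacts(nat, "A", "B", cutoff = 5)
  dec_contacts <- brute_force_contacts(dec, "A", "B", cutoff = 5)
  expect_gt(length(nat_contacts), 0)
  expected <- length(intersect(nat_contacts, dec_contacts)) /
    length(nat_contacts)
  expect_equal(pair_fnat(nat, dec, "A", "B"), expected)
  expect_gte(expected, 0)
  expect_lte(expected, 1)

  # a pair with no native contacts has undefined fnat
  lin <- make_synthetic_native(n_chains = 4, residues_per_chain = 12,
                               arrangement = "line")
  expect_true(is.na(pair_fnat(lin, lin, "A", "D")))
})
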