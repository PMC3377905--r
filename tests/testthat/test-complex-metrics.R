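test_that("chain mapping modes validate and resolve correctly", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 12)
  m <- resolve_chain_mapping(nat, nat, "identity")
  expect_identical(unname(m$entries), chain_ids(nat))
  expect_identical(m$source, "identity")

  relabelled <- relabel_chains(nat, c(A = "X", B = "Y", C = "Z"))
  expect_error(resolve_chain_mapping(nat, relabelled, "identity"),
               class = "fpair_validation_error")

  um <- c(X = "A", Y = "B", Z = "C")
  mu <- resolve_chain_mapping(nat, relabelled, "user", user_map = um)
  expect_identical(mu$entries[["X"]], "A")
  expect_error(
    resolve_chain_mapping(nat, relabelled, "user",
                          user_map = c(X = "A", Y = "A", Z = "C")),
    class = "fpair_validation_error")

  two <- make_synthetic_native(n_chains = 2, residues_per_chain = 12)
  expect_error(resolve_chain_mapping(nat, two),
               class = "fpair_validation_error")
})

test_that("permutation search recovers a homodimer label swap", {
  nat <- make_synthetic_native(n_chains = 2, residues_per_chain = 14, seed = 2)
  # perturb chain B, then swap the labels: the correct correspondence is
  # the swap, not the identity
  dec <- relabel_chains(make_decoy(nat, "B", translation = 12, seed = 5),
                        c(A = "B", B = "A"))
  m <- resolve_chain_mapping(nat, dec, "search")
  expect_identical(m$source, "permutation_search")

  # oracle: evaluate both bijections explicitly
  r_ident <- global_rmsd(nat, dec, resolve_chain_mapping(nat, dec, "identity"))
  r_swap <- global_rmsd(
    nat, dec, resolve_chain_mapping(nat, dec, "user",
                                    user_map = c(A = "B", B = "A")))
  expect_lt(r_swap, r_ident)
  expect_identical(unname(m$entries[c("A", "B")]), c("B", "A"))
  expect_equal(global_rmsd(nat, dec, m), r_swap, tolerance = 1e-12)
})

test_that("global RMSD is zero under rigid motion and matches bio3d otherwise", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 15, seed = 3)
  expect_lt(global_rmsd(nat, nat), 1e-6)

  withr::local_seed(8)
  moved <- transform_structure(nat, random_rotation_matrix(), rnorm(3, sd = 25))
  expect_lt(global_rmsd(nat, moved), 1e-6)

  dec <- translate_chain(nat, "C", c(9, -4, 14))
  ca <- function(s) {
    at <- tibble::as_tibble(s)
    at <- at[at$elety == "CA", ]
    at <- at[order(match(at$chain, c("A", "B", "C")), at$resno), ]
    as.matrix(at[, c("x", "y", "z")])
  }
  expect_equal(global_rmsd(nat, dec), bio3d_fit_rmsd(ca(dec), ca(nat)),
               tolerance = 1e-6)
})

test_that("fpair is the exact hit fraction with a guarded denominator", {
  expect_equal(compute_fpair(c(TRUE, TRUE, FALSE), 3), 2 / 3)
  expect_equal(compute_fpair(rep(FALSE, 3), 3), 0)
  expect_equal(compute_fpair(rep(TRUE, 15), 6), 1)
  evals <- tibble::tibble(is_hit = c(TRUE, FALSE, FALSE))
  expect_equal(compute_fpair(evals, 3), 1 / 3)
  expect_error(compute_fpair(c(TRUE, FALSE), 3),
               class = "fpair_validation_error")
  expect_error(compute_fpair(c(TRUE, NA, FALSE), 3),
               class = "fpair_validation_error")
})

test_that("report rounding is half-up at two decimals", {
  expect_equal(round_half_up(2 / 3, 2), 0.67)
  expect_equal(round_half_up(0.125, 2), 0.13)  # base round() would give 0.12
  expect_equal(round_half_up(11 / 15, 2), 0.73)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("RMSD classes are half-open, lower-inclusive", {
  expect_identical(as.character(classify_bin(0)), "0-4")
  expect_identical(as.character(classify_bin(15.12)), "12-16")
  expect_identical(as.character(classify_bin(c(4, 8, 12, 16, 20))),
                   c("4-8", "8-12", "12-16", "16-20", "20+"))
  expect_identical(as.character(classify_bin(3.999)), "0-4")
  expect_identical(as.character(classify_bin(1000)), "20+")
  expect_identical(levels(classify_bin(0)),
                   c("0-4", "4-8", "8-12", "12-16", "16-20", "20+"))
  expect_error(classify_bin(-0.1), class = "fpair_validation_error")
})

test_that("evaluating the native against itself is perfect for every size", {
  for (n in c(2, 3, 6)) {
    nat <- make_synthetic_native(n_chains = n, residues_per_chain = 12,
                                 seed = n)
    ev <- evaluate_complex(nat, nat)
    expect_equal(ev$fpair, 1)
    expect_identical(ev$n_hits, as.integer(choose(n, 2)))
    expect_identical(ev$rmsd_bin, "0-4")
    expect_lt(ev$global_rmsd, 1e-6)
  }
})

test_that("displacing chains leaves exactly the undisturbed pairs as hits", {
  nat3 <- make_synthetic_native(n_chains = 3, residues_per_chain = 24, seed = 1)
  ev3 <- evaluate_complex(nat3, make_decoy(nat3, "C", translation = 50,
                                           rotation = c(90, 170), seed = 2))
  expect_identical(ev3$n_hits, 1L)
  expect_equal(round_half_up(ev3$fpair, 2), 0.33)

  nat4 <- make_synthetic_native(n_chains = 4, residues_per_chain = 24, seed = 1)
  ev4 <- evaluate_complex(nat4, make_decoy(nat4, c("C", "D"),
                                           translation = 50,
                                           rotation = c(90, 170), seed = 3))
  expect_identical(ev4$n_hits, 1L)  # only A-B survives
  hits <- tidy(ev4)
  expect_true(hits$is_hit[hits$chain_x == "A" & hits$chain_y == "B"])
  expect_equal(round_half_up(ev4$fpair, 2), 0.17)
})

test_that("tidy and glance expose the evaluation as tables", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 12)
  ev <- evaluate_complex(nat, make_decoy(nat, "B", translation = 10, seed = 4))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  expect_true(all(c("chain_x", "chain_y", "irmsd", "is_hit") %in% names(td)))
  gl <- glance(ev)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_hits, sum(td$is_hit))
  expect_equal(gl$fpair, gl$n_hits / 3)
})

test_that("fnat columns appear when requested", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 12, seed = 5)
  ev <- evaluate_complex(nat, nat, eval_config(fnat = TRUE))
  expect_true("fnat" %in% names(tidy(ev)))
  expect_true(all(tidy(ev)$fnat == 1, na.rm = TRUE))
})

test_that("decoy-set evaluation aggregates, conserves and survives bad decoys", {
  nat <- make_synthetic_native(n_chains = 6, residues_per_chain = 12, seed = 2)
  copies <- lapply(1:5, function(i) {
    fpair:::new_complex_structure(sprintf("copy_%d", i), nat$atoms)
  })
  rep5 <- evaluate_decoy_set(nat, copies)
  h <- hit_histogram(rep5)
  expect_identical(nrow(h), 1L)
  expect_identical(as.character(h$bin), "0-4")
  expect_identical(h$n_hits, 15L)
  expect_identical(h$n_decoys, 5L)

  expect_error(evaluate_decoy_set(nat, list()),
               class = "fpair_validation_error")

  nat3 <- make_synthetic_native(n_chains = 3, residues_per_chain = 12, seed = 3)
  pop <- make_decoy_population(nat3, 24, seed = 9)
  rep24 <- evaluate_decoy_set(nat3, pop)
  expect_identical(sum(hit_histogram(rep24)$n_decoys), 24L)  # conservation
  expect_identical(nrow(tidy(rep24)), 24L)

  # one malformed decoy: recorded, run continues
  mixed <- c(pop[1:3], list(file.path(tempdir(), "missing_decoy.pdb")))
  rep_mixed <- evaluate_decoy_set(nat3, mixed)
  expect_identical(nrow(rep_mixed$errors), 1L)
  expect_identical(nrow(tidy(rep_mixed)), 3L)

  # every decoy failing is a run error
  expect_error(
    evaluate_decoy_set(nat3, list(file.path(tempdir(), "missing_decoy.pdb"))),
    class = "fpair_run_error")
})

test_that("reports serialize to TSV and JSON and plot", {
  nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 12, seed = 4)
  rep <- evaluate_decoy_set(nat, make_decoy_population(nat, 8, seed = 5))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_decoy_report(rep, tsv = tsv, json = json)

  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_identical(nrow(tab), 8L)
  expect_true(all(c("decoy_id", "global_rmsd", "bin", "n_hits", "n_pairs",
                    "fpair", "iRMSD_A-B", "iRMSD_A-C", "iRMSD_B-C")
                  %in% names(tab)))
  js <- jsonlite::read_json(json)
  expect_identical(js$n_decoys, 8L)
  expect_identical(
    sum(unlist(lapply(js$bins, function(b) b$total))), 8L)

  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
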