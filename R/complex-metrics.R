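#' Resolve the decoy-to-native chain correspondence
#'
#' Model pipelines do not always label chains the way the native entry does.
#' Three modes are supported: `"identity"` requires equal chain id sets and
#' maps each chain to itself; `"user"` validates a supplied bijection;
#' `"search"` groups chains by identical residue sequence, evaluates every
#' sequence-compatible bijection, and returns the one minimizing the global
#' C-alpha RMSD (ties broken by lexicographic permutation order).  The
#' search cost grows factorially within sequence-identical groups and is
#' refused beyond groups of 8 chains.
#'
#' @param native,decoy `complex_structure` objects with equal chain counts.
#' @param mode `"identity"`, `"user"` or `"search"`.
#' @param user_map Named character vector (decoy chain -> native chain),
#'   required for `"user"` mode.
#'
#' @return A `chain_mapping`: list with `entries` (named character vector,
#'   decoy chain -> native chain) and `source`.
#' @export
resolve_chain_mapping <- function(native, decoy,
                                  mode = c("identity", "user", "search"),
                                  user_map = NULL) {
  mode <- match.arg(mode)
  nat_ch <- chain_ids(native)
  dec_ch <- chain_ids(decoy)
  if (length(nat_ch) != length(dec_ch)) {
    abort(paste0("chain-count mismatch: native has ", length(nat_ch),
                 ", decoy has ", length(dec_ch)),
          class = "fpair_validation_error")
  }

  if (mode == "identity") {
    if (!setequal(nat_ch, dec_ch)) {
      abort(paste0("identity mapping impossible: decoy chains {",
                   paste(sort(dec_ch), collapse = ","),
                   "} differ from native {",
                   paste(sort(nat_ch), collapse = ","), "}"),
            class = "fpair_validation_error")
    }
    entries <- setNames(nat_ch, nat_ch)
  } else if (mode == "user") {
    if (is.null(user_map) || is.null(names(user_map))) {
      abort("user mode requires a named user_map (decoy -> native)",
            class = "fpair_validation_error")
    }
    if (anyDuplicated(user_map) || anyDuplicated(names(user_map)) ||
        !setequal(names(user_map), dec_ch) ||
        !setequal(unname(user_map), nat_ch)) {
      abort("user_map must be a bijection from decoy chains onto native chains",
            class = "fpair_validation_error")
    }
    entries <- user_map[dec_ch]
  } else {
    entries <- search_chain_mapping(native, decoy)
  }
  structure(list(entries = entries, source = switch(
    mode, identity = "identity", user = "user_supplied",
    search = "permutation_search")), class = "chain_mapping")
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat("<chain_mapping> (", x$source, ") ",
      paste(names(x$entries), x$entries, sep = "->", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

search_chain_mapping <- function(native, decoy) {
  seq_of <- function(s, ch) {
    r <- residue_table(s)
    paste(r$resname[r$chain == ch], collapse = "-")
  }
  nat_ch <- chain_ids(native)
  dec_ch <- chain_ids(decoy)
  nat_seq <- vapply(nat_ch, seq_of, "", s = native)
  dec_seq <- vapply(dec_ch, seq_of, "", s = decoy)
  if (!identical(sort(table(nat_seq)), sort(table(dec_seq))) ||
      !setequal(nat_seq, dec_seq)) {
    abort("chain sequences of native and decoy cannot be matched",
          class = "fpair_validation_error")
  }

  groups <- split(seq_along(dec_ch), dec_seq)
  per_group <- lapply(names(groups), function(sq) {
    dec_g <- sort(dec_ch[groups[[sq]]])
    nat_g <- sort(nat_ch[nat_seq == sq])
    if (length(nat_g) != length(dec_g)) {
      abort("chain sequences of native and decoy cannot be matched",
            class = "fpair_validation_error")
    }
    if (length(dec_g) > 8) {
      abort(paste0("permutation search refused: ", length(dec_g),
                   " sequence-identical chains (cap is 8)"),
            class = "fpair_validation_error")
    }
    # each candidate: named vector dec_g -> permuted nat_g
    lapply(permutations(nat_g), function(p) setNames(p, dec_g))
  })

  # cross groups; lexicographic order within and across groups
  candidates <- Reduce(function(acc, g) {
    unlist(lapply(acc, function(a) lapply(g, function(b) c(a, b))),
           recursive = FALSE)
  }, per_group[-1], init = per_group[[1]])

  best <- NULL
  best_rmsd <- Inf
  for (cand in candidates) {
    entries <- cand[dec_ch]
    r <- tryCatch(
      global_rmsd(native, decoy,
                  mapping = structure(list(entries = entries,
                                           source = "permutation_search"),
                                      class = "chain_mapping")),
      error = function(e) Inf)
    if (r < best_rmsd - 1e-12) {
      best_rmsd <- r
      best <- entries
    }
  }
  if (is.null(best)) {
    abort("no permutation yields a computable global RMSD",
          class = "fpair_validation_error")
  }
  best
}

# All permutations of a character vector, in lexicographic order.
permutations <- function(v) {
  v <- sort(v)
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(permutations(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

#' Relabel decoy chains onto the native frame
#'
#' Renames decoy chains to their mapped native ids and reorders them to the
#' native chain order, so all downstream per-chain joins line up.
#'
#' @param decoy A `complex_structure`.
#' @param mapping A `chain_mapping` from [resolve_chain_mapping()].
#' @param chain_order Optional chain order for the result (the native's).
#' @return A relabelled `complex_structure`.
#' @export
apply_chain_mapping <- function(decoy, mapping, chain_order = NULL) {
  stopifnot(inherits(mapping, "chain_mapping"))
  atoms <- decoy$atoms
  atoms$chain <- unname(mapping$entries[atoms$chain])
  if (is.null(chain_order)) chain_order <- sort(unique(atoms$chain))
  atoms <- atoms[order(match(atoms$chain, chain_order), atoms$resno,
                       atoms$ins), , drop = FALSE]
  new_complex_structure(decoy$id, atoms)
}

#' Global C-alpha RMSD of a decoy
#'
#' One simultaneous least-squares superposition of every mapped C-alpha atom
#' of the decoy onto the native — the conventional whole-complex "RMSD to
#' the native".  A backbone (N, CA, C, O) scope is available but C-alpha is
#' the default.
#'
#' @param native,decoy `complex_structure` objects.
#' @param mapping Optional `chain_mapping` (identity by default).
#' @param atom_scope `"calpha"` (default) or `"backbone"`.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' s <- make_synthetic_native(n_chains = 3, residues_per_chain = 12)
#' global_rmsd(s, s)  # 0
global_rmsd <- function(native, decoy, mapping = NULL,
                        atom_scope = c("calpha", "backbone")) {
  atom_scope <- match.arg(atom_scope)
  scope <- if (atom_scope == "calpha") "CA" else c("N", "CA", "C", "O")
  if (is.null(mapping)) {
    mapping <- resolve_chain_mapping(native, decoy, "identity")
  }
  decoy2 <- apply_chain_mapping(decoy, mapping, chain_order = chain_ids(native))
  common <- common_residues(native, decoy2)
  residues <- tibble(chain = common$chain_a, resno = common$resno,
                     ins = common$ins)
  paired <- paired_scope_atoms(native, decoy2, residues, scope)
  if (nrow(paired$native) < 3) {
    abort("too few shared atoms for a global superposition",
          class = "fpair_validation_error")
  }
  kabsch_superpose(paired$decoy, paired$native)$rmsd
}

#' Fraction of pairwise hits
#'
#' fpair = sum over all unordered chain pairs p of I(iRMSD(p) < 4 A),
#' divided by the total number of pairs N(N-1)/2.  The full-precision
#' fraction is returned; printed reports round half-up to two decimals (see
#' [round_half_up()]).
#'
#' @param pair_evals Either a logical hit vector or a data frame with an
#'   `is_hit` column (as produced by [pair_irmsd()]), one entry per chain
#'   pair.
#' @param n_chains Number of chains N; the number of evaluations must equal
#'   N(N-1)/2.
#' @return The fraction of hits, in 0..1.
#' @export
#' @examples
#' compute_fpair(c(TRUE, TRUE, FALSE), n_chains = 3)  # 2/3
compute_fpair <- function(pair_evals, n_chains) {
  hits <- if (is.data.frame(pair_evals)) pair_evals$is_hit else pair_evals
  if (!is.logical(hits) || anyNA(hits)) {
    abort("pair evaluations must provide non-missing logical hit flags",
          class = "fpair_validation_error")
  }
  n_pairs <- choose(n_chains, 2)
  if (length(hits) != n_pairs) {
    abort(paste0("expected ", n_pairs, " pair evaluations for ", n_chains,
                 " chains, got ", length(hits)),
          class = "fpair_validation_error")
  }
  sum(hits) / n_pairs
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.5 -> 3), the convention used for
#' the two-decimal fpair values in tabular reports; base R's `round()`
#' rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify a global RMSD into accuracy classes
#'
#' Assigns each RMSD to one of the half-open classes 0-4, 4-8, 8-12, 12-16,
#' 16-20 and 20+ Angstrom (lower bound inclusive), the binning used for
#' decoy-set summaries.
#'
#' @param global_rmsd Numeric vector of RMSD values (Angstrom, >= 0).
#' @param breaks Increasing upper boundaries of the finite classes.
#' @return A factor with one level per class.
#' @export
#' @examples
#' classify_bin(c(0, 4, 15.12))  # 0-4, 4-8, 12-16
classify_bin <- function(global_rmsd, breaks = c(4, 8, 12, 16, 20)) {
  if (any(!is.finite(global_rmsd)) || any(global_rmsd < 0)) {
    abort("global RMSD must be finite and non-negative",
          class = "fpair_validation_error")
  }
  labels <- bin_labels(breaks)
  idx <- findInterval(global_rmsd, breaks) + 1L
  factor(labels[idx], levels = labels)
}

bin_labels <- function(breaks = c(4, 8, 12, 16, 20)) {
  lower <- c(0, breaks)
  c(paste0(head(lower, -1), "-", breaks), paste0(tail(breaks, 1), "+"))
}

#' Evaluation settings
#'
#' Bundles the thresholds and modes used by [evaluate_complex()] and
#' [evaluate_decoy_set()].
#'
#' @param irmsd_threshold Pairwise hit criterion in Angstrom (strict `<`).
#' @param interface_cutoff Native interface heavy-atom cutoff, Angstrom.
#' @param atom_scope iRMSD atom scope, `"backbone"` or `"calpha"`.
#' @param fnat Also compute the fraction of native contacts per pair?
#' @param fnat_cutoff fnat heavy-atom contact cutoff, Angstrom.
#' @param bins Upper boundaries of the finite RMSD classes.
#' @param chain_map `"identity"`, `"user"` or `"search"`.
#' @param user_map Named vector for `"user"` mode.
#' @return A list of class `fpair_config`.
#' @export
eval_config <- function(irmsd_threshold = 4,
                        interface_cutoff = 10,
                        atom_scope = c("backbone", "calpha"),
                        fnat = FALSE,
                        fnat_cutoff = 5,
                        bins = c(4, 8, 12, 16, 20),
                        chain_map = c("identity", "user", "search"),
                        user_map = NULL) {
  stopifnot(irmsd_threshold > 0, interface_cutoff > 0, fnat_cutoff > 0,
            all(diff(bins) > 0), all(bins > 0))
  structure(list(
    irmsd_threshold = irmsd_threshold,
    interface_cutoff = interface_cutoff,
    atom_scope = match.arg(atom_scope),
    fnat = isTRUE(fnat),
    fnat_cutoff = fnat_cutoff,
    bins = bins,
    chain_map = match.arg(chain_map),
    user_map = user_map), class = "fpair_config")
}

#' Evaluate one decoy against the native complex
#'
#' The end-to-end per-decoy evaluation: resolves the chain mapping,
#' restricts to residues shared with the native, computes the global
#' C-alpha RMSD and its accuracy class, evaluates the iRMSD and hit flag of
#' every chain pair against the native interfaces, and summarizes them as
#' the hit count and fpair.
#'
#' @param native,decoy `complex_structure` objects.
#' @param config An [eval_config()].
#' @return A `complex_evaluation` object; see [tidy()][generics::tidy] for
#'   the per-pair table and [glance()][generics::glance] for the one-row
#'   summary.
#' @export
#' @examples
#' nat <- make_synthetic_native(n_chains = 3, residues_per_chain = 15)
#' dec <- make_decoy(nat, chains = "C", translation = 25, seed = 1)
#' glance(evaluate_complex(nat, dec))
evaluate_complex <- function(native, decoy, config = eval_config()) {
  stopifnot(inherits(native, "complex_structure"),
            inherits(decoy, "complex_structure"),
            inherits(config, "fpair_config"))
  if (n_chains(native) < 2) {
    abort("native must have at least 2 chains",
          class = "fpair_validation_error")
  }
  withCallingHandlers(
    evaluate_complex_impl(native, decoy, config),
    error = function(e) {
      abort(paste0("decoy ", decoy$id, ": ", conditionMessage(e)),
            class = "fpair_evaluation_error", parent = e)
    })
}

evaluate_complex_impl <- function(native, decoy, config) {
  mapping <- resolve_chain_mapping(native, decoy, config$chain_map,
                                   config$user_map)
  decoy2 <- apply_chain_mapping(decoy, mapping,
                                chain_order = chain_ids(native))
  common <- common_residues(native, decoy2)
  grmsd <- global_rmsd(native, decoy2)

  pairs <- enumerate_pairs(native)
  evals <- purrr::pmap_dfr(pairs, function(chain_x, chain_y) {
    iface <- native_interface(native, chain_x, chain_y,
                              config$interface_cutoff)
    ev <- pair_irmsd(native, decoy2, chain_x, chain_y,
                     interface = iface,
                     atom_scope = config$atom_scope,
                     hit_threshold = config$irmsd_threshold,
                     common = common)
    if (config$fnat) {
      ev$fnat <- pair_fnat(native, decoy2, chain_x, chain_y,
                           contact_cutoff = config$fnat_cutoff,
                           common = common)
    }
    ev
  })

  n <- n_chains(native)
  structure(list(
    decoy_id = decoy$id,
    native_id = native$id,
    n_chains = n,
    global_rmsd = grmsd,
    rmsd_bin = as.character(classify_bin(grmsd, config$bins)),
    pairs = evals,
    n_pairs = nrow(evals),
    n_hits = sum(evals$is_hit),
    fpair = compute_fpair(evals, n),
    mapping = mapping,
    config = config), class = "complex_evaluation")
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat("<complex_evaluation> ", x$decoy_id, " vs ", x$native_id, "\n",
      "  global C-alpha RMSD: ", format(x$global_rmsd, digits = 4),
      " A (class ", x$rmsd_bin, ")\n",
      "  pairwise hits: ", x$n_hits, "/", x$n_pairs,
      "  fpair = ", format(round_half_up(x$fpair, 2), nsmall = 2),
      "\n", sep = "")
  invisible(x)
}

#' @rdname evaluate_complex
#' @param x A `complex_evaluation`.
#' @param ... Unused.
#' @export
tidy.complex_evaluation <- function(x, ...) {
  dplyr::bind_cols(tibble(decoy_id = x$decoy_id), x$pairs)
}

#' @rdname evaluate_complex
#' @export
glance.complex_evaluation <- function(x, ...) {
  tibble(decoy_id = x$decoy_id,
         global_rmsd = x$global_rmsd,
         bin = x$rmsd_bin,
         n_pairs = x$n_pairs,
         n_hits = x$n_hits,
         fpair = x$fpair)
}

#' Evaluate a set of decoys
#'
#' Runs [evaluate_complex()] on every decoy and aggregates the per-class
#' distribution of pairwise hit counts — the summary used to ask how many
#' correctly predicted chain pairs survive in globally inaccurate models.
#' A decoy that fails to evaluate is recorded in the error table and the
#' run continues; only all decoys failing is an error.
#'
#' @param native A `complex_structure` (or path to a PDB file).
#' @param decoys List of `complex_structure` objects and/or PDB file paths;
#'   must be non-empty.
#' @param config An [eval_config()].
#' @return A `decoy_set_report`: list with `native_id`, `decoys` (one row
#'   per evaluated decoy, including one `iRMSD_X-Y` column per chain pair),
#'   `histogram` (`bin` x `n_hits` decoy counts), `errors` and `config`.
#'   See [hit_histogram()], [autoplot.decoy_set_report()],
#'   [write_decoy_report()].
#' @export
evaluate_decoy_set <- function(native, decoys, config = eval_config()) {
  if (is.character(native)) native <- read_pdb(native)
  if (inherits(decoys, "complex_structure")) decoys <- list(decoys)
  if (length(decoys) == 0) {
    abort("no decoys to evaluate", class = "fpair_validation_error")
  }

  rows <- list()
  pair_rows <- list()
  errors <- list()
  for (i in seq_along(decoys)) {
    d <- decoys[[i]]
    res <- tryCatch({
      if (is.character(d)) d <- read_pdb(d)
      evaluate_complex(native, d, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      id <- if (is.character(d)) basename(d) else d$id
      errors[[length(errors) + 1]] <-
        tibble(decoy_id = id, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- glance(res)
      pair_rows[[length(pair_rows) + 1]] <- tidy(res)
    }
  }
  if (length(rows) == 0) {
    abort("all decoys failed to evaluate", class = "fpair_run_error")
  }

  summary_tbl <- dplyr::bind_rows(rows)
  wide_irmsd <- dplyr::bind_rows(pair_rows) %>%
    dplyr::mutate(pair = paste0("iRMSD_", .data$chain_x, "-", .data$chain_y)) %>%
    dplyr::select("decoy_id", "pair", "irmsd") %>%
    tidyr::pivot_wider(names_from = "pair", values_from = "irmsd")
  decoys_tbl <- dplyr::left_join(summary_tbl, wide_irmsd, by = "decoy_id")

  labels <- bin_labels(config$bins)
  histogram <- summary_tbl %>%
    dplyr::count(bin = factor(.data$bin, levels = labels), .data$n_hits,
                 name = "n_decoys") %>%
    dplyr::arrange(.data$bin, .data$n_hits)

  structure(list(
    native_id = native$id,
    decoys = decoys_tbl,
    histogram = histogram,
    errors = if (length(errors)) dplyr::bind_rows(errors) else
      tibble(decoy_id = character(), error = character()),
    config = config), class = "decoy_set_report")
}

#' @export
print.decoy_set_report <- function(x, ...) {
  cat("<decoy_set_report> native ", x$native_id, ": ",
      nrow(x$decoys), " decoy(s) evaluated, ",
      nrow(x$errors), " failed\n", sep = "")
  print(hit_histogram(x))
  invisible(x)
}

#' Per-class histogram of pairwise hit counts
#'
#' @param report A `decoy_set_report`.
#' @return Tibble with columns `bin`, `n_hits`, `n_decoys`.
#' @export
hit_histogram <- function(report) {
  stopifnot(inherits(report, "decoy_set_report"))
  report$histogram
}

#' @export
tidy.decoy_set_report <- function(x, ...) x$decoys

#' @export
glance.decoy_set_report <- function(x, ...) {
  tibble(native_id = x$native_id,
         n_decoys = nrow(x$decoys),
         n_errors = nrow(x$errors),
         n_bins_populated = dplyr::n_distinct(x$histogram$bin),
         best_global_rmsd = min(x$decoys$global_rmsd),
         best_fpair = max(x$decoys$fpair))
}

#' Write a decoy-set report to disk
#'
#' The TSV holds one row per decoy (id, global RMSD, class, hit count,
#' fpair, one iRMSD column per chain pair); the JSON summary holds the
#' per-class hit-count histogram.
#'
#' @param report A `decoy_set_report`.
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return Invisibly, `report`.
#' @export
write_decoy_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "decoy_set_report"))
  if (!is.null(tsv)) {
    out <- report$decoys
    out$fpair <- round_half_up(out$fpair, 2)
    readr::write_tsv(out, tsv)
  }
  if (!is.null(json)) {
    hist_list <- report$histogram %>%
      dplyr::mutate(bin = as.character(.data$bin)) %>%
      split(.$bin) %>%
      lapply(function(d) {
        list(total = sum(d$n_decoys),
             hits = setNames(as.list(d$n_decoys), d$n_hits))
      })
    jsonlite::write_json(
      list(native_id = report$native_id,
           n_decoys = nrow(report$decoys),
           n_errors = nrow(report$errors),
           bins = hist_list),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Plot a decoy-set report
#'
#' Grouped bar chart of decoy counts per global-RMSD class, coloured by the
#' number of pairwise hits — the standard way to see that models with a
#' large global RMSD can still contain correctly predicted chain pairs.
#'
#' @param object A `decoy_set_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoy_set_report <- function(object, ...) {
  h <- hit_histogram(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$n_decoys,
                                  fill = factor(.data$n_hits))) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "global C-alpha RMSD class (Å)",
                  y = "decoys",
                  fill = "pairwise hits",
                  title = paste0("Pairwise hit counts per RMSD class: ",
                                 object$native_id)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.decoy_set_report
#' @param report A `decoy_set_report`.
#' @export
plot_hit_histogram <- function(report, ...) autoplot(report, ...)
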