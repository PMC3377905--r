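---
title: "Evaluating multiple protein docking models by correct pairwise subunits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multiple protein docking models by correct pairwise subunits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpair)
```

## The problem

Predicted structures of multi-chain protein complexes are conventionally
judged by a single global measure — the Cα RMSD of the whole model after
optimal superposition onto the experimental (native) structure.  For
multimeric models this conflates two very different failure modes: a model
in which *every* inter-subunit arrangement is wrong, and a model in which
most subunit pairs are docked correctly but one chain is misplaced.  Both
can have a global RMSD of 15-20 Å; only the second is biologically useful,
because it contains interfaces that are essentially right.

`fpair` quantifies that local accuracy.  Every unordered chain pair of an
N-chain complex is evaluated on its own, with the pairwise-docking
community's standard yardstick, and the result is summarized as the
fraction of pairs predicted acceptably:

$$ f_{pair} \;=\; \frac{\sum_{p\in P} I\!\left(\mathrm{iRMSD}(p) < 4\,\text{Å}\right)}{N(N-1)/2} $$

`I` is the indicator function and `P` the set of all
$\binom{N}{2}$ chain pairs.  A pair below 4 Å interface RMSD — the CAPRI
acceptable-prediction criterion — is a *pairwise hit*.

## The metrics and their construction

**Interface RMSD (iRMSD).**  For a pair (X, Y) the interface is defined on
the *native* structure only: all residues of X with any heavy atom within
10 Å of any heavy atom of Y, plus the symmetric set (10 Å is the CAPRI
interface convention; the cutoff is configurable).  The backbone atoms
(N, Cα, C, O; a Cα-only mode is available) of those residues are collected
from both structures in identical order, restricted to residues present in
both, and the decoy's atoms are superposed onto the native's by least
squares.  The minimized RMSD is the iRMSD.  Only the pair's own atoms
enter the fit — the rest of the complex is ignored, which is exactly what
makes the measure local: a pair moved rigidly as a unit scores 0.

Fitting and measuring on the same interface atom set is the standard
iRMSD construction; the hit criterion is a strict `<` at the 4 Å
threshold.

**Non-contacting pairs.**  In complexes with more than three chains some
pairs never touch in the native.  Their interface is empty, but the fpair
denominator counts *all* pairs, so the evaluation falls back to
superposing all shared backbone atoms of the two chains and flags the
result `used_fallback`.  This keeps the denominator honest while marking
that the number measures mutual placement rather than an interface.  The
fallback value is interpretively weaker: for two small, distant chains a
whole-pair fit has more freedom to absorb a perturbation (see
*Limitations*).

**fnat.**  As a supporting metric, `pair_fnat()` reports the fraction of
native residue-residue contacts (any heavy-atom distance ≤ 5 Å, the CAPRI
convention) reproduced in the model, and is undefined (`NA`) for pairs
with no native contacts.

**Global RMSD and classes.**  `global_rmsd()` superposes *all* mapped Cα
atoms simultaneously and decoys are binned into the six half-open classes
0-4, 4-8, 8-12, 12-16, 16-20 and 20+ Å (lower bound inclusive; the
boundary convention is ours, the source classes being stated without one).
Reported fpair values are rounded half-up to two decimals; full precision
is kept in the objects and JSON output.

**Chain mapping.**  Decoy chains are matched to native chains by identity
of chain ids by default.  A user-supplied bijection is validated; for
complexes with sequence-identical chains an exhaustive permutation search
(within sequence groups, capped at 8 identical chains) minimizes the
global Cα RMSD, with ties broken in lexicographic permutation order.

## The superposition core

All RMSDs rest on one least-squares rigid superposition
(`kabsch_superpose()`): the SVD solution of the cross-covariance matrix,
with the reflection branch corrected so the returned rotation always has
determinant +1.  Orthonormality is maintained to 1e-8 and RMSD
comparisons in the tests use 1e-6 Å.  Degenerate inputs — fewer than
three points, collinear or coincident configurations, for which the
optimal rotation is not unique — raise a typed error instead of returning
an arbitrary frame.  The test suite cross-checks the implementation
against a brute-force minimum over an Euler-angle grid refined by
Nelder-Mead, and against `bio3d`'s independent fitting routine.

## Synthetic natives and decoys

The generator exists so the whole stack can be exercised, deterministically
and at any scale, without external data.

`make_synthetic_native()` builds N poly-alanine chains of ideal backbone
bond geometry.  Each chain is a compact three-segment
helix-turn-helix-turn-helix bundle whose torsions are varied per residue
(seeded, ±10° around the helical values).  Two properties of real subunits
are deliberately reproduced:

* **Chains are conformationally unique and globular.**  A perfectly
  regular helix is a thin rod with two cheap rigid self-motions (a roll
  about its own axis costs only ~2 Å RMSD, and its screw symmetry nearly
  maps the chain onto itself).  With such chains, a whole-pair
  superposition can absorb a genuinely large rigid-body perturbation of a
  distant chain through a small lever-arm rotation, producing spurious
  "hits".  Globular, irregular chains make every rigid self-motion
  expensive, which is the regime real proteins are in.
* **Adjacent chains are guaranteed to touch.**  In the `"line"`
  arrangement each chain is slid along x until its nearest-atom distance
  to the previous chain is exactly the `inter_chain_gap` (default 5 Å, an
  ordinary inter-subunit approach distance well inside the 10 Å interface
  cutoff), so exactly the N−1 adjacent pairs are in contact and the
  non-adjacent pairs exercise the fallback path.  In the `"ring"`
  arrangement chains are tangent to a circle and per-chain radial offsets
  are relaxed until every adjacent gap is close to the target, so all
  adjacent pairs contact; for N = 3 that is every pair.

`make_decoy()` applies an independent random rigid move to each selected
chain: a rotation about the chain centroid (isotropic axis, angle from a
given range) plus a translation in a random direction.  Unmoved chains are
copied verbatim, so constructions like "displace k of N chains far beyond
the hit criterion" have a known expected outcome: the
$\binom{N-k}{2}$ pairs among unmoved chains are hits and nothing else is,
which is the combinatorial mechanism behind high-RMSD decoys that retain
correct sub-complexes.

`make_decoy_population()` cycles translation magnitudes
{0, 2, 6, 12, 25, 50} Å across moved-chain counts 1..N−1.  The magnitudes
were chosen from the superposition geometry: displacing one chain of a
3-chain complex by t shifts the fitted global Cα RMSD by roughly 0.47 t,
so the largest magnitude is what populates the 20+ Å class, and the
smaller ones spread the rest of the range.  Every generator function is
deterministic given its seed, down to the written PDB bytes.

## Problem sizes in the tests

The suite runs entirely on generated data at desk scale: chains of 10-24
residues, complexes of 2-6 chains, populations of up to 60 decoys, 100
rigid-invariance trials and 20 superposition-oracle instances — a couple
of minutes end to end.  These sizes are chosen because every property
checked (combinatorial identities, rigid invariance, oracle agreement) is
scale-free; nothing in the implementation is specific to small inputs.

## What the synthetic tests do and do not show

Passing on synthetic bundles demonstrates the *metrics* — the geometry,
the bookkeeping, the combinatorics and the determinism — under controlled
conditions where expected outcomes are provable.  It does not demonstrate
anything about real decoy populations: synthetic chains have no side
chains, no sequence variety, idealized interfaces and rigid internal
structure, and synthetic perturbations are exactly rigid, whereas real
docking models also deform chains internally.  Real PDB models are
evaluated through the same `read_pdb()` path (altloc resolution,
hydrogen/HETATM filtering, residue intersection), which the synthetic
route does not exercise as richly as crystallographic files do; the
fixture tests therefore include hand-written PDB edge cases for those
rules.

## Numerical and design choices

* Altlocs resolve to the highest-occupancy variant, ties to the smallest
  altloc code; first MODEL only; residues without Cα are dropped with a
  warning rather than erroring, so truncated termini do not abort a run.
* Residue identity is (chain, residue number, insertion code); decoys are
  assumed to preserve native numbering, and gaps are handled by
  intersection.
* Bin boundaries are lower-inclusive half-open intervals.
* The hit threshold is strict (`irmsd < 4`), per the criterion's wording.
* Rounding for reports is half-up at two decimals (`round_half_up()`),
  matching how the reference values are printed; `round()`'s banker
  rounding would differ on exact halves.
* The permutation search refuses groups larger than 8 sequence-identical
  chains (40320 candidate bijections) rather than attempt a factorial
  search silently.
* Per-decoy failures in `evaluate_decoy_set()` are recorded and skipped;
  only a fully failing set is an error — a real decoy stream may contain
  malformed files.

## Limitations

* The iRMSD of a genuinely non-contacting pair (fallback path) is a
  weaker statement than an interface iRMSD, and for very small chains at
  long separation a pair fit can absorb a surprising amount of rigid
  motion.  The `used_fallback` flag is carried through all outputs so
  downstream analysis can treat those pairs separately.
* Interfaces with very few residues (3-5) constrain the fit weakly; hits
  on such pairs are correspondingly noisier near the threshold.
* Chain mapping by permutation search optimizes global Cα RMSD, which may
  not be the mapping that maximizes fpair in pathological cases.
* No side-chain or ligand handling; mmCIF and NMR ensembles are out of
  scope.
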