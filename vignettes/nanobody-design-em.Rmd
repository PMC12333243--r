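---
title: "Iterative nanobody CDRH3 design by expectation-maximization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative nanobody CDRH3 design by expectation-maximization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoem)
```

## The problem

Generative CDR design conditions on a nanobody-antigen complex; producing
that complex computationally requires docking, and docking requires the
nanobody structure -- including the very CDRH3 loop that is being
designed. Linear workflows break this circularity by fixing one side
once. `nanoem` instead treats the complex as a latent variable and
alternates, in the style of expectation-maximization:

* **E-step** -- given the current best CDRH3 guesses, generate candidate
  complexes: dock each nanobody into `d` rigid poses, refine, reject
  poses with residual steric clashes or whose interface involves neither
  the CDRH3 nor the desired epitope, rank survivors by *epitope recall*
  `|E_original ∩ E_j| / |E_original|`, and carry the best poses forward.
* **M-step** -- given the selected complexes, design new CDRH3 loops: a
  generative engine proposes `k` variants per complex, each is
  side-chain packed, refined and re-screened, then ranked by predicted
  binding energy delta (absolute dG for de novo design, ddG against a
  reference complex for optimization; lower is better in both).

A beam of the best `n` designs seeds the next iteration. Two scheduling
details matter and are implemented as stated:

* **First-iteration lineage elitism.** Initialization randomizes the
  scaffold's CDRH3 `r` times (length-preserving, uniform over the
  20-letter alphabet), creating `r` lineages. After the first M-step the
  best design *of each lineage* is kept (up to `r` survivors) rather
  than the global top `n`: energies are still equilibrating in the first
  round, and per-lineage selection preserves diversity. All later
  iterations keep the global top `n` by delta.
* **The first-iteration accounting.** With top-`n`-per-lineage E-step
  selection, the first design pool holds exactly `r * n * k` candidates
  before quality control. The E-step selection scope for later
  iterations is global top-`n`; both scopes are implementation-defined
  in one place (`e_step`) should a different schedule be wanted.

When filtering annihilates a pool the run stops with an exhaustion error
naming the dominant filter reason rather than silently relaxing
thresholds; the caller can retry with larger `d`.

## Quality control

A pose or design is rejected for any of three reasons, which accumulate:

1. `clash_after_refinement` -- the complex still contains steric clashes
   after refinement. An atom pair clashes when its distance is below
   `vdw_i + vdw_j - tolerance` (default tolerance 0.4 Angstrom; van der
   Waals radii C 1.70, N 1.55, O 1.52, S 1.80, H 1.20). Atoms of the
   same residue, and backbone-backbone pairs of chain-adjacent residues,
   are exempt as covalently bonded. The cell-grid implementation is
   required (and tested) to equal the quadratic definition exactly.
   Intra- and inter-chain clashes both count: a strict reading under
   which even a clash far from the interface rejects the pose.
2. `cdrh3_not_in_interface` -- no antigen interface residue lies within
   the contact cutoff (default 5.0 Angstrom, heavy atoms) of the CDRH3.
3. `epitope_not_in_interface` -- the predicted epitope shares no residue
   with the desired epitope.

The interface itself is determined by differential solvent-accessible
surface area: `dSASA(residue) = SASA(isolated chain group) -
SASA(complex)`, with residues above 1.0 square Angstrom of burial
(configurable) classed as interfacial. SASA uses the Shrake-Rupley
algorithm with a deterministic golden-spiral point set (default 960
points, probe 1.4 Angstrom). Both the burial threshold and the contact
cutoff are conventions rather than published values, and are exposed as
configuration.

Refinement is a pluggable contract. The bundled reference engine is a
soft-sphere minimizer: gradient descent on a purely repulsive potential
over clashing pairs, stepping until clash-free or the step budget is
exhausted, never returning a structure with more clashes than its input.
A molecular-dynamics engine can be substituted behind the same contract;
nothing in the tests requires one.

## Engines

The five heavy stages are contracts with seeded mock reference
implementations, pure functions of their inputs and seed:

* *Structure prediction*: threads a sequence onto the template backbone;
  CDR residues receive a deterministic jitter keyed by their local
  3-mer, so different loop sequences get different loop geometry,
  reproducibly, and an unchanged sequence reproduces the template
  bit-for-bit.
* *Docking*: samples `d` rigid poses, by default 80% guided (CDRH3
  centroid oriented onto the epitope centroid at contact distance, with
  angular and translational noise) and 20% unrestrained; scores poses by
  negative epitope-paratope contact count and returns them sorted.
* *CDR design*: proposes `k` variants with 1-3 substitutions confined
  to the selected CDRs, re-threaded through the predictor.
* *Side-chain packing*: leaves the backbone untouched and places a
  pseudo-CB 1.53 Angstrom from each non-glycine CA along the local chain
  binormal (idempotent; glycine receives no CB).
* *Binding energy*: sums a fixed 20x20 pairwise affinity table over
  cross-chain CA-CA contacts below 8 Angstrom, plus one kcal/mol per
  clash. The table is `m(a, b) = -5 + 0.25 * circdist(a, comp(b)) +
  0.0005 * idx(a)` with `comp` a fixed alphabet rotation: for every
  antigen residue there is a unique strictly-best partner
  (`planted_complement()`), so the mock landscape has a verifiable
  planted optimum; the tiny index term makes every argmin strict. The
  1-substitution neighborhood of the planted optimum is checked by brute
  force in the tests.

Randomness is organized as one master seed with stage-level substreams
derived by stable hashing of (stage, iteration, candidate index), so
changing `k` does not perturb the docking draws, and two runs with the
same configuration produce bit-identical ledgers.

## The synthetic fixture system

The generator builds a desk-scale world in which every pipeline stage is
exercised end to end:

* a 113-residue single-chain **nanobody** carrying a consensus VHH
  framework sequence with CDR windows H1 26-33, H2 50-57, H3 97-102,
  the H3 flanked by the conserved Cys96...Trp103 junction. Framework
  residues lie on a serpentine sheet; the CDRH3 protrudes below it as
  the sole contact tip, its residue spacing matched to the antigen
  lattice so the loop can lie along a surface row;
* a 60-residue **antigen** slab (6 x 5 x 2 lattice, 4.5 Angstrom
  spacing, seeded uniform jitter of 0.2 Angstrom) whose designated
  epitope is the fully exposed 6-residue top-edge row;
* a reference **complex** posing the loop diagonally onto that row at a
  3.6 + 3.6 Angstrom offset, clash-free by construction, with an
  optional number of planted, isolated inter-chain clash pairs for
  filter tests.

Geometric margins are chosen so that no nanobody-antigen CA pair sits
near the 8 Angstrom energy-contact boundary: the predictor's threading
jitter (0.15 Angstrom per coordinate) can therefore never flip a contact
set, which is what makes the planted-optimum brute-force check exact.

These are CA-trace toys. They emulate chain topology, a planted surface
epitope, dockable geometry, steric exclusion and a nontrivial
sequence-energy landscape. They do **not** emulate side-chain chemistry,
backbone flexibility, real binding physics, or the size and diversity of
curated structure collections -- so green tests certify the algorithmic
machinery (filtering, ranking, accounting, selection scheduling,
determinism, metric correctness), not predictive performance on real
antigens. Real engines (structure predictors, docking programs, force
fields) would be attached behind the engine contracts for that.

## Evaluation battery

`aar` (equal-length sequence identity), `kabsch` (SVD superposition with
reflection correction), `rmsd_region` (region CA RMSD after alignment on
a chosen residue set), `tm_score` (d0 = 1.24 (L-15)^(1/3) - 1.8,
maximized over superpositions by deterministic iterative subset
refinement seeded from the whole-chain fit), `lddt` (CA-only,
superposition-free, thresholds 0.5/1/2/4 Angstrom within a 15 Angstrom
inclusion radius), `dockq` (fnat at 5 Angstrom heavy-atom contacts,
ligand RMSD after receptor superposition, interface RMSD over the 10
Angstrom interface, combined with scales 1.5/8.5), `success_rate`
(percent of designs with negative ddG) and `ci_margin`
(`1.96 * sigma / sqrt(n)`). Constants for TM-score, lDDT and DockQ are
the canonical ones from their defining publications. Choices the sources
leave open, resolved here:

* the CDRH3 RMSD is **framework-anchored** by default (superpose on the
  whole chain, measure over the loop); aligning on the loop itself is
  available through `align_on`;
* `sigma` in `ci_margin` is the **population** standard deviation
  (`sd_type = "sample"` switches);
* lDDT is CA-only, since designed side chains come from a packing
  engine that is not under test;
* residues inside CDR ranges are ordered by `(resseq, icode)` as they
  appear in the chain, covering numbering-scheme insertions.

## Numerical choices and edge cases

* Shrake-Rupley with a fixed point set is exactly invariant under
  translation but only approximately under rotation (the quadrature
  directions live in the lab frame): total-area deviation is about 1%
  at 960 points and shrinks roughly linearly in the point count. The
  tests assert convergence rather than pretending exact invariance.
* Pipeline-internal interface detection uses 320 sphere points (the
  standalone default stays 960): burial classification at a 1 square
  Angstrom threshold is insensitive to the coarser quadrature, and the
  E/M loops evaluate thousands of interfaces per run. Only residues
  within occlusion reach of the other chain can change exposure, so
  dSASA is computed exactly but only where it can be non-zero.
* The clash grid uses cells at least as large as the largest pair
  cutoff, which makes it provably equal to the all-pairs rule.
* Kabsch handles degenerate (collinear) inputs through the sign
  correction on the smallest singular vector; rank-deficient cases
  still return a proper rotation.
* Ties are broken deterministically everywhere: epitope-recall ranking
  by larger desired-epitope overlap then docking rank; delta ranking by
  lineage id then insertion order.
* CDR location is primarily user-supplied. The heuristic maps fixed
  windows through a BLOSUM62 global alignment to a built-in VHH
  framework profile and anchors the H3 on the Cys...Trp junction motif,
  falling back to a direct motif scan, and errors with advice rather
  than guessing when neither resolves. Full HMM-based numbering is
  deliberately out of scope: downstream stages consume positions, not
  numbering.

## Default parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `r` | 4 | count | randomized CDRH3 lineages at initialization |
| `d` | 20 | count | docked poses per nanobody per E-step |
| `n` | 4 | count | beam width |
| `k` | 8 | count | designs per complex per M-step |
| `iterations` | 10 | count | EM iterations (matches the published runs) |
| `dsasa_threshold` | 1.0 | sq. Angstrom | interface burial threshold |
| `contact_cutoff` | 5.0 | Angstrom | per-CDR heavy-atom contact cutoff |
| `overlap_tolerance` | 0.4 | Angstrom | allowed van der Waals overlap |
| `probe_radius` | 1.4 | Angstrom | solvent probe |
| `sasa_n_points` | 320 | count | pipeline-internal sphere sampling |
| `refine_max_steps` | 200 | count | soft-sphere descent budget per pose |

The bundled benchmark (`benchmark_em_vs_linear()`) runs the EM loop at
`r = 4, d = 20, n = 4, k = 8` for 6 iterations against the
single-iteration linear workflow on 30 paired master seeds, de novo
mode, scoring success as a negative best ddG against the fixture's
scaffold reference complex. These problem sizes keep a full paired
benchmark to minutes on one CPU while leaving every stage non-trivially
loaded.

## Known limitations

* The mock energy has a large dynamic range driven by contact count;
  against the fixed scaffold reference both the EM and the linear arm
  can saturate the *binary* success criterion, in which case the paired
  best-delta comparison (reported alongside) is the discriminating
  signal. The EM arm can never be worse there: with shared
  initialization substreams its first iteration reproduces the linear
  workflow and later iterations only extend the search.
* A single-domain binder and one antigen chain per complex; no light
  chains, no multi-antigen batches.
* PDB input only (no mmCIF), protein residues only; waters, ligands and
  nucleic acids are skipped on read.
* CDRH3 randomization and design preserve loop length; length
  resampling would require a predictor contract that can re-map residue
  correspondence.
* Early stopping on stalled delta is available but off by default, to
  match the fixed-iteration published protocol.
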