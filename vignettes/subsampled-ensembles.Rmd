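---
title: "Conformational ensembles from subsampled alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensembles from subsampled alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subfold)
```

## The problem

Deep-learning structure predictors are trained to return a protein's
ground-state conformation, yet many proteins of pharmacological interest
— kinases being the canonical example — populate several conformations
with functionally decisive relative populations. Subsampling the input
multiple sequence alignment (MSA) before inference weakens and
perturbs the co-evolutionary signal the network decodes, and across
many independently seeded predictions the resulting structures spread
over the protein's conformational landscape. Counting how many
predictions fall into each conformational state then gives a
high-throughput estimate of relative state populations — good enough,
empirically, to rank the effects of single point mutations on a
kinase's active-state occupancy.

`subfold` implements that protocol end to end, with the neural-network
predictor isolated behind a pluggable backend so that every other stage
— subsampling, manifest bookkeeping, projection, binning, population
statistics, MD comparison — is exactly testable on synthetic data with
planted ground truth.

## The subsampling heuristic

Given an alignment of $N$ rows, the predictor's featurization draws
`max_seq` rows uniformly without replacement as *cluster centers*; the
query (target) row is always one of them. Every remaining row is
assigned to the center minimizing the Hamming distance (number of
differing columns), each cluster is featurized as per-column symbol
frequencies over the 20 amino acids plus gap, and `extra_seq`
additional non-center rows are sampled for the cheaper input track.
`subsample_msa()` reproduces this pipeline deterministically under a
seed.

Decisions the upstream description leaves open, and how this package
resolves them:

* **Gap handling.** The gap is a 21st ordinary symbol: two gaps match,
  gap versus residue mismatches. Simple, symmetric, and directly
  testable; no weighting scheme is attested.
* **Tie-breaking.** Equidistant rows go to the center appearing
  earliest in `center_indices`. This makes assignment deterministic and
  independent of the RNG state.
* **Global versus per-cluster extras.** Published descriptions of the
  extra-sequence sample disagree between "a sample from each cluster"
  and a global draw of non-center rows; the global reading is
  implemented (it is the one consistent with a single `extra_seq`
  count), and the per-cluster variant is noted as future work.
* **Shallow alignments.** When $N \le$ `max_seq`, every row becomes a
  center, assignment is empty, and a warning notes that subsampling has
  no effect — the regime in which a 112-sequence alignment differs
  qualitatively from a 600,000-sequence one.
* **Non-canonical letters.** Real alignments contain X/B/Z; they are
  mapped to an explicit `X` bucket so profile columns still sum to 1.

The canonical protocol parameters are `max_seq = 256`,
`extra_seq = 512` — the combination found to maximize activation-loop
diversity for a kinase core — with 3 replicates × 32 seeds × 5 models
(480 predictions), 3 recycles, and inference-time dropout of 10%
(Evoformer) / 25% (structure module). Dropout and recycles are
pass-through metadata here: no network is run inside the package, and
adapters for external predictors translate them to tool flags.

Per-task seeds are derived from the master seed by a frozen integer
mixing function (`mix_seed`), so a manifest is fully reproducible from
`(n_replicates, n_seeds, n_models, master_seed)` alone. Each task
re-subsamples the MSA with its own derived seed; whether the original
protocol re-subsampled per seed is not documented, and per-task
subsampling is the choice that makes every prediction independent.

## Ensemble analysis

Predicted structures (PDB files, per-residue pLDDT in the B-factor
column) are projected onto two reference states by backbone RMSD
(atoms N, CA, C, O). Superposition is least-squares (Kabsch, with the
determinant correction), fitted on a stable `fit_range` — for a kinase,
the core, residues 242–459 — and measured on a separate `calc_range` —
the activation loop, 379–395 — *without refitting*, so a mobile element
is measured in the frame of the stable scaffold.

**State binning.** The exact thresholds used in the original analysis
are not published. The package bins by nearest reference with an
absolute cutoff plus a separation margin: a conformer is `state_A` when
RMSD(A) ≤ `cutoff_A` *and* RMSD(B) − RMSD(A) ≥ `margin`
(symmetrically for B), `intermediate` otherwise. Defaults
(3.5 Å / 3.5 Å / 1.0 Å) are conservative; all four numbers are
configuration, and no claim is made that they match the unpublished
scheme.

**Populations.** Within each replicate the state fraction is a simple
count ratio; the reported estimate is the across-replicate mean ±
standard error (sample SD over replicates, $n-1$ denominator, divided
by $\sqrt{n}$), matching the mean ± SEM over three independent runs
convention. Unfolded conformers stay in the denominator by default and
are reported as their own state; a switch excludes them.

**Unfolded detection.** Aggressive subsampling of shallow alignments
occasionally produces partially unfolded predictions. A conformer is
flagged when its backbone radius of gyration exceeds 1.25× the
reference's, or its global backbone RMSD exceeds 10 Å. Both criteria
are deliberately blunt compactness proxies — they catch gross expansion
and gross misfolds, not subtle local unfolding — and are configurable.

**Parameter scans.** `scan_parameters()` ranks `(max_seq, extra_seq)`
pairs by ensemble diversity, measured as the standard deviation of the
calc-range RMSD to reference A after excluding unfolded-flagged
conformers. The original ranking metric is unpublished; the standard
deviation is transparent, and the unfolded fraction is reported next to
it so a diversity gained through artefacts is visible.

## MD comparison

A predicted ensemble can be compared against snapshots from an MD
trajectory through arbitrary observables: region backbone RMSD,
atom-pair distances (e.g., the backbone-oxygen distances E377–L409 and
L409–G457 that track a kinase activation-loop transition), and
dihedrals. `compare_to_snapshots()` reports, per (snapshot, conformer)
pair, core RMSD, region RMSD in the core-fitted frame, and signed
distance deltas (conformer − snapshot).

*Pathway coverage* quantifies whether predictions populate the
transition rather than only its endpoints: the observable's range along
the trajectory is split into `n_bins` equal bins (10 by default) and
coverage is the fraction of bins holding at least one prediction.
Out-of-range predictions clamp to the terminal bins — coverage stays
≤ 1 and informative extremes are not discarded. A degenerate range
(constant observable) is an error, not a coverage of 1.

The dihedral sign follows the IUPAC convention (checked against an
independent normal-vector construction and a third-party library);
the quadruple of atoms is always explicit, because the published
description of the relevant side-chain dihedral ("the D381 dihedral
with the plane of the A380 side chain") does not determine a unique
atom set.

## The synthetic world

All statistical guarantees are demonstrated on generated data with
planted truth:

* **Toy folds** are ideal-geometry backbones (N–CA 1.458 Å, CA–C
  1.525 Å, C–N 1.329 Å; helix φ/ψ = −57°/−47°, ω = 180°) assembled
  from helix and loop segments. State B rigidly displaces one
  designated mobile segment — by default a 17-residue loop moved 15 Å,
  mirroring the scale of a kinase activation-loop rearrangement.
* **Two-state ensembles** draw each conformer from state A with
  probability `p_ground` plus isotropic Gaussian noise (default σ =
  0.3 Å, comfortably below the 12–15 Å state separation). `"exact"`
  sampling plants round-to-nearest per-replicate counts so small-$n$
  tests are not flaky; `"bernoulli"` sampling drives the statistical
  recovery tests. Defaults (3 × 160 conformers, `p_ground` = 0.9)
  mirror the regime of a kinase near 90% active-state occupancy.
* **Unfolded decoys** are coordinates scaled ×2 about the centroid
  (Rg ratio exactly 2), guaranteeing deterministic detection by the
  1.25 criterion; their pLDDT is written as 40 versus 90 for folded
  conformers — two constants, not an emulation of real confidence
  behaviour.
* **Planted-cluster MSAs** mutate the query at a between-cluster rate
  (0.4) to make seeds, and each seed at a within-cluster rate (0.02)
  to make members, so nearest-center assignment provably recovers the
  planted partition.
* **The mock backend** maps each `max_seq` to a `(p_ground, σ)` pair,
  which suffices to exercise manifest bookkeeping, determinism, failure
  quarantine, and scan ranking end to end.

What a green synthetic test does *not* establish: that any real
predictor's ensembles are calibrated, that the default binning
thresholds suit a given protein, or that populations transfer
quantitatively to Boltzmann ratios (explicitly an open question for
this class of method). The generators emulate geometry and sampling
statistics, not predictor physics.

## Numerical choices

* Profile columns sum to 1 within 1e−9; empty clusters cannot occur
  (the center is always a member).
* Superposition requires ≥ 3 paired atoms; the reflection case is
  handled by the determinant correction.
* Medians use midpoint interpolation for even counts (R's default
  `quantile` type 7), matching box-plot conventions.
* PDB coordinates round-trip at the fixed-column precision of 0.001 Å;
  tests compare at 1e−3.
* All RNG use is localized (`with_seed`): callers' RNG state is never
  clobbered, and identical seeds give bitwise-identical outputs.
* Derived seeds stay below 2³¹ and distinct within any realistic
  manifest.

## Known limitations

* Only single-chain, author-numbered structures; no mmCIF, no altlocs,
  no insertion codes.
* MD ingestion is PDB frames only; binary trajectory formats are out of
  scope.
* The backend shipped in the package is the mock; wrapping a real
  predictor is the user's adapter (the contract is three arguments:
  featurized subsample, seed, model id).
* Binning is threshold-based; clustering into unanticipated states
  (beyond a third reference) is not provided.
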