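---
title: "Pair-count scoring functions: model, protocols and design notes"
author: "pairscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-count scoring functions: model, protocols and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscore)
```

## The model

A scoring function (SF) maps a 3D protein–ligand complex to a number meant
to track binding strength. `pairscore` implements the classical
pair-count family of machine-learned SFs: the complex is represented by
counts of target–ligand atomic pairs, binned by distance, and a small fully
connected neural network regresses those counts onto affinity labels.

**Representation.** For every combination of a target-side species
$A \in \{$H, C, N, O, F, P, S, Cl, Br, I$\}$, a ligand-side species
$A' \in \{$H, C, N, O, P, S$\}$ and a distance interval
$k = 1, \dots, k_{\max}$, the descriptor $N_k^{AA'}$ counts pairs (target
atom of species $A$, ligand atom of species $A'$) whose Euclidean distance
$d$ satisfies $(k-1)\ell \le d < k\ell$. Hydrogens are part of the
representation, so structures are expected to be protonated. The two
species lists give $10 \times 6 = 60$ channels per interval; the default
scheme uses $\ell = 2$ Å and $k_{\max} = 4$ (an 8 Å cutoff), i.e. 240
descriptors. That default is the representation optimum found by scanning
widths 1.5/2/3 Å against interval counts up to 6/7/5 — the scan itself is
available as `scanDescriptors()`.

Ligand atoms outside the six-species list (halogens, metals) are ignored by
the featurizer; `speciesFilterReport()` surfaces them. Target-side
halogen channels are kept even where they are constantly zero: dense
networks learn to ignore constant inputs, and a fixed channel layout keeps
descriptor matrices and saved models portable.

**Normalization.** Raw counts spread over orders of magnitude, so the
whole matrix is divided by one scalar: the maximum entry over all channels
of all fitted complexes (`fitNormalizer()` / `applyNormalizer()`). Held-out
complexes may exceed 1 after scaling; that is expected.

**Targets.** Labels are pKd ($-\log_{10} K_d$, `pKdFromKd()`), pKi, or
negated docking scores (`negateDockingScore()`, so higher = putatively
stronger). For training they are standardized, $d' = (d - \mu)/\sigma$;
being a positive affine map this cannot change the Pearson correlation, and
reported MSE is always computed after inverting it, on the original scale.
$\sigma$ is the population SD (divisor $n$): the database-scale difference
between $n$ and $n-1$ is immaterial, but the choice must be fixed for
reproducibility.

**Regressor.** A dense network with $N_l$ tanh hidden layers of $N_h$
units each and a single linear output, trained by mini-batch ADAM
(defaults: learning rate $10^{-3}$, moment decays 0.9/0.999, $\epsilon =
10^{-8}$) minimizing MSE plus an L2 penalty $\lambda \sum w^2$ on the
weights (biases excluded). $\lambda$ defaults to 0: regularization was not
found to help this architecture/representation combination. Weight
initialization is symmetric-uniform with Glorot fan scaling, a standard
choice for tanh units; it is seeded, and a fixed seed gives a bit-identical
training trajectory in single-threaded BLAS. Reference architectures:
2×20 suits databases of a few thousand complexes, 4×40 tens of thousands
(deeper networks extract more from larger databases but overfit sparse
ones); `scanArchitecture()` reproduces that comparison.

**Early stopping.** Training runs until the monitored MSE stops improving
for `patience` epochs, then restores the best-monitor weights. Two
monitoring modes exist. `mode = "clean"` (default) holds out 10% of the
training complexes as a validation monitor, so the test set never
influences training. `mode = "legacy"` monitors the test set itself —
the historical protocol, adopted when databases were too small to spare a
validation set; it leaks the stopping decision and tends to slightly
overestimate performance, which is exactly why it is not the default but
remains available for protocol replication. The same leak/no-leak switch
governs whether the normalizer and standardizer are fitted on the training
portion only (clean) or on the whole database (legacy).

## Evaluation protocols

- **Horizontal** (`horizontalSplit()`): uniformly random test complexes,
  around 20% of the database (`testFraction` is rounded to the nearest
  count; an explicit `nTest` takes precedence). The same protein may appear
  on both sides bound to different ligands, which is what makes horizontal
  scores optimistic for universal SFs.
- **Vertical** (`verticalSplit()`): all complexes of the held-out proteins
  form the test set; none of their complexes are trained on.
- **Leave-one-target-out** (`leaveOneTargetOut()`): one vertical plan per
  protein; the test sets partition the database.
- **Per-target** (`perTargetSplit()`): both sides restricted to one
  protein — the regime of an SF built on demand for a single target.

`evaluateProtocol()` repeats train/test ten times by default, reporting the
mean and the SEM (sample SD of repeats / $\sqrt{n}$) of Rp and MSE; the
averaging suppresses fluctuations from accidentally easy or hard test
draws. When $10\,n_{\text{test}}$ fits in the database the ten horizontal
test sets are drawn pairwise-disjoint ("non-overlapping splittings");
otherwise independent splits are drawn with a warning. One master seed
deterministically spawns per-repeat seeds, so any repeat can be re-run in
isolation. `learningCurve()` evaluates a grid of training-set sizes
$N_t$ (fresh subsample per repeat — subsets at different $N_t$ are
independent, not nested) and also reports $100 N_t / N$.

**MW baseline.** `fitMwBaseline()` fits affinity $= A + B\,m$ by ordinary
least squares, $m$ being the ligand molecular weight from tabulated atomic
masses. It is fitted on the whole per-target database with no held-out
set, so its Rp is in-sample by construction; it exists as the null model
against which a per-target SF must be judged — for some targets mere
ligand size predicts affinity remarkably well.

## Synthetic databases

`FixtureSpec()`/`generateDatabase()` produce complexes with planted,
known structure–affinity relationships so the whole pipeline is testable
without external downloads. Each protein is a fixed atom cloud sampled in
a 2–12 Å shell around the origin and **reused across all of its ligands**,
so protein identity is geometrically real and vertical splits are
meaningful; each ligand is a fresh cloud in a 4 Å ball. Element
frequencies are skewed to drug-like composition (H/C/N/O at
0.35/0.35/0.15/0.10 with 2.5% P and S each). Affinity models:

- `pair_linear`: a linear function of the descriptor channels — the
  recoverable ground truth for the network;
- `mw_linear`: $A + B \cdot \text{MW}$ — the baseline's ground truth;
- `protein_id_only`: a per-protein constant — affinity carries no
  ligand information at all;
- `nonlinear`: a smooth nonlinear function of two descriptor sums —
  used to order network capacities.

Gaussian noise (default SD 0.5 pKi units, a plausible experimental
spread) is added on the affinity scale, seeded per complex so databases
regenerate bit-identically.

The geometry is deliberately crude: no bonds, no sterics, no docking. The
featurizer only sees distances and species, so extra realism would buy the
tests nothing — but it means passing tests demonstrate *algorithmic*
correctness and protocol behavior, not predictive performance on real
crystallographic or docked structures. Scores on real databases depend on
data curation and chemistry these fixtures do not emulate.

The `protein_id_only` fixture deserves emphasis: it reproduces, as a unit
test, the central methodological phenomenon that motivates vertical
benchmarks. When affinity depends only on protein identity, a horizontal
evaluation looks excellent (the network recognizes the protein from its
descriptor signature) while leave-one-target-out correlation collapses to
zero — the model never learned anything about binding. The acceptance
suite asserts horizontal mean Rp ≥ 0.8 and leave-one-target-out
|mean Rp| ≤ 0.2 on this fixture.

## Numerical choices and edge cases

- **Bin edges** are half-open, $[r_{\min}, r_{\max})$, so every pair falls
  in exactly one bin; $d = 0$ belongs to $k = 1$ and pairs at
  $d \ge k_{\max}\ell$ are not counted.
- **Channel order** is interval-major, then target species, then ligand
  species, each in listed order; names are `"A-A'-k"`.
- **Pair counting** is vectorized over the full target × ligand distance
  matrix; it is equivalence-tested against an independent brute-force
  double loop (the test-suite oracle). At the pocket sizes relevant here
  (≲ a few hundred atoms after the distance cutoff) a spatial index would
  not pay for itself.
- **Element resolution** when reading PDB: element columns 77–78 if
  present, else the leading alphabetic characters of the atom name with
  two-letter symbols (CL, BR) recognized before one-letter ones. Waters
  (HOH) are dropped; alternate locations other than blank/'A' are dropped;
  all other hetero records are kept as their element. Coordinates are Å
  throughout.
- **Degenerate inputs** error loudly rather than returning placeholders:
  constant affinities (zero-variance standardizer), all-zero descriptor
  matrices (degenerate normalizer), constant vectors in `pearsonR()`,
  constant molecular weights in the baseline, non-finite training loss.
- **Persistence**: model bundles serialize weights as 17-significant-digit
  decimal strings, which round-trip IEEE doubles exactly; a checksum and a
  scheme fingerprint are verified on load.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at desk scale: planted-linear
recovery uses 10 proteins × 230 ligands (2,000 training / 300 test
complexes, the 2×20 network, three seeds, asserting test Rp ≥ 0.95);
the horizontal-versus-vertical contrast uses 8 proteins × 110 ligands with
noise SD 0.5; scan and learning-curve tests use a few hundred complexes
with reduced epoch budgets. These sizes were chosen as the smallest at
which the corresponding effects are unambiguous.

## Known limitations

- Pair counts discard directionality, charge, hybridization and hydrogen
  bonds; the representation cannot distinguish complexes with identical
  pair-distance statistics.
- The fixtures do not mimic docking-pose physics, so conclusions about
  docked-structure databases require real data.
- `mode = "legacy"` intentionally reproduces a protocol with test-set
  leakage into early stopping and normalization; use the default clean
  mode for honest generalization estimates.
- No scaffold- or similarity-based splits; vertical splits treat protein
  identity as the only relatedness structure.
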