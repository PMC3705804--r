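---
title: "Methods: descriptor-based pIC50 modeling with mRMR-BFS and SVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor-based pIC50 modeling with mRMR-BFS and SVR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsardpp)
```

# Scope and model

`qsardpp` builds regression models that map physicochemical descriptors of
small molecules to their DPP-IV inhibitory potency, expressed as pIC50
(dimensionless, −log10 of the molar IC50). The modeling chain is:
descriptor computation from V2000 connection tables, a two-stage feature
selection (mRMR ranking followed by LOOCV-driven backward elimination),
an ε-insensitive support vector regression with an RBF kernel, and
q²/RMSE validation on training, cross-validation, and external test
predictions.

The statistical assumptions are the usual QSAR ones: the training
compounds span the chemistry of the queries (interpolation, not
extrapolation), descriptors are complete (missing cells are errors, not
imputed), and activity noise is homoscedastic on the log scale. The
external-split procedure — rank by activity, hold out every fourth
compound — guarantees that the test set spans the full activity range
rather than being a random (possibly range-truncated) sample; its cost is
that test compounds are never extreme: the most and least potent
compounds always stay in training, which flatters neither q² nor RMSE but
does mean the split is not random and should not be treated as an
unbiased generalization estimate over chemical space.

# Descriptors

* **Elemental analysis** (`OComposition`, and `mass_fraction()` for any
  element): percent by mass, computed after materializing implicit
  hydrogens with standard valence rules (C 4, N 3, O 2, S 2/4/6, P 3/5,
  halogens 1; aromatic bonds count 1.5 toward used valence). Mass percent
  rather than atom-count percent is a package decision — the two differ,
  and mass percent is what elemental analysis conventionally reports.
  Atomic masses are the IUPAC 2021 standard atomic weights, pinned in a
  packaged table so results do not drift with external data updates.
* **Topology**: `ring_bond_count()` counts bonds on at least one cycle
  (non-bridges). `aliphatic_ring_count()` counts smallest-set-of-smallest-
  rings members whose bonds are not all aromatic. The SSSR is a minimal
  cycle basis: smallest ring through every cycle bond, accepted greedily
  under GF(2) independence; the ring *count* is fixed at the circuit rank
  (bonds − atoms + components), which is well defined even where the SSSR
  itself is ambiguous (e.g. fused symmetric systems). When a file carries
  no aromatic flags, six-membered rings of strictly alternating
  single/double bonds are perceived aromatic; five-membered heteroaromatics
  drawn kekulized are *not* detected — files should carry flag-4 bonds
  when that matters.
* **Geometry**: `projection_areas()` treats atoms as van der Waals disks
  (Bondi radii, Å) projected on the plane orthogonal to each sampled view
  direction; the union-of-disks area is integrated by counting covered
  grid-cell centers. Defaults: 200 directions, 0.05 Å grid. Directions
  form a deterministic lattice whose first entries are the two poles and
  the equator, followed by a golden-angle spiral with van-der-Corput
  latitudes; prefixes are nested, so increasing `n_orientations` can only
  widen (never contract) the observed min–max bracket. The conformer is
  the caller's responsibility: projection areas are a property of the 3D
  coordinates in the file, and no conformer search is attempted.
* **BasicpKa** is deliberately *not* predicted. Reliable basic-pKa
  prediction needs an empirical model trained on ionization data, which
  is out of scope; the descriptor is a passthrough column keyed by sample
  id (`sample_id,BasicpKa` CSV).

# mRMR ranking

Relevance and redundancy are mutual informations estimated after
discretization; the integral over joint densities becomes a finite double
sum over the empirical joint table, with 0·log 0 ≡ 0 and natural
logarithms (rankings are invariant to the log base). The default
discretization is the classic three-state mean ± σ split
(`mean_sigma`, σ-factor 1.0); equal-frequency binning is available as an
alternative for heavy-tailed descriptors. The activity is discretized
with the same scheme, since the estimator needs a joint distribution.

The score is the *difference* form: relevance minus mean redundancy
against the already-selected set. At the first step the redundancy
average is empty and defined as 0, so the first pick is the argmax of
relevance. Ties break by larger relevance, then earlier column order —
the ranking is deterministic and invariant under column permutation up to
that tie-break. Default pool size passed to elimination: top 50.

# ε-SVR

Features and target are min-max scaled to [0, 1] with training-set
constants; queries are transformed with the same constants and may fall
outside [0, 1]. Target scaling makes the trained model expressible as
`pIC50(x) = s · [Σ β_i K(x, x_i) + b] + y_min` with `s` and `y_min` the
training-activity range and minimum — for the packaged benchmark's
training set those constants are 2.10 and 6.60, as its fixture tests
verify. The tube half-width ε is interpreted in scaled-target units; the
command-line `train` subcommand offers `--epsilon-raw` to specify it in
pIC50 units instead (it divides by the target range).

Defaults C = 2.0, ε = 0.05, γ = 1.0 are the settings of the packaged
benchmark model; γ = 1 is a sensible width *because* features are scaled
to the unit interval.

The dual is solved in the β = α − α\* parametrization: maximize
−½βᵀKβ + yᵀβ − εΣ|β_i| subject to Σβ_i = 0, |β_i| ≤ C. The compiled
solver is SMO-style pairwise ascent with most-violating-pair selection on
the directional derivatives; each pair step maximizes the one-dimensional
piecewise quadratic exactly (stationary points of all sign regions plus
breakpoints), so every step is monotone and the solver is deterministic
given input order. Stopping: maximum dual violation below 10⁻⁸ (scaled
units) or 2·10⁵ iterations. The bias is recovered from the KKT
conditions: free support vectors (strictly inside the box, outside
`kkt_tolerance` = 10⁻³ of the bounds) pin it exactly and are averaged;
if none is free, the midpoint of the interval admitted by all box and
tube constraints is used. Degenerate cases are defined, not crashed:
constant feature columns scale to 0; a constant activity is an error
(the target range would be 0); a model with zero support vectors predicts
the constant `s·b + y_min`.

# Validation and backward elimination

`evaluate()` computes q² = 1 − SS_res/SS_tot and RMSE with the mean taken
over the evaluated set itself (per-set convention, recorded in the
report). The alternative — a global mean shared across subsets — is not
used anywhere; mixing conventions silently changes q² and is a classic
reproducibility trap, so the report carries the convention explicitly.

LOOCV refits the min-max scaler inside every fold (the held-out sample
must not leak its range into scaling), with a fixed feature subset and
fixed hyperparameters. Because backward elimination evaluates roughly
k²/2 candidate subsets for a k-feature pool (each a full LOOCV), the fold
loop is compiled; a test asserts the compiled path equals the plain
train/predict composition. Note the selection-bias caveat: the LOOCV RMSE
that *drives* the elimination is also the statistic reported along the
path, so the best-subset RMSE is an optimistically biased estimate; an
honest error estimate requires the untouched external test set.

Elimination runs from the full ranked pool down to one feature and picks
the global LOOCV-RMSE minimizer over all recorded sets (including the
untouched starting pool), with ties toward the smaller subset. Within a
step, tied removals drop the feature with the worst mRMR rank first, then
earlier column order — the trace is deterministic.

The every-fourth split sorts by activity descending with a stable
tie-break on input order and assigns ranks k, 2k, … to the test set
(default k = 4 gives a 3:1 split); original row order is preserved in the
outputs.

`mlr_baseline()` is ordinary least squares with per-fold LOOCV refits,
kept as the reference point a kernel model must beat to justify itself.

# The synthetic generator

`generate_synthetic()` emulates the *shape* of a descriptor-pool
screening problem: by default 48 samples and 75 features, of which 6
informative drive the target, 9 are correlated copies (ρ = 0.9) of
informative parents, and 60 are independent noise — the feature-funnel
geometry (75 → 50 → few) the selection stages are designed for. Target
noise defaults to σ = 0.3, a realistic assay-reproducibility scale on
log-potency data. Links: `linear`, `sin`, `mixed`. The sinusoidal link is
`sin((π/2)·x)` — half an oscillation per two standard deviations — chosen
so the nonlinearity is resolvable by an RBF kernel of width comparable to
the scaled feature range at the default hyperparameters, while remaining
poorly approximated by a straight line; a higher-frequency sine would be
unlearnable at n ≈ 50 and would make the planted signal undetectable by
construction. For the kernel-vs-linear comparison the package's tests use
the single-planted-sine configuration (1 informative, 5 noise features,
σ = 0.1).

What the generator does **not** emulate: real descriptor distributions
(counts, heavy tails, bounded percentages), inter-descriptor correlation
structure beyond the planted copies, activity cliffs, or assay
censoring. Passing tests on synthetic tables therefore demonstrate that
the machinery recovers planted structure under Gaussian conditions — not
that any particular chemistry will yield a good model.

The packaged benchmark table (48 cyanopyrrolidine-amide DPP-IV
inhibitors: experimental, fitted, and LOOCV pIC50 at two decimals, with
12 test flags) is transcription-checked by checksum and digit-level tests;
all benchmark statistics in the package are recomputed from this table at
run time, never hard-coded as results.

# Problem sizes and runtime

The test suite and the reproduction script run at desk scale by design:
benchmark statistics are closed-form functions of 48 tabulated rows;
solver-vs-oracle checks use ≤ 6-point duals, where an interior-point QP
solve is an independent reference; the selection end-to-end test uses the
default 48 × 75 generator table with a 50-feature elimination
(≈ 1.3 × 10³ LOOCV evaluations, a few seconds compiled). Projection-area
convergence tests use 1–2 disk systems against the closed-form
union-of-disks area at 0.02 Å resolution.

# Known limitations

* The descriptor registry covers six descriptors with documented,
  self-consistent definitions; agreement with any proprietary
  implementation of similarly named descriptors is not a contract.
* Aromaticity perception beyond file flags is a benzenoid heuristic.
* The MI estimator is discretization-based; continuous (k-NN/kernel)
  estimators are out of scope, and very small samples (n ≲ 20) make
  three-state MI estimates noisy.
* Backward elimination cost grows quadratically in the pool size; pools
  far beyond ~10² features call for a different search strategy.
* ε-SVR provides no predictive uncertainty; q²/RMSE describe aggregate,
  not per-compound, accuracy.
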