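---
title: "Modelling PAH retention from molecular descriptors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PAH retention from molecular descriptors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrr)
```

# The problem

Quantitative structure–retention relationship (QSRR) modelling predicts the
chromatographic retention time of an analyte from numeric descriptors of its
molecular structure, optionally together with the instrument settings of the
run. `qsrr` implements a complete QSRR workflow for polycyclic aromatic
hydrocarbons (PAHs) separated by gradient-elution reversed-phase
chromatography: the retention time `tr` (minutes) of each analyte is
modelled as a function of 3D molecular descriptors and three run conditions —
eluent flow rate `F` (mL/min), column temperature `T` (°C) and gradient
duration `tg` (min).

The package covers every stage: building or reading molecular geometries,
computing descriptors, generating the experimental design, pruning and
scaling the descriptor matrix, selecting variables (genetic algorithm, VIP,
covariance selection), and fitting two regression models — NIPALS partial
least squares (linear) and a small backpropagation neural network
(nonlinear) — with honest validation throughout.

# Geometries

PAH skeletons are planar to a good approximation, so the package builds
idealized geometries on a hexagonal lattice (`build_cata_pah()`): flat-top
hexagons addressed by axial coordinates, C–C bonds exactly 1.40 Å, hydrogens
at 1.09 Å on the external bisector of every carbon with fewer than three
carbon neighbours. This gives deterministic, reproducible structures for
cata- and peri-fused PAHs. Force-field-optimized geometries differ from the
ideal lattice by a few hundredths of an Ångström; descriptor values computed
from lattice geometries are therefore close to, but not identical with,
values computed from optimized structures. No conformational search is
attempted (planar PAHs have essentially one conformer). Arbitrary geometries
can be read from XYZ or SDF V2000 files; `perceive_bonds()` adds a bond
table from distance cutoffs (defaults C–C 1.75 Å, C–H 1.20 Å, which separate
bonded from non-bonded distances on the lattice by a wide margin).

# Descriptors

Four descriptor families are implemented, chosen because they are the ones a
PAH retention model actually uses:

* **MW** — sum of standard atomic weights.
* **nCIR / nR10** — circuit counts of the heavy-atom graph. `nCIR` counts
  *all* simple cycles (rings and larger circuits), `nR10` the 10-membered
  ones — the signature of two fused six-membered rings (naphthalene has
  nCIR = 3: two 6-circuits and one 10-circuit). Enumeration is exhaustive
  (rooted depth-first search over simple paths), with a configurable cap on
  circuit size (24) and heavy-atom count (60) because the number of simple
  cycles grows exponentially; the PAHs of interest are far below the cap.
  Hydrogens are excluded from the cycle graph.
* **RDF** — radial distribution function
  $\mathrm{RDF}(R) = \sum_{i<j} w_i w_j e^{-B(R - r_{ij})^2}$, evaluated at
  the radius encoded in the descriptor name (`RDF030` means R = 3.0 Å).
  The smoothing parameter defaults to B = 100 Å⁻², the conventional value;
  it is configurable because published descriptor sets do not always state
  it.
* **3D-MoRSE** — $\mathrm{Mor}(s) = \sum_{i<j} w_i w_j \sin(s r_{ij})/(s r_{ij})$,
  with the kernel equal to 1 at s = 0 by continuity. The mapping from the
  two-digit signal number to s follows the Dragon convention s = signal − 1
  (so `Mor01` has s = 0). Descriptor catalogues are occasionally read as
  s = signal; that mapping is available via `convention = "signal"`. Neither
  is asserted as the only correct reading.

Mass weighting (`m` suffix) uses atomic mass relative to carbon, so weighted
and unweighted values coincide exactly on pure-carbon frameworks — a
convenient, testable invariant. Hydrogens are included in the RDF/MoRSE pair
sums (geometric descriptors describe the whole molecule) and excluded from
ring perception (circuits are skeletal); both choices are switchable.

# Design of experiments and dataset assembly

`chromatographic_design()` generates a three-level full factorial in
(F, T, tg) — 27 points — plus the centres of the eight cubic subspaces the
three levels define: every combination of the two midpoints between adjacent
levels per factor, 2³ = 8 points, 35 conditions in all. "Centres of the
eight cubic subspaces" is the only reading that yields exactly eight centre
points in a three-level cube. Defaults span F ∈ [0.6, 0.8] mL/min,
T ∈ [25, 35] °C, tg ∈ [4, 8] min.

Crossing 16 analytes with the 35 conditions gives the canonical 560-record
dataset. Splitting (`split_by_analyte()`) is analyte-wise for the external
test set — all 35 records of 3 held-out molecules (105 records), so the
models never see the test molecules in any condition — and record-wise
(random, seeded) for the 80/20 train/validation partition of the remaining
455 records, giving 364/91. The record-wise choice for train/validation
reproduces those counts exactly; validation size is
`round(0.2 × n_remaining)`. Test analytes default to a stratified pick over
the retention ranking (`pick_test_analytes()`) so the held-out molecules
span the studied retention range.

# Pruning and scaling

`variance_filter()` removes descriptors whose variance is at or below a
tolerance (default 1e-8 on the raw scale; "little variance" is inherently a
judgement call). `correlation_prune()` makes a greedy pass and drops any
column whose absolute Pearson correlation with an already-kept column
exceeds 0.95, so one representative survives per collinear block. Columns
are visited in order of decreasing variance by default — the most
informative member of a block is the one kept — with `order = "given"` for a
plain left-to-right pass; no published rule exists for this tie-break.
Pruning operates on the raw scale (correlation is scale-invariant, variance
filtering is not). `fit_apply_scaling()` implements mean-centering and
autoscaling, always estimating statistics on the training records only and
applying them unchanged to validation and test data.

# Genetic-algorithm descriptor selection

`ga_select()` evolves binary descriptor-inclusion chromosomes scored by the
leave-one-out cross-validated R² of the multilinear model on the selected
columns (`loo_cv_r2()`, computed exactly via the OLS leverage shortcut
`e_i/(1 − h_{ii})`, which the suite verifies against explicit n-refit
leave-one-out). Defaults: population 100, uniform crossover (independent
coin flip per gene), 2% elitism, subsets constrained to 5–7 descriptors, 50
independent runs of at most 10 cycles, early stop after 5 cycles without
improvement. Two parameter ambiguities exist in the tradition this follows —
mutation probability is quoted both as 1% and as 0.1%, and the cycle budget
both as 50 cycles and as 50 runs × 10 cycles. The defaults here are
mutation 0.01 and the 50 × 10 structure; both alternatives are one
`ga_config()` argument away.

Design choices the published descriptions leave open, resolved as follows:
parent selection is roulette on *rank-transformed* fitness (robust to the
−∞ sentinel assigned to rank-deficient subsets); chromosomes leaving the
5–7 window after crossover/mutation are repaired by randomly flipping bits
back into range before evaluation, so every evaluated subset is feasible;
all subsets ever evaluated (cached, deduplicated) are pooled and ranked
across runs.

# PLS, VIP, CovSel, duplex splitting

`fit_pls()` is single-response NIPALS: weights `w = X'y/|X'y|`, scores
`t = Xw`, loadings `p = X't/(t't)`, y-loading `q = y't/(t't)`, deflation of
both matrices, regression vector `B = W(P'W)⁻¹q`. At full rank B equals the
least-squares solution (verified to 1e-8); scores are mutually orthogonal.
If the response is exhausted early (noiseless data), the component count is
truncated with a warning rather than failing.

`venetian_blinds_cv()` uses interleaved cancellation groups (record i goes
to group `(i − 1) mod 5 + 1`). The selected complexity is the smallest A
whose RMSECV is within 2% of the minimum — a parsimony rule this package
adopts because no standard rule is universal.

`vip_scores()` implements variable importance in projection with
per-component explained response variance `SSY_a = q_a² t_a't_a`; squared
VIPs average to exactly 1, so the customary VIP > 1 retention rule keeps
above-average contributors. `covsel()` greedily selects the predictor with
the largest squared covariance with the current response, then
orthogonalizes both X and y against the selected column; deflating y as
well as X is the classical procedure, and an X-only variant is available
(`deflate_y = FALSE`). `kennard_stone_duplex()` is the deterministic
max–min splitter: farthest pair to train, next farthest pair to test, then
alternating max–min assignments until the test quota is filled.

A note on what duplex splitting does and does not buy: the construction
guarantees the held-out points are *spread out* (the minimum pairwise
distance within the duplex test set far exceeds that of random test sets),
but it does not make the test set's nearest-train coverage radius smaller
than a random split's — extremes are deliberately routed into both sets, so
the most isolated points sit in the test set too. The test suite asserts
the spread property, which the construction actually guarantees.

# The neural network

`train_ann()` fits a one-hidden-layer network — tanh hidden units, identity
output — by full-batch gradient descent with momentum on the mean squared
error, with weights initialized uniformly in [−1, 1]. The canonical
architecture for the 9-predictor retention problem is 9-2-1. Inputs are
autoscaled and the response min–max scaled to [−0.8, 0.8] (training
statistics only; the 0.2 margin keeps targets off the tanh saturation
plateau). Optimizer defaults — learning rate 0.01, momentum 0.9, at most
5000 epochs, early-stopping patience 50 — are this package's own choices;
published descriptions of such models typically name only
"backpropagation". Early stopping returns the weights of the epoch with the
lowest validation RMSE. Analytic gradients are verified against central
finite differences to 1e-6 relative.

`ensemble_train_ann()` retrains from `n_restarts` (default 100) random
initializations, averages the per-split RMSE and R² across restarts, and
retains the best-validation network. Prediction offers both `type = "best"`
and `type = "average"` (mean of the member networks' predictions). The
pipeline and the acceptance analysis use the averaged prediction for the
ANN-vs-PLS comparison: under analyte-wise holdout an occasional restart
achieves the best validation score (computed on records of *training*
analytes) yet extrapolates poorly to the held-out molecules, and averaging
damps exactly that failure mode. Averaging restart outcomes is also the
historically used protocol for this architecture.

# The synthetic study generator

Because the measured retention tables of real PAH studies are rarely
machine-readable, the package ships a generator
(`synthetic_config()`, `generate_descriptor_matrix()`,
`generate_retention()`) that reproduces the *statistical structure* the
analysis assumes rather than any particular instrument's numbers:

* 16 analytes × 35 conditions = 560 records;
* 6 informative descriptor columns hidden among 44 noise columns arranged
  in correlated blocks (pairwise ρ = 0.7 within a block of 4) — the
  few-signals-among-collinear-noise situation descriptor matrices present;
* a hydrophobicity score h (standardized weighted sum of the informative
  columns) driving retention up (+1.2 min per SD), flow rate driving it
  down (−3 min per mL/min), gradient time up (+0.35 min/min), temperature
  weakly down (−0.02 min/°C), around a 5 min baseline — so retention spans
  roughly 1–9 min, plausible for a fast gradient separation;
* a single multiplicative interaction γ·h·(tg − mean tg) with γ = 0.3 as
  the minimal nonlinearity that defeats a linear model while remaining
  learnable by two tanh units;
* Gaussian measurement noise σ = 0.05 min, a realistic repeatability for
  retention times.

These defaults are fixed; they define the study conditions every
statistical test runs under. What the generator does *not* emulate:
mechanistic gradient-elution theory (log-linear solvent-strength
behaviour), peak shapes, heteroscedastic noise, or descriptor distributions
tied to actual structures (descriptor columns are Gaussian draws with
familiar names). A model that passes here has demonstrated correct
algorithmic behaviour on data with the right correlation and nonlinearity
structure — not validated chromatographic accuracy on real measurements.

`simulate_planted()` builds the selection benchmark: 5 informative columns
with unit coefficients among 45 independent noise columns at n = 200, with
noise sized for a population R² of 0.9. The genetic algorithm is expected
to recover the full planted support in at least 45 of 50 seeded searches;
in practice it recovers 50/50.

# Numerical choices and degenerate inputs

* Rank-deficient or oversaturated GA subsets score −∞ rather than raising,
  keeping evolution total.
* `correlation_prune()` refuses zero-variance columns (run
  `variance_filter()` first) because their correlation is undefined.
* `covsel()` stops early with a warning when every remaining column
  deflates to numerical zero (norm below 1e-12 of the largest).
* `kennard_stone_duplex()` falls back to index order, with a warning, when
  all points coincide.
* Circuit enumeration refuses molecules above the heavy-atom cap with an
  error naming the cap.
* Lattice vertices are merged at 1e-6 Å; XYZ round-trips are exact to
  1e-6 Å (10 decimal places written).
* All seeded routines restore the caller's RNG state on exit and derive
  per-stage seeds from one master seed, so a single integer reproduces an
  entire pipeline run.

# Problem sizes used in the test suite

The suite exercises the same machinery at sizes chosen to keep a complete
run comfortable on one CPU: the full 560-record study for dataset-level
checks; 50 seeded GA searches (population 100, 5 runs × ≤10 cycles each)
for planted recovery; 20-seed permutation nulls at n = 200; a 10-restart
network ensemble for the head-to-head comparison; 999-shuffle permutation
tests for residual structure. Larger settings (100 restarts, 50 GA runs)
remain the function defaults.

# Known limitations

* Only the descriptor families above are computed from structure; other
  catalogue descriptors (edge-adjacency, GETAWAY, 3D-matrix-based) appear
  in the synthetic generator as named noise columns, not as computed
  quantities.
* Lattice geometries are idealized; descriptor values differ slightly from
  force-field-optimized structures.
* PLS is single-response only; no kernel/OPLS/sparse variants.
* The network is deliberately small (one hidden layer, full-batch descent);
  it is the reference architecture for this problem, not a general-purpose
  learner.
* Whether reported ensemble metrics should refer to the best restart or the
  restart average is genuinely ambiguous in the tradition; the package
  reports both (summary = averages, `best` = best-validation network).
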