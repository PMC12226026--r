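---
title: "Persistence fingerprints under the opposition distance: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence fingerprints under the opposition distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topobind)
```

## The model

`topobind` treats a protein–ligand complex as a labeled 3D point cloud of
heavy-atom centers and studies its shape through persistent homology under
the *opposition distance*: Euclidean between a protein and a ligand atom,
infinite between atoms on the same side. The opposition distance is not a
metric (it violates the triangle inequality) and has no meaning on its
own; its purpose is what it does to the Vietoris–Rips filtration. Since no
three atoms have pairwise-finite distances, the filtration never contains
a 2-simplex, and its entire persistent homology lives in the bipartite
cross-distance graph:

* 0-dimensional classes are connected components. All are born at radius
  0; one dies each time a cross edge merges two components, at that edge's
  length. With `p` protein and `q` ligand points this gives exactly
  `p + q − 1` finite death radii (the spanning tree of the complete
  bipartite graph), plus one essential class that never dies and is
  discarded (it carries no finite critical value).
* 1-dimensional classes are loops. Because no triangle ever enters the
  complex, no loop ever dies; one is born each time a cross edge closes a
  cycle, at that edge's length — `pq − (p + q − 1)` birth radii.

Each class is thus summarized by one scalar, its *critical value*, and
the sweep that computes all of them is Kruskal's algorithm with a
union–find structure over the sorted cross edges. This reduction is a
derivation, not an assumption: the test suite checks it against an
independent boundary-matrix Vietoris–Rips reduction
(`persistence_oracle()`) on hundreds of random clouds, and the
`p + q − 1` / `pq − (p + q − 1)` counting identities are asserted
exactly.

Critical values of one channel — a (protein element, ligand element,
dimension) triple — are smoothed into an *internuclear persistence
contour* by summing unit-mass Gaussians, then integrated over fixed bins
into *IPC densities*. Ten selected densities form the *persistence
fingerprint*; the ensemble models map fingerprints to binding free energy
(kcal/mol, via `ΔG = RT ln Kd` for labels given as dissociation
constants) or truncated IPC stacks to binder/decoy scores.

## Parameters that matter

* **Gaussian σ = 0.1 Å** (default, `sigma`). Sets the smoothing scale of
  the contours; 0.1 Å is well below bond-length variation, so nearby
  critical values remain distinguishable while coordinate noise of
  crystallographic magnitude moves bin masses smoothly.
* **Bin grid** (`bin_grid()`): width 0.5 Å, span [0, 15) Å in 30 bins.
  The width matches the fingerprint's defining bins. The span is a
  package choice: the largest fingerprint bin ends at 10.5 Å and the
  screen model truncates at 15 Å, so [0, 15) embraces every density the
  models consume. Bins are half-open `[lo, hi)` so they partition the
  line without double counting; with σ = 0.1 Å the mass affected by edge
  assignment is negligible.
* **Element sets**: protein {C, N, O, S} × ligand {C, N, O, S, P, F, Cl,
  Br, I} = 36 subsets, the published convention of the predecessor
  featurization this package's channels follow. Both sets are
  config-overridable; the exact published subset table was not available
  for confirmation, so the product convention is the documented default.
* **Truncation cutoff 15 Å** (`cutoff_radius`). Dropping protein atoms
  farther than the cutoff from every ligand atom preserves *exactly*
  every critical value below the cutoff (those atoms have no cross edge
  shorter than it, so the union–find sweep over the retained edges is
  unchanged), and each discarded critical value can leak at most
  `pnorm(-(cutoff - max_bin)/σ)` of its unit mass into any fingerprint
  bin. At 15 Å against a 10.5 Å top bin that tail is a 45σ event —
  numerically zero — which is why the measured approximation error in
  the test suite is at machine precision. `compute_fingerprint_approx()`
  reports the bound (`n_dropped × q × tail`) with its result.
* **Ensemble defaults**: 13 trees, depth 3, learning rate 0.1, squared
  error. The tree count is the reference method's headline constant; the
  depth and rate are not pinned by it, are recorded in every serialized
  model as `paper_verified: false`, and are deliberately conservative.
  Note that 13 trees at rate 0.1 capture only `1 − 0.9^13 ≈ 75%` of even
  a perfectly tree-shaped signal, so convergence-style checks in the
  tests (noise-free recovery, parameter recovery, feature selection) use
  hotter, explicitly passed settings (rate 0.3–1.0, up to 50 trees) —
  a training-protocol choice made once, not a tuning loop.

## The synthetic generators

The package is testable without downloads because every input is
generated:

* `make_pair()`, `make_square()`, `make_k22()` are analytic fixtures
  whose critical values are known in closed form (a single death; three
  tied deaths plus one tied birth; three generic deaths plus the
  cycle-closing maximum). They probe exactness, tie handling and the 1D
  channel.
* `make_random_complex()` places atoms uniformly with a hard minimum
  separation (1.0 Å), mirroring the fixed lower bound on interatomic
  distances that real structures obey and the truncation analysis
  assumes. Element frequencies default to a protein-like C/N/O/S mix
  (62/17/18/3%).
* `make_screening_set()` emulates the geometry that separates binders
  from decoys: binders have the ligand buried at the protein's center
  (dense 4–10 Å carbon–carbon contacts), decoys have it displaced 14 Å
  outward (sparse contacts). This is a *geometric* caricature of a
  screening library: it validates that the stack features carry
  contact-shell information and that the screen model can use it, not
  that the model would reach any particular accuracy on real actives
  and property-matched decoys.
* `make_training_table()` plants a piecewise-constant response — the
  function class a shallow tree ensemble represents exactly — with
  uniform features and Gaussian noise, so parameter recovery has a known
  target.

What passing these tests shows: the topology, vectorization, truncation,
attribution and learning machinery are correct and stable. What they do
not show: predictive performance on experimental affinities, which
depends on real training data (curated complex sets with measured
labels) outside the package's scope. The shipped demo models are trained
on synthetic tables and labeled as such.

## Numerical choices

* Bin integrals use the Gaussian CDF closed form (`pnorm` differences),
  never quadrature: exact to machine precision and O(1) per value.
* Cross edges are sorted by `(weight, protein_id, ligand_id)` so the
  sweep is deterministic under ties; the critical-value *multisets* are
  tie-invariant regardless (a matroid property, tested on the degenerate
  square), only the edge labels can differ.
* Tree splits are exact greedy with thresholds at midpoints of adjacent
  observed values; ties between features resolve to the lowest column
  index. Fitting uses no randomness, so refits are bit-stable and the
  `seed` argument exists only for interface symmetry.
* Model JSON is written with 17 significant digits so doubles survive
  the decimal round trip exactly; export→import reproduces predictions
  identically.
* Degenerate inputs are legal throughout: coincident atoms give
  weight-0 critical values; an empty protein or ligand side yields an
  all-zero fingerprint with a warning (screening pipelines must not
  crash on a bad complex).

## Design decisions that were genuinely open

* **Attribution of 1D classes.** A loop has no unique representative
  cycle, so "the atoms of a hole" needs a convention. The package uses
  the unique cycle the class's critical edge closes in the spanning
  forest of shorter edges, and splits the class's in-bin mass evenly
  over those atoms; 0D classes split evenly over the two atoms of the
  merging edge. This is deterministic, conserves mass exactly (per-atom
  contributions sum to the feature value), degrades gracefully to the
  unambiguous two-atom case, and reproduces the intuitive symmetric
  answer on the square fixture (four equal quarters). The rejected
  alternative — attributing only to the critical edge's endpoints — is
  simpler but assigns nothing to atoms that plainly lie on the hole.
* **Essential classes.** The 0D class that survives to infinity is
  dropped: contours need finite critical values, and the surviving
  component count carries no cross-distance information.
* **Grid origin and extent** (not pinned by the reference method):
  [0, 15) as argued above, overridable per run.
* **The screen model is a regressor on 0/1 labels**, not a calibrated
  classifier: its output is a ranking score and ROC construction is the
  caller's concern.
* **Ablation protocol**: 90:10 train/validation split, stop when
  validation RMSE degrades more than 1% relative to the best seen. At
  desk-scale validation sizes the RMSE estimate is noisy enough that
  ablation often stops early and returns a superset; the planted-feature
  recovery checks therefore assert survival and importance rank, not
  minimality.

## Problem sizes used in the checks

Oracle comparisons run on 200 clouds of up to 6+6 points (the reduction
is exponential-ish by design); stability and attribution on complexes of
50–80 protein atoms; truncation soundness on 100 complexes of 50–300
protein atoms in a 40 Å box; parameter recovery on 2,000 rows; the
screening benchmark on 500 complexes of 40+8 atoms; selection recovery on
1,000 rows × 72 columns. These sizes exercise every code path at full
fidelity while keeping the whole suite around a minute.

## Known limitations

* A tree ensemble emits a finite set of values — at most the product of
  per-tree leaf counts — so predictions are piecewise constant in
  feature space.
* Fingerprints are blind to same-side geometry by construction: any
  rearrangement of protein atoms that preserves all protein–ligand
  distances is invisible.
* Hydrogens are dropped at parse time and never featurized.
* Structure parsing resolves alternate locations (highest occupancy,
  ties toward altloc A) and excludes waters; it does not protonate,
  perceive bonds, or validate chemistry beyond element symbols.
* The feature-selection procedure can rediscover *a* sparse feature set
  on new data but is not guaranteed to reproduce the published 10-bin
  table, which was selected on a specific curated training corpus.
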