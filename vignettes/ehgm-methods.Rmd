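---
title: "Exact hypergraph matching and posture models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact hypergraph matching and posture models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgm)
```

This vignette is the package's own account of the science it implements:
the matching model and its assumptions, the search algorithm, the three
posture models, the synthetic-data generator, and the numerical and design
choices that were genuinely open.

## The matching model

An assignment maps each of `n1` model vertices injectively to one of `n2`
observed points; points beyond `n1` simply remain unmatched.  The
objective is a sum over hyperedge degrees: for each degree `d` a
dissimilarity tensor charges every in-scope vertex `d`-tuple for the point
`d`-tuple it receives.  Degree 1 is linear assignment, degree 2 the
quadratic assignment problem, and maximum degree `d = n1` scores the
complete correspondence jointly.  Two structural contracts make the solver
exact and keep models honest:

* **Nonnegativity.** Every tensor cost must be finite and `>= 0`.  The
  branch-and-bound bound is the accumulated partial cost; it is a valid
  lower bound on any completion only under this contract, so the tensor
  evaluation path enforces it and models with negative raw scores must be
  shifted by the caller.
* **Sparse, explicit scope.** Tensors are stored per vertex tuple
  (canonically strictly increasing in branch order), and a lookup outside
  the stored scope is an error rather than an implicit zero, so a
  mis-built model fails loudly.

## The search

Vertices are assigned `k` at a time over `M = n1 / k` branches.  Branch
`m`'s queue holds every feasible ordered `k`-tuple of unused points,
sorted ascending by the selection rule: the sum of all precomputed
(degree `<= 2k`) tensor terms that involve at least one branch-`m` vertex
and otherwise only committed vertices.  Upon descending into an entry, the
aggregation rule adds the lazily evaluated higher-degree terms
(`2k < d <= mk`) that have just become computable.  Summed along any
root-to-leaf path these two rules reproduce the full objective exactly
(`decompose_objective()` checks the identity at `1e-9` relative
tolerance), which is what licenses pruning: a node whose accumulated cost
exceeds the incumbent bound cannot lead to a better completion.

Design choices that were open:

* **Depth-first, cheapest-first.** The search always descends into the
  cheapest unexplored queue entry.  This finds a strong incumbent early,
  which powers pruning; best-first variants would need exponential memory.
* **Top-`x` pruning.** The bound is the pool's x-th best cost, not the
  best, so one search proves the exact top-`x` set — the set from which
  top-1/2/3 accuracies are reported.  Pruning against the top-1 bound
  would be faster but the lower-ranked pool entries would then be only
  heuristic.  At the bound boundary, an entry with cost exactly equal to
  the x-th best is admitted only if lexicographically smaller, making
  pools deterministic.
* **Bound initialization.** The incumbent starts at `+Inf`; a warm-start
  assignment may be supplied and is simply inserted into the pool.
* **Seeds.** Known identities restrict their vertex's queue slot to the
  seeded point, and seeded points are withheld from other vertices.
  Seeds need not align with branch boundaries.
* **Time budget.** The deadline is checked cooperatively between node
  expansions; on expiry the pool holds the best solutions found and the
  result is flagged unproven.  The conventional cap for full-size worms
  is four hours per sample.
* **Accounting.** `nodes_expanded` counts every queue entry popped and
  examined, including entries discarded by the bound check immediately
  after popping; `prunes` counts bound-discarded entries.

## Posture models

Branch size is `k = 2` — one bilateral pair per branch — and the branch
order runs posterior to anterior (`T, V6, [Q,] V5, ..., H0`), because the
tail pair's near-constant width makes it the most reliable anchor for the
initial selection rule.  Within a branch the odd vertex is the left
nucleus.  The Q pair, present only in the last hours of development,
occupies its anatomical position between V6 and V5 in branch order; the
pair count (10 pre-Q, 11 post-Q) is an explicit caller input, because the
imaging protocol knows the stage and inferring it from the detection count
would be corrupted by spurious detections.

Features are charged as `weight * ((value - mean(t)) / sd(t))^2` against a
fitted template.  The squared z-score was chosen over `|z|` because it is
smooth, nonnegative, and additive across features; weights default to 1
for every family and are exposed for experimentation.  Degree-1 (unary)
terms are empty in all three models — a lone point carries no geometric
information here.

Two geometric conventions were genuinely underdetermined and are worth
stating.  The midpoint bend angle is the *interior* angle at the middle
pair's midpoint, so a locally straight body scores 180 degrees and the
angle's mean falls as bends sharpen; with elongation the simulated body
straightens locally, so template means rise toward 180 over development.
The side-chord cosine compares the left-side chord with the right-side
chord of the same segment (the companion three-pair form, each side
against its own next chord, is available as a separate function but is not
used by the default models).

## Template fitting

For every feature family and body position, the template stores the
per-time-bin sample mean and sd of the feature over the corpus, with knots
at the deciles of observed normalized time and piecewise-linear
interpolation between them (constant beyond the ends).  Piecewise-linear
was chosen as the least-assumption interpolant for a smooth, slow trend.
Time is normalized per embryo as `frame / (total_frames - 1)`.  A bin with
fewer than two samples borrows the family's corpus-wide sd, with a
warning.  Standard deviations are floored at `1e-6` of the family's
corpus-wide sd (absolute floor `1e-8`): at zero measurement noise some
features are deterministic and their bin sd collapses to zero; the floor
keeps costs finite while preserving the enormous penalty for violating a
deterministic constraint.  Pre-Q and post-Q corpora are fit separately —
the body positions do not align between stages, so pooling them would
blur both templates.

## The synthetic generator

The generator exists so that every claim the package makes can be checked
end-to-end with no external data.  It emulates the statistical structure
the models assume:

* a smooth backbone of exact arclength `L(t)`, elongating from 60 to
  170 µm (reduced preset: 40 to 90 µm) across normalized development;
* bilateral pairs equally spaced in arclength, offset by a tapering
  half-width profile (thicker mid-body, thinner extremities) with a
  constant-width tail pair (5 µm);
* a coiled shape that is resampled *completely* between frames — the
  regime that defeats coherent-transform matchers — while per-frame
  feature statistics follow the template trend;
* bend angles that straighten as the body elongates (the total heading
  bend, 5 rad at `t = 0`, is halved by `t = 1`);
* isotropic Gaussian detection jitter per nucleus (default 0.5 µm;
  "moderate noise" in the model-comparison experiments is 1.0 µm, twice
  the default);
* a uniformly random shuffle of the nuclei with recorded ground truth,
  plus a random rigid repositioning of each frame.

One property deserves emphasis because it is easy to get wrong.  Swapping
*every* left/right label of a posture negates both axes of every pair,
and any feature built from pairs of axes — including the signed twist
dihedral — is invariant under that joint negation; midpoints are
unchanged, and the only families that can notice are the side-chord
lengths, via systematically different left and right templates.  A
generator with perfect bilateral symmetry therefore produces postures
whose global mirror relabeling is *statistically indistinguishable* from
the truth, and no model in this family could identify left from right.
Real embryos are not symmetric in this sense: they coil around the inside
of the eggshell with consistent handedness while the body twists about
its own axis.  The generator reproduces exactly that — a near-planar
spiral backbone with single-signed curvature plus a consistent twist
drift of the left-right axis (0.3 rad per pair, with 0.15 rad random
wander) — which places one seam row consistently toward the inside of the
coil at each body position.  The fitted left- and right-chord templates
then differ, and left/right relabelings are penalized.  Backbones whose
distant stations approach within twice the maximum body width are
rejection-resampled to avoid self-intersection.

Defaults are simulator conventions that loosely mirror late-stage embryo
biology, not measurements of any particular dataset.  What the simulator
does **not** emulate: anisotropic or depth-dependent localization error,
missing and spurious detections, inter-embryo shape variability beyond
the random coil, and any appearance/intensity cues.  Passing tests
therefore demonstrate correctness of the algorithm and internal
consistency of the models on geometry like the real problem's — not
field performance on real microscopy data.

## Problem sizes used in verification

The test suite and the acceptance script verify, among others: exactness
of the solver against an exhaustive oracle on 50 random instances
(`n1 = 6`, `k = 2`, `n2` in 6–8, tensor degrees {1, 2, 4, 6}); the
decomposition identity on 100 random problem/assignment pairs with
degrees up to `n1`; the linear-assignment reduction on 20 instances with
`n1 = n2 = 8`; seeded-search equivalence with the seed-constrained oracle
on the exactness suite; perfect recovery of 20 zero-noise reduced worms
(5 pairs, templates fit from a 12-embryo generator corpus) under the
Pairs and Posture models, with every single-pair perturbation strictly
costlier; and the Sides/Pairs/Posture comparison on 50 noisy reduced
worms.  Reduced five-pair worms keep oracle-verified end-to-end runs in
seconds; full 10/11-pair problems are solved by the same code path (a
T-seeded Posture search on a 10-pair synthetic worm takes well under a
minute).

## Known limitations

* Exactness restricts practical problem sizes to roughly `n1 <= 22`;
  larger point sets should lean on lower-degree models or seeding.
* The exact analytic conventions of the original twist and plane-angle
  features are not published in full; the constructions here follow the
  published descriptions, and the template standardization layer absorbs
  monotone reparameterizations, but per-feature values are not guaranteed
  to match other implementations numerically.
* Feature weights are fixed at 1, not learned.
* The queue at each branch is materialized in full (`<= n2!/(n2-k)!`
  entries); this is small for `k = 2` but would not scale to large `k`.
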