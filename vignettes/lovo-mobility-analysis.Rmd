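---
title: "Robust mobility analysis of MD trajectories by low-order-value optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust mobility analysis of MD trajectories by low-order-value optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovofit)
```

## The problem

The standard way to quantify structural mobility in a molecular-dynamics
simulation is to rigid-body align every frame to a reference structure
(typically the first frame or the crystallographic model) and report the
RMSD over time and the per-atom RMSF. The whole-structure least-squares
alignment, however, is not robust: a single mobile loop drags the fitted
transform toward itself, inflating the apparent deviation of atoms that in
fact barely move, and a genuinely rigid core can be invisible in the
resulting numbers.

`lovofit` treats the choice of which atoms to fit as part of the
optimization. For a user-chosen fraction $\phi \in (0, 1]$ of the $N$
C$\alpha$ atoms, it seeks the rigid transform *and* the subset of
$N_L = \phi N$ atoms that jointly minimize the subset's summed squared
deviation. This is a low-order-value optimization (LOVO) problem: the
objective at any orientation is the sum of the $N_L$ *smallest* per-atom
squared deviations

$$\mathrm{MSD}_i(t) = \lVert x_i(t) - x_i^{\mathrm{ref}} \rVert^2, \qquad
\mathrm{MSD}_L(t) = \sum_{i \in \text{bottom-}N_L} \mathrm{MSD}_i(t).$$

## The algorithm

For each frame the package iterates two exact steps:

1. **Fit.** Superpose the current subset on the reference with the Kearsley
   quaternion method: build the $4 \times 4$ symmetric matrix from the
   centered coordinate sums and differences; the eigenvector of its smallest
   eigenvalue is the unit quaternion of the optimal proper rotation. This is
   the exact global minimizer of the rigid-body problem for that subset, and
   the rotation is proper by construction ($\det R = +1$ even for
   mirror-symmetric inputs, because unit quaternions parameterize only
   rotations). The whole frame is then transformed.
2. **Re-select.** Recompute all $N$ squared deviations under the new
   orientation and take the $N_L$ smallest (ties broken by atom index).

Each step can only decrease $\mathrm{MSD}_L$, so the objective descends
monotonically over a finite set of subsets and the iteration terminates at a
local minimizer. Because local minimizers exist (notably when two internally
rigid domains move relative to each other), the per-frame solve is
globalized by multistart: one deterministic start (the bottom $N_L$ after a
whole-structure alignment) plus `nStarts - 1` uniformly random
$N_L$-subsets, keeping the result with the smallest objective. After
convergence the package reports, under the single converged transform,

* `rmsd_L` — RMSD over the identified least-mobile subset,
* `rmsd_H` — RMSD over the remaining atoms,
* `rmsd_T` — RMSD over all atoms,

which satisfy the exact decomposition
$N\,\mathrm{rmsd}_T^2 = N_L\,\mathrm{rmsd}_L^2 + (N - N_L)\,\mathrm{rmsd}_H^2$
on every frame (this identity is asserted throughout the test suite).

## Parameters and conventions

* **`phi`** — fraction of atoms fitted, in $(0, 1]$. The subset size is
  committed as $N_L = \max(3, \mathrm{round}(\phi N))$ with round-half-away-
  from-zero; the realized fraction $N_L / N$ is shown by the objects. Three
  atoms is the smallest subset that determines a rigid fit. At $\phi = 1$
  the method reduces exactly to whole-structure Kearsley alignment.
* **`nStarts`** (default 100) — multistart initial subsets per frame. On
  random 10-atom instances, 100 starts reach the exhaustively enumerated
  global optimum in well over 95% of cases; the two-domain situation is
  the motivating case for keeping it at 100.
* **`convergenceTol`** (default $10^{-9}$ Å$^2$) — the iteration stops when
  the change in $\mathrm{MSD}_L$ falls below this *and* the selected subset
  is stable. Subsets that differ only among numerically tied deviations
  (the outgoing subset scores within the tolerance of the incoming one)
  count as stable; without this tie rule an exactly superposable frame,
  where every deviation is $\sim 10^{-30}$, can cycle through tied
  orderings for many iterations. The dual rule preserves the finite-
  termination argument. Non-convergence within `maxIterations` (default
  200) is reported in the output, never raised, so one pathological frame
  cannot abort a trajectory run.
* **Seeds.** All randomness flows from one integer seed. In trajectory
  runs each frame derives its own stream as `bitwXor(seed, frameIndex)`,
  so results are reproducible and independent of frame processing order.
* **Reference.** Default is the first frame; any external structure sharing
  the atom roster can be passed instead. All units are Å throughout; squared
  deviations are kept internally and square roots are taken only at
  reporting boundaries.

## The φ-scan

`phiScan()` repeats the analysis over a grid of fractions (default 0.01 to
0.99 in steps of 0.01). Where the structure has a rigid core of fraction
$c$, `mean_rmsd_L` stays at the noise level for $\phi \le c$ and rises
sharply beyond it, so the scan localizes $c$ within one grid step. Two
summary statistics are reported per $\phi$ (mean and max of `rmsd_L` over
frames) because both "typical" and "worst-frame" views are in routine use;
an `endpoints` mode additionally supports the first-versus-last-frame
comparison that is natural for steadily diverging (e.g. unfolding)
trajectories. These three summaries are deliberately all exposed rather
than committing to one.

## RMSF conventions

`computeRMSF()` supports two referents: the reference coordinates
(default — the displacement from the initial structure, which is what the
annotated structure figures color) and the trajectory-average coordinates
(the classical fluctuation about the mean). The two differ for persistent
displacements: an atom sitting at a constant offset $d$ from the reference
has RMSF $d$ in reference mode and 0 in average mode. The per-frame,
per-atom displacement series (`deviationSeries()`) is the reference-mode
quantity before averaging; its root mean square over frames equals the
reference-mode RMSF exactly.

## PDB conventions

The reader parses fixed-width multi-MODEL PDB files; the `calpha` selection
takes `ATOM` records named `CA` and excludes calcium ions (residue name or
element `CA`). Alternate locations other than blank/`A` are dropped,
`HETATM` records are excluded from selection, and insertion codes are part
of the atom identity. The atom roster is fixed by the first model and any
later mismatch is an error naming the model and atom. The writer emits one
MODEL per frame with occupancy 1.00/0.00 marking *per-frame* low-set
membership and the b-factor carrying that frame's per-atom displacement in
Å (clamped at 999.99); per-frame membership is written, while the
consensus classification (membership in at least half the frames) lives in
the per-atom TSV. When the original all-atom file is supplied, all atoms
are written, transformed by the frame's rigid motion, with non-C$\alpha$
atoms inheriting their residue's C$\alpha$ classification — matching how
cartoon representations are colored. Binary trajectory formats are out of
scope; the reader interface is format-agnostic so others could be added.

## What the synthetic generator emulates — and what it does not

`syntheticTrajectory()` builds a self-avoiding pseudo-C$\alpha$ chain
(3.8 Å steps, 3.2 Å clash distance) and perturbs it per frame with
isotropic Gaussian noise on every atom plus a controlled displacement of a
contiguous mobile segment, optionally under a per-frame global rigid
motion. The `constant` schedule emulates a stable core with a flailing
loop; the `ramp` schedule emulates progressive divergence from the initial
structure. Each mobile atom is displaced along its own random direction,
redrawn every frame: a deliberately *non-rigid* mobile segment. A segment
translating coherently would itself be a rigid body — a second domain —
and for such two-domain geometries the LOVO objective has two equally good
optima; the multistart solver then locks onto one of them (which one is
seed-dependent, the objective value is not), a behaviour exercised by a
dedicated two-domain test fixture rather than by the generator defaults.

Passing tests on this generator therefore demonstrate correct core
identification under isotropic noise, unambiguous core/mobile separation
and removable global motion. They do not demonstrate performance on real
force-field dynamics: correlated motions, anisotropic fluctuations,
breathing modes and gradual core deformation are absent, and the chain has
no secondary structure. Validation problem sizes were chosen to mirror a
small single-domain protein: 200 atoms (140 core + 60 mobile), 20 frames,
0.1 Å core noise, 5 Å mobile displacement — the scale at which the
consensus core, the χ-scaled noise band of `rmsd_L`
($\sqrt{6}\,\sigma \approx 0.24$ Å when the reference is itself a noisy
frame) and the φ-scan rise past the true core fraction are all sharply
testable.

## Numerical choices

* Degenerate fit subsets (fewer than 3 atoms, or reference subset with the
  two smallest principal variances below $10^{-12}$ Å$^2$, i.e. collinear
  or coincident) raise an error naming the condition rather than returning
  a silently arbitrary rotation.
* The residual is always recomputed from the transformed coordinates
  rather than taken from the Kearsley eigenvalue: the eigenvalue is exact
  in theory but recomputation is robust to round-off near zero residuals
  (the eigenvalue can come out at $-10^{-16}$).
* Selection ties are broken by original atom index via a stable sort, so
  results are independent of the sorting library and platform.
* Monotone descent is asserted with a $10^{-9}$ relative slack to absorb
  floating-point churn near convergence.

## Known limitations

* PDB is the only trajectory format; large trajectories should be reduced
  to their C$\alpha$ trace before analysis.
* No mass- or B-factor-weighted superposition.
* The correspondence between frames is positional: the method aligns the
  same structure across time and performs no sequence or structural
  correspondence search.
* For adversarial geometries (several equally rigid domains of exactly the
  same size) the reported low set is one of several equivalent optima;
  inspect `lowFraction()` across seeds if this matters.
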