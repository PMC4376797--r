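# lovofit

Robust rigid-body alignment and mobility analysis for molecular-dynamics
trajectories, for structural biologists and simulators who need RMSD/RMSF
numbers that are not contaminated by a few highly mobile atoms.

## The method

The usual trajectory RMSD aligns *all* Cα atoms of each frame to a
reference; one flexible loop then drags the fit and inflates the apparent
mobility of everything else. `lovofit` instead fixes a fraction
φ ∈ (0, 1] and, for every frame, finds **both** the proper rigid transform
and the subset of N<sub>L</sub> = φN atoms that minimize the subset's summed
squared deviation

MSD<sub>i</sub>(t) = ‖x<sub>i</sub>(t) − x<sub>i</sub><sup>ref</sup>‖²,  
MSD<sub>L</sub>(t) = Σ over the N<sub>L</sub> smallest MSD<sub>i</sub>(t),

a low-order-value optimization (LOVO). Each frame is solved by iterating
(i) exact Kearsley quaternion superposition on the current subset, (ii)
transformation of the whole frame, and (iii) re-selection of the bottom
N<sub>L</sub> deviations, until MSD<sub>L</sub> and the subset are stable;
the objective descends monotonically so the iteration terminates at a local
minimizer, and a 100-point multistart (one deterministic start plus random
subsets) recovers the global one. The converged transform yields three
mutually consistent mobility measures per frame —

* **RMSD_L** over the automatically identified least-mobile subset,
* **RMSD_H** over the remaining (mobile) atoms,
* **RMSD_T** over the whole structure,

with N·RMSD_T² = N<sub>L</sub>·RMSD_L² + (N−N<sub>L</sub>)·RMSD_H² exactly —
plus per-atom RMSF, per-frame low-set membership, and a φ-scan
(φ = 0.01…0.99) that localizes rigid structural cores. Aligned trajectories
are written as multi-MODEL PDB with the low set flagged in the occupancy
field and per-atom displacements in the b-factor field, ready for
visualization.

## Worked example

A synthetic 100-atom Cα trace (70 rigid core atoms with 0.1 Å noise, a
30-atom loop flailing by 5 Å, a random global rigid motion each frame):

```r
library(lovofit)
syn <- syntheticTrajectory(nCore = 70, nMobile = 30, nFrames = 10,
                           coreNoiseSigma = 0.1, mobileOffset = 5,
                           globalMotion = TRUE, seed = 11)
report <- alignTrajectory(syn$trajectory, phi = 0.7,
                          options = lovoOptions(nStarts = 100, seed = 11))
report
#> MobilityReport: phi = 0.7 (nLow = 70/100), 10 frames
#>   mean rmsd_L = 0.212492  rmsd_H = 6.359221  rmsd_T = 3.487656 A
#>   consensus core: 70 atoms; 0 frame(s) not converged
head(frameStats(report), 3)
#>   frame    rmsd_L   rmsd_H   rmsd_T iters converged
#> 1     1 0.0000000 0.000000 0.000000     2      TRUE
#> 2     2 0.2463288 7.296416 4.001722     3      TRUE
#> 3     3 0.2249505 6.404588 3.512983     4      TRUE
```

The whole-structure RMSD (`rmsd_T` ≈ 3.5 Å) suggests large overall
mobility, but the method shows a core of 70 atoms superposable to ~0.21 Å
(`rmsd_L`, the χ-scaled noise level for σ = 0.1 Å against a noisy first
frame) while the loop alone accounts for the rest (`rmsd_H` ≈ 6.4 Å).
The recovered consensus core matches the generator's ground truth exactly:

```r
core <- consensusCore(report)
sum(core & syn$coreLabels) / sum(core | syn$coreLabels)   # Jaccard
#> [1] 1
```

A φ-scan pinpoints the core fraction — `mean_rmsd_L` sits at the noise
level up to the true core fraction 0.70 and rises sharply past it:

```r
phiScan(syn$trajectory, phiGrid = seq(0.60, 0.80, 0.05),
        options = lovoOptions(nStarts = 100, seed = 11))
#>    phi n_L mean_rmsd_L max_rmsd_L mean_rmsd_H mean_rmsd_T
#> 1 0.60  60   0.1814268  0.2243269    5.512884    3.489512
#> 2 0.65  65   0.1942931  0.2372718    5.890967    3.488693
#> 3 0.70  70   0.2124925  0.2532124    6.359221    3.487656
#> 4 0.75  75   0.6859590  0.9144143    6.880797    3.491616
#> 5 0.80  80   1.2748252  1.7151540    7.380357    3.494308
```

`writeAnnotatedPDB(report, "aligned.pdb")` writes the aligned frames with
occupancy marking the per-frame low set, and `writeFrameTable()` /
`writeAtomTable()` / `writePhiScanTable()` emit the TSV outputs. The same
workflow is available from a shell via `inst/cli/lovofit.R`
(`align`, `scan`, `rmsf`, `synth` subcommands).

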