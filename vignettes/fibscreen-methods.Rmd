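---
title: "Models and methods behind fibscreen"
author: "fibscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibscreen)
```

# The problem

Amyloid fibers present flat, repetitive binding surfaces rather than the
concave pockets classical docking tools expect. On the amyloid-beta
spine segment KLVFFA (residues 16-21), the relevant surface features are a
ladder of lysine side chains -- the *Lys rail* -- whose ammonium nitrogens
repeat every 4.8 Angstrom along the fiber axis, and an adjacent apolar
face formed by valine and phenylalanine side chains. Flat, polyaromatic
compounds carrying well-spaced hydrogen-bond acceptors (the orange-G
chemotype) can lie in the groove, stack on the apolar face and
hydrogen-bond two or more rail lysines on adjacent strands. `fibscreen`
implements the full computational side of a screening campaign for such
fiber binders, plus the analysis of the binding (NMR titration) and
cell-protection (MTT) assays used to validate hits.

# Idealized fiber models

`buildFiber()` constructs a deterministic, dependency-free beta-sheet
fiber: one extended strand built from ideal bond lengths and angles
(backbone torsions -119/+113 degrees for parallel sheets, -139/+135 for
antiparallel), replicated along the +z fiber axis at a configurable rise
(default 4.8 Angstrom). Strands are exact copies, so same-face atom
spacings are exact multiples of the rise -- the 9.6 Angstrom Lys
Cbeta/NZ spacing two strands apart is a construction invariant, not a
fitted quantity. Antiparallel sheets rotate every other strand 180
degrees about the fiber axis, which reverses the strand direction and
exposes a given residue on one face only on alternating strands; the rail
spacing on one face is then still 9.6 Angstrom, matching the observation
that both sheet polarities present the same di-lysine geometry.

Out-of-register sheets, associated with toxic oligomers, are represented
by a *stand-in*: a uniform lateral shear per strand along the strand
direction. The only property this stand-in reproduces is the consequence
that matters for the binding model -- the same-face lysine spacing grows
to `sqrt((2 rise)^2 + (2 shear)^2)`, i.e. the 11-14 Angstrom range, which
a 9.6 Angstrom di-acceptor probe can no longer bridge
(`registerCompatibility()`). It makes no attempt to model beta-barrel
oligomer geometry itself.

Side chains are placed in a single canonical rotamer from an internal
template table (no rotamer library ships with the package). Most side
chains are fully extended; rings are turned to present a face; lysine
uses a bent (trans, gauche-, trans, gauche+) rotamer. The lysine choice
deserves a note: with a fully extended Lys, the NZ sits about 3 Angstrom
proud of the apolar surface and no rigid flat ligand can simultaneously
hydrogen-bond the rail and stack on the Val/Phe face -- a geometry
contradiction that zipper crystal structures resolve by bending the
lysine so the ammonium lies near the sheet plane. The bent default
reproduces that surface-level presentation. Supported residues are
A G V L I F Y S T N Q D E K; other letters are an input error.

The surface frame used for stacking dihedrals is a least-squares plane
through the selected side-chain atoms *constrained to be parallel to the
fiber axis*. An unconstrained fit to a z-periodic atom pattern acquires a
small axis component in its normal (about 4e-3 at six strands), which
would make the "frame perpendicular to the axis" property hold only
approximately; since the physical surface of a periodic fiber contains
the axis by construction, the constrained fit is the right estimator, and
it is exact at any strand count.

# Library preparation

`canonicalizeAndIndex()` canonicalizes SMILES through Open Babel
(via ChemmineR/ChemmineOB), collapses duplicate spellings, and computes
the descriptors the flat-compound filters need. Two definitions the
screening literature leaves vague are fixed here:

* **Freely rotatable bond**: a non-ring single bond between two
  non-terminal heavy atoms, excluding amide C-N. Terminality is judged on
  the heavy-atom graph.
* **Additional planar group**: a conjugated sp2 substituent of at least
  three atoms attached to an aromatic ring, matched by SMARTS patterns
  (nitro, carboxyl/carboxylate, ester/amide carbonyl, aryl ketone or
  aldehyde, azo, vinyl).

`flatFilter()` offers both published selection modes -- *strict* (phenol
present and fewer than three rotatable bonds) and *broad* (two or more
aromatic rings, or one ring plus a planar group) -- because the two modes
genuinely select different chemistry and the choice belongs to the user.
Molecular weight is computed from the anhydrous neutral formula, so salt
and hydrate decorations do not shift it. Unparsable entries go to a
rejects table rather than aborting a library build.

`makeProbeLigand()` generates the synthetic test chemotype: a planar
fused-hexagon scaffold with two negatively charged acceptor oxygens
placed exactly the requested distance apart on the long axis (auto-sizing
the scaffold so the acceptors attach at a bonded distance). A 9.6
Angstrom probe is the minimal caricature of a flat di-sulfonate dye
bridging the rail two strands apart.

# Near-native conformer ensembles

Screening poses stay close to the input conformation. For each rotatable
bond the torsion is perturbed by -5, 0 or +5 degrees and the full 3^k
product is enumerated (`enumerateLigandPerturbations()`); products beyond
10,000 candidates are down-sampled deterministically by seed, always
keeping the identity and all single-bond perturbations. The cap is a
package choice -- some cap is unavoidable once k grows, and 10,000 keeps
the ensemble build under a second for ordinary ligands.

`clusterEnsemble()` then k-means-clusters the superposed heavy-atom
coordinates with k = min(candidates, 100), takes cluster medoids, and
greedily drops representatives within 0.5 Angstrom heavy-atom RMSD of an
already retained one, so the retained set obeys both the 100-conformer
cap and the minimum-separation rule by construction. RMSD is computed
after optimal (Kabsch) superposition without graph-symmetry correction --
a symmetric ligand can therefore count a symmetry-equivalent conformer as
distinct, a documented limitation. When the candidate count is within the
cap, k-means with k = n is the identity and is skipped.

Fiber side-chain flexibility follows the same near-native philosophy:
`sidechainRotamerPerturbations()` applies deviations of 0, +/-0.33,
+/-0.67 and +/-1.0 standard deviations per chi angle (seven values), with
a default SD of 10 degrees per torsion since no backbone-dependent
rotamer library ships with the package.

# The interaction energy

The scoring function is a deliberately simple, fully documented
component-wise potential -- it is **not** a re-implementation of any
published force field, and its absolute kcal/mol values are not
comparable to published docking scores:

* **Lennard-Jones**, split Rosetta-style into an attractive branch
  (clamped at -epsilon inside the minimum) and a repulsive branch
  (linearized below 0.6 sigma so short contacts stay finite), per-element
  radii and well depths from a small internal table, 6 Angstrom cutoff
  with a cosine switch.
* **Hydrogen bonding**: a smooth windowed product
  `-E0 w(d1) w(theta1) w(theta2)` with E0 = 2 kcal/mol; the windows are
  the pharmacophore windows below, with cosine falloffs (0.4 Angstrom,
  20 degrees) so the term is continuous everywhere and strictly negative
  inside the windows. Geometry convention: theta1 at the acceptor
  (antecedent-acceptor-donor), theta2 at the donor
  (antecedent-donor-acceptor), measured on heavy atoms.
* **Electrostatics**: Coulomb with distance-dependent dielectric
  eps(r) = 10r, i.e. `332 q1 q2 / (10 r^2)`, same cutoff and switch.
* **Solvation**: an optional buried-apolar-contact reward, off by
  default (weight 0).

The total is the exact sum of components (enforced by a class validity
check), and `bindingEnergy()` -- E(complex) - E(fiber) - E(ligand) --
reduces analytically to the interaction energy; `systemEnergy()` exists
so tests can verify that identity by brute force. All components are
invariant under joint rigid transforms to 1e-6.

# Docking protocol

`dock()` runs three stages. The *coarse stage* scans a grid of
placements along the rail groove (1 Angstrom default spacing, 12
rotations about the surface normal, every conformer), with the ligand
oriented flat-face-down via its principal axes. The *Monte Carlo stage*
runs Metropolis sampling (default 500 cycles, temperature 1 kcal/mol)
over bounded rigid-body translations (within 5 Angstrom of the coarse
anchor), rotations (up to 360 degrees), conformer swaps and near-native
rail-lysine chi moves. The *refinement stage* is a derivative-free
coordinate descent on the six rigid-body parameters (0.25/0.1 Angstrom
and 5/2 degree steps) -- the contract is local improvement, not a
specific optimizer. Cycle counts, temperature and grid density are
package choices; nothing in the published protocols fixes them. The
best-so-far energy is logged every step and is non-increasing by
construction, and a zero-temperature run reduces to greedy descent.

# Post-docking filtering and ranking

`applyHardFilters()` removes poses with attractive van der Waals energy
above -7.0 kcal/mol or hydrogen-bond energy above -0.2 kcal/mol (both
configurable). `componentTopfraction()` keeps compounds ranked in the top
40% of *every* component -- total, Lennard-Jones, solvation, hydrogen
bonding, electrostatics -- computed on the per-compound best pose, with
ties at the cutoff broken by compound id. `finalRank()` orders by
tightest binding energy, then highest shape complementarity, then id.

Shape complementarity (`shapeComplementarity()`) follows the
surface-statistic idea: dot surfaces at 2 points per square Angstrom,
and for each buried interface sample the product of facing-normal
alignment with a Gaussian weight exp(-0.5 d^2) to its nearest
opposite-surface point; the score is the median over the buried samples
of both surfaces (burial cut 2 Angstrom, widened to the closest approach
when surfaces stand off). A missing interface is an explicit error, never
a zero score. The parameters (density 2 per square Angstrom, weight 0.5
per square Angstrom, median aggregation) are package choices; the
published statistic names no values.

# The geometric pharmacophore

`checkPharmacophore()` encodes the binder geometry as inclusive windows:

| quantity | window | meaning |
|---|---|---|
| d1 | 2.8-3.5 A | acceptor to rail NZ distance |
| theta1 | 100-150 deg | angle at the acceptor |
| theta2 | 130-180 deg | angle at NZ |
| d2 | 4.0-5.0 A | ring centroid to apolar center |
| phi | 0-40 deg | ring plane vs surface plane |
| contacts | >= 2 strands | distinct rail lysines bonded |
| span | 2-4 strands | strands covered by all contacts |

Two conventions the published windows leave open are fixed and
documented: theta1 is measured antecedent-acceptor-NZ and theta2 is
measured CE-NZ-acceptor (the third atom of each angle is not named in
the original description); a salt bridge counts as a hydrogen-bond
contact whose acceptor carries formal negative charge. Apolar side-chain
centers are the ring centroid for Phe/Tyr and the CB-to-CG midpoint for
Val. Window boundaries are inclusive with a 1e-9 numeric slack so exact
boundary values never fall out through floating-point rounding.

`idealProbePose()` constructs, by penalized rigid-body search, a probe
placement satisfying every window simultaneously (acceptors on the NZ of
two chosen strands, one ring stacked on an apolar center). It is the
package's geometric fixture generator: it demonstrates the windows are
jointly satisfiable on the antiparallel fiber and gives tests a
known-good pose without depending on the stochastic docking path.

# The 1:N titration binding model

For a ligand L binding fiber sites of N monomers (default N = 3), with
S = F_T/N + L_T + Kd, the bound-complex concentration is the smaller
root of the binding quadratic:

$$[F_N L] = \frac{S - \sqrt{S^2 - 4 (F_T/N) L_T}}{2},
\qquad f_{obs} = f_{max} \frac{[F_N L]}{L_T}$$

This is the ligand-depletion form: it stays correct when the bound
fraction is not small. `fitKd()` fits (Kd, f_max) to fractional
peak-area decreases by ordinary least squares with N fixed, under a
fast-exchange assumption (peak area is the population-weighted average;
no lineshape modeling). The fit is seeded by a profiled grid search --
the model is linear in f_max, so for each trial Kd on a log grid the
best f_max has a closed form -- and refined with Levenberg-Marquardt
under the bounds Kd > 0, 0 <= f_max <= 1. The grid seeding exists
because a single midpoint start can leave the two Jacobian columns
nearly collinear, aborting the fit before it begins. Noiseless round
trips recover generating parameters to well beyond three significant
figures; identifiability failures (flat series) are explicit errors.

The parameter-recovery simulation used in the tests runs the titration
design of the 43-micromolar reference compound: ligand 50 micromolar,
fiber monomer 0-950 micromolar in 10 points, 2% Gaussian noise, 200
seeds. Titrating at a ligand concentration near (not far above) the Kd
scale is what keeps the isotherm Kd-sensitive; designs with ligand far
above Kd are depletion-dominated and recover Kd several-fold worse.

# Assay normalization and statistics

`rescuePercentage()` maps viabilities to a rescue scale anchored at the
buffer control (100%) and the fiber-alone condition (0%); values outside
[0, 100] are preserved (added harm, super-rescue). `groupTTest()`
computes pooled or Welch two-sample t statistics from summary statistics
(mean, SD, n), one- or two-tailed. Printed p-values in summary tables of
this kind rarely state their tail and pooling conventions; the package
therefore exposes both variants and the tests validate against
`stats::t.test` on reconstructed raw data, not against any printed value.

# What the synthetic data do and do not show

The generators emulate: in-register and sheared lysine rail geometry
(exactly); a flat di-acceptor probe chemotype (schematically); titration
curves from the depletion model with Gaussian noise; and viability
summary tables. They do not emulate real crystal or ssNMR coordinates,
real ligand chemistry beyond the descriptor level, NMR spectra (inputs
are integrated areas), fiber polymorphism, or any cell biology. Passing
tests therefore demonstrate the correctness and internal consistency of
the algorithms -- geometric invariants, estimator calibration, filter
semantics -- not predictive accuracy on experimental fibers. Absolute
docking energies in particular are on the package's own scale and are
not comparable to published values from other force fields.

# Numerical choices and problem sizes

Tolerances: 1e-9 for geometric identities, 1e-6 for isometry checks,
inclusive-boundary slack 1e-9, bisection/quadratic agreement 1e-9.
Tie-breaks everywhere are by compound id. Degenerate inputs (collinear
plane selections, coincident atoms, empty interfaces, non-identifiable
titrations) raise typed errors rather than returning sentinel values.
The test and example workloads use 6-strand KLVFFA fibers (306 atoms),
probe ligands of 10-14 ring atoms, ensembles up to 243 candidates, and
docking runs of 15-100 Monte Carlo cycles -- sizes chosen so the full
suite exercises every stage in a few minutes on one core while leaving
all algorithmic paths identical to production-scale runs.

# Known limitations

* Fibers are idealized; no crystallographic symmetry, no two-sheet
  zipper packing, no backbone flexibility.
* One canonical rotamer per residue; side-chain sampling is a
  perturbation around it, not a rotamer library.
* The energy function is a teaching-grade potential: no polarization,
  no explicit water, Gasteiger charges for ligands and a fixed
  group-charge scheme for the fiber.
* RMSD deduplication ignores molecular symmetry.
* The out-of-register stand-in models only the rail-spacing consequence
  of shearing, not oligomer structure.
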