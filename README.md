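# fibscreen

Structure-based screening of compounds that bind the flat surface of
amyloid fibers, in R.

Amyloid-beta fibers are not classical drug targets: their surfaces are
flat and repetitive, organized around a ladder of lysine side chains (the
*Lys rail*, NZ atoms every 4.8 Å along the fiber axis) flanking an apolar
Val/Phe face. Flat polyaromatic compounds with two well-spaced
hydrogen-bond acceptors can lie in this groove, stacking on the apolar
face while their acceptors bridge rail lysines on strands two apart
(≈9.6 Å). `fibscreen` implements the computational pipeline for finding
such *binders of amyloid fibers* and the analysis of the assays used to
validate them:

- **Idealized fiber models** — in-register parallel, antiparallel, and a
  sheared out-of-register stand-in whose rail stretches to the 11–14 Å
  spacing of toxic oligomer sheets (`buildFiber`, `lysineRail`,
  `registerCompatibility`).
- **Library preparation** — SMILES canonicalization and indexing,
  intersection by canonical key, flat-compound filters (strict: phenol
  and < 3 rotatable bonds; broad: multiple rings or ring + planar
  group), synthetic di-acceptor probe ligands
  (`canonicalizeAndIndex`, `flatFilter`, `makeProbeLigand`).
- **Near-native conformer ensembles** — ±5° torsion perturbations,
  k-means clustering, 0.5 Å RMSD deduplication, ≤ 100 conformers
  (`buildEnsemble`); side-chain χ perturbations at ±0.33/0.67/1 SD.
- **Docking** — three stages (coarse groove grid → Metropolis Monte
  Carlo with 5 Å / 360° rigid-body moves → local refinement) scored by a
  simple component-wise potential: split Lennard-Jones, geometric
  hydrogen bonding, screened Coulomb, optional solvation (`dock`,
  `scorePose`, `bindingEnergy`).
- **Filtering and ranking** — hard filters (vdW attractive ≤ −7.0,
  H-bond ≤ −0.2 kcal/mol), top-40 %-in-every-component selection, shape
  complementarity in [−1, 1], final ranking by tightest binding energy
  (`applyHardFilters`, `componentTopfraction`, `shapeComplementarity`,
  `finalRank`).
- **Geometric pharmacophore** — inclusive windows d1 2.8–3.5 Å,
  Θ1 100–150°, Θ2 130–180°, d2 4.0–5.0 Å, Φ 0–40°, ≥ 2 rail lysines on
  2–4 adjacent strands (`checkPharmacophore`, `hbondContacts`,
  `stackingContacts`).
- **Binding and viability assays** — the 1:N ligand-depletion NMR
  titration model with N = 3 monomers per site,

  ```
  [FNL] = (S − sqrt(S² − 4 (F_T/N) L_T)) / 2,  S = F_T/N + L_T + Kd
  f_obs = f_max [FNL] / L_T
  ```

  fitted by least squares (`boundFraction`, `simulateTitration`,
  `fitKd`), plus MTT rescue normalization (PBS = 100 %, fiber alone =
  0 %) and summary-statistic t tests (`rescuePercentage`, `groupTTest`).

## Worked example

```r
library(fibscreen)

# An in-register KLVFFA fiber: the rail repeats every 4.8 A, so lysines
# two strands apart sit 9.6 A apart
fib <- buildFiber("KLVFFA", 6)
rail <- lysineRail(fib)
diff(rail$nz.z)
#> [1] 4.8 4.8 4.8 4.8 4.8

# A flat probe with acceptors 9.6 A apart bridges it; a sheared
# (out-of-register) fiber with a 12 A rail rejects it
registerCompatibility(fib, 9.6, tolerance = 0.5)
#> [1] "compatible"
sheared <- buildFiber("KLVFFA", 6, "out_of_register", shear = 3.6)
registerCompatibility(sheared, 9.6, tolerance = 0.5)
#> [1] "incompatible"

# Dock the probe on the antiparallel segment fiber and inspect energies
ap <- buildFiber("KLVFFA", 6, "antiparallel")
probe <- makeProbeLigand(9.6)
res <- dock(ap, buildEnsemble(probe), dockingConfig(nCycles = 100, seed = 42))
res$energy
#> EnergyBreakdown (kcal/mol):
#>   lj_attractive     -5.999
#>   lj_repulsive       0.773
#>   hbond             -3.999
#>   electrostatics    -2.200
#>   solvation          0.000
#>   total            -11.425

# A geometrically ideal pose satisfies the full pharmacophore
pose <- idealProbePose(ap, probe)
checkPharmacophore(applyPose(probe, pose), ap)
#> PharmacophoreReport: PASS
#>   2 H-bond contact(s), 1 stacking contact(s), span 3 strand(s)

# Fit an apparent Kd from a simulated NMR titration (1:3 model)
s <- simulateTitration(kd = 43, fMax = 0.46, n = 3, ligandTotal = 50,
                       fiberGrid = seq(0, 950, length.out = 10))
fitKd(s, n = 3)
#> BindingFit: Kd = 43 uM (SE 5.9e-14), f_max = 0.46 (SE 1.4e-16), N = 3

# Rescue percentage: viability 0.93 vs fiber-alone 0.40 (PBS = 1.0)
rescuePercentage(0.93, 0.40)
#> [1] 88.33333
```

The negative docking total means a favorable fiber–ligand interaction
(tighter is more negative); the pharmacophore report certifies the pose
hydrogen-bonds two rail lysines on strands 0 and 2 while one ring stacks
on the apolar face; the Kd fit recovers the generating parameters of a
noiseless titration exactly.

A command-line front end over the same functions (subcommands
`build-fiber`, `prep-ligands`, `conformers`, `dock`, `filter-rank`,
`pharm-check`, `fit-kd`, `rescue`, `run`) ships at
`inst/cli/fibscreen.R`; `run` drives the full screen from a YAML config
(`readScreenConfig` / `runScreen`).

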