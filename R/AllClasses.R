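#' @import methods
NULL

# Atom tables ------------------------------------------------------------
# Atoms are rows of a data.frame rather than individual objects: columns
# elety (atom name), elesy (element), resid (3-letter), resno (1-based within
# strand), strand (0-based), x, y, z, charge, donor, acceptor, aromatic,
# apolar. Ligand atom tables use the same x/y/z/charge/role columns with
# `name` and `elesy`.

.ATOM_COLS <- c("elety", "elesy", "resid", "resno", "strand",
                "x", "y", "z", "charge", "donor", "acceptor",
                "aromatic", "apolar")

#' FiberModel: an idealized or parsed beta-sheet fiber
#'
#' Atoms of all strands in one table (see package vignette for the coordinate
#' convention: fiber axis +z, sheet face normal +x, strand direction +y).
#'
#' @slot atoms data.frame of atoms (one row per atom).
#' @slot sequence one-letter residue sequence of a single strand.
#' @slot registration one of "in_register_parallel", "antiparallel",
#'   "out_of_register".
#' @slot rise numeric, Angstrom translation per strand along the fiber axis.
#' @slot shear numeric, lateral offset per strand (0 unless out-of-register).
#' @slot axis unit 3-vector, the fiber axis.
#' @exportClass FiberModel
setClass("FiberModel",
  representation(atoms = "data.frame", sequence = "character",
                 registration = "character", rise = "numeric",
                 shear = "numeric", axis = "numeric"),
  validity = function(object) {
    msg <- character(0)
    a <- object@atoms
    if (!all(.ATOM_COLS %in% names(a))) {
      msg <- c(msg, "atom table missing required columns")
    } else {
      if (!all(is.finite(c(a$x, a$y, a$z)))) msg <- c(msg, "non-finite coordinates")
      if (any(!nzchar(a$elesy))) msg <- c(msg, "empty element symbols")
      if (any(a$elesy == "C" & a$acceptor)) {
        msg <- c(msg, "carbon atoms cannot be hydrogen-bond acceptors")
      }
      n_per <- table(a$strand)
      if (length(unique(n_per)) > 1) msg <- c(msg, "strands differ in atom count")
    }
    if (!object@registration %in% c("in_register_parallel", "antiparallel",
                                    "out_of_register")) {
      msg <- c(msg, "unknown registration")
    }
    if (object@rise <= 0) msg <- c(msg, "rise must be positive")
    if (object@registration == "out_of_register" && abs(object@shear) <= 0) {
      msg <- c(msg, "out_of_register requires |shear| > 0")
    }
    if (abs(.vnorm(object@axis) - 1) > 1e-9) msg <- c(msg, "axis must be unit length")
    if (length(msg)) msg else TRUE
  }
)

#' SurfaceFrame: local frame of a fiber face
#'
#' @slot origin 3-vector, Angstrom.
#' @slot normal unit 3-vector, oriented away from the sheet interior.
#' @slot inPlane 3 x 2 matrix of two in-plane unit axes.
#' @exportClass SurfaceFrame
setClass("SurfaceFrame",
  representation(origin = "numeric", normal = "numeric", inPlane = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (abs(.vnorm(object@normal) - 1) > 1e-9) msg <- c(msg, "normal not unit length")
    for (k in 1:2) {
      if (abs(.vnorm(object@inPlane[, k]) - 1) > 1e-9) {
        msg <- c(msg, "in-plane axis not unit length")
      }
      if (abs(sum(object@normal * object@inPlane[, k])) > 1e-9) {
        msg <- c(msg, "in-plane axis not perpendicular to normal")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Ligand: a small molecule with coordinates, bonds and interaction roles
#'
#' @slot id character identifier.
#' @slot atoms data.frame: name, elesy, x, y, z, charge, donor, acceptor,
#'   aromatic, apolar.
#' @slot bonds data.frame: a1, a2 (atom row indices), order, rotatable.
#' @slot rings list of integer vectors (atom indices of each ring) with
#'   attribute "aromatic" per ring entry.
#' @exportClass Ligand
setClass("Ligand",
  representation(id = "character", atoms = "data.frame", bonds = "data.frame",
                 rings = "list"),
  validity = function(object) {
    a <- object@atoms
    msg <- character(0)
    if (!all(is.finite(c(a$x, a$y, a$z)))) msg <- c(msg, "non-finite coordinates")
    if (any(a$elesy == "C" & a$acceptor)) {
      msg <- c(msg, "carbon atoms cannot be hydrogen-bond acceptors")
    }
    if (nrow(object@bonds)) {
      if (max(object@bonds$a1, object@bonds$a2) > nrow(a)) {
        msg <- c(msg, "bond indices out of range")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' EnsembleConfig: near-native perturbation settings
#'
#' Defaults follow the screening protocol: ligand torsions perturbed by
#' +/- 5 degrees, conformers closer than 0.5 Angstrom heavy-atom RMSD
#' deduplicated, at most 100 conformers kept, side-chain chi angles perturbed
#' at +/- 0.33, 0.67 and 1.0 standard deviations.
#'
#' @slot ligandTorsionDelta degrees.
#' @slot dedupRmsd Angstrom.
#' @slot maxConformers integer.
#' @slot sidechainSdMultipliers numeric vector.
#' @slot enumCap integer, hard cap on enumerated torsion combinations.
#' @slot seed integer random seed.
#' @exportClass EnsembleConfig
setClass("EnsembleConfig",
  representation(ligandTorsionDelta = "numeric", dedupRmsd = "numeric",
                 maxConformers = "integer", sidechainSdMultipliers = "numeric",
                 enumCap = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@maxConformers < 1L) msg <- c(msg, "maxConformers must be >= 1")
    if (object@dedupRmsd <= 0) msg <- c(msg, "dedupRmsd must be > 0")
    if (object@enumCap < 1L) msg <- c(msg, "enumCap must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' ConformerEnsemble: retained near-native conformers of one ligand
#'
#' @slot ligand the parent \linkS4class{Ligand}.
#' @slot conformers list of n x 3 coordinate matrices.
#' @slot provenance list of per-conformer torsion deltas applied.
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
  representation(ligand = "Ligand", conformers = "list", provenance = "list"),
  validity = function(object) {
    if (length(object@conformers) < 1) return("ensemble must hold >= 1 conformer")
    n <- nrow(object@ligand@atoms)
    ok <- vapply(object@conformers, function(m) is.matrix(m) && nrow(m) == n, TRUE)
    if (!all(ok)) return("conformer coordinate matrices must match atom count")
    TRUE
  }
)

#' Pose: rigid-body placement of a conformer on the fiber
#'
#' @slot conformerIndex integer index into the ensemble.
#' @slot rotation 3 x 3 orthonormal matrix (det +1).
#' @slot translation 3-vector, Angstrom.
#' @slot sidechain named list of chi-angle assignments
#'   ("strand.resno" -> numeric chi vector); empty when side chains are at
#'   their build rotamer.
#' @exportClass Pose
setClass("Pose",
  representation(conformerIndex = "integer", rotation = "matrix",
                 translation = "numeric", sidechain = "list"),
  validity = function(object) {
    R <- object@rotation
    if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
    if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
    TRUE
  }
)

#' EnergyBreakdown: component-wise interaction energy of a pose
#'
#' All values in kcal/mol; total is the exact sum of the components.
#'
#' @slot ljAttractive attractive Lennard-Jones component (<= 0).
#' @slot ljRepulsive repulsive Lennard-Jones component (>= 0).
#' @slot hbond hydrogen-bond component (<= 0).
#' @slot electrostatics screened Coulomb component.
#' @slot solvation buried-apolar-area reward (0 when disabled).
#' @slot total sum of components.
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
  representation(ljAttractive = "numeric", ljRepulsive = "numeric",
                 hbond = "numeric", electrostatics = "numeric",
                 solvation = "numeric", total = "numeric"),
  validity = function(object) {
    msg <- character(0)
    s <- object@ljAttractive + object@ljRepulsive + object@hbond +
      object@electrostatics + object@solvation
    if (abs(object@total - s) > 1e-9) msg <- c(msg, "total != sum of components")
    if (object@ljAttractive > 1e-12) msg <- c(msg, "ljAttractive must be <= 0")
    if (object@ljRepulsive < -1e-12) msg <- c(msg, "ljRepulsive must be >= 0")
    if (object@hbond > 1e-12) msg <- c(msg, "hbond must be <= 0")
    if (length(msg)) msg else TRUE
  }
)

#' DockingConfig: three-stage docking settings
#'
#' @slot maxTranslation Angstrom bound on rigid-body translation moves
#'   (default 5).
#' @slot rotationRange degrees of rotational freedom (default 360).
#' @slot nCycles Monte Carlo cycles in stage 2.
#' @slot temperature Metropolis temperature, kcal/mol.
#' @slot seed integer random seed.
#' @slot interactionCutoff Angstrom pair cutoff of the energy function.
#' @slot gridStep Angstrom spacing of the coarse placement grid.
#' @slot nRotations coarse-stage rotations about the surface normal.
#' @exportClass DockingConfig
setClass("DockingConfig",
  representation(maxTranslation = "numeric", rotationRange = "numeric",
                 nCycles = "integer", temperature = "numeric",
                 seed = "integer", interactionCutoff = "numeric",
                 gridStep = "numeric", nRotations = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@maxTranslation <= 0) msg <- c(msg, "maxTranslation must be > 0")
    if (object@nCycles < 0L) msg <- c(msg, "nCycles must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' FilterConfig: post-docking hard filters and top-fraction selection
#'
#' Defaults follow the screening protocol: poses with attractive van der
#' Waals energy above -7.0 kcal/mol or hydrogen-bond energy above -0.2
#' kcal/mol are removed, then compounds must rank in the top 40 percent of
#' every energy component.
#'
#' @slot vdwAttractiveMax kcal/mol (default -7.0).
#' @slot hbondMax kcal/mol (default -0.2).
#' @slot topFraction in (0, 1] (default 0.40).
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(vdwAttractiveMax = "numeric", hbondMax = "numeric",
                 topFraction = "numeric"),
  validity = function(object) {
    if (object@topFraction <= 0 || object@topFraction > 1) {
      return("topFraction must be in (0, 1]")
    }
    TRUE
  }
)

#' GeometryWindows: geometric pharmacophore acceptance windows
#'
#' Defaults: hydrogen-bond distance d1 in [2.8, 3.5] Angstrom, acceptor angle
#' theta1 in [100, 150] degrees, donor angle theta2 in [130, 180] degrees,
#' stacking distance d2 in [4.0, 5.0] Angstrom, ring-plane dihedral phi in
#' [0, 40] degrees, at least 2 lysine contacts, contacts spanning 2-4
#' adjacent strands. Window boundaries are inclusive.
#'
#' @slot d1 numeric length-2 interval, Angstrom.
#' @slot theta1 numeric length-2 interval, degrees.
#' @slot theta2 numeric length-2 interval, degrees.
#' @slot d2 numeric length-2 interval, Angstrom.
#' @slot phi numeric length-2 interval, degrees.
#' @slot minLysContacts integer.
#' @slot strandSpan integer length-2 interval.
#' @exportClass GeometryWindows
setClass("GeometryWindows",
  representation(d1 = "numeric", theta1 = "numeric", theta2 = "numeric",
                 d2 = "numeric", phi = "numeric", minLysContacts = "integer",
                 strandSpan = "integer"),
  validity = function(object) {
    msg <- character(0)
    for (s in c("d1", "theta1", "theta2", "d2", "phi", "strandSpan")) {
      iv <- slot(object, s)
      if (length(iv) != 2 || iv[1] > iv[2]) {
        msg <- c(msg, paste0(s, " must be a lo <= hi interval"))
      }
    }
    if (object@minLysContacts < 1L) msg <- c(msg, "minLysContacts must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' PharmacophoreReport: geometric evaluation of one pose
#'
#' @slot hbondContacts data.frame: strand, acceptor, d1, theta1, theta2.
#' @slot stackContacts data.frame: strand, resno, resid, d2, phi.
#' @slot strandsSpanned integer.
#' @slot passes logical.
#' @slot failureReasons character vector of violated conditions.
#' @exportClass PharmacophoreReport
setClass("PharmacophoreReport",
  representation(hbondContacts = "data.frame", stackContacts = "data.frame",
                 strandsSpanned = "integer", passes = "logical",
                 failureReasons = "character"))

#' TitrationSeries: one NMR fiber-into-ligand titration
#'
#' @slot ligandTotal total ligand concentration, micromolar.
#' @slot fiberTotals fiber concentrations (as monomer), micromolar,
#'   strictly increasing.
#' @slot fractionalDecreases observed fractional peak-area decreases
#'   (Delta A / A_L), dimensionless in [0, 1].
#' @exportClass TitrationSeries
setClass("TitrationSeries",
  representation(ligandTotal = "numeric", fiberTotals = "numeric",
                 fractionalDecreases = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fiberTotals) != length(object@fractionalDecreases)) {
      msg <- c(msg, "fiberTotals and fractionalDecreases differ in length")
    }
    if (any(object@fiberTotals < 0)) msg <- c(msg, "concentrations must be >= 0")
    if (any(diff(object@fiberTotals) <= 0)) {
      msg <- c(msg, "fiberTotals must be strictly increasing")
    }
    fr <- object@fractionalDecreases
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractional decreases must lie in [0, 1]")
    if (object@ligandTotal < 0) msg <- c(msg, "ligandTotal must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' BindingFit: fitted 1:N ligand-depletion binding parameters
#'
#' @slot kd apparent dissociation constant, micromolar.
#' @slot fMax maximum fractional signal decrease at saturation.
#' @slot n monomers per binding site (fixed during the fit).
#' @slot standardErrors named numeric (kd, fMax).
#' @slot residuals numeric fit residuals.
#' @slot series the fitted \linkS4class{TitrationSeries}.
#' @exportClass BindingFit
setClass("BindingFit",
  representation(kd = "numeric", fMax = "numeric", n = "numeric",
                 standardErrors = "numeric", residuals = "numeric",
                 series = "TitrationSeries"),
  validity = function(object) {
    msg <- character(0)
    if (object@kd <= 0) msg <- c(msg, "kd must be > 0")
    if (object@fMax < 0 || object@fMax > 1) msg <- c(msg, "fMax must lie in [0, 1]")
    if (object@n < 1) msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
  }
)
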