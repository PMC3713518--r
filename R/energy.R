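#' @include AllClasses.R AllGenerics.R fiber.R ligand.R
NULL

# Simplified component-wise interaction energy (NOT a Rosetta
# re-implementation): a 6-12 pair potential split into attractive and
# repulsive parts with linearized repulsion at very short range, a smooth
# geometric hydrogen-bond term windowed in (d1, theta1, theta2), screened
# Coulomb electrostatics with distance-dependent dielectric eps(r) = 10 r,
# and an optional buried-apolar-contact solvation reward (off by default).

# per-element Lennard-Jones radii (Angstrom, r_min = R_i + R_j) and well
# depths (kcal/mol, eps_ij = sqrt(eps_i eps_j))
.LJ_RADIUS <- c(C = 1.90, N = 1.75, O = 1.70, S = 2.00, P = 2.00, H = 1.20,
                F = 1.65, CL = 1.90, BR = 2.00, I = 2.15)
.LJ_EPS <- c(C = 0.12, N = 0.16, O = 0.18, S = 0.20, P = 0.20, H = 0.02,
             F = 0.15, CL = 0.25, BR = 0.30, I = 0.35)
.COULOMB_K <- 332.0637
.HB_E0 <- 2.0          # kcal/mol depth of an ideal hydrogen bond
.HB_MARGIN_D <- 0.4    # Angstrom falloff outside the d1 window
.HB_MARGIN_A <- 20     # degrees falloff outside the angle windows

.ljParam <- function(elesy, what) {
  tab <- if (what == "r") .LJ_RADIUS else .LJ_EPS
  v <- tab[toupper(elesy)]
  v[is.na(v)] <- if (what == "r") 1.80 else 0.10
  unname(v)
}

# Split 6-12 potential for a vector of distances: attractive branch equals
# the potential beyond r_min and is clamped at -eps inside it; the repulsive
# branch is the remainder, linearized below 0.6 sigma. A cosine switch
# tapers both to zero between (cutoff - 0.5) and cutoff.
.ljSplit <- function(r, rmin, eps, cutoff = 6) {
  v <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  attr_ <- ifelse(r >= rmin, v, -eps)
  rep_ <- ifelse(r < rmin, v + eps, 0)
  sigma <- rmin / 2^(1 / 6)
  r0 <- 0.6 * sigma
  short <- r < r0
  if (any(short)) {
    rm_s <- rmin[short]; eps_s <- eps[short]; r0_s <- r0[short]
    v0 <- eps_s * ((rm_s / r0_s)^12 - 2 * (rm_s / r0_s)^6) + eps_s
    slope <- eps_s * (-12 * rm_s^12 / r0_s^13 + 12 * rm_s^6 / r0_s^7)
    rep_[short] <- v0 + slope * (r[short] - r0_s)
  }
  sw <- .switchFun(r, cutoff)
  list(attractive = attr_ * sw, repulsive = rep_ * sw)
}

.switchFun <- function(r, cutoff, width = 0.5) {
  lo <- cutoff - width
  s <- rep(1, length(r))
  mid <- r > lo & r < cutoff
  s[mid] <- 0.5 * (1 + cos(pi * (r[mid] - lo) / width))
  s[r >= cutoff] <- 0
  s
}

# Smooth window: 1 inside [lo, hi], cosine ramp to 0 over margin outside.
.smoothWindow <- function(x, lo, hi, margin) {
  w <- numeric(length(x))
  inside <- x >= lo & x <= hi
  w[inside] <- 1
  below <- x < lo & x > lo - margin
  w[below] <- 0.5 * (1 + cos(pi * (lo - x[below]) / margin))
  above <- x > hi & x < hi + margin
  w[above] <- 0.5 * (1 + cos(pi * (x[above] - hi) / margin))
  w
}

#' Geometric hydrogen-bond energy
#'
#' Smooth, strictly negative inside the acceptance windows and decaying
#' continuously to zero outside a cosine falloff envelope:
#' E = -E0 * w(d1) * w(theta1) * w(theta2), with d1 the donor-heavy to
#' acceptor distance, theta1 the angle at the acceptor
#' (acceptor-antecedent - acceptor - donor) and theta2 the angle at the
#' donor (donor-antecedent - donor - acceptor).
#'
#' @param donor 3-vector, donor heavy-atom position (e.g. lysine NZ).
#' @param donorAntecedent 3-vector, heavy atom bonded to the donor (CE).
#' @param acceptor 3-vector, acceptor atom position.
#' @param acceptorAntecedent 3-vector, heavy atom bonded to the acceptor.
#' @param windows a \linkS4class{GeometryWindows} (defaults used if omitted).
#' @return energy in kcal/mol (<= 0).
#' @export
hbondEnergy <- function(donor, donorAntecedent, acceptor, acceptorAntecedent,
                        windows = geometryWindows()) {
  d1 <- .vnorm(acceptor - donor)
  if (d1 < 1e-6) stop("numeric guard: coincident donor/acceptor", call. = FALSE)
  th1 <- .angle3(acceptorAntecedent, acceptor, donor)
  th2 <- .angle3(donorAntecedent, donor, acceptor)
  -.HB_E0 *
    .smoothWindow(d1, windows@d1[1], windows@d1[2], .HB_MARGIN_D) *
    .smoothWindow(th1, windows@theta1[1], windows@theta1[2], .HB_MARGIN_A) *
    .smoothWindow(th2, windows@theta2[1], windows@theta2[2], .HB_MARGIN_A)
}

# Donor/acceptor inventories with antecedent coordinates.
.fiberPolarSites <- function(atoms) {
  idx <- which((atoms$donor | atoms$acceptor) &
               atoms$elety %in% names(.FIBER_ANTECEDENT))
  if (!length(idx)) {
    return(data.frame(i = integer(0)))
  }
  ante <- vapply(idx, function(i) {
    ae <- .FIBER_ANTECEDENT[[atoms$elety[i]]]
    j <- which(atoms$strand == atoms$strand[i] & atoms$resno == atoms$resno[i] &
               atoms$elety == ae)
    if (length(j)) j[1] else NA_integer_
  }, 1L)
  ok <- !is.na(ante)
  data.frame(i = idx[ok], ante = ante[ok],
             donor = atoms$donor[idx[ok]], acceptor = atoms$acceptor[idx[ok]])
}

.ligandPolarSites <- function(atoms, bonds) {
  idx <- which(atoms$donor | atoms$acceptor)
  if (!length(idx)) return(data.frame(i = integer(0)))
  ante <- vapply(idx, function(i) {
    nbrs <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
    nbrs <- nbrs[atoms$elesy[nbrs] != "H"]
    if (length(nbrs)) nbrs[1] else NA_integer_
  }, 1L)
  ok <- !is.na(ante)
  data.frame(i = idx[ok], ante = ante[ok],
             donor = atoms$donor[idx[ok]], acceptor = atoms$acceptor[idx[ok]])
}

# Core pairwise interaction energy between two atom tables. Each table needs
# x, y, z, elesy, charge, apolar; polar site tables supply H-bond geometry.
.interactionEnergy <- function(atomsA, atomsB, sitesA, sitesB,
                               cutoff = 6, windows = geometryWindows(),
                               solvationWeight = 0) {
  xa <- as.matrix(atomsA[, c("x", "y", "z")])
  xb <- as.matrix(atomsB[, c("x", "y", "z")])
  # pair distances within cutoff
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  pair <- which(d < cutoff, arr.ind = TRUE)
  lj_attr <- 0; lj_rep <- 0; elec <- 0; solv <- 0
  if (nrow(pair)) {
    r <- d[pair]
    if (any(r < 1e-6)) {
      stop("numeric guard: coincident atoms between the two molecules",
           call. = FALSE)
    }
    ia <- pair[, 1]; ib <- pair[, 2]
    rmin <- .ljParam(atomsA$elesy[ia], "r") + .ljParam(atomsB$elesy[ib], "r")
    eps <- sqrt(.ljParam(atomsA$elesy[ia], "e") * .ljParam(atomsB$elesy[ib], "e"))
    lj <- .ljSplit(r, rmin, eps, cutoff)
    lj_attr <- sum(lj$attractive)
    lj_rep <- sum(lj$repulsive)
    q <- atomsA$charge[ia] * atomsB$charge[ib]
    # distance-dependent dielectric eps(r) = 10 r
    elec <- sum(.COULOMB_K * q / (10 * r^2) * .switchFun(r, cutoff))
    if (solvationWeight > 0) {
      ap <- atomsA$apolar[ia] & atomsB$apolar[ib]
      if (any(ap)) {
        w <- pmax(0, pmin(1, (6 - r[ap]) / 2))
        solv <- -solvationWeight * sum(w)
      }
    }
  }
  hb <- 0
  if (nrow(sitesA) && nrow(sitesB)) {
    for (p in seq_len(nrow(sitesA))) {
      for (q2 in seq_len(nrow(sitesB))) {
        if (sitesA$donor[p] && sitesB$acceptor[q2]) {
          hb <- hb + hbondEnergy(
            unlist(xa[sitesA$i[p], ]), unlist(xa[sitesA$ante[p], ]),
            unlist(xb[sitesB$i[q2], ]), unlist(xb[sitesB$ante[q2], ]),
            windows)
        }
        if (sitesA$acceptor[p] && sitesB$donor[q2]) {
          hb <- hb + hbondEnergy(
            unlist(xb[sitesB$i[q2], ]), unlist(xb[sitesB$ante[q2], ]),
            unlist(xa[sitesA$i[p], ]), unlist(xa[sitesA$ante[p], ]),
            windows)
        }
      }
    }
  }
  new("EnergyBreakdown", ljAttractive = lj_attr, ljRepulsive = lj_rep,
      hbond = hb, electrostatics = elec, solvation = solv,
      total = lj_attr + lj_rep + hb + elec + solv)
}

# Ligand atom table in fiber-compatible column layout.
.ligandAsAtoms <- function(lig) {
  a <- lig@atoms
  data.frame(elety = a$name, elesy = a$elesy, resid = "LIG", resno = 1L,
             strand = -1L, x = a$x, y = a$y, z = a$z, charge = a$charge,
             donor = a$donor, acceptor = a$acceptor, aromatic = a$aromatic,
             apolar = a$apolar, stringsAsFactors = FALSE)
}

#' Score a ligand pose against a fiber
#'
#' Computes the component-wise fiber-ligand interaction energy for a placed
#' conformer. Deterministic; all components are summed over atom pairs
#' within the interaction cutoff.
#'
#' @param fiber a \linkS4class{FiberModel}.
#' @param x a \linkS4class{ConformerEnsemble} or \linkS4class{Ligand}.
#' @param pose a \linkS4class{Pose} (optional for a pre-placed ligand).
#' @param config a \linkS4class{DockingConfig} (cutoff taken from it).
#' @param windows \linkS4class{GeometryWindows} for the hydrogen-bond term.
#' @param solvationWeight weight of the optional buried-apolar reward
#'   (default 0 = off).
#' @return an \linkS4class{EnergyBreakdown}.
#' @export
scorePose <- function(fiber, x, pose = NULL, config = dockingConfig(),
                      windows = geometryWindows(), solvationWeight = 0) {
  lig <- if (is.null(pose)) {
    if (is(x, "ConformerEnsemble")) x@ligand else x
  } else {
    applyPose(x, pose)
  }
  fib <- fiber
  if (!is.null(pose) && length(pose@sidechain)) {
    fib <- .applySidechains(fib, pose@sidechain)
  }
  fa <- fib@atoms
  la <- .ligandAsAtoms(lig)
  .interactionEnergy(fa, la,
                     .fiberPolarSites(fa),
                     .ligandPolarSites(lig@atoms, lig@bonds),
                     cutoff = config@interactionCutoff, windows = windows,
                     solvationWeight = solvationWeight)
}

# All-pairs energy within one atom table (i < j), same potential as the
# cross-molecular scorer. Used to evaluate E(complex), E(fiber), E(ligand)
# by definition.
.selfEnergy <- function(atoms, sites, cutoff = 6, windows = geometryWindows(),
                        solvationWeight = 0) {
  x <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(x)
  if (n < 2) return(0)
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  sel <- upper.tri(d) & d < cutoff
  pair <- which(sel, arr.ind = TRUE)
  tot <- 0
  if (nrow(pair)) {
    r <- d[sel]
    if (any(r < 1e-6)) stop("numeric guard: coincident atoms", call. = FALSE)
    ia <- pair[, 1]; ib <- pair[, 2]
    rmin <- .ljParam(atoms$elesy[ia], "r") + .ljParam(atoms$elesy[ib], "r")
    eps <- sqrt(.ljParam(atoms$elesy[ia], "e") * .ljParam(atoms$elesy[ib], "e"))
    lj <- .ljSplit(r, rmin, eps, cutoff)
    q <- atoms$charge[ia] * atoms$charge[ib]
    tot <- sum(lj$attractive) + sum(lj$repulsive) +
      sum(.COULOMB_K * q / (10 * r^2) * .switchFun(r, cutoff))
    if (solvationWeight > 0) {
      ap <- atoms$apolar[ia] & atoms$apolar[ib]
      w <- pmax(0, pmin(1, (6 - r[ap]) / 2))
      tot <- tot - solvationWeight * sum(w)
    }
  }
  if (nrow(sites) >= 2) {
    for (p in seq_len(nrow(sites))) {
      for (q2 in seq_len(nrow(sites))) {
        if (p == q2) next
        if (sites$donor[p] && sites$acceptor[q2]) {
          tot <- tot + hbondEnergy(
            unlist(x[sites$i[p], ]), unlist(x[sites$ante[p], ]),
            unlist(x[sites$i[q2], ]), unlist(x[sites$ante[q2], ]), windows)
        }
      }
    }
  }
  tot
}

#' Total energy of a fiber, a ligand, or their complex
#'
#' Sum of all pairwise interactions within the given system (both molecules
#' when both are supplied). \code{bindingEnergy} equals
#' \code{systemEnergy(fiber, ligand) - systemEnergy(fiber) -
#' systemEnergy(ligand = ligand)} by construction; this evaluator exists so
#' that identity can be checked by definition.
#'
#' @inheritParams scorePose
#' @param ligand a placed \linkS4class{Ligand} (already posed).
#' @return kcal/mol (numeric scalar).
#' @export
systemEnergy <- function(fiber = NULL, ligand = NULL,
                         config = dockingConfig(),
                         windows = geometryWindows(), solvationWeight = 0) {
  cutoff <- config@interactionCutoff
  tot <- 0
  if (!is.null(fiber)) {
    fa <- fiber@atoms
    tot <- tot + .selfEnergy(fa, .fiberPolarSites(fa), cutoff, windows,
                             solvationWeight)
  }
  if (!is.null(ligand)) {
    la <- .ligandAsAtoms(ligand)
    lsites <- .ligandPolarSites(ligand@atoms, ligand@bonds)
    la_sites <- lsites
    tot <- tot + .selfEnergy(la, la_sites, cutoff, windows, solvationWeight)
  }
  if (!is.null(fiber) && !is.null(ligand)) {
    eb <- .interactionEnergy(fiber@atoms, .ligandAsAtoms(ligand),
                             .fiberPolarSites(fiber@atoms),
                             .ligandPolarSites(ligand@atoms, ligand@bonds),
                             cutoff, windows, solvationWeight)
    tot <- tot + eb@total
  }
  tot
}

#' Binding energy of a pose
#'
#' Defined as E(complex) - E(fiber alone) - E(ligand alone), where each
#' total is the sum of all pairwise interactions within the system. The
#' intramolecular sums cancel, so the result equals the fiber-ligand
#' interaction energy; negative values are favorable.
#'
#' @inheritParams scorePose
#' @return kcal/mol (numeric scalar).
#' @export
bindingEnergy <- function(fiber, x, pose = NULL, config = dockingConfig(),
                          windows = geometryWindows(), solvationWeight = 0) {
  eb <- scorePose(fiber, x, pose, config, windows, solvationWeight)
  eb@total
}
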