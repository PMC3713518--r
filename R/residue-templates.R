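# Internal residue template table: ideal bond lengths/angles (Engh-Huber-like
# values) and side-chain construction records. Side-chain atoms are placed by
# NeRF from three reference atoms; dihedrals may be tied to a chi angle with
# an additive offset, so the same template serves rotamer perturbation.

.AA1TO3 <- c(A = "ALA", G = "GLY", V = "VAL", L = "LEU", I = "ILE",
             F = "PHE", Y = "TYR", S = "SER", T = "THR", N = "ASN",
             Q = "GLN", D = "ASP", E = "GLU", K = "LYS")
.AA3TO1 <- setNames(names(.AA1TO3), .AA1TO3)

# Backbone ideal geometry
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

# Strand backbone torsions per registration
.PHI_PSI <- list(
  in_register_parallel = c(phi = -119, psi = 113),
  antiparallel = c(phi = -139, psi = 135),
  out_of_register = c(phi = -139, psi = 135)
)

.sc <- function(name, refs, bond, ang, chi = NA, offset = 0, dih = NA) {
  list(name = name, refs = refs, bond = bond, ang = ang,
       chi = chi, offset = offset, dih = dih)
}

# Side-chain templates (heavy atoms). CB is placed separately (improper).
.SIDECHAINS <- list(
  GLY = list(),
  ALA = list(),
  VAL = list(
    .sc("CG1", c("N", "CA", "CB"), 1.521, 110.5, chi = 1),
    .sc("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1, offset = -122.3)
  ),
  LEU = list(
    .sc("CG", c("N", "CA", "CB"), 1.530, 116.3, chi = 1),
    .sc("CD1", c("CA", "CB", "CG"), 1.521, 110.7, chi = 2),
    .sc("CD2", c("CA", "CB", "CG"), 1.521, 110.7, chi = 2, offset = 122.6)
  ),
  ILE = list(
    .sc("CG1", c("N", "CA", "CB"), 1.530, 110.4, chi = 1),
    .sc("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1, offset = -122.3),
    .sc("CD1", c("CA", "CB", "CG1"), 1.513, 113.9, chi = 2)
  ),
  PHE = list(
    .sc("CG", c("N", "CA", "CB"), 1.502, 113.8, chi = 1),
    .sc("CD1", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2),
    .sc("CD2", c("CA", "CB", "CG"), 1.384, 120.8, chi = 2, offset = 180),
    .sc("CE1", c("CB", "CG", "CD1"), 1.382, 120.8, dih = 180),
    .sc("CE2", c("CB", "CG", "CD2"), 1.382, 120.8, dih = 180),
    .sc("CZ", c("CG", "CD1", "CE1"), 1.382, 120.0, dih = 0)
  ),
  TYR = list(
    .sc("CG", c("N", "CA", "CB"), 1.512, 113.9, chi = 1),
    .sc("CD1", c("CA", "CB", "CG"), 1.389, 120.8, chi = 2),
    .sc("CD2", c("CA", "CB", "CG"), 1.389, 120.8, chi = 2, offset = 180),
    .sc("CE1", c("CB", "CG", "CD1"), 1.382, 121.1, dih = 180),
    .sc("CE2", c("CB", "CG", "CD2"), 1.382, 121.1, dih = 180),
    .sc("CZ", c("CG", "CD1", "CE1"), 1.378, 119.5, dih = 0),
    .sc("OH", c("CD1", "CE1", "CZ"), 1.376, 119.9, dih = 180)
  ),
  SER = list(
    .sc("OG", c("N", "CA", "CB"), 1.417, 110.8, chi = 1)
  ),
  THR = list(
    .sc("OG1", c("N", "CA", "CB"), 1.433, 109.6, chi = 1),
    .sc("CG2", c("N", "CA", "CB"), 1.521, 110.5, chi = 1, offset = -120)
  ),
  ASN = list(
    .sc("CG", c("N", "CA", "CB"), 1.516, 112.6, chi = 1),
    .sc("OD1", c("CA", "CB", "CG"), 1.231, 120.8, chi = 2),
    .sc("ND2", c("CA", "CB", "CG"), 1.328, 116.4, chi = 2, offset = 180)
  ),
  GLN = list(
    .sc("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    .sc("CD", c("CA", "CB", "CG"), 1.516, 112.6, chi = 2),
    .sc("OE1", c("CB", "CG", "CD"), 1.231, 120.8, chi = 3),
    .sc("NE2", c("CB", "CG", "CD"), 1.328, 116.4, chi = 3, offset = 180)
  ),
  ASP = list(
    .sc("CG", c("N", "CA", "CB"), 1.516, 112.6, chi = 1),
    .sc("OD1", c("CA", "CB", "CG"), 1.249, 118.4, chi = 2),
    .sc("OD2", c("CA", "CB", "CG"), 1.249, 118.4, chi = 2, offset = 180)
  ),
  GLU = list(
    .sc("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    .sc("CD", c("CA", "CB", "CG"), 1.516, 112.6, chi = 2),
    .sc("OE1", c("CB", "CG", "CD"), 1.249, 118.4, chi = 3),
    .sc("OE2", c("CB", "CG", "CD"), 1.249, 118.4, chi = 3, offset = 180)
  ),
  LYS = list(
    .sc("CG", c("N", "CA", "CB"), 1.520, 114.1, chi = 1),
    .sc("CD", c("CA", "CB", "CG"), 1.520, 111.3, chi = 2),
    .sc("CE", c("CB", "CG", "CD"), 1.520, 111.3, chi = 3),
    .sc("NZ", c("CG", "CD", "CE"), 1.489, 111.9, chi = 4)
  )
)

.N_CHI <- vapply(.SIDECHAINS, function(tpl) {
  chis <- vapply(tpl, function(a) ifelse(is.na(a$chi), 0L, as.integer(a$chi)), 1L)
  if (length(chis)) max(chis) else 0L
}, 1L)

# Canonical default rotamer: fully extended, except (i) rings turned to
# present a face and (ii) lysine bent (a tgtg+ rotamer) so the ammonium
# nitrogen sits near the sheet face rather than 3 A proud of it -- the
# geometry zipper structures show for the Lys16 rail, and the one that lets
# a flat ligand hydrogen-bond the rail while stacking on the apolar face.
.defaultChi <- function(resid) {
  n <- .N_CHI[[resid]]
  if (n == 0L) return(numeric(0))
  chi <- rep(180, n)
  if (resid %in% c("PHE", "TYR")) chi[2] <- 90
  if (resid == "LYS") chi <- c(180, -60, 180, 60)
  chi
}

# chi angle measurement atoms (4 names per chi)
.CHI_DEF <- list(
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ"))
)

# Per-atom chemical annotation: partial charge (simple fixed-group scheme,
# enough to anchor charged/acceptor chemistry) and interaction roles.
.atomAnnotation <- function(resid, elety) {
  elesy <- sub("^[0-9]*", "", elety)
  elesy <- substr(elesy, 1, 1)
  q <- 0
  donor <- FALSE
  acceptor <- FALSE
  aromatic <- FALSE
  if (elety == "N") { q <- -0.30; donor <- TRUE }
  else if (elety == "CA") q <- 0.10
  else if (elety == "C") q <- 0.45
  else if (elety %in% c("O", "OXT")) { q <- -0.45; acceptor <- TRUE }
  else if (resid == "LYS" && elety == "NZ") { q <- 0.70; donor <- TRUE }
  else if (resid == "LYS" && elety == "CE") q <- 0.20
  else if (resid %in% c("PHE", "TYR") &&
           elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")) aromatic <- TRUE
  else if (resid == "TYR" && elety == "OH") { q <- -0.50; donor <- TRUE; acceptor <- TRUE }
  else if (elety %in% c("OG", "OG1")) { q <- -0.50; donor <- TRUE; acceptor <- TRUE }
  else if (elety %in% c("OD1", "OD2", "OE1", "OE2")) {
    acceptor <- TRUE
    q <- if (resid %in% c("ASP", "GLU")) -0.60 else -0.45
  } else if (elety %in% c("ND2", "NE2")) { q <- -0.35; donor <- TRUE }
  else if (resid %in% c("ASP", "ASN") && elety == "CG") q <- 0.40
  else if (resid %in% c("GLU", "GLN") && elety == "CD") q <- 0.40
  # carbon never accepts hydrogen bonds; apolar = carbon outside rings
  apolar <- (elesy == "C") && !aromatic
  list(elesy = elesy, charge = q, donor = donor, acceptor = acceptor,
       aromatic = aromatic, apolar = apolar)
}

# Antecedent atom used when measuring hydrogen-bond geometry at a fiber
# donor/acceptor (the bonded heavy neighbour).
.FIBER_ANTECEDENT <- c(
  N = "CA", O = "C", OXT = "C", NZ = "CE", OH = "CZ", OG = "CB", OG1 = "CB",
  OD1 = "CG", OD2 = "CG", OE1 = "CD", OE2 = "CD", ND2 = "CG", NE2 = "CD"
)
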