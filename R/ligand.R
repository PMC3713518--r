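#' @include AllClasses.R AllGenerics.R
NULL

#' ProbeLigand: synthetic flat di-acceptor fiber probe
#'
#' A \linkS4class{Ligand} subclass carrying the constructed
#' acceptor-pair separation and the planarity deviation of its scaffold.
#'
#' @slot acceptorSeparation Angstrom distance between the two acceptor atoms.
#' @slot planarityDeviation Angstrom, max distance of a ring atom from the
#'   least-squares scaffold plane.
#' @exportClass ProbeLigand
setClass("ProbeLigand", contains = "Ligand",
  representation(acceptorSeparation = "numeric",
                 planarityDeviation = "numeric"),
  validity = function(object) {
    if (sum(object@atoms$acceptor) < 2) return("probe needs >= 2 acceptor atoms")
    TRUE
  }
)

# ---- MOL2 parsing -------------------------------------------------------

.parseMol2 <- function(mol2_text, id) {
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1]]
  sec <- function(tag) {
    i <- grep(paste0("^@<TRIPOS>", tag, "$"), lines)
    if (!length(i)) return(character(0))
    j <- grep("^@<TRIPOS>", lines)
    j <- j[j > i[1]]
    end <- if (length(j)) j[1] - 1 else length(lines)
    lines[(i[1] + 1):end]
  }
  at_lines <- sec("ATOM")
  bd_lines <- sec("BOND")
  at_lines <- at_lines[nzchar(trimws(at_lines))]
  bd_lines <- bd_lines[nzchar(trimws(bd_lines))]
  if (!length(at_lines)) stop("input error: MOL2 conversion produced no atoms",
                              call. = FALSE)
  af <- read.table(text = at_lines, stringsAsFactors = FALSE,
                   col.names = c("idx", "name", "x", "y", "z", "type",
                                 "subst", "substName", "charge"),
                   fill = TRUE)
  bf <- read.table(text = bd_lines, stringsAsFactors = FALSE,
                   col.names = c("idx", "a1", "a2", "type"), fill = TRUE)
  elesy <- toupper(sub("\\..*$", "", af$type))
  aromatic <- grepl("\\.ar$", af$type)
  order <- ifelse(bf$type == "ar", 1.5,
                  ifelse(bf$type == "am", 1, suppressWarnings(as.numeric(bf$type))))
  order[is.na(order)] <- 1
  # heavy-atom degree and H attachment
  nb <- function(i) c(bf$a2[bf$a1 == i], bf$a1[bf$a2 == i])
  has_h <- vapply(seq_len(nrow(af)), function(i) any(elesy[nb(i)] == "H"), TRUE)
  degree <- vapply(seq_len(nrow(af)), function(i) length(nb(i)), 0L)
  donor <- elesy %in% c("N", "O") & has_h
  acceptor <- (elesy == "O") | (elesy == "N" & !has_h & degree <= 2)
  apolar <- elesy %in% c("C", "H") & !aromatic
  atoms <- data.frame(
    name = af$name, elesy = elesy, x = af$x, y = af$y, z = af$z,
    charge = af$charge, donor = donor, acceptor = acceptor,
    aromatic = aromatic, apolar = apolar, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = bf$a1, a2 = bf$a2, order = order,
                      rotatable = FALSE)
  bonds$rotatable <- .flagRotatable(atoms, bonds)
  rings <- .aromaticRingSystems(atoms, bonds)
  new("Ligand", id = id, atoms = atoms, bonds = bonds, rings = rings)
}

# A bond is in a ring iff its endpoints stay connected after its removal.
.bondInRing <- function(bonds, k) {
  from <- bonds$a1[k]; to <- bonds$a2[k]
  adj <- bonds[-k, c("a1", "a2"), drop = FALSE]
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(c(adj$a2[adj$a1 %in% frontier], adj$a1[adj$a2 %in% frontier]))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# Rotatable bond: non-ring single bond between two non-terminal heavy atoms,
# excluding amide C-N.
.flagRotatable <- function(atoms, bonds) {
  heavy <- atoms$elesy != "H"
  hdeg <- vapply(seq_len(nrow(atoms)), function(i) {
    nbrs <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
    sum(heavy[nbrs])
  }, 0L)
  out <- logical(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    if (bonds$order[k] != 1) next
    if (!heavy[i] || !heavy[j]) next
    if (hdeg[i] < 2 || hdeg[j] < 2) next
    if (.isAmideCN(atoms, bonds, i, j)) next
    if (.bondInRing(bonds, k)) next
    out[k] <- TRUE
  }
  out
}

.isAmideCN <- function(atoms, bonds, i, j) {
  pair <- c(atoms$elesy[i], atoms$elesy[j])
  if (!setequal(pair, c("C", "N"))) return(FALSE)
  cat_idx <- if (atoms$elesy[i] == "C") i else j
  dbl_o <- (bonds$order == 2) &
    ((bonds$a1 == cat_idx & atoms$elesy[bonds$a2] == "O") |
     (bonds$a2 == cat_idx & atoms$elesy[bonds$a1] == "O"))
  any(dbl_o)
}

# Aromatic ring systems: connected components of aromatic atoms.
.aromaticRingSystems <- function(atoms, bonds) {
  arom <- which(atoms$aromatic)
  if (!length(arom)) return(list())
  comp <- setNames(rep(NA_integer_, nrow(atoms)), NULL)
  cur <- 0L
  for (seed in arom) {
    if (!is.na(comp[seed])) next
    cur <- cur + 1L
    frontier <- seed
    comp[seed] <- cur
    while (length(frontier)) {
      nxt <- unique(c(bonds$a2[bonds$a1 %in% frontier],
                      bonds$a1[bonds$a2 %in% frontier]))
      nxt <- nxt[nxt %in% arom & is.na(comp[nxt])]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  lapply(seq_len(cur), function(k) which(comp == k))
}

# ---- construction from SMILES ------------------------------------------

#' Build a 3D Ligand object from a SMILES string
#'
#' Generates 3D coordinates, adds hydrogens, assigns Gasteiger partial
#' charges, perceives aromaticity and flags rotatable bonds (non-ring single
#' bonds between non-terminal heavy atoms, amide C-N excluded).
#'
#' @param smiles a single SMILES string.
#' @param id ligand identifier.
#' @return a \linkS4class{Ligand}.
#' @export
smilesToLigand <- function(smiles, id = "ligand") {
  sdf <- tryCatch(ChemmineR::smiles2sdf(stats::setNames(smiles, id)),
                  error = function(e) stop("input error: unparsable SMILES \"",
                                           smiles, "\"", call. = FALSE))
  sdf <- ChemmineR::generate3DCoords(sdf)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  ChemmineR::write.SDF(sdf, tf)
  mol2 <- ChemmineOB::convertFormat(
    "SDF", "MOL2", source = paste(readLines(tf), collapse = "\n"),
    options = data.frame(names = "p", args = "gasteiger"))
  .parseMol2(mol2, id)
}

#' Construct a flat di-acceptor probe ligand
#'
#' Builds a planar fused-hexagon scaffold (an acene-like ring system in the
#' z = 0 plane) and attaches two negatively charged hydrogen-bond acceptor
#' oxygens on the long axis, exactly \code{acceptorSeparation} apart. The
#' probe mimics the binding chemistry of flat di-sulfonate dyes whose two
#' acceptor groups bridge rail lysines of adjacent strands.
#'
#' @param acceptorSeparation Angstrom distance between the two acceptors
#'   (e.g. 9.6 to bridge an in-register lysine rail two strands apart).
#' @param nRingAtoms scaffold ring atom count: 6, 10, 14, ... (6 + 4k);
#'   when NULL (default) the smallest scaffold whose ends reach the
#'   requested acceptors at a bonded distance is chosen.
#' @return a \linkS4class{ProbeLigand}.
#' @export
makeProbeLigand <- function(acceptorSeparation, nRingAtoms = NULL) {
  if (acceptorSeparation <= 0) {
    stop("input error: acceptorSeparation must be > 0", call. = FALSE)
  }
  if (is.null(nRingAtoms)) {
    b <- 1.40
    dx <- b * sqrt(3)
    for (k in 0:8) {
      # scaffold end vertex sits at ((k x dx)/2 + dx/2, +/-b/2); acceptors at
      # +/- separation/2 on the long axis
      xmax <- (k * dx + dx) / 2
      reach <- sqrt((acceptorSeparation / 2 - xmax)^2 + (b / 2)^2)
      if (acceptorSeparation / 2 >= xmax && reach >= 1.2 && reach <= 2.8) {
        nRingAtoms <- 6 + 4 * k
        break
      }
    }
    if (is.null(nRingAtoms)) {
      stop("geometry error: no fused-ring scaffold reaches a separation of ",
           acceptorSeparation, " A", call. = FALSE)
    }
  }
  if (nRingAtoms < 6 || (nRingAtoms - 6) %% 4 != 0) {
    stop("input error: nRingAtoms must be 6 + 4k", call. = FALSE)
  }
  n_rings <- (nRingAtoms - 6) / 4 + 1
  b <- 1.40                      # aromatic C-C
  dx <- b * sqrt(3)              # fused hexagon center spacing
  centers <- (seq_len(n_rings) - (n_rings + 1) / 2) * dx
  pts <- list()
  for (cx in centers) {
    for (ang in seq(30, 330, by = 60)) {
      p <- c(cx + b * cos(.deg2rad(ang)), b * sin(.deg2rad(ang)), 0)
      dup <- FALSE
      for (q in pts) if (.vnorm(p - q) < 1e-6) { dup <- TRUE; break }
      if (!dup) pts[[length(pts) + 1]] <- p
    }
  }
  ring_xyz <- do.call(rbind, pts)
  # two acceptors on the long axis, exactly the requested distance apart
  acc <- rbind(c(-acceptorSeparation / 2, 0, 0),
               c(acceptorSeparation / 2, 0, 0))
  attach_dist <- apply(acc, 1, function(p)
    min(sqrt(rowSums(sweep(ring_xyz, 2, p)^2))))
  if (any(attach_dist < 1.2) || any(attach_dist > 2.8)) {
    stop("geometry error: requested separation incompatible with scaffold size ",
         "(attachment reach ", sprintf("%.2f/%.2f", attach_dist[1], attach_dist[2]),
         " A outside [1.2, 2.8])", call. = FALSE)
  }
  n_ring <- nrow(ring_xyz)
  atoms <- data.frame(
    name = c(paste0("C", seq_len(n_ring)), "O1", "O2"),
    elesy = c(rep("C", n_ring), "O", "O"),
    x = c(ring_xyz[, 1], acc[, 1]),
    y = c(ring_xyz[, 2], acc[, 2]),
    z = c(ring_xyz[, 3], acc[, 3]),
    charge = c(rep(0, n_ring), -0.5, -0.5),
    donor = FALSE,
    acceptor = c(rep(FALSE, n_ring), TRUE, TRUE),
    aromatic = c(rep(TRUE, n_ring), FALSE, FALSE),
    apolar = c(rep(FALSE, n_ring), FALSE, FALSE),
    stringsAsFactors = FALSE)
  # ring bonds: any pair at ~1.4 A; acceptor bonds to the nearest ring atom
  bonds <- list()
  for (i in seq_len(n_ring - 1)) {
    for (j in (i + 1):n_ring) {
      if (abs(.vnorm(ring_xyz[i, ] - ring_xyz[j, ]) - b) < 1e-6) {
        bonds[[length(bonds) + 1]] <- data.frame(a1 = i, a2 = j, order = 1.5,
                                                 rotatable = FALSE)
      }
    }
  }
  for (k in 1:2) {
    near <- which.min(sqrt(rowSums(sweep(ring_xyz, 2, acc[k, ])^2)))
    bonds[[length(bonds) + 1]] <- data.frame(a1 = near, a2 = n_ring + k,
                                             order = 1, rotatable = FALSE)
  }
  bonds <- do.call(rbind, bonds)
  rings <- lapply(seq_len(n_rings), function(r) {
    ctr <- c(centers[r], 0, 0)
    which(sqrt(rowSums(sweep(ring_xyz, 2, ctr)^2)) < b + 1e-6)
  })
  pl <- .lsPlane(ring_xyz)
  dev <- max(abs(sweep(ring_xyz, 2, pl$origin) %*% pl$normal))
  new("ProbeLigand", id = sprintf("probe_%.1fA", acceptorSeparation),
      atoms = atoms, bonds = bonds, rings = rings,
      acceptorSeparation = acceptorSeparation, planarityDeviation = dev)
}

# ---- pose application ---------------------------------------------------

#' Rigid-body transforms of ligands and poses
#'
#' \code{transformLigand} applies rotation R then translation t to a ligand;
#' \code{applyPose} places a conformer of an ensemble (or a bare ligand)
#' according to a \linkS4class{Pose}.
#'
#' @param ligand a \linkS4class{Ligand}.
#' @param R 3 x 3 proper rotation matrix.
#' @param t translation 3-vector.
#' @return a transformed \linkS4class{Ligand}.
#' @export
transformLigand <- function(ligand, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(ligand@atoms[, c("x", "y", "z")])
  ligand@atoms[, c("x", "y", "z")] <- .xform(xyz, R, t)
  ligand
}

#' @rdname transformLigand
#' @param x a \linkS4class{ConformerEnsemble} or \linkS4class{Ligand}.
#' @param pose a \linkS4class{Pose}.
#' @export
applyPose <- function(x, pose) {
  if (is(x, "ConformerEnsemble")) {
    lig <- x@ligand
    xyz <- x@conformers[[pose@conformerIndex]]
  } else {
    lig <- x
    xyz <- as.matrix(lig@atoms[, c("x", "y", "z")])
  }
  lig@atoms[, c("x", "y", "z")] <- .xform(xyz, pose@rotation, pose@translation)
  lig
}
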