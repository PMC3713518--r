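#' @include AllClasses.R AllGenerics.R fiber.R ligand.R
NULL

#' Construct a GeometryWindows object
#'
#' Acceptance windows of the geometric pharmacophore; all boundaries are
#' inclusive. See \linkS4class{GeometryWindows} for the defaults and units.
#'
#' @param d1,theta1,theta2,d2,phi length-2 numeric intervals.
#' @param minLysContacts minimum lysine hydrogen-bond contacts on distinct
#'   strands.
#' @param strandSpan length-2 integer interval of strands spanned.
#' @return a \linkS4class{GeometryWindows}.
#' @export
geometryWindows <- function(d1 = c(2.8, 3.5), theta1 = c(100, 150),
                            theta2 = c(130, 180), d2 = c(4.0, 5.0),
                            phi = c(0, 40), minLysContacts = 2L,
                            strandSpan = c(2L, 4L)) {
  new("GeometryWindows", d1 = d1, theta1 = theta1, theta2 = theta2,
      d2 = d2, phi = phi, minLysContacts = as.integer(minLysContacts),
      strandSpan = as.integer(strandSpan))
}

# inclusive window membership with a small numeric slack so values sitting
# exactly on a boundary are never lost to floating-point rounding
.inWindow <- function(x, iv, eps = 1e-9) {
  x >= iv[1] - eps & x <= iv[2] + eps
}

#' Hydrogen-bond contacts between a placed ligand and the lysine rail
#'
#' Lists every (ligand acceptor, rail NZ) pair whose geometry falls inside
#' the acceptance windows (inclusive): d1 = NZ-acceptor distance, theta1 at
#' the acceptor (antecedent-acceptor-NZ), theta2 at NZ (CE-NZ-acceptor).
#' Salt bridges count as hydrogen-bond contacts (a negatively charged
#' acceptor is still an acceptor).
#'
#' @param ligand a placed \linkS4class{Ligand}.
#' @param fiber a \linkS4class{FiberModel}.
#' @param windows a \linkS4class{GeometryWindows}.
#' @return data.frame: strand, resno, acceptor, d1, theta1, theta2 (zero
#'   rows if no contact).
#' @export
hbondContacts <- function(ligand, fiber, windows = geometryWindows()) {
  fa <- fiber@atoms
  la <- ligand@atoms
  nz <- fa[fa$resid == "LYS" & fa$elety == "NZ", ]
  acc_idx <- which(la$acceptor)
  out <- list()
  sites <- .ligandPolarSites(la, ligand@bonds)
  for (i in acc_idx) {
    ante_i <- sites$ante[match(i, sites$i)]
    if (is.na(ante_i)) next
    p_acc <- c(la$x[i], la$y[i], la$z[i])
    p_ante <- c(la$x[ante_i], la$y[ante_i], la$z[ante_i])
    for (k in seq_len(nrow(nz))) {
      p_nz <- c(nz$x[k], nz$y[k], nz$z[k])
      d1 <- .vnorm(p_acc - p_nz)
      if (!.inWindow(d1, windows@d1)) next
      ce <- fa[fa$strand == nz$strand[k] & fa$resno == nz$resno[k] &
               fa$elety == "CE", ]
      p_ce <- c(ce$x[1], ce$y[1], ce$z[1])
      th1 <- .angle3(p_ante, p_acc, p_nz)
      th2 <- .angle3(p_ce, p_nz, p_acc)
      if (!.inWindow(th1, windows@theta1)) next
      if (!.inWindow(th2, windows@theta2)) next
      out[[length(out) + 1]] <- data.frame(
        strand = nz$strand[k], resno = nz$resno[k], acceptor = la$name[i],
        d1 = d1, theta1 = th1, theta2 = th2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(strand = integer(0), resno = integer(0),
                      acceptor = character(0), d1 = numeric(0),
                      theta1 = numeric(0), theta2 = numeric(0)))
  }
  do.call(rbind, out)
}

# Apolar side-chain interaction centers: ring centroid (and normal) for
# Phe/Tyr, CB-to-CG midpoint for Val.
.apolarCenters <- function(fiber) {
  fa <- fiber@atoms
  res <- unique(fa[fa$resid %in% c("PHE", "TYR", "VAL"),
                   c("strand", "resno", "resid")])
  out <- list()
  for (i in seq_len(nrow(res))) {
    r <- fa[fa$strand == res$strand[i] & fa$resno == res$resno[i], ]
    if (res$resid[i] %in% c("PHE", "TYR")) {
      ring <- r[r$elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), ]
      ctr <- colMeans(as.matrix(ring[, c("x", "y", "z")]))
    } else {
      cb <- unlist(r[r$elety == "CB", c("x", "y", "z")])
      cg <- colMeans(as.matrix(r[r$elety %in% c("CG1", "CG2"),
                                 c("x", "y", "z")]))
      ctr <- (cb + cg) / 2
    }
    out[[length(out) + 1]] <- data.frame(
      strand = res$strand[i], resno = res$resno[i], resid = res$resid[i],
      x = ctr[1], y = ctr[2], z = ctr[3], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Aromatic stacking contacts between a placed ligand and the apolar face
#'
#' A contact is recorded when a ligand aromatic ring centroid sits within
#' the d2 window of an apolar side-chain center (Phe/Tyr ring centroid,
#' Val CB-CG midpoint) and the dihedral between the ring plane and the
#' fiber surface plane lies in the phi window (boundaries inclusive).
#'
#' @param ligand a placed \linkS4class{Ligand} with >= 1 aromatic ring.
#' @param fiber a \linkS4class{FiberModel}.
#' @param windows a \linkS4class{GeometryWindows}.
#' @param frame a \linkS4class{SurfaceFrame} for the apolar face.
#' @return data.frame: strand, resno, resid, ring, d2, phi.
#' @export
stackingContacts <- function(ligand, fiber, windows = geometryWindows(),
                             frame) {
  if (!length(ligand@rings)) {
    stop("input error: ligand has no aromatic ring", call. = FALSE)
  }
  centers <- .apolarCenters(fiber)
  la <- ligand@atoms
  out <- list()
  for (rg in seq_along(ligand@rings)) {
    idx <- ligand@rings[[rg]]
    ring_xyz <- as.matrix(la[idx, c("x", "y", "z")])
    ctr <- colMeans(ring_xyz)
    pl <- .lsPlane(ring_xyz)
    phi <- .angle3(pl$normal + c(0, 0, 0), c(0, 0, 0), frame@normal)
    phi <- min(phi, 180 - phi)
    if (!.inWindow(phi, windows@phi)) next
    if (is.null(centers) || !nrow(centers)) next
    for (k in seq_len(nrow(centers))) {
      d2 <- .vnorm(ctr - c(centers$x[k], centers$y[k], centers$z[k]))
      if (!.inWindow(d2, windows@d2)) next
      out[[length(out) + 1]] <- data.frame(
        strand = centers$strand[k], resno = centers$resno[k],
        resid = centers$resid[k], ring = rg, d2 = d2, phi = phi,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(strand = integer(0), resno = integer(0),
                      resid = character(0), ring = integer(0),
                      d2 = numeric(0), phi = numeric(0)))
  }
  do.call(rbind, out)
}

# Default apolar-face frame: all Phe/Tyr/Val residues presenting side
# chains on the given face.
.apolarFaceFrame <- function(fiber, face = "+x") {
  fa <- fiber@atoms
  sgn <- if (face == "+x") 1 else -1
  res <- unique(fa[fa$resid %in% c("PHE", "TYR", "VAL"),
                   c("strand", "resno")])
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    r <- fa[fa$strand == res$strand[i] & fa$resno == res$resno[i], ]
    ca <- unlist(r[r$elety == "CA", c("x", "y", "z")])
    cb <- unlist(r[r$elety == "CB", c("x", "y", "z")])
    keep[i] <- (cb[1] - ca[1]) * sgn > 0
  }
  sel <- res[keep, , drop = FALSE]
  if (!nrow(sel)) stop("geometry error: no apolar residue on face ", face,
                       call. = FALSE)
  surfaceFrame(fiber, sel)
}

#' Evaluate a placed ligand against the geometric pharmacophore
#'
#' Pass requires (i) hydrogen-bond contacts to rail lysine NZ atoms on at
#' least \code{minLysContacts} distinct strands, (ii) all contacts spanning
#' a number of adjacent strands inside the strandSpan window, and (iii) at
#' least one aromatic stacking contact. Failure reasons enumerate every
#' violated condition.
#'
#' @param ligand a placed \linkS4class{Ligand}.
#' @param fiber a \linkS4class{FiberModel}.
#' @param windows a \linkS4class{GeometryWindows}.
#' @param frame optional \linkS4class{SurfaceFrame}; defaults to the apolar
#'   face frame on the ligand's side of the sheet.
#' @return a \linkS4class{PharmacophoreReport}.
#' @export
checkPharmacophore <- function(ligand, fiber, windows = geometryWindows(),
                               frame = NULL) {
  if (is.null(frame)) {
    lig_ctr <- colMeans(as.matrix(ligand@atoms[, c("x", "y", "z")]))
    fib_ctr <- colMeans(as.matrix(fiber@atoms[, c("x", "y", "z")]))
    face <- if (lig_ctr[1] >= fib_ctr[1]) "+x" else "-x"
    frame <- .apolarFaceFrame(fiber, face)
  }
  hb <- hbondContacts(ligand, fiber, windows)
  st <- if (length(ligand@rings)) {
    stackingContacts(ligand, fiber, windows, frame)
  } else {
    data.frame(strand = integer(0), resno = integer(0), resid = character(0),
               ring = integer(0), d2 = numeric(0), phi = numeric(0))
  }
  strands <- c(hb$strand, st$strand)
  span <- if (length(strands)) {
    as.integer(max(strands) - min(strands) + 1L)
  } else 0L
  reasons <- character(0)
  if (length(unique(hb$strand)) < windows@minLysContacts) {
    reasons <- c(reasons, "min_lys_contacts")
  }
  if (span < windows@strandSpan[1] || span > windows@strandSpan[2]) {
    reasons <- c(reasons, "strand_span")
  }
  if (!nrow(st)) reasons <- c(reasons, "stacking")
  new("PharmacophoreReport", hbondContacts = hb, stackContacts = st,
      strandsSpanned = span, passes = !length(reasons),
      failureReasons = reasons)
}

#' Register compatibility of a di-acceptor probe with a fiber's lysine rail
#'
#' A probe whose two acceptors sit a fixed distance apart can bridge two
#' rail NZ atoms only if some same-face NZ pair separation matches that
#' distance within tolerance. In-register fibers present ~9.6 Angstrom
#' pairs (two strands at 4.8 Angstrom rise); sheared out-of-register
#' stand-ins stretch the rail to 11-14 Angstrom and lose compatibility.
#'
#' @param fiber a \linkS4class{FiberModel}.
#' @param probeSeparation Angstrom acceptor-pair separation of the probe.
#' @param tolerance Angstrom matching tolerance (default 0.5).
#' @param face fiber face to query.
#' @return "compatible" or "incompatible".
#' @export
registerCompatibility <- function(fiber, probeSeparation, tolerance = 0.5,
                                  face = "+x") {
  rail <- lysineRail(fiber, face = face)
  if (nrow(rail) < 2) {
    stop("input error: need >= 2 rail entries to assess compatibility",
         call. = FALSE)
  }
  nz <- as.matrix(rail[, c("nz.x", "nz.y", "nz.z")])
  n <- nrow(nz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(.vnorm(nz[i, ] - nz[j, ]) - probeSeparation) <= tolerance) {
        return("compatible")
      }
    }
  }
  "incompatible"
}

#' Consensus pharmacophore from a pose overlay
#'
#' Overlays placed ligand poses (all in the same fiber frame) and reports,
#' per feature class, the consensus centroid and RMS spread: acceptor
#' feature = mean position of acceptor atoms per pose; ring feature = mean
#' aromatic ring centroid per pose.
#'
#' @param poses list of placed \linkS4class{Ligand} objects.
#' @param frames optional character vector naming each pose's fiber frame;
#'   mixing frames is an error.
#' @return list with elements \code{acceptor} and \code{ring}, each a list
#'   (centroid, spread, n).
#' @export
consensusPharmacophore <- function(poses, frames = NULL) {
  if (!length(poses)) stop("input error: no poses", call. = FALSE)
  if (!is.null(frames) && length(unique(frames)) > 1) {
    stop("input error: poses come from mixed fiber frames", call. = FALSE)
  }
  feat <- function(lig, what) {
    a <- lig@atoms
    if (what == "acceptor") {
      idx <- which(a$acceptor)
      if (!length(idx)) return(NULL)
      colMeans(as.matrix(a[idx, c("x", "y", "z")]))
    } else {
      if (!length(lig@rings)) return(NULL)
      ctrs <- t(vapply(lig@rings, function(idx)
        colMeans(as.matrix(a[idx, c("x", "y", "z")])), numeric(3)))
      colMeans(ctrs)
    }
  }
  out <- list()
  for (what in c("acceptor", "ring")) {
    pts <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(poses, feat, what = what)))
    if (is.null(pts)) {
      out[[what]] <- list(centroid = NULL, spread = NA_real_, n = 0L)
    } else {
      ctr <- colMeans(pts)
      spread <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
      out[[what]] <- list(centroid = ctr, spread = spread, n = nrow(pts))
    }
  }
  out
}
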