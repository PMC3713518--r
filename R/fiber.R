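#' @include AllClasses.R AllGenerics.R
NULL

# ---- internal construction ---------------------------------------------

# Place CB from backbone N, CA, C (improper dihedral keeps L chirality).
.placeCB <- function(n, ca, c) {
  .placeAtom(c, n, ca, bond = 1.530, ang = 110.4, dih = 122.6)
}

# Build side-chain heavy atoms for one residue from its backbone coordinates.
# Returns a named list of 3-vectors (includes CB unless Gly).
.buildSidechain <- function(resid, n, ca, c, chi = NULL) {
  if (resid == "GLY") return(list())
  if (is.null(chi)) chi <- .defaultChi(resid)
  pos <- list(N = n, CA = ca, C = c, CB = .placeCB(n, ca, c))
  for (a in .SIDECHAINS[[resid]]) {
    dih <- if (!is.na(a$chi)) chi[a$chi] + a$offset else a$dih
    pos[[a$name]] <- .placeAtom(pos[[a$refs[1]]], pos[[a$refs[2]]],
                                pos[[a$refs[3]]], a$bond, a$ang, dih)
  }
  pos[setdiff(names(pos), c("N", "CA", "C"))]
}

# One extended strand in canonical orientation: strand direction +y,
# odd-numbered residues presenting side chains toward +x, all-atom centroid
# at the origin.
.buildStrand <- function(seq3, phipsi) {
  L <- length(seq3)
  phi <- phipsi[["phi"]]
  psi <- phipsi[["psi"]]
  bb <- .BB
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(bb$b_n_ca, 0, 0)
  C[[1]] <- .placeAtom(c(0, 1, 0), N[[1]], CA[[1]], bb$b_ca_c, bb$a_n_ca_c, 55)
  for (i in 2:L) {
    N[[i]] <- .placeAtom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         bb$b_c_n, bb$a_ca_c_n, psi)
    CA[[i]] <- .placeAtom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          bb$b_n_ca, bb$a_c_n_ca, bb$omega)
    C[[i]] <- .placeAtom(C[[i - 1]], N[[i]], CA[[i]],
                         bb$b_ca_c, bb$a_n_ca_c, phi)
  }
  rows <- list()
  for (i in seq_len(L)) {
    resid <- seq3[i]
    O <- .placeAtom(N[[i]], CA[[i]], C[[i]], bb$b_c_o, bb$a_ca_c_o, psi + 180)
    res_atoms <- c(list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O),
                   .buildSidechain(resid, N[[i]], CA[[i]], C[[i]]))
    for (nm in names(res_atoms)) {
      ann <- .atomAnnotation(resid, nm)
      rows[[length(rows) + 1]] <- data.frame(
        elety = nm, elesy = ann$elesy, resid = resid, resno = i, strand = 0L,
        x = res_atoms[[nm]][1], y = res_atoms[[nm]][2], z = res_atoms[[nm]][3],
        charge = ann$charge, donor = ann$donor, acceptor = ann$acceptor,
        aromatic = ann$aromatic, apolar = ann$apolar,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])

  # orient: CA(first) -> CA(last) along +y
  ca_idx <- which(atoms$elety == "CA")
  u <- .unit(xyz[ca_idx[length(ca_idx)], ] - xyz[ca_idx[1], ])
  ax <- .cross(u, c(0, 1, 0))
  if (.vnorm(ax) > 1e-9) {
    ang <- .angle3(u + c(0, 0, 0), c(0, 0, 0), c(0, 1, 0))
    xyz <- xyz %*% t(.rotAxis(ax, ang))
  } else if (u[2] < 0) {
    xyz <- xyz %*% t(.rotAxis(c(1, 0, 0), 180))
  }
  # rotate about y so residue 1's CB points toward +x
  cb_res <- which(seq3 != "GLY")[1]
  if (!is.na(cb_res)) {
    i_cb <- which(atoms$elety == "CB" & atoms$resno == cb_res)
    i_ca <- which(atoms$elety == "CA" & atoms$resno == cb_res)
    v <- xyz[i_cb, ] - xyz[i_ca, ]
    v[2] <- 0
    if (.vnorm(v) > 1e-9) {
      ang <- .rad2deg(atan2(v[3], v[1]))
      xyz <- xyz %*% t(.rotAxis(c(0, 1, 0), ang))
    }
  }
  xyz <- sweep(xyz, 2, colMeans(xyz))
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# ---- exported operations -----------------------------------------------

#' Build an idealized beta-sheet fiber model
#'
#' Constructs an extended-strand fiber by stacking copies of one idealized
#' strand along the fiber axis (+z) at the given rise. In-register parallel
#' fibers are pure translations, so identical atoms on strands i and i+k are
#' exactly k * rise apart; with the canonical 4.8 Angstrom rise the
#' same-face lysine C-beta atoms two strands apart sit 9.6 Angstrom apart,
#' the spacing that flat di-acceptor fiber binders bridge. Antiparallel
#' fibers rotate every other strand 180 degrees about the fiber axis, so a
#' given residue is presented on one face only on alternating strands.
#' The out-of-register stand-in additionally shears each strand along the
#' strand direction by \code{shear * strand_index}, stretching the same-face
#' lysine spacing to sqrt((2 rise)^2 + (2 shear)^2) -- the 11-14 Angstrom
#' rail geometry of sheared sheets.
#'
#' @param sequence one-letter residue string (e.g. "KLVFFA"); supported
#'   letters are \code{A G V L I F Y S T N Q D E K}.
#' @param nStrands number of strands (>= 1).
#' @param registration "in_register_parallel", "antiparallel" or
#'   "out_of_register".
#' @param rise Angstrom translation per strand along the axis (default 4.8).
#' @param shear Angstrom lateral offset per strand (required non-zero for
#'   out-of-register).
#' @return a \linkS4class{FiberModel}.
#' @examples
#' fib <- buildFiber("KLVFFA", 6)
#' rail <- lysineRail(fib)
#' @export
buildFiber <- function(sequence, nStrands,
                       registration = c("in_register_parallel",
                                        "antiparallel", "out_of_register"),
                       rise = 4.8, shear = 0) {
  registration <- match.arg(registration)
  if (nStrands < 1) stop("input error: nStrands must be >= 1", call. = FALSE)
  if (nchar(sequence) < 2) stop("input error: sequence length must be >= 2", call. = FALSE)
  if (rise <= 0) stop("input error: rise must be > 0", call. = FALSE)
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(.AA1TO3))
  if (length(bad)) {
    stop("input error: unknown residue letter(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  if (registration == "out_of_register" && abs(shear) <= 0) {
    stop("input error: out_of_register requires non-zero shear", call. = FALSE)
  }
  seq3 <- unname(.AA1TO3[letters1])
  strand0 <- .buildStrand(seq3, .PHI_PSI[[registration]])
  xyz0 <- as.matrix(strand0[, c("x", "y", "z")])
  flipZ <- .rotAxis(c(0, 0, 1), 180)
  all_strands <- vector("list", nStrands)
  for (s in seq_len(nStrands) - 1L) {
    a <- strand0
    xyz <- xyz0
    if (registration == "antiparallel" && s %% 2L == 1L) {
      xyz <- xyz %*% t(flipZ)
    }
    off <- c(0, 0, rise * s)
    if (registration == "out_of_register") off[2] <- off[2] + shear * s
    xyz <- sweep(xyz, 2, off, "+")
    a[, c("x", "y", "z")] <- xyz
    a$strand <- s
    all_strands[[s + 1L]] <- a
  }
  atoms <- do.call(rbind, all_strands)
  rownames(atoms) <- NULL
  new("FiberModel", atoms = atoms, sequence = sequence,
      registration = registration, rise = rise,
      shear = if (registration == "out_of_register") shear else 0,
      axis = c(0, 0, 1))
}

#' Locate the lysine rail on one fiber face
#'
#' Lists, strand by strand, the lysine side chains presented on the queried
#' face (classified by the direction of the C-alpha to C-beta vector). These
#' NZ atoms are the polar anchor points that ligand acceptor groups must
#' bridge.
#'
#' @param model a \linkS4class{FiberModel}.
#' @param face "+x" (default) or "-x", the sheet face normal to query.
#' @return data.frame with columns strand, resno and NZ/CB coordinates
#'   (nz.x, nz.y, nz.z, cb.x, cb.y, cb.z), ordered by strand; zero rows if
#'   the face presents no lysine.
#' @export
lysineRail <- function(model, face = c("+x", "-x")) {
  face <- match.arg(face)
  sgn <- if (face == "+x") 1 else -1
  a <- model@atoms
  lys <- unique(a[a$resid == "LYS", c("strand", "resno")])
  out <- list()
  if (nrow(lys)) {
    for (i in seq_len(nrow(lys))) {
      s <- lys$strand[i]; r <- lys$resno[i]
      res <- a[a$strand == s & a$resno == r, ]
      ca <- unlist(res[res$elety == "CA", c("x", "y", "z")])
      cb <- unlist(res[res$elety == "CB", c("x", "y", "z")])
      nz <- unlist(res[res$elety == "NZ", c("x", "y", "z")])
      if ((cb[1] - ca[1]) * sgn > 0) {
        out[[length(out) + 1]] <- data.frame(
          strand = s, resno = r,
          nz.x = nz[1], nz.y = nz[2], nz.z = nz[3],
          cb.x = cb[1], cb.y = cb[2], cb.z = cb[3])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = integer(0), resno = integer(0),
                      nz.x = numeric(0), nz.y = numeric(0), nz.z = numeric(0),
                      cb.x = numeric(0), cb.y = numeric(0), cb.z = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$resno), ]
  rownames(res) <- NULL
  res
}

#' Fit a local frame to a fiber surface patch
#'
#' Least-squares surface plane through the side-chain atoms of the selected
#' residues. Because the fiber face repeats along the fiber axis, the plane
#' is constrained to be parallel to the axis: atoms are projected onto the
#' plane perpendicular to the axis, the principal direction of the
#' projected scatter is taken as the second in-plane axis, and the normal
#' is their cross product, oriented away from the sheet interior (the
#' all-atom fiber centroid). This frame defines the reference plane against
#' which the ring-plane dihedral of stacking contacts is measured.
#'
#' @param model a \linkS4class{FiberModel}.
#' @param selection data.frame with columns strand and resno.
#' @return a \linkS4class{SurfaceFrame}.
#' @export
surfaceFrame <- function(model, selection) {
  if (!nrow(selection)) stop("input error: empty selection", call. = FALSE)
  a <- model@atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(selection))) {
    keep <- keep | (a$strand == selection$strand[i] &
                    a$resno == selection$resno[i])
  }
  sel <- a[keep & !(a$elety %in% c("N", "CA", "C", "O")), ]
  if (nrow(sel) < 3) stop("geometry error: fewer than 3 side-chain atoms selected",
                          call. = FALSE)
  xyz <- as.matrix(sel[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  ax <- .unit(model@axis)
  # scatter in the plane perpendicular to the fiber axis
  x0 <- sweep(xyz, 2, ctr)
  perp <- x0 - outer(as.vector(x0 %*% ax), ax)
  s <- svd(perp, nu = 0)
  if (s$d[1] < 1e-9) {
    stop("geometry error: degenerate (collinear) selection", call. = FALSE)
  }
  inplane2 <- .unit(as.vector(s$v[, 1]) -
                    sum(s$v[, 1] * ax) * ax)
  nrm <- .unit(.cross(ax, inplane2))
  interior <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  if (sum(nrm * (ctr - interior)) < 0) nrm <- -nrm
  new("SurfaceFrame", origin = ctr, normal = nrm,
      inPlane = cbind(ax, inplane2, deparse.level = 0))
}

#' Apply a rigid-body transform to a whole fiber model
#'
#' @param model a \linkS4class{FiberModel}.
#' @param R 3 x 3 proper rotation matrix.
#' @param t translation 3-vector.
#' @return the transformed \linkS4class{FiberModel} (axis rotated with it).
#' @export
transformFiber <- function(model, R = diag(3), t = c(0, 0, 0)) {
  m <- model
  xyz <- as.matrix(m@atoms[, c("x", "y", "z")])
  m@atoms[, c("x", "y", "z")] <- .xform(xyz, R, t)
  m@axis <- as.vector(R %*% m@axis)
  m
}

# Rebuild side chains of selected residues at perturbed chi angles.
# assignment: named list "strand.resno" -> chi vector.
.applySidechains <- function(model, assignment) {
  if (!length(assignment)) return(model)
  a <- model@atoms
  for (key in names(assignment)) {
    sr <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
    idx <- a$strand == sr[1] & a$resno == sr[2]
    res <- a[idx, ]
    resid <- res$resid[1]
    bb <- lapply(c("N", "CA", "C"), function(e)
      unlist(res[res$elety == e, c("x", "y", "z")]))
    sc <- .buildSidechain(resid, bb[[1]], bb[[2]], bb[[3]],
                          chi = assignment[[key]])
    for (nm in names(sc)) {
      a[idx & a$elety == nm, c("x", "y", "z")] <- as.list(sc[[nm]])
    }
  }
  model@atoms <- a
  model
}

# ---- PDB I/O ------------------------------------------------------------

#' Write a fiber model to a PDB file
#'
#' One chain per strand (chains A, B, C, ...), residues numbered 1-based
#' within each strand. Model metadata (registration, rise, shear) is stored
#' in a REMARK 300 line so that \code{readFiber} round-trips exactly.
#'
#' @param model a \linkS4class{FiberModel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFiber <- function(model, path) {
  a <- model@atoms
  chains <- LETTERS[(a$strand %% 26) + 1]
  lines <- character(0)
  lines <- c(lines, sprintf(
    "REMARK 300 FIBSCREEN registration=%s rise=%.6f shear=%.6f",
    model@registration, model@rise, model@shear))
  serial <- 0L
  prev_chain <- NULL
  for (i in seq_len(nrow(a))) {
    if (!is.null(prev_chain) && chains[i] != prev_chain) {
      serial <- serial + 1L
      lines <- c(lines, sprintf("TER   %5d      %3s %s", serial,
                                a$resid[i - 1], prev_chain))
    }
    serial <- serial + 1L
    nm <- a$elety[i]
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm_fmt, a$resid[i], chains[i], a$resno[i],
      a$x[i], a$y[i], a$z[i], 1, 0, a$elesy[i]))
    prev_chain <- chains[i]
  }
  serial <- serial + 1L
  lines <- c(lines, sprintf("TER   %5d      %3s %s", serial,
                            a$resid[nrow(a)], prev_chain), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a fiber model from a PDB file
#'
#' Strand index is inferred from the chain identifier (first chain seen is
#' strand 0, second strand 1, ...). Registration, rise and shear are read
#' from the REMARK 300 metadata line when present; otherwise rise is
#' estimated from consecutive strand centroid separations along the fiber
#' axis and registration defaults to in-register parallel. Atom roles and
#' charges are re-derived from residue and atom names.
#'
#' @param path PDB file path.
#' @return a \linkS4class{FiberModel}.
#' @export
readFiber <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  atom_lines <- grep("^(ATOM|HETATM)", raw)
  if (!length(atom_lines)) {
    stop("input error: no ATOM/HETATM records in ", path, call. = FALSE)
  }
  for (ln in atom_lines) {
    xyz_txt <- substr(raw[ln], 31, 54)
    vals <- suppressWarnings(as.numeric(c(substr(raw[ln], 31, 38),
                                          substr(raw[ln], 39, 46),
                                          substr(raw[ln], 47, 54))))
    if (any(is.na(vals))) {
      stop("parse error at line ", ln, ": malformed coordinates \"",
           xyz_txt, "\"", call. = FALSE)
    }
  }
  meta <- grep("^REMARK 300 FIBSCREEN", raw, value = TRUE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chains <- at$chain
  chains[is.na(chains)] <- "A"
  strand_of <- setNames(seq_along(unique(chains)) - 1L, unique(chains))
  rows <- data.frame(
    elety = at$elety, resid = at$resid, resno = at$resno,
    strand = unname(strand_of[chains]),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  ann <- mapply(.atomAnnotation, rows$resid, rows$elety, SIMPLIFY = FALSE)
  rows$elesy <- vapply(ann, `[[`, "", "elesy")
  rows$charge <- vapply(ann, `[[`, 0, "charge")
  rows$donor <- vapply(ann, `[[`, TRUE, "donor")
  rows$acceptor <- vapply(ann, `[[`, TRUE, "acceptor")
  rows$aromatic <- vapply(ann, `[[`, TRUE, "aromatic")
  rows$apolar <- vapply(ann, `[[`, TRUE, "apolar")
  rows <- rows[, .ATOM_COLS]

  # per-strand sequence (first strand)
  s0 <- rows[rows$strand == 0L, ]
  seq3 <- s0$resid[!duplicated(s0$resno)]
  seq1 <- paste(ifelse(seq3 %in% names(.AA3TO1), .AA3TO1[seq3], "X"),
                collapse = "")

  registration <- "in_register_parallel"
  rise <- NA_real_
  shear <- 0
  if (length(meta)) {
    kv <- regmatches(meta[1], gregexpr("[a-z_]+=[^ ]+", meta[1]))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      if (parts[1] == "registration") registration <- parts[2]
      if (parts[1] == "rise") rise <- as.numeric(parts[2])
      if (parts[1] == "shear") shear <- as.numeric(parts[2])
    }
  }
  if (is.na(rise)) {
    ctrs <- vapply(sort(unique(rows$strand)), function(s)
      mean(rows$z[rows$strand == s]), 0)
    rise <- if (length(ctrs) > 1) mean(diff(ctrs)) else 4.8
    if (!is.finite(rise) || rise <= 0) rise <- 4.8
  }
  new("FiberModel", atoms = rows, sequence = seq1, registration = registration,
      rise = rise, shear = shear, axis = c(0, 0, 1))
}
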