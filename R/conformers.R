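#' @include AllClasses.R AllGenerics.R ligand.R
NULL

#' Construct an EnsembleConfig
#'
#' @param ligandTorsionDelta degrees of torsion perturbation per rotatable
#'   bond (default 5).
#' @param dedupRmsd Angstrom heavy-atom RMSD below which conformers are
#'   considered redundant (default 0.5).
#' @param maxConformers maximum retained conformers (default 100).
#' @param sidechainSdMultipliers multipliers of the per-chi standard
#'   deviation (default 0.33, 0.67, 1.0, applied as +/-).
#' @param enumCap cap on enumerated torsion combinations before clustering
#'   (default 10000); larger enumerations are down-sampled
#'   deterministically by seed.
#' @param seed integer random seed.
#' @return an \linkS4class{EnsembleConfig}.
#' @export
ensembleConfig <- function(ligandTorsionDelta = 5, dedupRmsd = 0.5,
                           maxConformers = 100L,
                           sidechainSdMultipliers = c(0.33, 0.67, 1.0),
                           enumCap = 10000L, seed = 1L) {
  new("EnsembleConfig", ligandTorsionDelta = ligandTorsionDelta,
      dedupRmsd = dedupRmsd, maxConformers = as.integer(maxConformers),
      sidechainSdMultipliers = sidechainSdMultipliers,
      enumCap = as.integer(enumCap), seed = as.integer(seed))
}

# Atoms moved when bond k rotates: the component containing a2 after bond
# removal.
.movedSet <- function(bonds, k) {
  to <- bonds$a2[k]
  adj <- bonds[-k, c("a1", "a2"), drop = FALSE]
  seen <- to
  frontier <- to
  while (length(frontier)) {
    nxt <- unique(c(adj$a2[adj$a1 %in% frontier], adj$a1[adj$a2 %in% frontier]))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# Rotate the moved side of bond k by delta degrees about the bond axis.
.applyTorsion <- function(xyz, bonds, k, delta, moved = NULL) {
  if (abs(delta) < 1e-12) return(xyz)
  if (is.null(moved)) moved <- .movedSet(bonds, k)
  i <- bonds$a1[k]; j <- bonds$a2[k]
  axis <- xyz[j, ] - xyz[i, ]
  R <- .rotAxis(axis, delta)
  pivot <- xyz[j, ]
  moved <- setdiff(moved, j)
  xyz[moved, ] <- sweep(sweep(xyz[moved, , drop = FALSE], 2, pivot) %*% t(R),
                        2, pivot, "+")
  xyz
}

#' Enumerate near-native torsion perturbations of a ligand
#'
#' For each rotatable bond the torsion is set to -delta, 0 or +delta
#' degrees around the input value, and the full Cartesian product is
#' enumerated (3^k candidates for k rotatable bonds). Products larger than
#' the configured cap are down-sampled deterministically by seed, always
#' retaining the identity and the single-bond perturbations.
#'
#' @param ligand a \linkS4class{Ligand} with 3D coordinates.
#' @param config an \linkS4class{EnsembleConfig}.
#' @return list with elements \code{conformers} (list of n x 3 matrices)
#'   and \code{deltas} (matrix of per-bond torsion deltas, one row per
#'   candidate).
#' @export
enumerateLigandPerturbations <- function(ligand, config = ensembleConfig()) {
  xyz <- as.matrix(ligand@atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    stop("input error: ligand lacks 3D coordinates", call. = FALSE)
  }
  rot <- which(ligand@bonds$rotatable)
  k <- length(rot)
  delta <- config@ligandTorsionDelta
  if (k == 0) {
    return(list(conformers = list(xyz), deltas = matrix(0, 1, 0)))
  }
  if (3^k <= config@enumCap) {
    grids <- rep(list(c(-delta, 0, delta)), k)
    combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  } else {
    base <- matrix(0, 1, k)
    singles <- NULL
    for (b in seq_len(k)) {
      for (d in c(-delta, delta)) {
        row <- rep(0, k); row[b] <- d
        singles <- rbind(singles, row)
      }
    }
    n_extra <- config@enumCap - nrow(base) - nrow(singles)
    set.seed(config@seed)
    extra <- matrix(sample(c(-delta, 0, delta), n_extra * k, replace = TRUE),
                    ncol = k)
    combos <- rbind(base, singles, extra)
  }
  dimnames(combos) <- NULL
  moved_sets <- lapply(rot, function(kk) .movedSet(ligand@bonds, kk))
  confs <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    cur <- xyz
    for (b in seq_len(k)) {
      cur <- .applyTorsion(cur, ligand@bonds, rot[b], combos[r, b],
                           moved = moved_sets[[b]])
    }
    confs[[r]] <- cur
  }
  list(conformers = confs, deltas = combos)
}

#' Cluster torsion candidates into a conformer ensemble
#'
#' K-means clustering (k = min(number of candidates, maxConformers)) on
#' superposed heavy-atom coordinates; the medoid of each cluster is taken
#' as representative and representatives closer than \code{dedupRmsd}
#' heavy-atom RMSD (after optimal superposition) to an already retained one
#' are omitted. Deterministic for a fixed seed.
#'
#' @param ligand the parent \linkS4class{Ligand}.
#' @param candidates output of \code{\link{enumerateLigandPerturbations}}.
#' @param config an \linkS4class{EnsembleConfig}.
#' @return a \linkS4class{ConformerEnsemble}.
#' @export
clusterEnsemble <- function(ligand, candidates, config = ensembleConfig()) {
  confs <- candidates$conformers
  n <- length(confs)
  if (n < 1) stop("input error: no candidates", call. = FALSE)
  heavy <- which(ligand@atoms$elesy != "H")
  # superpose all candidates onto the first (heavy atoms)
  ref <- confs[[1]][heavy, , drop = FALSE]
  sup <- lapply(confs, function(m) {
    kb <- .kabsch(ref, m[heavy, , drop = FALSE])
    sweep(m[heavy, , drop = FALSE] %*% t(kb$R), 2, kb$t, "+")
  })
  k <- min(n, config@maxConformers)
  if (n <= k) {
    # k-means with k = n is the identity partition
    reps <- seq_len(n)
  } else {
    feat <- do.call(rbind, lapply(sup, as.vector))
    set.seed(config@seed)
    km <- suppressWarnings(stats::kmeans(feat, centers = k, nstart = 1,
                                         iter.max = 50))
    reps <- vapply(seq_len(k), function(cl) {
      members <- which(km$cluster == cl)
      d2 <- rowSums(sweep(feat[members, , drop = FALSE], 2,
                          km$centers[cl, ])^2)
      members[which.min(d2)]
    }, 1L)
    reps <- sort(reps)
  }
  kept <- integer(0)
  for (r in reps) {
    ok <- TRUE
    for (q in kept) {
      if (.rmsdXYZ(sup[[q]], sup[[r]], fit = TRUE) < config@dedupRmsd) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, r)
  }
  new("ConformerEnsemble", ligand = ligand, conformers = confs[kept],
      provenance = list(deltas = candidates$deltas[kept, , drop = FALSE],
                        candidateIndex = kept))
}

#' Build the near-native conformer ensemble of a ligand
#'
#' Convenience wrapper: enumerate torsion perturbations, then cluster and
#' deduplicate.
#'
#' @inheritParams clusterEnsemble
#' @return a \linkS4class{ConformerEnsemble}.
#' @export
buildEnsemble <- function(ligand, config = ensembleConfig()) {
  clusterEnsemble(ligand, enumerateLigandPerturbations(ligand, config), config)
}

#' Enumerate near-native side-chain chi-angle assignments
#'
#' Per chi angle the values {0, +/-0.33 SD, +/-0.67 SD, +/-1.0 SD} (seven
#' deviations) are applied around the input torsion; the Cartesian product
#' over chi angles is enumerated, capped and deterministically
#' down-sampled by seed. Residues without side-chain torsions (Gly, Ala)
#' yield the single identity assignment.
#'
#' @param resid 3-letter residue code.
#' @param baseChi numeric vector of input chi angles (degrees); defaults to
#'   the canonical build rotamer.
#' @param sdPerChi standard deviation per chi angle, degrees (default 10).
#' @param config an \linkS4class{EnsembleConfig}.
#' @return matrix of chi assignments, one row per assignment.
#' @export
sidechainRotamerPerturbations <- function(resid, baseChi = NULL,
                                          sdPerChi = 10,
                                          config = ensembleConfig()) {
  if (!resid %in% names(.N_CHI)) {
    stop("input error: unsupported residue ", resid, call. = FALSE)
  }
  nchi <- .N_CHI[[resid]]
  if (is.null(baseChi)) baseChi <- .defaultChi(resid)
  if (nchi == 0L) return(matrix(numeric(0), nrow = 1, ncol = 0))
  if (length(baseChi) != nchi) {
    stop("input error: baseChi must have ", nchi, " angles", call. = FALSE)
  }
  if (length(sdPerChi) == 1) sdPerChi <- rep(sdPerChi, nchi)
  mults <- config@sidechainSdMultipliers
  per_chi <- lapply(seq_len(nchi), function(i) {
    devs <- unique(c(0, -mults * sdPerChi[i], mults * sdPerChi[i]))
    baseChi[i] + devs
  })
  combos <- as.matrix(expand.grid(per_chi, KEEP.OUT.ATTRS = FALSE))
  dimnames(combos) <- NULL
  if (nrow(combos) > config@enumCap) {
    set.seed(config@seed)
    keep <- sort(c(1L, sample(2:nrow(combos), config@enumCap - 1L)))
    combos <- combos[keep, , drop = FALSE]
  }
  combos
}
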