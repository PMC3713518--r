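#' @include AllClasses.R AllGenerics.R energy.R
NULL

#' Construct a FilterConfig
#'
#' @param vdwAttractiveMax poses with attractive van der Waals energy above
#'   this value are removed (default -7.0 kcal/mol).
#' @param hbondMax poses with hydrogen-bond energy above this value are
#'   removed (default -0.2 kcal/mol).
#' @param topFraction per-component top fraction compounds must reach in
#'   every energy component (default 0.40).
#' @return a \linkS4class{FilterConfig}.
#' @export
filterConfig <- function(vdwAttractiveMax = -7.0, hbondMax = -0.2,
                         topFraction = 0.40) {
  new("FilterConfig", vdwAttractiveMax = vdwAttractiveMax,
      hbondMax = hbondMax, topFraction = topFraction)
}

.checkResultCols <- function(results,
                             cols = c("id", "lj_attractive", "hbond")) {
  miss <- setdiff(cols, names(results))
  if (length(miss)) {
    stop("input error: results table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Apply the post-docking hard filters
#'
#' Keeps results whose attractive van der Waals component and hydrogen-bond
#' component are at least as favorable as the configured bounds. Returns a
#' subset of the input; applying the filter twice gives the same table
#' (idempotent).
#'
#' @param results data.frame of per-compound best-pose energies with
#'   columns id, lj_attractive, hbond (and any others, preserved).
#' @param config a \linkS4class{FilterConfig}.
#' @return the surviving rows of \code{results}.
#' @export
applyHardFilters <- function(results, config = filterConfig()) {
  if (!nrow(results)) return(results)
  .checkResultCols(results)
  keep <- results$lj_attractive <= config@vdwAttractiveMax &
    results$hbond <= config@hbondMax
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Component-wise top-fraction selection
#'
#' A compound survives if it ranks in the top fraction (most favorable,
#' i.e. lowest energy) of every component considered: total,
#' Lennard-Jones (attractive + repulsive), solvation, hydrogen bonding and
#' electrostatics. Ties at the cutoff are broken by compound id (stable,
#' documented).
#'
#' @param results data.frame with columns id, total, lj_attractive,
#'   lj_repulsive, solvation, hbond, electrostatics.
#' @param config a \linkS4class{FilterConfig}.
#' @return the surviving rows of \code{results}.
#' @export
componentTopfraction <- function(results, config = filterConfig()) {
  if (!nrow(results)) return(results)
  .checkResultCols(results, c("id", "total", "lj_attractive", "lj_repulsive",
                              "solvation", "hbond", "electrostatics"))
  n <- nrow(results)
  k <- ceiling(config@topFraction * n)
  comp <- list(
    total = results$total,
    lj = results$lj_attractive + results$lj_repulsive,
    solvation = results$solvation,
    hbond = results$hbond,
    electrostatics = results$electrostatics)
  survivors <- rep(TRUE, n)
  for (v in comp) {
    ord <- order(v, results$id)
    top <- ord[seq_len(k)]
    inset <- rep(FALSE, n)
    inset[top] <- TRUE
    survivors <- survivors & inset
  }
  out <- results[survivors, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- shape complementarity ---------------------------------------------

# Dot-surface samples: per atom, Fibonacci-lattice points on its vdW sphere
# (density points per square Angstrom), discarding points buried inside a
# neighbouring atom. Returns points and outward normals.
.surfacePoints <- function(atoms, density = 2) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- .ljParam(atoms$elesy, "r")
  pts <- list(); nrm <- list()
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i]
    n <- max(8L, ceiling(4 * pi * r^2 * density))
    sph <- .fibSphere(n)
    p <- sweep(sph * r, 2, xyz[i, ], "+")
    keep <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      if (.vnorm(xyz[j, ] - xyz[i, ]) > r + radii[j]) next
      dj <- sqrt(rowSums(sweep(p, 2, xyz[j, ])^2))
      keep <- keep & dj >= radii[j] - 1e-3
    }
    if (any(keep)) {
      pts[[length(pts) + 1]] <- p[keep, , drop = FALSE]
      nrm[[length(nrm) + 1]] <- sph[keep, , drop = FALSE]
    }
  }
  list(points = do.call(rbind, pts), normals = do.call(rbind, nrm))
}

# Score sample pairs: for each point in A, find the nearest point in B and
# accumulate alignment x Gaussian proximity; w in 1/Angstrom^2.
.scSamples <- function(pa, na, pb, nb, w = 0.5) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  j <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(pa)), j)])
  align <- rowSums(na * -nb[j, , drop = FALSE])
  align * exp(-w * dmin^2)
}

#' Shape complementarity of a docked interface
#'
#' Median, over molecular-surface sample points of the buried interface, of
#' the product of facing-normal alignment and a Gaussian weight in the
#' point separation (weight 0.5 per square Angstrom; sampling density 2
#' points per square Angstrom). Ranges over [-1, 1]: values near 1 indicate
#' snugly packed, anti-parallel facing surfaces; negative values indicate
#' misaligned surfaces.
#'
#' @param fiber a \linkS4class{FiberModel}, or a plain atom data.frame with
#'   columns elesy, x, y, z (the receptor side).
#' @param ligand a placed \linkS4class{Ligand}.
#' @param contactDistance Angstrom; an interface must exist, i.e. at least
#'   one fiber-ligand atom pair within this distance (default 5), else an
#'   error of class "noInterfaceError" is thrown.
#' @param density surface sampling density, points per square Angstrom.
#' @param w Gaussian distance weight, 1/Angstrom^2.
#' @return numeric scalar in [-1, 1].
#' @export
shapeComplementarity <- function(fiber, ligand, contactDistance = 5,
                                 density = 2, w = 0.5) {
  fa <- if (is(fiber, "FiberModel")) fiber@atoms else fiber
  la <- ligand@atoms
  fxyz <- as.matrix(fa[, c("x", "y", "z")])
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(fxyz^2), rowSums(lxyz^2), "+") - 2 * fxyz %*% t(lxyz)
  if (min(d2) > contactDistance^2) {
    stop(structure(class = c("noInterfaceError", "error", "condition"),
                   list(message = "no interface: no fiber-ligand atom pair within contact distance",
                        call = sys.call())))
  }
  # restrict fiber atoms to the interface neighbourhood
  near <- which(apply(d2, 1, min) < (contactDistance + 4)^2)
  sf <- .surfacePoints(fa[near, , drop = FALSE], density)
  sl <- .surfacePoints(la, density)
  # buried-interface samples only: points whose nearest opposite-surface
  # point lies within 2 Angstrom (widened to the closest approach when the
  # surfaces stand further apart)
  d2x <- outer(rowSums(sf$points^2), rowSums(sl$points^2), "+") -
    2 * sf$points %*% t(sl$points)
  d2x[d2x < 0] <- 0
  dl <- sqrt(apply(d2x, 2, min))   # per ligand sample
  df <- sqrt(apply(d2x, 1, min))   # per fiber sample
  burial <- max(2, min(dl) + 0.5)
  close_l <- dl <= burial
  close_f <- df <= burial
  s1 <- .scSamples(sl$points[close_l, , drop = FALSE],
                   sl$normals[close_l, , drop = FALSE],
                   sf$points, sf$normals, w)
  s2 <- .scSamples(sf$points[close_f, , drop = FALSE],
                   sf$normals[close_f, , drop = FALSE],
                   sl$points, sl$normals, w)
  stats::median(c(s1, s2))
}

#' Final ranking of screening results
#'
#' Orders by tightest binding energy (most negative first), then by best
#' (highest) shape complementarity, then by compound id; assigns ranks
#' 1..n. The ordering is a total order: permuting the input rows does not
#' change the assigned ranks.
#'
#' @param results data.frame with columns id, binding_energy, sc.
#' @return the table sorted with a \code{rank} column added.
#' @export
finalRank <- function(results) {
  .checkResultCols(results, c("id", "binding_energy", "sc"))
  ord <- order(results$binding_energy, -results$sc, results$id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
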