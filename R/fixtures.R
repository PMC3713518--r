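#' @include AllClasses.R AllGenerics.R fiber.R ligand.R pharmacophore.R
NULL

#' Construct an idealized probe-on-rail pose
#'
#' Places a flat di-acceptor probe on the fiber so that its two acceptors
#' hydrogen-bond the rail NZ atoms of two strands a given number of strands
#' apart, while one ring stacks on an apolar side-chain center -- i.e. a
#' pose satisfying every pharmacophore window. The placement is found by
#' minimizing a smooth penalty over the six rigid-body parameters (hinge
#' losses on d1, theta1, theta2, d2 and phi, with targets slightly inside
#' the windows), restarted deterministically from seeded perturbations of
#' an analytic initial guess. Used as a geometric fixture generator; errors
#' if no window-satisfying placement is found.
#'
#' @param fiber a \linkS4class{FiberModel} with a lysine rail on the +x
#'   face.
#' @param probe a \linkS4class{ProbeLigand} (its acceptor separation should
#'   match the rail spacing of the targeted strand pair).
#' @param strands length-2 integer: the two rail strands to bridge
#'   (default c(0, 2)).
#' @param windows a \linkS4class{GeometryWindows}.
#' @param maxRestarts random restarts of the local search (default 60).
#' @return a \linkS4class{Pose} (conformer index 1).
#' @export
idealProbePose <- function(fiber, probe, strands = c(0L, 2L),
                           windows = geometryWindows(), maxRestarts = 60L) {
  rail <- lysineRail(fiber, face = "+x")
  if (!all(strands %in% rail$strand)) {
    stop("input error: requested strands lack rail lysines", call. = FALSE)
  }
  nzA <- unlist(rail[rail$strand == strands[1], c("nz.x", "nz.y", "nz.z")])[1:3]
  nzB <- unlist(rail[rail$strand == strands[2], c("nz.x", "nz.y", "nz.z")])[1:3]
  fa <- fiber@atoms
  ceOf <- function(s) {
    r <- rail[rail$strand == s, ][1, ]
    unlist(fa[fa$strand == s & fa$resno == r$resno & fa$elety == "CE",
              c("x", "y", "z")])
  }
  ceA <- ceOf(strands[1]); ceB <- ceOf(strands[2])
  frame <- .apolarFaceFrame(fiber, "+x")
  centers <- .apolarCenters(fiber)
  face_keep <- vapply(seq_len(nrow(centers)), function(i) {
    r <- fa[fa$strand == centers$strand[i] & fa$resno == centers$resno[i], ]
    ca <- unlist(r[r$elety == "CA", c("x", "y", "z")])
    cb <- unlist(r[r$elety == "CB", c("x", "y", "z")])
    cb[1] > ca[1]
  }, TRUE)
  cxyz <- as.matrix(centers[face_keep, c("x", "y", "z")])
  if (!nrow(cxyz)) stop("geometry error: no apolar center on the +x face",
                        call. = FALSE)
  a <- probe@atoms
  iacc <- which(a$acceptor)
  sites <- .ligandPolarSites(a, probe@bonds)
  iante <- sites$ante[match(iacc, sites$i)]
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  # proper rotation: local long axis -> fiber z, local face normal -> fiber x
  R0 <- cbind(c(0, 0, 1), c(0, -1, 0), c(1, 0, 0))
  hinge <- function(x, lo, hi) max(0, lo - x, x - hi)
  # targets pulled slightly inside the acceptance windows
  d1t <- c(windows@d1[1] + 0.15, windows@d1[2] - 0.15)
  t1t <- c(windows@theta1[1] + 4, windows@theta1[2] - 4)
  t2t <- c(windows@theta2[1] + 4, windows@theta2[2] - 4)
  d2t <- c(windows@d2[1] + 0.15, windows@d2[2] - 0.15)
  phit <- c(windows@phi[1], windows@phi[2] - 7)
  pen <- function(p) {
    R <- .rotEuler(p[4], p[5], p[6]) %*% R0
    xyz <- sweep(xyz0 %*% t(R), 2, p[1:3], "+")
    acc <- xyz[iacc, , drop = FALSE]
    ante <- xyz[iante, , drop = FALSE]
    if (.vnorm(acc[1, ] - nzA) > .vnorm(acc[2, ] - nzA)) {
      acc <- acc[2:1, ]; ante <- ante[2:1, ]
    }
    v <- hinge(.vnorm(acc[1, ] - nzA), d1t[1], d1t[2])^2 +
      hinge(.vnorm(acc[2, ] - nzB), d1t[1], d1t[2])^2 +
      (hinge(.angle3(ante[1, ], acc[1, ], nzA), t1t[1], t1t[2]) / 15)^2 +
      (hinge(.angle3(ante[2, ], acc[2, ], nzB), t1t[1], t1t[2]) / 15)^2 +
      (hinge(.angle3(ceA, nzA, acc[1, ]), t2t[1], t2t[2]) / 15)^2 +
      (hinge(.angle3(ceB, nzB, acc[2, ]), t2t[1], t2t[2]) / 15)^2
    stack <- Inf
    for (rg in probe@rings) {
      rx <- xyz[rg, , drop = FALSE]
      ctr <- colMeans(rx)
      pl <- .lsPlane(rx)
      phi <- .angle3(pl$normal, c(0, 0, 0), frame@normal)
      phi <- min(phi, 180 - phi)
      d2s <- sqrt(rowSums(sweep(cxyz, 2, ctr)^2))
      s <- min(vapply(d2s, function(d) hinge(d, d2t[1], d2t[2]), 0)) +
        hinge(phi, phit[1], phit[2]) / 10
      stack <- min(stack, s)
    }
    v + stack^2
  }
  mid <- (nzA + nzB) / 2
  set.seed(1721L)
  best <- NULL
  for (trial in seq_len(maxRestarts)) {
    p0 <- c(mid + c(3.1, 0, 0) + stats::rnorm(3, 0, 1.2),
            stats::rnorm(3, 0, 30))
    opt <- stats::optim(p0, pen, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value < 1e-14) break
  }
  if (best$value > 1e-10) {
    stop("geometry error: no window-satisfying probe placement found ",
         sprintf("(residual penalty %.3g)", best$value), call. = FALSE)
  }
  R <- .rotEuler(best$par[4], best$par[5], best$par[6]) %*% R0
  new("Pose", conformerIndex = 1L, rotation = R, translation = best$par[1:3],
      sidechain = list())
}

#' Write a fiber + ligand pose as a PDB file
#'
#' Fiber atoms as ATOM records (one chain per strand), ligand atoms as
#' HETATM records (residue LIG, chain X). Suitable for visual inspection
#' and for the pose artifacts of a screen.
#'
#' @param fiber a \linkS4class{FiberModel}.
#' @param ligand a placed \linkS4class{Ligand}.
#' @param path output path.
#' @param remark optional character vector of REMARK payload lines.
#' @return the path, invisibly.
#' @export
writePosePdb <- function(fiber, ligand, path, remark = character(0)) {
  writeFiber(fiber, path)
  lines <- readLines(path)
  lines <- lines[lines != "END"]
  if (length(remark)) {
    lines <- c(sprintf("REMARK 300 %s", remark), lines)
  }
  la <- ligand@atoms
  serial <- sum(grepl("^(ATOM|TER)", lines))
  for (i in seq_len(nrow(la))) {
    serial <- serial + 1L
    nm <- substr(la$name[i], 1, 4)
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    lines <- c(lines, sprintf(
      "HETATM%5d %4s LIG X%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm_fmt, 1L, la$x[i], la$y[i], la$z[i], 1, 0, la$elesy[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
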