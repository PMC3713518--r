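#' @include AllClasses.R AllGenerics.R energy.R conformers.R
NULL

#' Construct a DockingConfig
#'
#' @param maxTranslation Angstrom bound on rigid-body translation moves
#'   around the coarse placement (default 5).
#' @param rotationRange degrees of rotational freedom (default 360, i.e.
#'   full rotations).
#' @param nCycles Monte Carlo cycles (default 500).
#' @param temperature Metropolis temperature in kcal/mol (default 1.0).
#' @param seed integer random seed.
#' @param interactionCutoff pair cutoff of the energy function, Angstrom.
#' @param gridStep coarse-grid translation spacing along the rail (default
#'   1 Angstrom).
#' @param nRotations coarse-stage rotations about the surface normal
#'   (default 12).
#' @return a \linkS4class{DockingConfig}.
#' @export
dockingConfig <- function(maxTranslation = 5, rotationRange = 360,
                          nCycles = 500L, temperature = 1.0, seed = 1L,
                          interactionCutoff = 6, gridStep = 1,
                          nRotations = 12L) {
  new("DockingConfig", maxTranslation = maxTranslation,
      rotationRange = rotationRange, nCycles = as.integer(nCycles),
      temperature = temperature, seed = as.integer(seed),
      interactionCutoff = interactionCutoff, gridStep = gridStep,
      nRotations = as.integer(nRotations))
}

# Orient a conformer: center at origin, flattest plane normal along +x
# (facing the sheet surface), long axis along +z (the fiber axis).
.orientConformer <- function(xyz) {
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  s <- svd(x0, nu = 0)
  # principal axis -> z, second -> y, normal -> x
  R <- rbind(as.vector(s$v[, 3]), as.vector(s$v[, 2]), as.vector(s$v[, 1]))
  if (det(R) < 0) R[2, ] <- -R[2, ]
  list(R = R, center = ctr)
}

.poseEnergy <- function(fiber, ensemble, pose, config, windows,
                        solvationWeight) {
  scorePose(fiber, ensemble, pose, config, windows, solvationWeight)
}

#' Dock a conformer ensemble onto the fiber surface
#'
#' Three-stage protocol. Stage 1 (coarse): the ligand, oriented with its
#' flat face toward the sheet, is scanned over a grid of translations along
#' the lysine-rail groove (gridStep spacing) crossed with rotations about
#' the surface normal, for every conformer; the best grid placement seeds
#' stage 2. Stage 2 (Monte Carlo): Metropolis sampling over rigid-body
#' perturbations (translations bounded by maxTranslation, rotations up to
#' rotationRange), conformer swaps, and near-native side-chain chi moves of
#' rail lysines. Stage 3: derivative-free local refinement (coordinate
#' descent) of the six rigid-body parameters. Deterministic for a fixed
#' seed; the best-so-far energy is non-increasing across accepted
#' improvements.
#'
#' @param fiber a \linkS4class{FiberModel}.
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param config a \linkS4class{DockingConfig}.
#' @param windows \linkS4class{GeometryWindows} for the hydrogen-bond term.
#' @param solvationWeight optional buried-apolar reward weight (default 0).
#' @param face fiber face to dock against ("+x" or "-x").
#' @param initialPose optional \linkS4class{Pose} to start from (skips the
#'   coarse stage; with \code{nCycles = 0} and \code{refine = FALSE} it is
#'   returned unchanged).
#' @param refine run the stage-3 local minimization (default TRUE).
#' @return list with elements \code{pose} (best \linkS4class{Pose}),
#'   \code{energy} (its \linkS4class{EnergyBreakdown}) and
#'   \code{trajectory} (data.frame log: stage, step, energy, best).
#' @export
dock <- function(fiber, ensemble, config = dockingConfig(),
                 windows = geometryWindows(), solvationWeight = 0,
                 face = "+x", initialPose = NULL, refine = TRUE) {
  if (!length(ensemble@conformers)) {
    stop("input error: empty ensemble", call. = FALSE)
  }
  set.seed(config@seed)
  traj <- list()
  log_step <- function(stage, step, e, best) {
    traj[[length(traj) + 1]] <<- data.frame(stage = stage, step = step,
                                            energy = e, best = best)
  }
  fa <- fiber@atoms
  sgn <- if (face == "+x") 1 else -1

  if (is.null(initialPose)) {
    # ---- stage 1: coarse grid over the rail groove ----
    rail <- lysineRail(fiber, face = if (sgn > 0) "+x" else "-x")
    if (nrow(rail)) {
      z_lo <- min(rail$nz.z); z_hi <- max(rail$nz.z)
      x_surf <- if (sgn > 0) max(fa$x) else min(fa$x)
      y_ctr <- mean(rail$nz.y)
    } else {
      z_lo <- min(fa$z); z_hi <- max(fa$z)
      x_surf <- if (sgn > 0) max(fa$x) else min(fa$x)
      y_ctr <- mean(fa$y)
    }
    z_grid <- seq(z_lo, z_hi, by = config@gridStep)
    rots <- seq(0, 360, length.out = config@nRotations + 1)[-(config@nRotations + 1)]
    best <- NULL
    step <- 0
    for (ci in seq_along(ensemble@conformers)) {
      ori <- .orientConformer(ensemble@conformers[[ci]])
      for (zz in z_grid) {
        for (rr in rots) {
          R <- .rotAxis(c(1, 0, 0), rr) %*% ori$R
          t0 <- c(x_surf + sgn * 3.4, y_ctr, zz) - as.vector(R %*% ori$center)
          pose <- new("Pose", conformerIndex = as.integer(ci), rotation = R,
                      translation = t0, sidechain = list())
          e <- tryCatch(
            .poseEnergy(fiber, ensemble, pose, config, windows,
                        solvationWeight)@total,
            error = function(err) Inf)
          step <- step + 1
          if (is.null(best) || e < best$e) {
            best <- list(pose = pose, e = e)
            log_step("coarse", step, e, e)
          }
        }
      }
    }
    cur_pose <- best$pose
    cur_e <- best$e
  } else {
    cur_pose <- initialPose
    cur_e <- .poseEnergy(fiber, ensemble, cur_pose, config, windows,
                         solvationWeight)@total
    log_step("init", 0, cur_e, cur_e)
  }
  anchor_t <- cur_pose@translation
  best_pose <- cur_pose
  best_e <- cur_e

  # rail lysines available for side-chain moves
  rail_all <- lysineRail(fiber, face = if (sgn > 0) "+x" else "-x")
  sc_choices <- if (nrow(rail_all)) {
    keys <- paste(rail_all$strand, rail_all$resno, sep = ".")
    perturb <- sidechainRotamerPerturbations("LYS",
                                             config = ensembleConfig(seed = config@seed))
    list(keys = keys, chi = perturb)
  } else NULL

  # ---- stage 2: Metropolis Monte Carlo ----
  n_conf <- length(ensemble@conformers)
  if (config@nCycles > 0) {
    for (cyc in seq_len(config@nCycles)) {
      cand <- cur_pose
      u <- stats::runif(1)
      if (u < 0.4) {
        dt <- stats::rnorm(3, 0, 0.5)
        newt <- cand@translation + dt
        # stay within maxTranslation of the coarse anchor
        off <- newt - anchor_t
        nrm <- .vnorm(off)
        if (nrm > config@maxTranslation) {
          newt <- anchor_t + off / nrm * config@maxTranslation
        }
        cand@translation <- newt
      } else if (u < 0.7) {
        ang <- stats::rnorm(1, 0, 15)
        ang <- max(min(ang, config@rotationRange / 2), -config@rotationRange / 2)
        ax <- stats::rnorm(3)
        cand@rotation <- .rotAxis(ax, ang) %*% cand@rotation
      } else if (u < 0.85 && n_conf > 1) {
        cand@conformerIndex <- as.integer(sample.int(n_conf, 1))
      } else if (!is.null(sc_choices)) {
        key <- sample(sc_choices$keys, 1)
        row <- sample.int(nrow(sc_choices$chi), 1)
        sc <- cand@sidechain
        sc[[key]] <- sc_choices$chi[row, ]
        cand@sidechain <- sc
      }
      e_new <- tryCatch(
        .poseEnergy(fiber, ensemble, cand, config, windows,
                    solvationWeight)@total,
        error = function(err) Inf)
      accept <- if (is.finite(e_new) && e_new <= cur_e) TRUE
      else if (!is.finite(e_new)) FALSE
      else if (config@temperature <= 0) FALSE
      else stats::runif(1) < exp(-(e_new - cur_e) / config@temperature)
      if (accept) {
        cur_pose <- cand
        cur_e <- e_new
        if (cur_e < best_e) {
          best_e <- cur_e
          best_pose <- cur_pose
        }
      }
      log_step("mc", cyc, if (accept) e_new else cur_e, best_e)
    }
  }

  # ---- stage 3: coordinate descent on rigid-body parameters ----
  if (refine) {
    steps <- c(0.25, 0.1)
    ang_steps <- c(5, 2)
    for (lev in seq_along(steps)) {
      improved <- TRUE
      sweep_i <- 0
      while (improved && sweep_i < 5) {
        improved <- FALSE
        sweep_i <- sweep_i + 1
        for (dim in 1:3) {
          for (sgn2 in c(-1, 1)) {
            cand <- best_pose
            cand@translation[dim] <- cand@translation[dim] + sgn2 * steps[lev]
            e <- tryCatch(.poseEnergy(fiber, ensemble, cand, config, windows,
                                      solvationWeight)@total,
                          error = function(err) Inf)
            if (e < best_e - 1e-9) {
              best_e <- e
              best_pose <- cand
              improved <- TRUE
            }
          }
        }
        for (axdim in 1:3) {
          ax <- c(0, 0, 0); ax[axdim] <- 1
          for (sgn2 in c(-1, 1)) {
            cand <- best_pose
            ctr <- colMeans(.xform(
              ensemble@conformers[[cand@conformerIndex]],
              cand@rotation, cand@translation))
            Rd <- .rotAxis(ax, sgn2 * ang_steps[lev])
            cand@rotation <- Rd %*% cand@rotation
            cand@translation <- as.vector(Rd %*% (cand@translation - ctr)) + ctr
            e <- tryCatch(.poseEnergy(fiber, ensemble, cand, config, windows,
                                      solvationWeight)@total,
                          error = function(err) Inf)
            if (e < best_e - 1e-9) {
              best_e <- e
              best_pose <- cand
              improved <- TRUE
            }
          }
        }
        log_step("minimize", sweep_i, best_e, best_e)
      }
    }
  }
  energy <- .poseEnergy(fiber, ensemble, best_pose, config, windows,
                        solvationWeight)
  list(pose = best_pose, energy = energy,
       trajectory = do.call(rbind, traj))
}
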