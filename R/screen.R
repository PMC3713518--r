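#' @include AllClasses.R AllGenerics.R library.R conformers.R dock.R filter.R fixtures.R
NULL

#' ScreenConfig: full pipeline configuration
#'
#' @slot sequence one-letter strand sequence of the fiber target.
#' @slot nStrands strands in the fiber models.
#' @slot rise Angstrom rise per strand.
#' @slot probeSeparations acceptor separations (Angstrom) of synthetic probe
#'   ligands to screen; used when no SMILES file is given.
#' @slot smilesFile optional path to a SMILES library file.
#' @slot filterMode flat-compound filter mode applied to a SMILES library
#'   ("strict", "broad" or "none").
#' @slot ensemble an \linkS4class{EnsembleConfig}.
#' @slot docking a \linkS4class{DockingConfig}.
#' @slot filter a \linkS4class{FilterConfig}.
#' @slot windows a \linkS4class{GeometryWindows}.
#' @slot outdir output directory.
#' @slot seed master seed; all stage seeds derive from it.
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(sequence = "character", nStrands = "integer",
                 rise = "numeric", probeSeparations = "numeric",
                 smilesFile = "character", filterMode = "character",
                 ensemble = "EnsembleConfig", docking = "DockingConfig",
                 filter = "FilterConfig", windows = "GeometryWindows",
                 outdir = "character", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nStrands < 1L) msg <- c(msg, "nStrands must be >= 1")
    if (!object@filterMode %in% c("strict", "broad", "none")) {
      msg <- c(msg, "filterMode must be strict, broad or none")
    }
    if (!length(object@probeSeparations) && !nzchar(object@smilesFile)) {
      msg <- c(msg, "need probeSeparations or a smilesFile")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ScreenConfig
#'
#' @param sequence fiber strand sequence (default "KLVFFA").
#' @param nStrands number of strands (default 6).
#' @param rise rise per strand, Angstrom (default 4.8).
#' @param probeSeparations probe acceptor separations, Angstrom.
#' @param smilesFile optional SMILES library path (overrides probes).
#' @param filterMode "strict", "broad" or "none".
#' @param ensemble,docking,filter,windows stage configurations.
#' @param outdir output directory.
#' @param seed master seed.
#' @return a \linkS4class{ScreenConfig}.
#' @export
screenConfig <- function(sequence = "KLVFFA", nStrands = 6L, rise = 4.8,
                         probeSeparations = c(9.6, 7.2, 12.0),
                         smilesFile = "", filterMode = "none",
                         ensemble = ensembleConfig(),
                         docking = dockingConfig(),
                         filter = filterConfig(),
                         windows = geometryWindows(),
                         outdir = "screen_out", seed = 1L) {
  new("ScreenConfig", sequence = sequence, nStrands = as.integer(nStrands),
      rise = rise, probeSeparations = probeSeparations,
      smilesFile = smilesFile, filterMode = filterMode, ensemble = ensemble,
      docking = docking, filter = filter, windows = windows,
      outdir = outdir, seed = as.integer(seed))
}

#' Read a ScreenConfig from a YAML file
#'
#' Top-level keys mirror \code{\link{screenConfig}} arguments; nested maps
#' \code{ensemble}, \code{docking}, \code{filter} and \code{windows} mirror
#' their constructors. Unknown keys are an error (full validation before
#' any compute).
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @param outdir optional output directory override.
#' @return a \linkS4class{ScreenConfig}.
#' @export
readScreenConfig <- function(path, seed = NULL, outdir = NULL) {
  if (!file.exists(path)) stop("input error: config not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- c("sequence", "nStrands", "rise", "probeSeparations",
             "smilesFile", "filterMode", "ensemble", "docking", "filter",
             "windows", "outdir", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("input error: unknown config keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  args <- y[setdiff(names(y), c("ensemble", "docking", "filter", "windows"))]
  if (!is.null(y$ensemble)) args$ensemble <- do.call(ensembleConfig, y$ensemble)
  if (!is.null(y$docking)) args$docking <- do.call(dockingConfig, y$docking)
  if (!is.null(y$filter)) args$filter <- do.call(filterConfig, y$filter)
  if (!is.null(y$windows)) args$windows <- do.call(geometryWindows, y$windows)
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(screenConfig, args)
}

# Stable fingerprint of a config (FNV-1a over its serialized fields).
# The output directory is excluded: it locates artifacts, it does not
# change what is computed.
.configHash <- function(config) {
  fields <- vapply(setdiff(slotNames(config), "outdir"), function(s) {
    v <- slot(config, s)
    if (isS4(v)) {
      paste(vapply(slotNames(v), function(s2)
        paste(format(slot(v, s2), digits = 12), collapse = ","), ""),
        collapse = ";")
    } else {
      paste(format(v, digits = 12), collapse = ",")
    }
  }, "")
  .fnv1a(paste(names(fields), fields, sep = "=", collapse = "|"))
}

#' Run the full screening pipeline
#'
#' Stages, mirroring the screen-then-rescreen design: (A) library
#' preparation (probe construction or SMILES canonicalization + flat
#' filter); (B) near-native conformer ensembles; (C) docking against the
#' antiparallel segment fiber; (D) hard energy filters; (E) re-docking of
#' survivors against the in-register parallel fiber stand-in; (F)
#' component-wise top-fraction selection, shape complementarity and final
#' ranking, plus per-compound pharmacophore reports. Every artifact is
#' stamped with the config hash and seed; identical config + seed gives
#' byte-identical ranked tables.
#'
#' @param config a \linkS4class{ScreenConfig}.
#' @return invisibly, a list with the ranked results table, the stage-A
#'   energy table, pharmacophore reports and artifact paths.
#' @export
runScreen <- function(config) {
  validObject(config)
  outdir <- config@outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "poses"), showWarnings = FALSE)
  dir.create(file.path(outdir, "pharm"), showWarnings = FALSE)
  hash <- .configHash(config)
  logfile <- file.path(outdir, "run.log")
  logcon <- file(logfile, open = "wt")
  t_start <- Sys.time()
  logmsg <- function(...) {
    line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
    writeLines(line, logcon)
    message(line)
  }
  fail_marker <- file.path(outdir, "FAILED")
  on.exit(close(logcon), add = TRUE)
  result <- tryCatch({
    logmsg("screen start: config ", hash, " seed ", config@seed)

    # ---- stage A: library ----
    if (nzchar(config@smilesFile)) {
      recs <- readSmilesFile(config@smilesFile)
      lib <- canonicalizeAndIndex(recs)
      if (config@filterMode != "none") {
        lib <- flatFilter(lib, config@filterMode)
      }
      logmsg("library: ", nrow(libraryRecords(lib)), " compounds after ",
             config@filterMode, " filter")
      ligands <- lapply(seq_len(nrow(libraryRecords(lib))), function(i) {
        r <- libraryRecords(lib)[i, ]
        smilesToLigand(r$smiles, r$id)
      })
    } else {
      ligands <- lapply(config@probeSeparations, makeProbeLigand)
      logmsg("library: ", length(ligands), " synthetic probes")
    }
    if (!length(ligands)) stop("input error: empty screening library",
                               call. = FALSE)

    # ---- fibers ----
    fiber_seg <- buildFiber(config@sequence, config@nStrands, "antiparallel",
                            rise = config@rise)
    fiber_full <- buildFiber(config@sequence, config@nStrands,
                             "in_register_parallel", rise = config@rise)

    # ---- stage B: ensembles ----
    ens_cfg <- config@ensemble
    ens_cfg@seed <- config@seed
    ensembles <- lapply(ligands, buildEnsemble, config = ens_cfg)
    logmsg("ensembles: sizes ", paste(vapply(ensembles, function(e)
      length(e@conformers), 0L), collapse = ","))

    dock_one <- function(fiber, ens, k) {
      cfg <- config@docking
      cfg@seed <- config@seed + k
      dock(fiber, ens, cfg, windows = config@windows)
    }
    energy_row <- function(id, d) {
      e <- energyComponents(d$energy)
      data.frame(id = id, lj_attractive = e[["lj_attractive"]],
                 lj_repulsive = e[["lj_repulsive"]], hbond = e[["hbond"]],
                 electrostatics = e[["electrostatics"]],
                 solvation = e[["solvation"]], total = e[["total"]],
                 stringsAsFactors = FALSE)
    }

    # ---- stage C: dock to segment fiber ----
    docksA <- lapply(seq_along(ensembles), function(k)
      dock_one(fiber_seg, ensembles[[k]], k))
    tabA <- do.call(rbind, lapply(seq_along(docksA), function(k)
      energy_row(ligands[[k]]@id, docksA[[k]])))
    utils::write.table(
      rbind(tabA),
      file.path(outdir, "energies_segment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    logmsg("stage C: docked ", nrow(tabA), " compounds to segment fiber")

    # ---- stage D: hard filters ----
    surv <- applyHardFilters(tabA, config@filter)
    logmsg("stage D: ", nrow(surv), " survive hard filters (vdw <= ",
           config@filter@vdwAttractiveMax, ", hbond <= ",
           config@filter@hbondMax, ")")

    # ---- stage E: re-dock survivors to the parallel fiber ----
    keep_idx <- match(surv$id, vapply(ligands, function(l) l@id, ""))
    ranked <- data.frame()
    reports <- list()
    if (length(keep_idx)) {
      docksB <- lapply(keep_idx, function(k)
        dock_one(fiber_full, ensembles[[k]], 1000L + k))
      tabB <- do.call(rbind, lapply(seq_along(keep_idx), function(j)
        energy_row(ligands[[keep_idx[j]]]@id, docksB[[j]])))
      tabB <- applyHardFilters(tabB, config@filter)
      tabB <- componentTopfraction(tabB, config@filter)
      logmsg("stage F: ", nrow(tabB), " in the top ",
             round(100 * config@filter@topFraction), "% of all components")
      if (nrow(tabB)) {
        rows <- lapply(seq_len(nrow(tabB)), function(j) {
          k <- match(tabB$id[j], vapply(ligands, function(l) l@id, ""))
          jj <- match(k, keep_idx)
          d <- docksB[[jj]]
          lig <- applyPose(ensembles[[k]], d$pose)
          be <- d$energy@total
          sc <- tryCatch(shapeComplementarity(fiber_full, lig),
                         error = function(e) NA_real_)
          pdb <- file.path(outdir, "poses", paste0(tabB$id[j], ".pdb"))
          writePosePdb(fiber_full, lig, pdb,
                       remark = sprintf("FIBSCREEN config=%s seed=%d",
                                        hash, config@seed))
          rep <- checkPharmacophore(lig, fiber_full, config@windows)
          repj <- list(config = hash, seed = config@seed, id = tabB$id[j],
                       passes = rep@passes,
                       failure_reasons = rep@failureReasons,
                       strands_spanned = rep@strandsSpanned,
                       hbond_contacts = rep@hbondContacts,
                       stack_contacts = rep@stackContacts)
          jsonlite::write_json(
            repj, file.path(outdir, "pharm", paste0(tabB$id[j], ".json")),
            auto_unbox = TRUE, digits = NA, dataframe = "rows")
          reports[[tabB$id[j]]] <<- rep
          cbind(tabB[j, , drop = FALSE],
                data.frame(binding_energy = be, sc = sc,
                           pharmacophore = rep@passes))
        })
        ranked <- finalRank(do.call(rbind, rows))
      }
    }
    ranked_path <- file.path(outdir, "ranked.tsv")
    con <- file(ranked_path, open = "wt")
    writeLines(sprintf("# fibscreen ranked results; config=%s seed=%d",
                       hash, config@seed), con)
    if (nrow(ranked)) {
      utils::write.table(ranked, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      writeLines("id", con)
    }
    close(con)
    logmsg("done: ", nrow(ranked), " ranked compounds; elapsed ",
           sprintf("%.1f s", as.numeric(difftime(Sys.time(), t_start,
                                                 units = "secs"))))
    if (file.exists(fail_marker)) unlink(fail_marker)
    list(ranked = ranked, energies_segment = tabA, reports = reports,
         hash = hash,
         paths = list(ranked = ranked_path, log = logfile,
                      energies = file.path(outdir, "energies_segment.tsv")))
  }, error = function(e) {
    writeLines(c("screen FAILED", conditionMessage(e)), fail_marker)
    stop(e)
  })
  invisible(result)
}
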