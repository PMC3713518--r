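#' @include AllClasses.R AllGenerics.R ligand.R
NULL

#' CompoundLibrary: an indexed, canonicalized compound collection
#'
#' @slot records data.frame keyed by canonical SMILES: id, smiles, key,
#'   formula, mw, nRotatableBonds, nAromaticRings, hasPhenol,
#'   hasPlanarGroup, sourceTags.
#' @slot rejects data.frame of entries that failed canonicalization
#'   (id, smiles, reason).
#' @exportClass CompoundLibrary
setClass("CompoundLibrary",
  representation(records = "data.frame", rejects = "data.frame"),
  validity = function(object) {
    r <- object@records
    msg <- character(0)
    if (nrow(r)) {
      if (anyDuplicated(r$key)) msg <- c(msg, "duplicate canonical keys")
      if (any(r$mw <= 0)) msg <- c(msg, "molecular weights must be > 0")
      if (any(r$nRotatableBonds < 0)) msg <- c(msg, "negative rotatable bond count")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "CompoundLibrary", function(object) {
  cat(sprintf("CompoundLibrary: %d compounds (%d rejected on input)\n",
              nrow(object@records), nrow(object@rejects)))
})

#' @rdname accessors
#' @export
setGeneric("libraryRecords", function(x) standardGeneric("libraryRecords"))

#' @rdname accessors
setMethod("libraryRecords", "CompoundLibrary", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("libraryRejects", function(x) standardGeneric("libraryRejects"))

#' @rdname accessors
setMethod("libraryRejects", "CompoundLibrary", function(x) x@rejects)

# ---- formula weight -----------------------------------------------------

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904,
                  I = 126.904, Na = 22.990, K = 39.098, B = 10.81,
                  Si = 28.085)

# Anhydrous molecular weight from a Hill-style formula string, e.g.
# "C17H14N2O5S" -> 358.37.
.formulaWeight <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  w <- 0
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- as.numeric(gsub("[^0-9]", "", tk))
    if (is.na(n)) n <- 1
    if (!el %in% names(.ATOMIC_MASS)) {
      stop("input error: unknown element in formula: ", el, call. = FALSE)
    }
    w <- w + .ATOMIC_MASS[[el]] * n
  }
  w
}

# ---- descriptor computation --------------------------------------------

# SMARTS patterns for "additional planar group": conjugated sp2 substituent
# of >= 3 atoms attached to an aromatic ring.
.PLANAR_GROUP_SMARTS <- c(
  nitro = "c[N+](=O)[O-]",
  nitro_neutral = "c[NX3](=O)=O",
  carboxyl = "cC(=O)[OX2H1]",
  carboxylate = "cC(=O)[O-]",
  ester_acyl = "cC(=O)[OX2]",
  amide = "cC(=O)[NX3]",
  aldehyde_ketone = "cC(=O)[#6,H]",
  azo = "cN=Nc",
  vinyl = "cC=C"
)

.descriptorsForSmiles <- function(smiles, id) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, id))
  pr <- ChemmineR::propOB(sdf)
  formula <- pr$formula[1]
  # MW computed from the anhydrous neutral formula
  mw <- .formulaWeight(formula)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- gsub("_.*$", "", rownames(ab))
  atoms <- data.frame(elesy = elements, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  nrot <- sum(.flagRotatable(
    data.frame(elesy = elements, stringsAsFactors = FALSE), bonds))
  rng <- tryCatch(
    ChemmineR::rings(sdf[[1]], upper = 10, type = "all", arom = TRUE),
    error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
  # inner rings only (<= 6 atoms), not fused-system envelopes
  small <- vapply(rng$RINGS, length, 0L) <= 6
  n_arom <- sum(unlist(rng$AROMATIC)[small])
  has_phenol <- ChemmineR::smartsSearchOB(sdf, "[c][OX2H]") > 0
  planar_hits <- vapply(.PLANAR_GROUP_SMARTS, function(pat) {
    any(vapply(strsplit(pat, "|", fixed = TRUE)[[1]], function(p)
      tryCatch(ChemmineR::smartsSearchOB(sdf, p) > 0, error = function(e) FALSE),
      TRUE))
  }, TRUE)
  list(formula = formula, mw = mw, nRotatableBonds = nrot,
       nAromaticRings = n_arom, hasPhenol = unname(has_phenol),
       hasPlanarGroup = any(planar_hits))
}

# ---- exported operations -----------------------------------------------

#' Canonicalize and index a compound collection
#'
#' Canonicalizes every SMILES (duplicate spellings collapse to one canonical
#' key), computes descriptors (molecular weight from the anhydrous formula,
#' rotatable bond count, aromatic ring count, phenol substructure flag,
#' planar-substituent flag) and returns an indexed library. Unparsable
#' entries are recorded in the rejects table, not fatal.
#'
#' @param records data.frame with columns id, smiles and optionally source.
#' @return a \linkS4class{CompoundLibrary}.
#' @examples
#' lib <- canonicalizeAndIndex(data.frame(
#'   id = c("tol1", "tol2"), smiles = c("Cc1ccccc1", "c1ccccc1C")))
#' nrow(libraryRecords(lib))  # 1: both spellings collapse
#' @export
canonicalizeAndIndex <- function(records) {
  stopifnot(all(c("id", "smiles") %in% names(records)))
  if (!"source" %in% names(records)) records$source <- ""
  recs <- list()
  rejects <- list()
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    id <- as.character(records$id[i])
    smi <- as.character(records$smiles[i])
    key <- tryCatch({
      out <- ChemmineOB::convertFormat("SMI", "CAN", source = smi)
      k <- trimws(strsplit(out, "[\t\n]")[[1]][1])
      if (!nzchar(k)) stop("empty canonicalization")
      k
    }, error = function(e) NA_character_)
    if (is.na(key)) {
      rejects[[length(rejects) + 1]] <- data.frame(
        id = id, smiles = smi, reason = "unparsable SMILES",
        stringsAsFactors = FALSE)
      next
    }
    if (key %in% seen) {
      j <- which(vapply(recs, function(r) r$key, "") == key)
      prev <- recs[[j]]
      prev$sourceTags <- paste(unique(c(
        strsplit(prev$sourceTags, ",")[[1]],
        records$source[i])), collapse = ",")
      recs[[j]] <- prev
      next
    }
    d <- tryCatch(.descriptorsForSmiles(smi, id), error = function(e) NULL)
    if (is.null(d)) {
      rejects[[length(rejects) + 1]] <- data.frame(
        id = id, smiles = smi, reason = "descriptor computation failed",
        stringsAsFactors = FALSE)
      next
    }
    seen <- c(seen, key)
    recs[[length(recs) + 1]] <- data.frame(
      id = id, smiles = smi, key = key, formula = d$formula, mw = d$mw,
      nRotatableBonds = d$nRotatableBonds, nAromaticRings = d$nAromaticRings,
      hasPhenol = d$hasPhenol, hasPlanarGroup = d$hasPlanarGroup,
      sourceTags = as.character(records$source[i]), stringsAsFactors = FALSE)
  }
  empty_rec <- data.frame(
    id = character(0), smiles = character(0), key = character(0),
    formula = character(0), mw = numeric(0), nRotatableBonds = integer(0),
    nAromaticRings = integer(0), hasPhenol = logical(0),
    hasPlanarGroup = logical(0), sourceTags = character(0),
    stringsAsFactors = FALSE)
  empty_rej <- data.frame(id = character(0), smiles = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  new("CompoundLibrary",
      records = if (length(recs)) do.call(rbind, recs) else empty_rec,
      rejects = if (length(rejects)) do.call(rbind, rejects) else empty_rej)
}

#' Intersect two compound libraries by canonical key
#'
#' Keeps records of \code{libA} whose canonical key also occurs in
#' \code{libB}, annotating survivors with B's source tags. Entries of A
#' without a match in B are omitted (the purchasability-style omission
#' rule).
#'
#' @param libA,libB \linkS4class{CompoundLibrary} objects.
#' @return a \linkS4class{CompoundLibrary} (subset of \code{libA}).
#' @export
intersectLibraries <- function(libA, libB) {
  a <- libA@records
  b <- libB@records
  keep <- a$key %in% b$key
  out <- a[keep, , drop = FALSE]
  if (nrow(out)) {
    btags <- b$sourceTags[match(out$key, b$key)]
    out$sourceTags <- mapply(function(x, y) {
      paste(setdiff(unique(c(strsplit(x, ",")[[1]], strsplit(y, ",")[[1]])), ""),
            collapse = ",")
    }, out$sourceTags, btags)
  }
  rownames(out) <- NULL
  new("CompoundLibrary", records = out, rejects = libA@rejects[0, ])
}

#' Select flat compounds from a library
#'
#' \code{strict} mode keeps compounds containing a phenol group with fewer
#' than three freely rotatable bonds. \code{broad} mode keeps compounds with
#' multiple aromatic rings, or one aromatic ring plus at least one
#' additional planar group (a conjugated sp2 substituent of three or more
#' atoms: nitro, carboxylate, azo, conjugated carbonyl and the like).
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param mode "strict" or "broad".
#' @return the filtered \linkS4class{CompoundLibrary} (a subset; idempotent).
#' @export
flatFilter <- function(library, mode = c("strict", "broad")) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("input error: unknown mode",
                                            call. = FALSE))
  r <- library@records
  keep <- if (mode == "strict") {
    r$hasPhenol & r$nRotatableBonds < 3
  } else {
    r$nAromaticRings >= 2 | (r$nAromaticRings == 1 & r$hasPlanarGroup)
  }
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("CompoundLibrary", records = out, rejects = library@rejects[0, ])
}

#' Read a compound table from a SMILES file
#'
#' One compound per line: \code{SMILES id [source]}, whitespace-separated.
#'
#' @param path file path.
#' @return data.frame with columns id, smiles, source suitable for
#'   \code{\link{canonicalizeAndIndex}}.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("input error: empty SMILES file", call. = FALSE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%03d", i), ""),
    smiles = vapply(parts, `[[`, "", 1),
    source = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    stringsAsFactors = FALSE)
}
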