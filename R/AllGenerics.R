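#' @include AllClasses.R
NULL

#' Accessors for fibscreen objects
#'
#' Small accessor generics so user code never reaches into slots directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fiberAtoms", function(x) standardGeneric("fiberAtoms"))

#' @rdname accessors
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))

#' @rdname accessors
#' @export
setGeneric("conformers", function(x) standardGeneric("conformers"))

#' @rdname accessors
#' @export
setGeneric("nStrands", function(x) standardGeneric("nStrands"))

#' @rdname accessors
#' @export
setGeneric("fiberSequence", function(x) standardGeneric("fiberSequence"))

#' @rdname accessors
#' @export
setGeneric("registration", function(x) standardGeneric("registration"))

#' @rdname accessors
#' @export
setGeneric("kdValue", function(x) standardGeneric("kdValue"))

#' @rdname accessors
#' @export
setGeneric("fMaxValue", function(x) standardGeneric("fMaxValue"))

#' @rdname accessors
#' @export
setGeneric("energyComponents", function(x) standardGeneric("energyComponents"))

#' @rdname accessors
setMethod("fiberAtoms", "FiberModel", function(x) x@atoms)

#' @rdname accessors
setMethod("ligandAtoms", "Ligand", function(x) x@atoms)

#' @rdname accessors
setMethod("ligandAtoms", "ConformerEnsemble", function(x) x@ligand@atoms)

#' @rdname accessors
setMethod("conformers", "ConformerEnsemble", function(x) x@conformers)

#' @rdname accessors
setMethod("nStrands", "FiberModel", function(x) length(unique(x@atoms$strand)))

#' @rdname accessors
setMethod("fiberSequence", "FiberModel", function(x) x@sequence)

#' @rdname accessors
setMethod("registration", "FiberModel", function(x) x@registration)

#' @rdname accessors
setMethod("kdValue", "BindingFit", function(x) x@kd)

#' @rdname accessors
setMethod("fMaxValue", "BindingFit", function(x) x@fMax)

#' @rdname accessors
setMethod("energyComponents", "EnergyBreakdown", function(x) {
  c(lj_attractive = x@ljAttractive, lj_repulsive = x@ljRepulsive,
    hbond = x@hbond, electrostatics = x@electrostatics,
    solvation = x@solvation, total = x@total)
})

setMethod("show", "FiberModel", function(object) {
  cat(sprintf("FiberModel: %d strands of \"%s\" (%s)\n",
              nStrands(object), object@sequence, object@registration))
  cat(sprintf("  rise %.2f A, shear %.2f A, %d atoms\n",
              object@rise, object@shear, nrow(object@atoms)))
})

setMethod("show", "Ligand", function(object) {
  cat(sprintf("Ligand \"%s\": %d heavy atoms, %d bonds, %d rings\n",
              object@id, nrow(object@atoms), nrow(object@bonds),
              length(object@rings)))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble of \"%s\": %d conformers\n",
              object@ligand@id, length(object@conformers)))
})

setMethod("show", "EnergyBreakdown", function(object) {
  v <- energyComponents(object)
  cat("EnergyBreakdown (kcal/mol):\n")
  for (nm in names(v)) cat(sprintf("  %-15s %8.3f\n", nm, v[[nm]]))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: Kd = %.3g uM (SE %.2g), f_max = %.3g (SE %.2g), N = %g\n",
              object@kd, object@standardErrors[["kd"]],
              object@fMax, object@standardErrors[["fMax"]], object@n))
})

setMethod("show", "PharmacophoreReport", function(object) {
  cat(sprintf("PharmacophoreReport: %s\n",
              if (object@passes) "PASS" else
                paste("FAIL:", paste(object@failureReasons, collapse = ", "))))
  cat(sprintf("  %d H-bond contact(s), %d stacking contact(s), span %d strand(s)\n",
              nrow(object@hbondContacts), nrow(object@stackContacts),
              object@strandsSpanned))
})
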