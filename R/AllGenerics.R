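# Accessor generics. Slot access from user code goes through these.

#' Number of titration points in a series
#' @param x a \linkS4class{TitrationSeries}
#' @return integer count
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "TitrationSeries", function(x) length(x@peaks))

#' Peak list of one titration point
#' @param x a \linkS4class{TitrationSeries}
#' @param i point index (1 = free reference)
#' @return data frame with columns residue, deltaH, deltaN (ppm)
#' @export
setGeneric("peakList", function(x, i) standardGeneric("peakList"))

#' @rdname peakList
#' @export
setMethod("peakList", "TitrationSeries", function(x, i) x@peaks[[i]])

#' Total protein / ligand concentrations of a titration series
#' @param x a \linkS4class{TitrationSeries}
#' @return numeric vector in micromolar, one entry per point
#' @export
setGeneric("proteinTotal", function(x) standardGeneric("proteinTotal"))

#' @rdname proteinTotal
#' @export
setMethod("proteinTotal", "TitrationSeries", function(x) x@proteinTotal)

#' @rdname proteinTotal
#' @export
setGeneric("ligandTotal", function(x) standardGeneric("ligandTotal"))

#' @rdname proteinTotal
#' @export
setMethod("ligandTotal", "TitrationSeries", function(x) x@ligandTotal)

#' Relaxation delay grid
#' @param x a \linkS4class{RelaxationSeries}
#' @return numeric vector of delays in seconds
#' @export
setGeneric("delays", function(x) standardGeneric("delays"))

#' @rdname delays
#' @export
setMethod("delays", "RelaxationSeries", function(x) x@delays)

#' Intensity table of a relaxation series
#' @param x a \linkS4class{RelaxationSeries}
#' @return numeric matrix (residues by delays, or sat/unsat columns)
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "RelaxationSeries", function(x) x@intensities)

#' Number of models in an ensemble
#' @param x a \linkS4class{StructureEnsemble}
#' @return integer count
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname nModels
#' @export
setMethod("nModels", "StructureEnsemble", function(x) dim(x@coords)[3])

#' Shared atom inventory of an ensemble
#' @param x a \linkS4class{StructureEnsemble}
#' @return data frame with residueId, residueName, atomName
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "StructureEnsemble", function(x) x@atoms)

#' Coordinates of one model
#' @param x a \linkS4class{StructureEnsemble}
#' @param i model index; if missing, the full nAtoms x 3 x nModels array
#' @return numeric matrix (or array) in Angstrom
#' @export
setGeneric("modelCoords", function(x, i) standardGeneric("modelCoords"))

#' @rdname modelCoords
#' @export
setMethod("modelCoords", "StructureEnsemble", function(x, i) {
  if (missing(i)) x@coords else x@coords[, , i, drop = TRUE]
})

#' Fitted dissociation constant
#' @param object a \linkS4class{BindingFit}
#' @return Kd in micromolar (named vector in per-residue mode)
#' @export
setGeneric("kdValue", function(object) standardGeneric("kdValue"))

#' @rdname kdValue
#' @export
setMethod("kdValue", "BindingFit", function(object) object@kd)

#' Fitted maximal CSPs
#' @param object a \linkS4class{BindingFit}
#' @return named numeric, ppm at saturation per residue
#' @export
setGeneric("cspMax", function(object) standardGeneric("cspMax"))

#' @rdname cspMax
#' @export
setMethod("cspMax", "BindingFit", function(object) object@cspMax)
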