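#' Number of fluxes (ambient dimension D)
#' @param x a polytope object.
#' @export
setGeneric("nFluxes", function(x) standardGeneric("nFluxes"))

#' Effective dimension d of a polytope
#' @param x a polytope object.
#' @export
setGeneric("effectiveDim", function(x) standardGeneric("effectiveDim"))

#' Inequality constraint matrix
#' @param x a polytope object.
#' @export
setGeneric("ineqMatrix", function(x) standardGeneric("ineqMatrix"))

#' Inequality right-hand side
#' @param x a polytope object.
#' @export
setGeneric("ineqBound", function(x) standardGeneric("ineqBound"))

#' Equality constraint matrix
#' @param x a polytope object.
#' @export
setGeneric("eqMatrix", function(x) standardGeneric("eqMatrix"))

#' Equality right-hand side
#' @param x a polytope object.
#' @export
setGeneric("eqBound", function(x) standardGeneric("eqBound"))

#' Flux identifiers
#' @param x an object carrying flux names.
#' @export
setGeneric("fluxNames", function(x) standardGeneric("fluxNames"))

#' Null-space basis of the equality system
#' @param x a reduced polytope.
#' @export
setGeneric("nullBasis", function(x) standardGeneric("nullBasis"))

#' Particular interior solution in flux space
#' @param x a reduced polytope.
#' @export
setGeneric("particularSolution", function(x) standardGeneric("particularSolution"))

#' Stored samples in original flux coordinates
#' @param x a \linkS4class{FluxSampleSet}.
#' @param drop unused.
#' @export
setGeneric("originalSamples", function(x, drop = FALSE) standardGeneric("originalSamples"))

#' Stored samples in rounded coordinates
#' @param x a \linkS4class{FluxSampleSet}.
#' @export
setGeneric("roundedSamples", function(x) standardGeneric("roundedSamples"))
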