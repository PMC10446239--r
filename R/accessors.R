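#' @describeIn nFluxes for raw/preprocessed polytopes
#' @export
setMethod("nFluxes", "FluxPolytope", function(x) ncol(x@Ain))

#' @describeIn nFluxes for reduced polytopes
#' @export
setMethod("nFluxes", "ReducedPolytope", function(x) nrow(x@K))

#' @describeIn nFluxes for rounded polytopes
#' @export
setMethod("nFluxes", "RoundedPolytope", function(x) nrow(x@parent@K))

#' @describeIn effectiveDim raw polytope: D minus rank of the equality system
#' @export
setMethod("effectiveDim", "FluxPolytope", function(x) {
  if (nrow(x@Aeq) == 0L) return(ncol(x@Ain))
  ncol(x@Ain) - qr(x@Aeq)$rank
})

#' @describeIn effectiveDim reduced polytope
#' @export
setMethod("effectiveDim", "ReducedPolytope", function(x) ncol(x@A))

#' @describeIn effectiveDim rounded polytope
#' @export
setMethod("effectiveDim", "RoundedPolytope", function(x) ncol(x@A))

#' @describeIn ineqMatrix raw polytope
#' @export
setMethod("ineqMatrix", "FluxPolytope", function(x) x@Ain)
#' @describeIn ineqMatrix reduced polytope
#' @export
setMethod("ineqMatrix", "ReducedPolytope", function(x) x@A)
#' @describeIn ineqMatrix rounded polytope
#' @export
setMethod("ineqMatrix", "RoundedPolytope", function(x) x@A)

#' @describeIn ineqBound raw polytope
#' @export
setMethod("ineqBound", "FluxPolytope", function(x) x@bin)
#' @describeIn ineqBound reduced polytope
#' @export
setMethod("ineqBound", "ReducedPolytope", function(x) x@b)
#' @describeIn ineqBound rounded polytope
#' @export
setMethod("ineqBound", "RoundedPolytope", function(x) x@b)

#' @describeIn eqMatrix raw polytope
#' @export
setMethod("eqMatrix", "FluxPolytope", function(x) x@Aeq)
#' @describeIn eqBound raw polytope
#' @export
setMethod("eqBound", "FluxPolytope", function(x) x@beq)

#' @describeIn fluxNames raw polytope
#' @export
setMethod("fluxNames", "FluxPolytope", function(x) x@fluxNames)
#' @describeIn fluxNames reduced polytope
#' @export
setMethod("fluxNames", "ReducedPolytope", function(x) x@fluxNames)
#' @describeIn fluxNames sample set
#' @export
setMethod("fluxNames", "FluxSampleSet", function(x) {
  if (length(x@samplesOriginal)) colnames(x@samplesOriginal[[1L]]) else character(0)
})

#' @describeIn nullBasis reduced polytope
#' @export
setMethod("nullBasis", "ReducedPolytope", function(x) x@K)
#' @describeIn particularSolution reduced polytope
#' @export
setMethod("particularSolution", "ReducedPolytope", function(x) x@nu0)

#' @describeIn originalSamples returns an array (nChains x N x D)
#' @export
setMethod("originalSamples", "FluxSampleSet", function(x, drop = FALSE) {
  chains <- x@samplesOriginal
  if (!length(chains)) return(array(0, c(0, 0, 0)))
  a <- array(NA_real_, c(length(chains), nrow(chains[[1L]]), ncol(chains[[1L]])),
             dimnames = list(NULL, NULL, colnames(chains[[1L]])))
  for (i in seq_along(chains)) a[i, , ] <- chains[[i]]
  a
})

#' @describeIn roundedSamples list of per-chain N x d matrices (may be empty)
#' @export
setMethod("roundedSamples", "FluxSampleSet", function(x) x@samplesRounded)

#' @rdname FluxPolytope-class
#' @param object a \linkS4class{FluxPolytope}
#' @export
setMethod("show", "FluxPolytope", function(object) {
  cat(sprintf("%s: D = %d fluxes, %d equalities, %d inequalities\n",
              class(object), ncol(object@Ain), nrow(object@Aeq), nrow(object@Ain)))
  if (is(object, "PreprocessedPolytope")) {
    pv <- object@provenance
    cat(sprintf("  preprocessing: %d rows removed, %d constraints tightened\n",
                length(pv$removedRows),
                if (is.null(pv$tightened)) 0L else nrow(pv$tightened)))
  }
  invisible(object)
})

#' @rdname ReducedPolytope-class
#' @param object a \linkS4class{ReducedPolytope}
#' @export
setMethod("show", "ReducedPolytope", function(object) {
  cat(sprintf("ReducedPolytope: d = %d (D = %d), %d inequality rows\n",
              ncol(object@A), nrow(object@K), nrow(object@A)))
  invisible(object)
})

#' @rdname RoundedPolytope-class
#' @param object a \linkS4class{RoundedPolytope}
#' @export
setMethod("show", "RoundedPolytope", function(object) {
  cat(sprintf("RoundedPolytope: d = %d, %d inequality rows (unit ball inscribed)\n",
              ncol(object@A), nrow(object@A)))
  invisible(object)
})

#' @rdname Ellipsoid-class
#' @param object an \linkS4class{Ellipsoid}
#' @export
setMethod("show", "Ellipsoid", function(object) {
  ev <- eigen(object@shape, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("Ellipsoid: d = %d, axis lengths in [%.4g, %.4g]\n",
              length(object@center), min(ev), max(ev)))
  invisible(object)
})

#' @rdname FluxSampleSet-class
#' @param object a \linkS4class{FluxSampleSet}
#' @export
setMethod("show", "FluxSampleSet", function(object) {
  cfg <- object@config
  cat(sprintf("FluxSampleSet: %d chains x %d samples, D = %d (tau = %s, seed = %s)\n",
              length(object@samplesOriginal),
              if (length(object@samplesOriginal)) nrow(object@samplesOriginal[[1]]) else 0L,
              if (length(object@samplesOriginal)) ncol(object@samplesOriginal[[1]]) else 0L,
              as.character(cfg$tau %||% "?"), as.character(cfg$seed %||% "?")))
  invisible(object)
})

#' @rdname DiagnosticsReport-class
#' @param object a \linkS4class{DiagnosticsReport}
#' @export
setMethod("show", "DiagnosticsReport", function(object) {
  cat(sprintf("DiagnosticsReport: min ESS = %.1f, max R-hat = %.4f -> %s\n",
              object@essMin, object@rhatMax,
              if (isTRUE(object@converged)) "converged" else "NOT converged"))
  if (length(object@excludedFluxes))
    cat(sprintf("  %d zero-variance flux(es) excluded\n", length(object@excludedFluxes)))
  if (isTRUE(object@nonStandard))
    cat("  note: fewer than 4 chains; gate evaluated but non-standard\n")
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
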