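#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Raw flux polytope of a constraint-based model
#'
#' Holds the full D-dimensional linear system of a metabolic model: steady-state
#' mass balances \code{Aeq \%*\% nu == beq} (the extended stoichiometric system)
#' and flux bounds / physiological constraints \code{Ain \%*\% nu < bin}.
#'
#' @slot Aeq equality constraint matrix (n_eq x D).
#' @slot beq equality right-hand side.
#' @slot Ain inequality constraint matrix (n_in x D).
#' @slot bin inequality right-hand side.
#' @slot fluxNames character vector of D flux (reaction) identifiers.
#' @slot units informational flux units, e.g. \code{"mmol/gDW/h"}.
#' @export
setClass("FluxPolytope",
  representation(
    Aeq = "matrix", beq = "numeric",
    Ain = "matrix", bin = "numeric",
    fluxNames = "character", units = "character"
  ),
  prototype(units = "mmol/gDW/h")
)

setValidity("FluxPolytope", function(object) {
  msg <- character(0)
  D <- length(object@fluxNames)
  if (ncol(object@Aeq) != D && nrow(object@Aeq) > 0L)
    msg <- c(msg, "Aeq column count must equal number of fluxes")
  if (ncol(object@Ain) != D)
    msg <- c(msg, "Ain column count must equal number of fluxes")
  if (nrow(object@Aeq) != length(object@beq))
    msg <- c(msg, "beq length must match Aeq rows")
  if (nrow(object@Ain) != length(object@bin))
    msg <- c(msg, "bin length must match Ain rows")
  if (length(msg)) msg else TRUE
})

#' Preprocessed flux polytope
#'
#' A \linkS4class{FluxPolytope} after redundancy removal and tightening of
#' near-degenerate inequalities into equalities, together with a provenance
#' record of what was removed or reclassified.
#'
#' @slot provenance list with elements \code{removedRows} (indices of pruned
#'   inequality rows, in raw row numbering), \code{tightened} (data.frame of
#'   reclassified constraints with their fixed values), and \code{log}
#'   (character messages).
#' @export
setClass("PreprocessedPolytope",
  contains = "FluxPolytope",
  representation(provenance = "list"),
  prototype(provenance = list(removedRows = integer(0),
                              tightened = NULL, log = character(0)))
)

#' Dimension-reduced flux polytope
#'
#' Inequality-only polytope in d independent coordinates,
#' \code{A \%*\% x < b}, with the affine embedding back to D-space:
#' \code{nu = K \%*\% x + nu0}. The reduced-space origin is strictly interior.
#'
#' @slot A inequality matrix (n_in x d).
#' @slot b inequality right-hand side.
#' @slot K null-space basis of the equality system (D x d, orthonormal columns
#'   unless constructed as identity for problems without equalities).
#' @slot nu0 particular interior solution in D-space.
#' @slot fluxNames flux identifiers carried through.
#' @export
setClass("ReducedPolytope",
  representation(
    A = "matrix", b = "numeric",
    K = "matrix", nu0 = "numeric",
    fluxNames = "character"
  )
)

setValidity("ReducedPolytope", function(object) {
  msg <- character(0)
  if (nrow(object@A) != length(object@b))
    msg <- c(msg, "b length must match A rows")
  if (ncol(object@K) != ncol(object@A))
    msg <- c(msg, "K must have d columns")
  if (nrow(object@K) != length(object@nu0))
    msg <- c(msg, "nu0 length must match K rows")
  if (length(object@fluxNames) && length(object@fluxNames) != nrow(object@K))
    msg <- c(msg, "fluxNames length must equal D")
  slack <- object@b   # A %*% 0
  if (length(slack) && any(slack <= 0))
    msg <- c(msg, "reduced-space origin must be strictly feasible (all b > 0)")
  if (length(msg)) msg else TRUE
})

#' Inscribed ellipsoid
#'
#' The ellipsoid \code{{center + shape \%*\% u : ||u|| <= 1}} with
#' symmetric positive-definite \code{shape}.
#'
#' @slot center numeric center (length d).
#' @slot shape symmetric positive-definite d x d matrix.
#' @slot provenance list with solver iterations and residuals.
#' @export
setClass("Ellipsoid",
  representation(center = "numeric", shape = "matrix", provenance = "list"),
  prototype(provenance = list())
)

setValidity("Ellipsoid", function(object) {
  msg <- character(0)
  d <- length(object@center)
  if (!all(dim(object@shape) == c(d, d)))
    msg <- c(msg, "shape must be d x d")
  if (d > 0) {
    if (max(abs(object@shape - t(object@shape))) > 1e-8 * max(1, max(abs(object@shape))))
      msg <- c(msg, "shape must be symmetric")
    ev <- tryCatch(eigen(object@shape, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA_real_)
    if (any(is.na(ev)) || min(ev) <= 0)
      msg <- c(msg, "shape must be positive definite")
  }
  if (length(msg)) msg else TRUE
})

#' Rounding transform
#'
#' Affine change of variables making the polytope isotropic: the maximum-volume
#' inscribed ellipsoid is mapped to the unit ball at the origin. For a reduced
#' point \code{x}, the rounded coordinate is \code{R \%*\% (x - shift)}; the
#' reverse map is \code{x = Rinv \%*\% xr + shift}. Both \code{R} and
#' \code{Rinv} are symmetric positive definite (\code{Rinv} is the ellipsoid
#' shape factor).
#'
#' @slot R d x d matrix, reduced -> rounded.
#' @slot Rinv d x d matrix, rounded -> reduced (equals \code{solve(R)}).
#' @slot shift ellipsoid center in reduced coordinates.
#' @slot provenance solver metadata (iterations, residuals, tolerance).
#' @export
setClass("RoundingTransform",
  representation(R = "matrix", Rinv = "matrix", shift = "numeric",
                 provenance = "list"),
  prototype(provenance = list())
)

setValidity("RoundingTransform", function(object) {
  d <- length(object@shift)
  msg <- character(0)
  if (!all(dim(object@R) == c(d, d)) || !all(dim(object@Rinv) == c(d, d)))
    msg <- c(msg, "R and Rinv must be d x d")
  if (d > 0) {
    err <- max(abs(object@R %*% object@Rinv - diag(d)))
    if (err > 1e-8 * max(1, max(abs(object@R))))
      msg <- c(msg, "R %*% Rinv must be the identity within tolerance")
  }
  if (length(msg)) msg else TRUE
})

#' Rounded polytope
#'
#' The reduced polytope after the rounding change of variables:
#' \code{{xr : A \%*\% xr < b}} with the unit ball at the origin inscribed.
#'
#' @slot A rounded inequality matrix (n_in x d).
#' @slot b rounded right-hand side.
#' @slot transform the \linkS4class{RoundingTransform} used.
#' @slot parent the \linkS4class{ReducedPolytope} this was derived from.
#' @export
setClass("RoundedPolytope",
  representation(A = "matrix", b = "numeric",
                 transform = "RoundingTransform", parent = "ReducedPolytope")
)

setValidity("RoundedPolytope", function(object) {
  if (nrow(object@A) != length(object@b))
    return("b length must match A rows")
  TRUE
})

#' Multi-chain flux sample set
#'
#' Stored states of independent CHRRT chains, in original D-dimensional flux
#' coordinates and (optionally) rounded coordinates, together with the sampler
#' configuration and per-chain wall-clock timings.
#'
#' @slot samplesOriginal list (one per chain) of N x D matrices.
#' @slot samplesRounded list of N x d matrices, or empty list.
#' @slot config list: N, tau, nChains, seed, burninFrac, zeroTol.
#' @slot timings data.frame with one row per chain: \code{updateTime},
#'   \code{transformTime} (seconds) and \code{nUpdates}.
#' @export
setClass("FluxSampleSet",
  representation(samplesOriginal = "list", samplesRounded = "list",
                 config = "list", timings = "data.frame")
)

setValidity("FluxSampleSet", function(object) {
  msg <- character(0)
  nc <- length(object@samplesOriginal)
  if (!is.null(object@config$nChains) && nc != object@config$nChains)
    msg <- c(msg, "number of chains must match config")
  if (nc > 0) {
    dims <- vapply(object@samplesOriginal, dim, integer(2))
    if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
      msg <- c(msg, "all chains must have identical dimensions")
    if (!is.null(object@config$N) && dims[1, 1] != object@config$N)
      msg <- c(msg, "stored sample count must equal config N")
  }
  if (length(msg)) msg else TRUE
})

#' Convergence diagnostics report
#'
#' Per-flux bulk effective sample size and rank-normalized split-R-hat with
#' worst-case aggregation and the convergence gate (R-hat < 1.01 and ESS > 400).
#'
#' @slot essPerFlux named numeric vector (NA for excluded fluxes).
#' @slot rhatPerFlux named numeric vector (NA for excluded fluxes).
#' @slot essTailPerFlux tail-ESS, informational only.
#' @slot essMin worst-case (minimum) ESS over included fluxes.
#' @slot rhatMax worst-case (maximum) R-hat over included fluxes.
#' @slot converged logical verdict.
#' @slot excludedFluxes integer indices of (near-)zero-variance fluxes.
#' @slot thresholds list(rhatLimit, essLimit).
#' @slot nonStandard TRUE when fewer than 4 chains were used (gate still
#'   evaluated, flagged).
#' @export
setClass("DiagnosticsReport",
  representation(
    essPerFlux = "numeric", rhatPerFlux = "numeric",
    essTailPerFlux = "numeric",
    essMin = "numeric", rhatMax = "numeric",
    converged = "logical", excludedFluxes = "integer",
    thresholds = "list", nonStandard = "logical"
  ),
  prototype(thresholds = list(rhatLimit = 1.01, essLimit = 400),
            nonStandard = FALSE)
)
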