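#' Thinning guideline
#'
#' Ready-to-apply thinning constants: \code{2 d} for d-dimensional simplices
#' and \code{d^2 / 6} for genome-scale metabolic models (round-half-up,
#' floored at 1).
#'
#' @param kind \code{"simplex"} or \code{"gem"}.
#' @param d effective polytope dimension (>= 1).
#' @param integerize return a positive integer (round-half-up, minimum 1);
#'   set \code{FALSE} for the raw guideline value.
#' @return recommended thinning constant tau.
#' @export
guidelineTau <- function(kind = c("simplex", "gem"), d, integerize = TRUE) {
  kind <- match.arg(kind)
  d <- as.numeric(d)
  if (length(d) != 1L || !is.finite(d) || d < 1)
    stop("d must be a positive dimension", call. = FALSE)
  val <- switch(kind, simplex = 2 * d, gem = d^2 / 6)
  if (integerize) max(1, floor(val + 0.5)) else val
}

#' Previously advised thinning constant
#'
#' The earlier rule of thumb of eight times the squared polytope dimension,
#' kept for comparison; it exceeds \code{\link{guidelineTau}("gem", d)} by a
#' factor of 48.
#'
#' @param d effective polytope dimension (>= 1).
#' @return \code{8 * d^2}.
#' @export
priorAdviceTau <- function(d) {
  d <- as.numeric(d)
  if (length(d) != 1L || !is.finite(d) || d < 1)
    stop("d must be a positive dimension", call. = FALSE)
  8 * d^2
}

#' Predicted sampling cost
#'
#' Cost model \code{t = N (tau t_update + t_transform)}: storing \code{N}
#' samples at thinning \code{tau} costs \code{N tau} updates plus \code{N}
#' back-transforms.
#'
#' @param N stored samples per chain.
#' @param tau thinning constant.
#' @param profile a \code{TimingProfile} from \code{\link{measureTimeRatio}}
#'   (or any list with \code{tUpdate} and \code{tTransform} in seconds).
#' @return predicted seconds.
#' @export
predictedCost <- function(N, tau, profile) {
  stopifnot(N > 0, tau > 0, profile$tUpdate > 0, profile$tTransform >= 0)
  N * (tau * profile$tUpdate + profile$tTransform)
}

#' Measure per-operation time costs
#'
#' Wall-clock cost of one coordinate hit-and-run update and of one
#' back-transform, averaged over repeated runs on the given rounded polytope.
#'
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param nReps independent repetitions (dispersion reported across them).
#' @param nUpdates,nTransforms operations per repetition.
#' @param seed RNG seed for the probe chains.
#' @return list of class \code{"TimingProfile"}: \code{tUpdate},
#'   \code{tTransform} (mean seconds per operation), \code{ratio}
#'   (\code{tTransform / tUpdate}), \code{nReps}, \code{dispersion}
#'   (std. errors) and the per-repetition table.
#' @export
measureTimeRatio <- function(poly, nReps = 4L, nUpdates = 20000L,
                             nTransforms = 500L, seed = 1L) {
  stopifnot(is(poly, "RoundedPolytope"), nReps >= 1L)
  tau <- max(1L, as.integer(ceiling(nUpdates / nTransforms)))
  per <- data.frame(rep = seq_len(nReps), tUpdate = NA_real_,
                    tTransform = NA_real_)
  cfg <- samplerConfig(N = nTransforms, tau = tau, nChains = 1L, seed = seed)
  for (r in seq_len(nReps)) {
    res <- .runChainRaw(poly, cfg, seed = .chainSubSeed(seed, r))
    per$tUpdate[r] <- res$updateTime / res$nUpdates
    per$tTransform[r] <- res$transformTime / cfg$N
  }
  tU <- mean(per$tUpdate); tT <- mean(per$tTransform)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(tUpdate = tU, tTransform = tT, ratio = tT / tU,
              nReps = nReps,
              dispersion = c(tUpdate = se(per$tUpdate),
                             tTransform = se(per$tTransform)),
              perRep = per)
  class(out) <- "TimingProfile"
  out
}

#' @export
print.TimingProfile <- function(x, ...) {
  cat(sprintf("TimingProfile: t_update = %.3g s, t_transform = %.3g s, ratio = %.3g (n = %d)\n",
              x$tUpdate, x$tTransform, x$ratio, x$nReps))
  invisible(x)
}

#' Benchmark sampling efficiency over thinning constants
#'
#' For each thinning constant, runs independent chains, evaluates the
#' worst-case (minimum over fluxes) bulk ESS on original-space samples,
#' records the sampling wall time (updates + back-transforms only; one-time
#' rounding costs excluded) and the efficiency ESS/t, and selects the best
#' thinning constant. When \code{tau = 1} is in the sweep, relative speed-ups
#' against the unthinned baseline are reported.
#'
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param taus vector of thinning constants (positive integers).
#' @param N stored samples per chain and per thinning constant.
#' @param nChains chains per run.
#' @param seed RNG seed (shared across the sweep; chains derive sub-seeds).
#' @return list of class \code{"EfficiencyCurve"}: \code{points} (one row per
#'   tau: tau, ess, wallTime, efficiency, converged, rhat),
#'   \code{tauBest}, \code{baseline} (tau = 1 row or NULL), \code{speedupBest}
#'   (efficiency(tauBest)/efficiency(1), NA without baseline), and \code{d}.
#' @export
benchmarkEfficiency <- function(poly, taus, N = 1000L, nChains = 4L, seed = 1L) {
  stopifnot(is(poly, "RoundedPolytope"), length(taus) >= 1L)
  taus <- sort(unique(as.integer(taus)))
  stopifnot(all(taus >= 1L))
  pts <- data.frame(tau = taus, ess = NA_real_, wallTime = NA_real_,
                    efficiency = NA_real_, converged = NA, rhat = NA_real_)
  for (i in seq_along(taus)) {
    cfg <- samplerConfig(N = N, tau = taus[i], nChains = nChains, seed = seed)
    ss <- runChains(poly, cfg)
    dg <- evaluateConvergence(ss)
    wall <- sum(ss@timings$updateTime) + sum(ss@timings$transformTime)
    pts$ess[i] <- dg@essMin
    pts$rhat[i] <- dg@rhatMax
    pts$wallTime[i] <- wall
    pts$efficiency[i] <- dg@essMin / wall
    pts$converged[i] <- dg@converged
  }
  best <- which.max(pts$efficiency)
  baseline <- if (any(pts$tau == 1L)) pts[pts$tau == 1L, ] else NULL
  out <- list(points = pts, tauBest = pts$tau[best],
              baseline = baseline,
              speedupBest = if (!is.null(baseline))
                pts$efficiency[best] / baseline$efficiency else NA_real_,
              d = effectiveDim(poly), N = N, nChains = nChains, seed = seed)
  class(out) <- "EfficiencyCurve"
  out
}

#' @export
print.EfficiencyCurve <- function(x, ...) {
  cat(sprintf("EfficiencyCurve (d = %d, N = %d x %d chains): best tau = %d\n",
              x$d, x$N, x$nChains, x$tauBest))
  if (!is.na(x$speedupBest))
    cat(sprintf("  speed-up vs unthinned baseline: %.1fx\n", x$speedupBest))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Candidate thinning constants from a pre-run
#'
#' Runs a short chain sweep at \code{tau = d}, estimates the integrated
#' autocorrelation time (in update units) from the worst-case ESS, and emits
#' at least five strictly increasing log-spaced candidate thinning constants
#' bracketing it; \code{tau = d} itself is always included.
#'
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param N stored samples per chain for the pre-run.
#' @param nChains chains.
#' @param seed RNG seed.
#' @param nCandidates minimum number of candidates.
#' @return increasing vector of positive integer thinning constants.
#' @export
preRunTauRange <- function(poly, N = 500L, nChains = 4L, seed = 1L,
                           nCandidates = 5L) {
  d <- effectiveDim(poly)
  cfg <- samplerConfig(N = N, tau = d, nChains = nChains, seed = seed)
  ss <- runChains(poly, cfg)
  dg <- evaluateConvergence(ss)
  nTotal <- N * nChains
  # integrated autocorrelation time of the stored (thinned-by-d) sequence,
  # re-expressed in update units
  iactUpdates <- max(1, d * nTotal / max(dg@essMin, 1))
  lo <- max(1, iactUpdates / 8)
  hi <- iactUpdates * 8
  cand <- unique(round(exp(seq(log(lo), log(hi),
                               length.out = max(nCandidates, 5L)))))
  cand <- sort(unique(c(as.integer(cand), as.integer(d))))
  cand[cand >= 1L]
}
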