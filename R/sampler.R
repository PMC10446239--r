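#' Sampler configuration
#'
#' Validated configuration for CHRRT runs.
#'
#' @param N number of samples to store per chain (>= 1).
#' @param tau thinning constant: updates per stored sample (>= 1). See
#'   \code{\link{guidelineTau}} for recommended values.
#' @param nChains number of independent chains (default 4, the recommended
#'   setup for the rank-normalized diagnostics).
#' @param seed integer seed; per-chain sub-seeds are derived deterministically.
#' @param start optional rounded-space starting state (default: the origin of
#'   the rounded polytope, i.e. the inscribed-ellipsoid center).
#' @param zeroTol tolerance below which chord coefficients count as zero.
#' @param burninFrac fraction of additional initial stored samples to discard
#'   (default 0; no burn-in is applied by default).
#' @param storeRounded also keep rounded-space states.
#' @return a validated list of class \code{"SamplerConfig"}.
#' @export
samplerConfig <- function(N, tau, nChains = 4L, seed = 1L, start = NULL,
                          zeroTol = 1e-12, burninFrac = 0,
                          storeRounded = FALSE) {
  N <- as.integer(N); nChains <- as.integer(nChains)
  stopifnot(N >= 1L, tau >= 1, nChains >= 1L,
            burninFrac >= 0, burninFrac < 1, zeroTol > 0)
  tau <- floor(tau)
  cfg <- list(N = N, tau = tau, nChains = nChains, seed = as.integer(seed),
              start = start, zeroTol = zeroTol, burninFrac = burninFrac,
              storeRounded = storeRounded)
  class(cfg) <- "SamplerConfig"
  cfg
}

#' Chord bounds along a coordinate
#'
#' Feasible step range \code{(dminus, dplus)} such that
#' \code{x + lambda * e_k} stays in the polytope for all
#' \code{lambda in (dminus, dplus)}: \code{dplus} is the minimum of
#' \code{slack_j / c_j} over rows with coefficient \code{c_j > zeroTol}, and
#' \code{dminus} the maximum over rows with \code{c_j < -zeroTol}.
#'
#' @param poly a \linkS4class{RoundedPolytope} (or any object with
#'   \code{ineqMatrix}/\code{ineqBound} methods).
#' @param x current state (strictly feasible).
#' @param k coordinate index in \code{1..d}.
#' @param zeroTol coefficient zero tolerance.
#' @return numeric \code{c(dminus, dplus)} with \code{dminus <= 0 <= dplus}.
#' @export
chordBounds <- function(poly, x, k, zeroTol = 1e-12) {
  A <- ineqMatrix(poly); b <- ineqBound(poly)
  d <- ncol(A)
  stopifnot(k >= 1L, k <= d, length(x) == d)
  s <- b - as.numeric(A %*% x)
  if (min(s) < -1e-9)
    stop("state is not feasible (negative slack beyond tolerance)", call. = FALSE)
  s[s < 0] <- 0
  ck <- A[, k]
  pos <- ck > zeroTol
  neg <- ck < -zeroTol
  if (!any(pos))
    stop("unbounded chord along coordinate ", k,
         " (no positive coefficient): polytope contract violated", call. = FALSE)
  if (!any(neg))
    stop("unbounded chord along coordinate ", k,
         " (no negative coefficient): polytope contract violated", call. = FALSE)
  c(dminus = max(s[neg] / ck[neg]), dplus = min(s[pos] / ck[pos]))
}

#' Single coordinate hit-and-run update
#'
#' Draws a coordinate \code{k} uniformly from \code{1..d} and a step
#' \code{lambda} uniformly from the feasible chord, then moves
#' \code{x <- x + lambda * e_k}. Consumes exactly two uniform draws from R's
#' RNG stream, matching the compiled chain loop, so seed-matched sequences are
#' identical between this function and \code{\link{runChain}}.
#'
#' @param state list with elements \code{x} (numeric, length d) and \code{i}
#'   (update counter).
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param zeroTol chord coefficient tolerance.
#' @return the updated state list.
#' @export
chrrtUpdate <- function(state, poly, zeroTol = 1e-12) {
  d <- ncol(ineqMatrix(poly))
  u1 <- stats::runif(1)
  k <- min(floor(u1 * d) + 1L, d)
  bounds <- chordBounds(poly, state$x, k, zeroTol = zeroTol)
  u2 <- stats::runif(1)
  lam <- bounds[[1L]] + u2 * (bounds[[2L]] - bounds[[1L]])
  state$x[k] <- state$x[k] + lam
  state$i <- (state$i %||% 0L) + 1L
  state
}

.chainSubSeed <- function(seed, chain) {
  s <- (as.double(seed) + 10007 * (as.double(chain) - 1)) %% 2147483647
  as.integer(s)
}

.runChainRaw <- function(poly, config, seed, warmup = 0L) {
  op <- backTransformOperator(poly)
  d <- ncol(ineqMatrix(poly))
  start <- config$start %||% numeric(d)
  if (length(start) != d)
    stop("start vector must have length d = ", d, call. = FALSE)
  burn <- floor(config$burninFrac * config$N)
  set.seed(seed)
  res <- .cpp_chrrt_chain(ineqMatrix(poly), ineqBound(poly), start,
                          config$N + burn, config$tau, op$M, op$c,
                          config$storeRounded, config$zeroTol,
                          as.integer(warmup))
  keep <- (burn + 1L):(burn + config$N)
  orig <- res$original[keep, , drop = FALSE]
  colnames(orig) <- poly@parent@fluxNames
  rounded <- if (config$storeRounded) res$rounded[keep, , drop = FALSE] else NULL
  list(original = orig, rounded = rounded,
       nUpdates = res$nUpdates, updateTime = res$updateTime,
       transformTime = res$transformTime)
}

#' Run a single CHRRT chain
#'
#' Coordinate hit-and-run on the rounded polytope with fixed-frequency
#' thinning: a sample is stored after every \code{tau}-th update (the first
#' store happens at update \code{tau}), so exactly \code{N * tau} updates are
#' performed for \code{N} stored samples. Each stored state is back-transformed
#' to original flux coordinates at storage time.
#'
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param config a \code{\link{samplerConfig}}.
#' @return list with \code{original} (N x D matrix), \code{rounded} (N x d or
#'   \code{NULL}), \code{nUpdates}, and wall-clock \code{updateTime} /
#'   \code{transformTime} in seconds.
#' @export
runChain <- function(poly, config) {
  stopifnot(is(poly, "RoundedPolytope"), inherits(config, "SamplerConfig"))
  .runChainRaw(poly, config, seed = config$seed, warmup = 0L)
}

#' Run independent parallel CHRRT chains
#'
#' Chains use deterministically derived sub-seeds. Chain 1 starts from the
#' configured start (default: rounded-space origin); chains 2..M are jittered
#' by a short warm run of d updates under their own sub-seed so that chains do
#' not coincide at t = 0.
#'
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param config a \code{\link{samplerConfig}}.
#' @return a \linkS4class{FluxSampleSet}.
#' @export
runChains <- function(poly, config) {
  stopifnot(is(poly, "RoundedPolytope"), inherits(config, "SamplerConfig"))
  d <- ncol(ineqMatrix(poly))
  chains <- vector("list", config$nChains)
  roundedChains <- vector("list", config$nChains)
  timings <- data.frame(chain = seq_len(config$nChains), nUpdates = NA_real_,
                        updateTime = NA_real_, transformTime = NA_real_)
  for (cix in seq_len(config$nChains)) {
    r <- .runChainRaw(poly, config, seed = .chainSubSeed(config$seed, cix),
                      warmup = if (cix > 1L) d else 0L)
    chains[[cix]] <- r$original
    roundedChains[[cix]] <- r$rounded
    timings$nUpdates[cix] <- r$nUpdates
    timings$updateTime[cix] <- r$updateTime
    timings$transformTime[cix] <- r$transformTime
  }
  new("FluxSampleSet",
      samplesOriginal = chains,
      samplesRounded = if (config$storeRounded) roundedChains else list(),
      config = unclass(config), timings = timings)
}
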