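## MCMC convergence diagnostics: autocorrelation, bulk/tail effective sample
## size and rank-normalized split-R-hat (split chains, folded variant), with
## worst-case aggregation over fluxes and the convergence gate
## (R-hat < 1.01 and ESS > 400 for four chains).

# biased (1/n) autocovariance via FFT
.acov <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  npad <- stats::nextn(2L * n)
  f <- stats::fft(c(xc, rep(0, npad - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] /
    (as.numeric(npad) * n)
}

#' Autocorrelation function of a sequence
#'
#' Normalized autocovariance estimated with the FFT; \code{rho[1]} is lag 0
#' (always 1).
#'
#' @param x numeric sequence of length >= 4.
#' @param lagMax largest lag to return (default \code{length(x) - 1}).
#' @return numeric vector of autocorrelations at lags \code{0..lagMax}.
#' @export
autocorrelation <- function(x, lagMax = length(x) - 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("sequence too short (need length >= 4)", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in sequence", call. = FALSE)
  ac <- .acov(x)
  if (ac[1L] <= 0 || !is.finite(ac[1L]))
    stop("degenerate sequence: zero variance", call. = FALSE)
  lagMax <- min(lagMax, n - 1L)
  (ac / ac[1L])[seq_len(lagMax + 1L)]
}

# split each column (chain) into first/second half; drops the middle draw
# when the chain length is odd
.splitChains <- function(X) {
  n <- nrow(X)
  n2 <- n %/% 2L
  cbind(X[seq_len(n2), , drop = FALSE],
        X[(n - n2 + 1L):n, , drop = FALSE])
}

# rank-normalization over the pooled draws (average ranks, normal scores)
.rankNormalize <- function(X) {
  S <- length(X)
  z <- stats::qnorm((rank(as.numeric(X), ties.method = "average") - 3 / 8) /
                      (S - 1 / 4))
  matrix(z, nrow = nrow(X), ncol = ncol(X))
}

# split-R-hat on a draws x chains matrix (no transformation applied here)
.rhatCore <- function(X) {
  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(X)
  s2 <- apply(X, 2L, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  varPlus <- (n - 1) / n * W + B / n
  if (W <= 0) return(NA_real_)
  sqrt(varPlus / W)
}

# combined-chain ESS (Vehtari et al. estimator with Geyer initial-monotone
# truncation) on a draws x chains matrix
.essCore <- function(X) {
  n <- nrow(X); m <- ncol(X)
  if (n < 4L) stop("chains too short for ESS (need >= 4 draws)", call. = FALSE)
  acovs <- matrix(0, n, m)
  for (j in seq_len(m)) acovs[, j] <- .acov(X[, j])
  chainVar <- acovs[1L, ] * n / (n - 1)
  W <- mean(chainVar)
  if (W <= 0 || !is.finite(W))
    stop("degenerate chains: zero variance", call. = FALSE)
  if (m > 1L) {
    B <- n * stats::var(colMeans(X))
    varPlus <- (n - 1) / n * W + B / n
  } else {
    # single chain, no splitting: reduces to the plain normalized
    # autocorrelation of the sequence
    varPlus <- acovs[1L, 1L]
    W <- acovs[1L, 1L]
  }
  meanAcov <- rowMeans(acovs)
  rho <- 1 - (W - meanAcov) / varPlus
  rho[1L] <- 1
  # Geyer pairs: P_k = rho_{2k} + rho_{2k+1}
  maxPairs <- (n - 1L) %/% 2L
  tauHat <- NA_real_
  P <- numeric(0)
  if (maxPairs >= 1L) {
    k <- seq_len(maxPairs)
    P <- rho[2L * k - 1L] + rho[2L * k]     # lags (2k-2, 2k-1), 1-based index
  }
  # initial positive sequence
  K <- length(P)
  firstNeg <- which(P <= 0)
  if (length(firstNeg)) K <- firstNeg[1L] - 1L
  if (K < 1L) {
    tauHat <- 1
  } else {
    Pk <- P[seq_len(K)]
    Pk <- cummin(Pk)                         # initial monotone sequence
    tauHat <- max(-1 + 2 * sum(Pk), 1 / 50)  # guard against tiny/negative tau
  }
  n * m / tauHat
}

#' Effective sample size
#'
#' Bulk effective sample size of one or several chains. By default the
#' split-chain (50/50), rank-normalized estimator with Geyer initial-monotone
#' truncation of the autocorrelation sum is used. With \code{split = FALSE} and
#' \code{rankNormalized = FALSE} on a single chain the estimator reduces to the
#' classical \code{N / (1 + 2 sum_t rho_t)} with truncated lag sum.
#'
#' @param chains numeric vector (one chain) or N x M matrix (one chain per
#'   column).
#' @param split split each chain 50/50 before estimation.
#' @param rankNormalized transform draws to normal scores of pooled ranks.
#' @return scalar ESS estimate (total across chains).
#' @export
ess <- function(chains, split = TRUE, rankNormalized = TRUE) {
  X <- if (is.matrix(chains)) chains else matrix(as.numeric(chains), ncol = 1L)
  if (nrow(X) < 8L) stop("need at least 8 draws per chain", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite draws", call. = FALSE)
  if (stats::var(as.numeric(X)) <= 0)
    stop("degenerate chains: zero variance", call. = FALSE)
  if (split) X <- .splitChains(X)
  if (rankNormalized) X <- .rankNormalize(X)
  .essCore(X)
}

#' Tail effective sample size (informational)
#'
#' Minimum of the ESS of the 5\% and 95\% quantile indicator sequences,
#' reported alongside the bulk ESS but not used by the convergence gate.
#'
#' @inheritParams ess
#' @return scalar tail-ESS estimate.
#' @export
essTail <- function(chains) {
  X <- if (is.matrix(chains)) chains else matrix(as.numeric(chains), ncol = 1L)
  qs <- stats::quantile(as.numeric(X), c(0.05, 0.95), names = FALSE)
  vals <- vapply(qs, function(q) {
    I <- matrix(as.numeric(X <= q), nrow = nrow(X))
    if (stats::var(as.numeric(I)) <= 0) return(NA_real_)
    ess(I, split = TRUE, rankNormalized = TRUE)
  }, numeric(1))
  min(vals, na.rm = TRUE)
}

#' Rank-normalized split-R-hat
#'
#' Maximum of the rank-normalized split-R-hat of the draws and of the folded
#' draws (absolute deviations from the pooled median); values near 1 indicate
#' mixing, the convergence gate requires \code{< 1.01}.
#'
#' @param chains numeric vector or N x M matrix (one chain per column).
#' @return scalar R-hat estimate (>= 1 up to estimator noise).
#' @export
rankNormalizedRhat <- function(chains) {
  X <- if (is.matrix(chains)) chains else matrix(as.numeric(chains), ncol = 1L)
  if (nrow(X) < 4L) stop("need at least 4 draws per chain", call. = FALSE)
  if (stats::var(as.numeric(X)) <= 0)
    stop("degenerate chains: zero variance", call. = FALSE)
  Xs <- .splitChains(X)
  bulk <- .rhatCore(.rankNormalize(Xs))
  folded <- .rhatCore(.rankNormalize(abs(Xs - stats::median(Xs))))
  max(bulk, folded)
}

#' Evaluate the convergence gate on a sample set
#'
#' Computes per-flux bulk ESS and rank-normalized split-R-hat on the
#' original-space (D-dimensional) samples, aggregates the worst case (minimum
#' ESS, maximum R-hat) over fluxes, and applies the gate
#' \code{R-hat < rhatLimit} and \code{ESS > essLimit}. The default ESS limit of
#' 400 is the requirement of 50 effective draws per split-half for each of 4
#' chains (4 x 2 x 50). Fluxes with pooled variance below \code{varTol}
#' (e.g. fixed by tightening) are excluded and listed rather than failing the
#' gate.
#'
#' @param samples a \linkS4class{FluxSampleSet} (original-space samples
#'   required), or an nChains x N x D array.
#' @param rhatLimit,essLimit gate thresholds.
#' @param varTol absolute variance threshold for excluding degenerate fluxes.
#' @param space \code{"original"} (default, the space in which flux statistics
#'   are reported) or \code{"rounded"} (debugging; requires stored rounded
#'   samples).
#' @return a \linkS4class{DiagnosticsReport}.
#' @export
evaluateConvergence <- function(samples, rhatLimit = 1.01, essLimit = 400,
                                varTol = 1e-14, space = c("original", "rounded")) {
  space <- match.arg(space)
  if (is(samples, "FluxSampleSet")) {
    chains <- if (space == "original") samples@samplesOriginal else {
      if (!length(samples@samplesRounded))
        stop("no rounded-space samples stored; rerun with storeRounded = TRUE",
             call. = FALSE)
      samples@samplesRounded
    }
  } else if (is.array(samples) && length(dim(samples)) == 3L) {
    chains <- lapply(seq_len(dim(samples)[1L]), function(i) samples[i, , ])
  } else stop("samples must be a FluxSampleSet or a 3-d array", call. = FALSE)

  M <- length(chains)
  D <- ncol(chains[[1L]])
  fluxIds <- colnames(chains[[1L]]) %||% paste0("v", seq_len(D))
  essV <- rhatV <- tailV <- stats::setNames(rep(NA_real_, D), fluxIds)
  excluded <- integer(0)
  for (j in seq_len(D)) {
    X <- vapply(chains, function(ch) ch[, j], numeric(nrow(chains[[1L]])))
    if (stats::var(as.numeric(X)) < varTol) {
      excluded <- c(excluded, j)
      next
    }
    essV[j] <- ess(X)
    rhatV[j] <- rankNormalizedRhat(X)
    tailV[j] <- essTail(X)
  }
  included <- setdiff(seq_len(D), excluded)
  if (!length(included))
    stop("all fluxes are degenerate (zero variance)", call. = FALSE)
  essMin <- min(essV[included])
  rhatMax <- max(rhatV[included])
  new("DiagnosticsReport",
      essPerFlux = essV, rhatPerFlux = rhatV, essTailPerFlux = tailV,
      essMin = essMin, rhatMax = rhatMax,
      converged = (rhatMax < rhatLimit) && (essMin > essLimit),
      excludedFluxes = as.integer(excluded),
      thresholds = list(rhatLimit = rhatLimit, essLimit = essLimit),
      nonStandard = M < 4L)
}
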