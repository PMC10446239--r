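#' Maximum-volume inscribed ellipsoid
#'
#' Computes the maximum-volume ellipsoid \code{{c + E u : ||u|| <= 1}}
#' inscribed in the reduced polytope \code{{x : A x <= b}} by solving the
#' log-det maximization \code{max log det E} subject to
#' \code{||E a_i|| + a_i . c <= b_i} with a primal-dual Newton interior-point
#' method on the dual-weight KKT system (at the optimum
#' \code{E^2 = (A' Y A)^-1} for dual weights \code{y}).
#'
#' @param poly a \linkS4class{ReducedPolytope} (or \code{A} matrix with
#'   \code{b} supplied via \code{bvec}).
#' @param tol duality-gap tolerance on the log-volume (relative); the KKT
#'   residuals are driven below \code{1e-9} as well.
#' @param maxIter Newton iteration cap.
#' @param bvec right-hand side when \code{poly} is a plain matrix.
#' @return an \linkS4class{Ellipsoid}; its \code{provenance} records
#'   iterations and final residuals.
#' @export
computeMVE <- function(poly, tol = 1e-6, maxIter = 200L, bvec = NULL) {
  if (is(poly, "ReducedPolytope")) {
    A <- poly@A; b <- poly@b
  } else {
    A <- as.matrix(poly); b <- as.numeric(bvec)
  }
  m <- nrow(A); d <- ncol(A)
  stopifnot(m >= d + 1L)

  # strictly interior starting point; row-normalize so slacks at x0 become 1
  cc <- chebyshevCenter(A, b)
  x0 <- cc$center
  s0 <- b - as.numeric(A %*% x0)
  if (min(s0) <= 0) stop("interior starting point not strictly feasible", call. = FALSE)
  bnrm <- sqrt(sum(b^2))
  At <- A / s0                       # At %*% (v - x0) <= 1

  # primal-dual Newton on the KKT system of the log-det program; the dual
  # weights satisfy E^2 = (At' Y At)^-1 at the optimum. Damped steps with
  # fraction-to-boundary caps; mu driven to minmu.
  minmu <- 1e-14
  tau0 <- 0.75
  rtol <- min(tol, 1e-9)

  x <- numeric(d)
  y <- rep(1, m)
  bmAx <- rep(1, m)
  z <- numeric(m)
  h <- numeric(m)
  converged <- FALSE
  res <- Inf
  iter <- 0L
  E2 <- diag(1, d)

  while (iter < maxIter) {
    iter <- iter + 1L
    Wm <- crossprod(At * y, At)
    E2 <- tryCatch(solve(Wm), error = function(e)
      stop("dual normal matrix singular while solving for the inscribed ellipsoid",
           call. = FALSE))
    E2 <- (E2 + t(E2)) / 2
    Q <- At %*% E2 %*% t(At)
    h <- sqrt(pmax(diag(Q), 1e-300))
    if (iter == 1L) {
      t0 <- min(bmAx / h)
      y <- y / t0^2
      h <- t0 * h
      Q <- t0^2 * Q
      E2 <- t0^2 * E2
      z <- pmax(0.1, bmAx - h)
    }
    yz <- y * z
    yh <- y * h
    gap <- sum(yz) / m
    rmu <- max(min(0.5, gap) * gap, minmu)

    R1 <- -as.numeric(crossprod(At, yh))
    R2 <- bmAx - h - z
    R3 <- rmu - yz
    res <- max(max(abs(R1)), max(abs(R2)), max(abs(R3)))
    if (res < rtol * (1 + bnrm) && rmu <= 10 * minmu) {
      converged <- TRUE
      break
    }

    YQ <- y * Q                       # rows scaled by y
    YQQY <- YQ * t(YQ)                # y_i Q_ij^2 y_j
    y2h <- 2 * yh
    G <- YQQY + diag(pmax(1e-12, y2h * z), m)
    YA <- y * At
    Tm <- solve(G, (h + z) * YA)
    ATP <- t(y2h * Tm - YA)
    R3Dy <- R3 / y
    R23 <- R2 - R3Dy
    dx <- tryCatch(solve(ATP %*% At, R1 + as.numeric(ATP %*% R23)),
                   error = function(e)
                     stop("Newton system singular in MVE solver at iteration ",
                          iter, call. = FALSE))
    Adx <- as.numeric(At %*% dx)
    dyDy <- as.numeric(solve(G, y2h * (Adx - R23)))
    dy <- y * dyDy
    dz <- R3Dy - z * dyDy

    ax <- -1 / min(min(-Adx / bmAx), -0.5)
    ay <- -1 / min(min(dyDy), -0.5)
    az <- -1 / min(min(dz / z), -0.5)
    astep <- max(tau0, 1 - res) * min(1, ax, ay, az)

    x <- x + astep * dx
    y <- pmax(y + astep * dy, .Machine$double.xmin)
    z <- pmax(z + astep * dz, .Machine$double.xmin)
    bmAx <- 1 - as.numeric(At %*% x)
    if (min(bmAx) <= 0)
      stop("MVE iterate left the polytope interior (numerical failure)",
           call. = FALSE)
  }
  if (!converged)
    stop(sprintf(paste0("inscribed-ellipsoid solver did not converge in %d ",
                        "iterations (residual %.3e)"), maxIter, res),
         call. = FALSE)

  eg <- eigen(E2, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop("computed ellipsoid shape is not positive definite", call. = FALSE)
  E <- eg$vectors %*% (sqrt(eg$values) * t(eg$vectors))
  E <- (E + t(E)) / 2
  new("Ellipsoid", center = x0 + x, shape = E,
      provenance = list(iterations = iter, residual = res, tol = tol))
}

#' Build the rounding transform and rounded polytope
#'
#' From an inscribed maximum-volume ellipsoid \code{{c + E u}}, the rounding
#' map sends a reduced point \code{x} to \code{xr = R (x - c)} with
#' \code{R = E^-1}, so the ellipsoid becomes the unit ball at the origin. The
#' rounded system is \code{A_R = A Rinv}, \code{b_R = b - A c} (rows are not
#' re-normalized unless \code{scaleRows = TRUE}).
#'
#' @param ellipsoid an \linkS4class{Ellipsoid} inscribed in \code{poly}.
#' @param poly the \linkS4class{ReducedPolytope}.
#' @param scaleRows optionally rescale rounded rows to unit norm (numerical
#'   hygiene; geometry unchanged).
#' @return a \linkS4class{RoundedPolytope}.
#' @export
buildRounding <- function(ellipsoid, poly, scaleRows = FALSE) {
  stopifnot(is(ellipsoid, "Ellipsoid"), is(poly, "ReducedPolytope"))
  E <- ellipsoid@shape
  eg <- eigen(E, symmetric = TRUE)
  if (min(eg$values) <= 1e-14 * max(eg$values))
    stop("singular ellipsoid shape matrix; cannot build rounding transform",
         call. = FALSE)
  R <- eg$vectors %*% ((1 / eg$values) * t(eg$vectors))
  R <- (R + t(R)) / 2
  tr <- new("RoundingTransform", R = R, Rinv = E, shift = ellipsoid@center,
            provenance = ellipsoid@provenance)
  AR <- poly@A %*% E
  bR <- poly@b - as.numeric(poly@A %*% ellipsoid@center)
  if (scaleRows) {
    nr <- sqrt(rowSums(AR^2))
    nr[nr < 1e-300] <- 1
    AR <- AR / nr
    bR <- bR / nr
  }
  new("RoundedPolytope", A = AR, b = bR, transform = tr, parent = poly)
}

#' Affine back-transform operator
#'
#' Precomputes the dense operator of the back-transformation
#' \code{nu = (K Rinv) xr + (K shift + nu0)} so repeated application costs one
#' D x d matrix-vector product plus a vector addition per sample.
#'
#' @param poly a \linkS4class{RoundedPolytope}.
#' @return list with matrix \code{M} (D x d) and offset \code{c} (length D).
#' @export
backTransformOperator <- function(poly) {
  stopifnot(is(poly, "RoundedPolytope"))
  parent <- poly@parent
  tr <- poly@transform
  M <- parent@K %*% tr@Rinv
  cvec <- as.numeric(parent@K %*% tr@shift) + parent@nu0
  list(M = M, c = cvec)
}

#' Back-transform a rounded-space sample to flux coordinates
#'
#' @param xRound numeric vector of length d (a rounded-space state).
#' @param poly a \linkS4class{RoundedPolytope}.
#' @param op optional precomputed \code{\link{backTransformOperator}}.
#' @return named flux vector of length D.
#' @export
backTransform <- function(xRound, poly, op = backTransformOperator(poly)) {
  xRound <- as.numeric(xRound)
  if (length(xRound) != ncol(op$M))
    stop("dimension mismatch: expected length ", ncol(op$M), call. = FALSE)
  stats::setNames(as.numeric(op$M %*% xRound) + op$c, poly@parent@fluxNames)
}

#' Back-transform a batch of rounded-space samples
#'
#' Row-wise identical (bit-for-bit) to repeated \code{\link{backTransform}}
#' calls.
#'
#' @param X matrix (n x d) of rounded-space states.
#' @param poly a \linkS4class{RoundedPolytope}.
#' @return matrix (n x D) of flux vectors.
#' @export
batchedBackTransform <- function(X, poly) {
  X <- as.matrix(X)
  op <- backTransformOperator(poly)
  if (ncol(X) != ncol(op$M) && nrow(X) > 0L)
    stop("dimension mismatch: expected ", ncol(op$M), " columns", call. = FALSE)
  D <- nrow(op$M)
  out <- matrix(NA_real_, nrow(X), D,
                dimnames = list(NULL, poly@parent@fluxNames))
  for (i in seq_len(nrow(X)))
    out[i, ] <- as.numeric(op$M %*% X[i, ]) + op$c
  out
}

#' Forward map from flux space to rounded coordinates
#'
#' For a flux vector in the affine subspace of the equality system,
#' \code{xr = R (K' (nu - nu0) - shift)}. Inverse of
#' \code{\link{backTransform}} on that subspace (exact when \code{K} has
#' orthonormal columns).
#'
#' @param nu flux vector (length D).
#' @param poly a \linkS4class{RoundedPolytope}.
#' @return rounded-space vector of length d.
#' @export
forwardTransform <- function(nu, poly) {
  stopifnot(is(poly, "RoundedPolytope"))
  parent <- poly@parent
  x <- as.numeric(crossprod(parent@K, as.numeric(nu) - parent@nu0))
  as.numeric(poly@transform@R %*% (x - poly@transform@shift))
}

#' Ratio of longest to shortest axis-aligned chord through the origin
#'
#' Isotropy summary used to verify that rounding improves conditioning.
#'
#' @param A,b inequality system with the origin strictly feasible (a
#'   \linkS4class{ReducedPolytope}/\linkS4class{RoundedPolytope} may be given).
#' @return scalar ratio >= 1.
#' @export
chordIsotropyRatio <- function(A, b) {
  if (missing(b) && (is(A, "ReducedPolytope") || is(A, "RoundedPolytope"))) {
    b <- ineqBound(A); A <- ineqMatrix(A)
  }
  d <- ncol(A)
  len <- numeric(d)
  for (k in seq_len(d)) {
    ck <- A[, k]
    pos <- ck > 1e-12
    negk <- ck < -1e-12
    if (!any(pos) || !any(negk))
      stop("polytope unbounded along coordinate ", k, call. = FALSE)
    dplus <- min(b[pos] / ck[pos])
    dminus <- max(b[negk] / ck[negk])
    len[k] <- dplus - dminus
  }
  max(len) / min(len)
}
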