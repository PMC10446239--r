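#' Solve a dense linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to
#' \code{Aub \%*\% x <= bub} and \code{Aeq \%*\% x == beq}, with free variables.
#' A dense two-phase primal simplex with a Dantzig/Bland pivoting rule; intended
#' for the moderate problem sizes arising in flux-polytope preprocessing
#' (boundedness checks, redundancy tests, flux ranges, Chebyshev centers).
#'
#' @param obj numeric objective vector (length n).
#' @param Aub,bub inequality system (may be \code{NULL}).
#' @param Aeq,beq equality system (may be \code{NULL}).
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivoting tolerance.
#' @param maxIter iteration cap across both phases.
#' @return list with \code{status} (one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"maxiter"}), \code{x} (solution, \code{NA} unless
#'   optimal) and \code{value} (objective at \code{x}).
#' @export
solveLP <- function(obj, Aub = NULL, bub = NULL, Aeq = NULL, beq = NULL,
                    maximize = FALSE, tol = 1e-9, maxIter = 50000L) {
  obj <- as.numeric(obj)
  n <- length(obj)
  if (!is.null(Aub)) {
    Aub <- matrix(as.numeric(Aub), ncol = n)
    bub <- as.numeric(bub)
    stopifnot(nrow(Aub) == length(bub))
  } else {
    Aub <- matrix(0, 0L, n); bub <- numeric(0)
  }
  if (!is.null(Aeq)) {
    Aeq <- matrix(as.numeric(Aeq), ncol = n)
    beq <- as.numeric(beq)
    stopifnot(nrow(Aeq) == length(beq))
  } else {
    Aeq <- matrix(0, 0L, n); beq <- numeric(0)
  }
  cvec <- if (maximize) -obj else obj

  mub <- nrow(Aub); meq <- nrow(Aeq); m <- mub + meq
  if (m == 0L) {
    # unconstrained: bounded only if objective is zero
    if (all(abs(cvec) <= tol)) {
      return(list(status = "optimal", x = rep(0, n), value = 0))
    }
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  }

  # free variables split as x = u - v; slack per inequality; artificials as needed
  A <- rbind(cbind(Aub, -Aub), cbind(Aeq, -Aeq))
  b <- c(bub, beq)
  S <- rbind(diag(1, mub), matrix(0, meq, mub))      # slack block
  M <- cbind(A, S)
  # normalize to b >= 0
  neg <- b < 0
  if (any(neg)) {
    M[neg, ] <- -M[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  ncols0 <- ncol(M)
  # rows whose slack column can start the basis: inequality rows not negated
  slackBasic <- logical(m)
  if (mub > 0L) slackBasic[seq_len(mub)] <- !neg[seq_len(mub)]
  artRows <- which(!slackBasic)
  nart <- length(artRows)
  if (nart > 0L) {
    Art <- matrix(0, m, nart)
    Art[cbind(artRows, seq_len(nart))] <- 1
    M <- cbind(M, Art)
  }
  nc <- ncol(M)
  basis <- integer(m)
  basis[slackBasic] <- 2L * n + which(slackBasic)
  basis[artRows] <- ncols0 + seq_len(nart)

  Tb <- cbind(M, b)

  pivotTo <- function(Tb, zrow, prow, pcol) {
    piv <- Tb[prow, pcol]
    Tb[prow, ] <- Tb[prow, ] / piv
    colv <- Tb[, pcol]
    colv[prow] <- 0
    upd <- which(abs(colv) > 0)
    if (length(upd)) Tb[upd, ] <- Tb[upd, ] - outer(colv[upd], Tb[prow, ])
    zpiv <- zrow[pcol]
    if (abs(zpiv) > 0) zrow <- zrow - zpiv * Tb[prow, ]
    list(Tb = Tb, zrow = zrow)
  }

  runPhase <- function(Tb, basis, costs, allowed, iterBudget) {
    # canonical z-row: reduced costs (length nc + 1; last entry = -objective)
    zrow <- c(costs, 0)
    for (i in seq_len(m)) {
      cb <- costs[basis[i]]
      if (abs(cb) > 0) zrow <- zrow - cb * Tb[i, ]
    }
    iter <- 0L
    blandAfter <- 2L * (m + nc)
    repeat {
      iter <- iter + 1L
      if (iter > iterBudget) return(list(status = "maxiter", Tb = Tb, basis = basis, zrow = zrow, used = iter))
      cand <- which(allowed & zrow[seq_len(nc)] < -tol)
      if (!length(cand)) {
        return(list(status = "optimal", Tb = Tb, basis = basis, zrow = zrow, used = iter))
      }
      pcol <- if (iter > blandAfter) cand[1L] else cand[which.min(zrow[cand])]
      colv <- Tb[, pcol]
      pos <- which(colv > tol)
      if (!length(pos)) {
        return(list(status = "unbounded", Tb = Tb, basis = basis, zrow = zrow, used = iter))
      }
      ratio <- Tb[pos, nc + 1L] / colv[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + 1e-12]
      prow <- tie[which.min(basis[tie])]   # lexicographic-ish anti-cycling
      res <- pivotTo(Tb, zrow, prow, pcol)
      Tb <- res$Tb; zrow <- res$zrow
      basis[prow] <- pcol
    }
  }

  isArt <- rep(FALSE, nc)
  if (nart > 0L) isArt[(ncols0 + 1L):nc] <- TRUE

  # phase 1
  if (nart > 0L) {
    costs1 <- as.numeric(isArt)
    ph1 <- runPhase(Tb, basis, costs1, allowed = rep(TRUE, nc), iterBudget = maxIter)
    if (ph1$status == "maxiter") return(list(status = "maxiter", x = rep(NA_real_, n), value = NA_real_))
    objeps <- max(tol, 1e-7) * max(1, max(abs(b)))
    if (-ph1$zrow[nc + 1L] > objeps) {
      return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
    }
    Tb <- ph1$Tb; basis <- ph1$basis
    # drive remaining artificials out of the basis where possible
    for (i in seq_len(m)) {
      if (isArt[basis[i]]) {
        row <- Tb[i, seq_len(ncols0)]
        j <- which(abs(row) > tol)
        if (length(j)) {
          res <- pivotTo(Tb, rep(0, nc + 1L), i, j[1L])
          Tb <- res$Tb
          basis[i] <- j[1L]
        }
        # else: redundant row; artificial stays basic at value 0 (harmless,
        # artificial columns are barred from entering in phase 2)
      }
    }
  }

  # phase 2
  costs2 <- c(cvec, -cvec, rep(0, nc - 2L * n))
  ph2 <- runPhase(Tb, basis, costs2, allowed = !isArt, iterBudget = maxIter)
  if (ph2$status == "maxiter") return(list(status = "maxiter", x = rep(NA_real_, n), value = NA_real_))
  if (ph2$status == "unbounded") return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))

  Tb <- ph2$Tb; basis <- ph2$basis
  xfull <- numeric(nc)
  xfull[basis] <- Tb[, nc + 1L]
  x <- xfull[seq_len(n)] - xfull[n + seq_len(n)]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = val)
}

#' Minimum and maximum of a linear functional over a polytope
#'
#' @param a coefficient vector.
#' @param Aub,bub,Aeq,beq constraint system.
#' @return list with \code{min}, \code{max} (possibly \code{-Inf}/\code{Inf}),
#'   \code{xmin}, \code{xmax} and \code{status}.
#' @keywords internal
linRange <- function(a, Aub, bub, Aeq = NULL, beq = NULL) {
  lo <- solveLP(a, Aub, bub, Aeq, beq, maximize = FALSE)
  hi <- solveLP(a, Aub, bub, Aeq, beq, maximize = TRUE)
  if (lo$status == "infeasible" || hi$status == "infeasible") {
    stop("infeasible polytope: no point satisfies the constraint system",
         call. = FALSE)
  }
  list(
    min = if (lo$status == "unbounded") -Inf else lo$value,
    max = if (hi$status == "unbounded") Inf else hi$value,
    xmin = lo$x, xmax = hi$x,
    status = c(lo$status, hi$status)
  )
}
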