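#' Construct a raw flux polytope
#'
#' Convenience constructor for \linkS4class{FluxPolytope} from dense matrices:
#' equalities \code{Aeq \%*\% nu == beq} (steady-state mass balances) and
#' inequalities \code{Ain \%*\% nu < bin} (flux bounds and other linear
#' constraints).
#'
#' @param Aeq,beq equality system (may be \code{NULL} for none).
#' @param Ain,bin inequality system.
#' @param fluxNames optional flux identifiers (defaults to \code{v1..vD}).
#' @param units informational unit string.
#' @return a \linkS4class{FluxPolytope}.
#' @export
fluxPolytope <- function(Ain, bin, Aeq = NULL, beq = NULL,
                         fluxNames = NULL, units = "mmol/gDW/h") {
  Ain <- as.matrix(Ain); storage.mode(Ain) <- "double"
  D <- ncol(Ain)
  if (is.null(Aeq)) {
    Aeq <- matrix(0, 0L, D); beq <- numeric(0)
  } else {
    Aeq <- as.matrix(Aeq); storage.mode(Aeq) <- "double"
  }
  if (is.null(fluxNames)) fluxNames <- paste0("v", seq_len(D))
  new("FluxPolytope", Aeq = Aeq, beq = as.numeric(beq),
      Ain = Ain, bin = as.numeric(bin),
      fluxNames = as.character(fluxNames), units = units)
}

.constraintSystem <- function(poly) {
  if (is(poly, "RoundedPolytope") || is(poly, "ReducedPolytope")) {
    list(Aub = ineqMatrix(poly), bub = ineqBound(poly), Aeq = NULL, beq = NULL)
  } else {
    Aeq <- eqMatrix(poly)
    list(Aub = ineqMatrix(poly), bub = ineqBound(poly),
         Aeq = if (nrow(Aeq)) Aeq else NULL,
         beq = if (nrow(Aeq)) eqBound(poly) else NULL)
  }
}

#' Per-coordinate boundedness check
#'
#' Solves two linear programs per coordinate (minimum and maximum) and reports
#' whether the polytope is bounded in every direction. Uniform sampling is
#' ill-defined on unbounded polytopes, so downstream stages reject them.
#'
#' @param poly a \linkS4class{FluxPolytope} or \linkS4class{ReducedPolytope}.
#' @return list with \code{bounded} (logical scalar), \code{lower} and
#'   \code{upper} (per-coordinate extrema, \code{-Inf}/\code{Inf} where
#'   unbounded) and \code{unboundedCoords} (indices).
#' @export
checkBoundedness <- function(poly) {
  cs <- .constraintSystem(poly)
  n <- ncol(cs$Aub)
  lower <- upper <- numeric(n)
  for (j in seq_len(n)) {
    a <- numeric(n); a[j] <- 1
    r <- linRange(a, cs$Aub, cs$bub, cs$Aeq, cs$beq)
    lower[j] <- r$min; upper[j] <- r$max
  }
  ub <- which(!is.finite(lower) | !is.finite(upper))
  list(bounded = length(ub) == 0L, lower = lower, upper = upper,
       unboundedCoords = ub)
}

# core redundancy pruning on a plain system; returns kept/removed indices
.pruneRedundant <- function(Ain, bin, Aeq = NULL, beq = NULL, tol = 1e-9) {
  m <- nrow(Ain)
  keep <- rep(TRUE, m)
  # pass 1: duplicate rows after unit-norm scaling (keep the tighter bound)
  nr <- sqrt(rowSums(Ain^2))
  if (any(nr <= 1e-14)) {
    # zero rows: vacuous if b > 0, infeasible otherwise
    zr <- which(nr <= 1e-14)
    bad <- zr[bin[zr] <= 0]
    if (length(bad)) stop("infeasible zero inequality row: ", bad[1L], call. = FALSE)
    keep[zr] <- FALSE
  }
  An <- Ain / pmax(nr, 1e-300)
  bn <- bin / pmax(nr, 1e-300)
  key <- apply(round(An, 10L), 1L, paste, collapse = ",")
  for (grp in split(seq_len(m)[keep], key[keep])) {
    if (length(grp) > 1L) {
      best <- grp[which.min(bn[grp])]
      keep[setdiff(grp, best)] <- FALSE
    }
  }
  # pass 2: LP test row-by-row against the surviving system
  for (i in which(keep)) {
    others <- which(keep); others <- others[others != i]
    if (!length(others)) next
    r <- solveLP(Ain[i, ], Aub = Ain[others, , drop = FALSE], bub = bin[others],
                 Aeq = Aeq, beq = beq, maximize = TRUE)
    if (r$status == "maxiter" || r$status == "infeasible")
      stop("LP failure while testing inequality row ", i, " (", r$status, ")",
           call. = FALSE)
    if (r$status == "optimal" && r$value <= bin[i] - tol) keep[i] <- FALSE
  }
  list(keep = which(keep), removed = which(!keep))
}

#' Remove redundant inequality rows
#'
#' An inequality row is pruned when dropping it cannot change the feasible set:
#' exact (scaled) duplicates are collapsed to the tighter bound, and a row
#' \code{a_i . nu < b_i} is removed when maximizing \code{a_i . nu} over all
#' remaining constraints stays below \code{b_i - tol}.
#'
#' @param poly a \linkS4class{FluxPolytope}.
#' @param tol redundancy slack tolerance (default 1e-9: below achievable flux
#'   precision, above LP solver noise).
#' @return a \linkS4class{PreprocessedPolytope} with provenance.
#' @export
removeRedundantInequalities <- function(poly, tol = 1e-9) {
  stopifnot(is(poly, "FluxPolytope"))
  Aeq <- poly@Aeq
  pr <- .pruneRedundant(poly@Ain, poly@bin,
                        Aeq = if (nrow(Aeq)) Aeq else NULL,
                        beq = if (nrow(Aeq)) poly@beq else NULL,
                        tol = tol)
  old <- if (is(poly, "PreprocessedPolytope")) poly@provenance else
    list(removedRows = integer(0), tightened = NULL, log = character(0))
  new("PreprocessedPolytope",
      Aeq = poly@Aeq, beq = poly@beq,
      Ain = poly@Ain[pr$keep, , drop = FALSE], bin = poly@bin[pr$keep],
      fluxNames = poly@fluxNames, units = poly@units,
      provenance = list(
        removedRows = c(old$removedRows, pr$removed),
        tightened = old$tightened,
        log = c(old$log, sprintf("removed %d redundant inequality row(s)",
                                 length(pr$removed)))))
}

#' Reformulate near-degenerate inequalities as equalities
#'
#' Fluxes whose achievable range (LP maximum minus minimum) is at most
#' \code{widthThreshold} are fixed at the range midpoint: an equality row is
#' added and inequality rows supported on that flux alone are dropped. With
#' \code{generalRows = TRUE} the same treatment is applied to arbitrary
#' inequality rows whose slack width falls below the threshold.
#'
#' @param poly a \linkS4class{FluxPolytope} (typically already pruned).
#' @param widthThreshold flux-units width below which a range counts as
#'   degenerate (default 1e-7).
#' @param generalRows also tighten general constraint rows, not only
#'   single-flux ranges.
#' @return a \linkS4class{PreprocessedPolytope}; provenance lists every
#'   reclassification.
#' @export
tightenNarrowInequalities <- function(poly, widthThreshold = 1e-7,
                                      generalRows = FALSE) {
  stopifnot(is(poly, "FluxPolytope"), widthThreshold > 0)
  Ain <- poly@Ain; bin <- poly@bin
  Aeq <- poly@Aeq; beq <- poly@beq
  D <- ncol(Ain)
  recs <- list()

  rangeOf <- function(a) {
    linRange(a, Ain, bin,
             Aeq = if (nrow(Aeq)) Aeq else NULL,
             beq = if (nrow(Aeq)) beq else NULL)
  }

  for (j in seq_len(D)) {
    a <- numeric(D); a[j] <- 1
    r <- rangeOf(a)
    if (!is.finite(r$min) || !is.finite(r$max)) next
    width <- r$max - r$min
    if (width <= widthThreshold) {
      mid <- (r$max + r$min) / 2
      Aeq <- rbind(Aeq, a); beq <- c(beq, mid)
      onlyJ <- which(abs(Ain[, j]) > 0 &
                       rowSums(abs(Ain[, -j, drop = FALSE])) == 0)
      if (length(onlyJ)) {
        Ain <- Ain[-onlyJ, , drop = FALSE]; bin <- bin[-onlyJ]
      }
      recs[[length(recs) + 1L]] <- data.frame(
        kind = "flux", index = j, name = poly@fluxNames[j],
        min = r$min, max = r$max, fixedAt = mid)
    }
  }
  if (generalRows && nrow(Ain)) {
    i <- 1L
    while (i <= nrow(Ain)) {
      r <- rangeOf(Ain[i, ])
      if (is.finite(r$min) && is.finite(r$max) &&
          (r$max - r$min) <= widthThreshold) {
        mid <- (r$max + r$min) / 2
        Aeq <- rbind(Aeq, Ain[i, , drop = FALSE]); beq <- c(beq, mid)
        Ain <- Ain[-i, , drop = FALSE]; bin <- bin[-i]
        recs[[length(recs) + 1L]] <- data.frame(
          kind = "row", index = i, name = NA_character_,
          min = r$min, max = r$max, fixedAt = mid)
      } else i <- i + 1L
    }
  }

  old <- if (is(poly, "PreprocessedPolytope")) poly@provenance else
    list(removedRows = integer(0), tightened = NULL, log = character(0))
  tightened <- if (length(recs)) do.call(rbind, recs) else old$tightened
  if (!is.null(old$tightened) && length(recs))
    tightened <- rbind(old$tightened, tightened)
  rownames(Aeq) <- NULL
  new("PreprocessedPolytope",
      Aeq = Aeq, beq = beq, Ain = Ain, bin = bin,
      fluxNames = poly@fluxNames, units = poly@units,
      provenance = list(
        removedRows = old$removedRows,
        tightened = tightened,
        log = c(old$log, sprintf("tightened %d constraint(s) to equalities",
                                 length(recs)))))
}

#' Full preprocessing chain
#'
#' Boundedness check, redundancy removal, and tightening of near-degenerate
#' inequality ranges, in that order.
#'
#' @inheritParams removeRedundantInequalities
#' @inheritParams tightenNarrowInequalities
#' @param checkBounded verify per-coordinate boundedness first (LPs); uniform
#'   sampling on unbounded polytopes is refused.
#' @return a \linkS4class{PreprocessedPolytope}.
#' @export
preprocessPolytope <- function(poly, tol = 1e-9, widthThreshold = 1e-7,
                               generalRows = FALSE, checkBounded = TRUE) {
  if (checkBounded) {
    bd <- checkBoundedness(poly)
    if (!bd$bounded)
      stop("polytope is unbounded in coordinate(s) ",
           paste(bd$unboundedCoords, collapse = ", "),
           "; the uniform sampling problem is ill-defined", call. = FALSE)
  }
  pre <- removeRedundantInequalities(poly, tol = tol)
  tightenNarrowInequalities(pre, widthThreshold = widthThreshold,
                            generalRows = generalRows)
}

#' Orthonormal null-space basis
#'
#' Basis \code{K} of the kernel of the (modified) stoichiometric system,
#' computed by singular value decomposition with rank cutoff
#' \code{max(dim(Aeq)) * eps * sigma_max}.
#'
#' @param Aeq equality matrix with D columns (zero rows allowed).
#' @return D x d matrix with orthonormal columns satisfying
#'   \code{Aeq \%*\% K ~ 0}; \code{d = D - rank(Aeq)}. For an empty equality
#'   system the identity is returned.
#' @export
nullspaceBasis <- function(Aeq) {
  Aeq <- as.matrix(Aeq)
  D <- ncol(Aeq)
  if (nrow(Aeq) == 0L) return(diag(1, D))
  sv <- svd(Aeq, nu = 0, nv = D)
  tolr <- max(dim(Aeq)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tolr)
  if (r >= D) return(matrix(0, D, 0L))
  sv$v[, (r + 1L):D, drop = FALSE]
}

#' Chebyshev center of an inequality system
#'
#' Center of the largest inscribed ball of \code{{x : A \%*\% x <= b}},
#' obtained by maximizing the radius \code{r} subject to
#' \code{A \%*\% x + r * ||a_i|| <= b}.
#'
#' @param A,b inequality system (a \linkS4class{ReducedPolytope} or
#'   \linkS4class{RoundedPolytope} can be given as \code{A} with \code{b}
#'   missing).
#' @return list with \code{center} and \code{radius}.
#' @export
chebyshevCenter <- function(A, b) {
  if (missing(b) && (is(A, "ReducedPolytope") || is(A, "RoundedPolytope"))) {
    b <- ineqBound(A); A <- ineqMatrix(A)
  }
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  nr <- sqrt(rowSums(A^2))
  Aub <- cbind(A, nr)
  obj <- c(numeric(n), 1)
  r <- solveLP(obj, Aub = Aub, bub = b, maximize = TRUE)
  if (r$status == "infeasible")
    stop("infeasible polytope: no point satisfies the constraint system",
         call. = FALSE)
  if (r$status == "unbounded")
    stop("inscribed-ball radius is unbounded; polytope must be bounded",
         call. = FALSE)
  if (r$status != "optimal")
    stop("LP did not converge while computing the Chebyshev center", call. = FALSE)
  if (r$value <= 0)
    stop("polytope has empty interior (Chebyshev radius <= 0)", call. = FALSE)
  list(center = r$x[seq_len(n)], radius = r$value)
}

#' Null-space dimension reduction
#'
#' Eliminates the equality system of a preprocessed polytope by a change of
#' variables \code{nu = K \%*\% x + nu0}, where \code{K} spans the kernel of
#' \code{Aeq} and \code{nu0} is a strictly interior particular solution (the
#' Chebyshev center of the reduced polytope, mapped back). The reduced system
#' is \code{A = Ain \%*\% K}, \code{b = bin - Ain \%*\% nu0}, so the
#' reduced-space origin is strictly feasible. Rows that become numerically zero
#' with positive slack are vacuous in the reduced space and are dropped.
#'
#' @param poly a \linkS4class{PreprocessedPolytope} (or raw
#'   \linkS4class{FluxPolytope} if no preprocessing is wanted).
#' @param checkBounded verify the reduced polytope is bounded in every
#'   direction (contract for downstream sampling).
#' @return a \linkS4class{ReducedPolytope}.
#' @export
reduceDimension <- function(poly, checkBounded = TRUE) {
  stopifnot(is(poly, "FluxPolytope"))
  Aeq <- poly@Aeq; beq <- poly@beq
  Ain <- poly@Ain; bin <- poly@bin
  D <- ncol(Ain)
  K <- nullspaceBasis(Aeq)
  d <- ncol(K)
  if (d == 0L)
    stop("equality system has a trivial kernel (d = 0); nothing to sample",
         call. = FALSE)
  # minimum-norm particular solution of the equality system
  if (nrow(Aeq)) {
    sv <- svd(Aeq)
    tolr <- max(dim(Aeq)) * .Machine$double.eps * max(sv$d)
    pos <- sv$d > tolr
    nup <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], beq)) / sv$d[pos])
    nup <- as.numeric(nup)
    if (max(abs(Aeq %*% nup - beq)) > 1e-7 * max(1, max(abs(beq))))
      stop("equality system is inconsistent (no particular solution)",
           call. = FALSE)
  } else {
    nup <- numeric(D)
  }
  Ared <- Ain %*% K
  bred <- bin - as.numeric(Ain %*% nup)
  cc <- chebyshevCenter(Ared, bred)
  nu0 <- nup + as.numeric(K %*% cc$center)
  b <- bin - as.numeric(Ain %*% nu0)

  rn <- sqrt(rowSums(Ared^2))
  vac <- rn < 1e-12 & b > 1e-12
  if (any(rn < 1e-12 & b <= 1e-12))
    stop("degenerate reduced row with non-positive slack", call. = FALSE)
  A <- Ared[!vac, , drop = FALSE]
  b <- b[!vac]

  red <- new("ReducedPolytope", A = A, b = b, K = K, nu0 = nu0,
             fluxNames = poly@fluxNames)
  if (checkBounded) {
    bd <- checkBoundedness(red)
    if (!bd$bounded)
      stop("reduced polytope unbounded in direction(s) ",
           paste(bd$unboundedCoords, collapse = ", "),
           "; contract violated", call. = FALSE)
  }
  red
}

#' Embed reduced-space points into flux space
#'
#' \code{nu = K \%*\% x + nu0}, row-wise for a matrix of points.
#'
#' @param poly a \linkS4class{ReducedPolytope}.
#' @param x numeric vector (length d) or matrix (n x d).
#' @return flux vector (length D) or matrix (n x D).
#' @export
embedFluxes <- function(poly, x) {
  stopifnot(is(poly, "ReducedPolytope"))
  if (is.matrix(x)) {
    out <- x %*% t(poly@K) + rep(poly@nu0, each = nrow(x))
    colnames(out) <- poly@fluxNames
    out
  } else {
    stats::setNames(as.numeric(poly@K %*% x) + poly@nu0, poly@fluxNames)
  }
}
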