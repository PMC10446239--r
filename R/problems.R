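#' Standard simplex test problem
#'
#' The d-dimensional simplex \code{{x : sum(x) <= 1, x_i >= 0}} as a
#' \linkS4class{ReducedPolytope}: d + 1 inequality rows, no equalities, the
#' null-space basis set to the identity, and the particular solution set to the
#' Chebyshev center \code{1/(d + sqrt(d))} per coordinate (so the reduced-space
#' origin is the center of the largest inscribed ball).
#'
#' @param d dimension (>= 1).
#' @return a \linkS4class{ReducedPolytope}.
#' @export
makeSimplex <- function(d) {
  d <- as.integer(d)
  stopifnot(d >= 1L)
  A <- rbind(-diag(1, d), rep(1, d))
  b0 <- c(rep(0, d), 1)
  nu0 <- rep(1 / (d + sqrt(d)), d)   # Chebyshev center of the standard simplex
  b <- b0 - as.numeric(A %*% nu0)
  new("ReducedPolytope", A = A, b = b, K = diag(1, d), nu0 = nu0,
      fluxNames = paste0("x", seq_len(d)))
}

#' Anisotropic box test problem
#'
#' Axis-aligned (optionally randomly rotated) box centered at the origin with
#' side lengths spaced geometrically from 1 to \code{aspect}. The maximum
#' volume inscribed ellipsoid is known analytically (center 0, shape
#' \code{diag(sides / 2)} in the box frame), which makes this family the
#' reference fixture for rounding tests.
#'
#' @param d dimension (>= 1).
#' @param aspect ratio of longest to shortest side (>= 1).
#' @param rotate apply a random rotation (seeded).
#' @param seed seed for the rotation.
#' @param details if \code{TRUE}, return a list with the polytope, the
#'   analytic MVE center/shape, and the rotation used.
#' @return a \linkS4class{ReducedPolytope}, or a list when
#'   \code{details = TRUE}.
#' @export
makeAnisotropicBox <- function(d, aspect = 4, rotate = FALSE, seed = 1L,
                               details = FALSE) {
  d <- as.integer(d)
  stopifnot(d >= 1L, aspect >= 1)
  sides <- if (d == 1L) aspect else aspect^((seq_len(d) - 1) / (d - 1))
  half <- sides / 2
  A <- rbind(diag(1, d), -diag(1, d))
  b <- c(half, half)
  Q <- diag(1, d)
  if (rotate && d > 1L) {
    set.seed(seed)
    qrd <- qr(matrix(stats::rnorm(d * d), d, d))
    Q <- qr.Q(qrd)
    Q <- Q %*% diag(sign(diag(qr.R(qrd))), d)
    A <- A %*% t(Q)    # rows become (±q_i)', box axes along columns of Q
  }
  poly <- new("ReducedPolytope", A = A, b = b, K = diag(1, d),
              nu0 = rep(0, d), fluxNames = paste0("x", seq_len(d)))
  if (!details) return(poly)
  list(polytope = poly,
       mveCenter = rep(0, d),
       mveShape = Q %*% diag(half, d) %*% t(Q),
       rotation = Q, sides = sides)
}

.sbmlAttr <- function(node, name, prefix = "fbc") {
  v <- xml2::xml_attr(node, paste0(prefix, ":", name))
  if (is.na(v)) v <- xml2::xml_attr(node, name)
  v
}

#' Read a constraint-based model from SBML
#'
#' Minimal SBML Level-3 FBC reader: builds the stoichiometric matrix from
#' \code{listOfReactants}/\code{listOfProducts} (boundary-condition species are
#' excluded from mass balancing), takes flux bounds from the
#' \code{fbc:lowerFluxBound}/\code{fbc:upperFluxBound} parameter references,
#' and encodes them as \code{+I/-I} inequality rows. Steady state is assumed
#' (equality right-hand side zero). Objectives, gene rules and compartments
#' are ignored; missing or infinite bounds are an error (uniform sampling
#' requires a bounded polytope, and default bounds are never invented).
#'
#' @param path path to an SBML file.
#' @return a \linkS4class{FluxPolytope} with \code{Aeq} the stoichiometric
#'   matrix (metabolites x reactions), \code{beq = 0}, and bound rows in
#'   \code{Ain}/\code{bin}.
#' @export
readSBMLModel <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  specNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  specIds <- xml2::xml_attr(specNodes, "id")
  boundary <- tolower(xml2::xml_attr(specNodes, "boundaryCondition")) %in% "true"
  mets <- specIds[!boundary]

  parNodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parVals <- stats::setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                             xml2::xml_attr(parNodes, "id"))

  rxnNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxnNodes)) stop("no reactions found in SBML file", call. = FALSE)
  rxnIds <- xml2::xml_attr(rxnNodes, "id")

  S <- matrix(0, length(mets), length(rxnNodes),
              dimnames = list(mets, rxnIds))
  lb <- ub <- stats::setNames(rep(NA_real_, length(rxnNodes)), rxnIds)
  for (i in seq_along(rxnNodes)) {
    rx <- rxnNodes[[i]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx, paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      for (j in seq_along(sp)) {
        if (sp[j] %in% mets) S[sp[j], i] <- S[sp[j], i] + st[j]
      }
    }
    lbRef <- .sbmlAttr(rx, "lowerFluxBound")
    ubRef <- .sbmlAttr(rx, "upperFluxBound")
    if (is.na(lbRef) || is.na(ubRef))
      stop("reaction '", rxnIds[i], "' has no flux bounds; refusing to invent defaults",
           call. = FALSE)
    if (!(lbRef %in% names(parVals)) || !(ubRef %in% names(parVals)))
      stop("reaction '", rxnIds[i], "' references undefined bound parameter(s)",
           call. = FALSE)
    lb[i] <- parVals[[lbRef]]
    ub[i] <- parVals[[ubRef]]
  }
  bad <- rxnIds[!is.finite(lb) | !is.finite(ub)]
  if (length(bad))
    stop("non-finite flux bounds for reaction(s): ",
         paste(bad, collapse = ", "),
         "; the flux polytope must be bounded", call. = FALSE)

  D <- length(rxnIds)
  Ain <- rbind(diag(1, D), -diag(1, D))
  bin <- c(ub, -lb)
  fluxPolytope(Ain = Ain, bin = bin,
               Aeq = S, beq = rep(0, length(mets)),
               fluxNames = rxnIds)
}
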