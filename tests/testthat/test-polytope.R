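unitBox <- function(d) {
  fluxPolytope(Ain = rbind(diag(d), -diag(d)),
               bin = c(rep(1, d), rep(0, d)))
}

test_that("boundedness check reports per-coordinate ranges and unbounded directions", {
  bd <- checkBoundedness(unitBox(3))
  expect_true(bd$bounded)
  expect_equal(bd$lower, rep(0, 3), tolerance = 1e-9)
  expect_equal(bd$upper, rep(1, 3), tolerance = 1e-9)

  # a single half-space cannot bound the plane
  half <- fluxPolytope(Ain = matrix(c(-1, 0), 1), bin = 0)
  bd <- checkBoundedness(half)
  expect_false(bd$bounded)
  expect_setequal(bd$unboundedCoords, c(1, 2))

  # simplex S_3: each coordinate ranges over [0, 1]
  s3 <- fluxPolytope(Ain = rbind(-diag(3), rep(1, 3)), bin = c(0, 0, 0, 1))
  bd <- checkBoundedness(s3)
  expect_true(bd$bounded)
  expect_equal(bd$lower, rep(0, 3), tolerance = 1e-9)
  expect_equal(bd$upper, rep(1, 3), tolerance = 1e-9)

  # infeasible raises a distinct error from unbounded
  bad <- fluxPolytope(Ain = rbind(c(1, 0), c(-1, 0)), bin = c(-1, -1))
  expect_error(checkBoundedness(bad), "infeasible")
})

test_that("redundancy removal drops duplicates and dominated rows, keeps the feasible set", {
  # unit square with x1 <= 1 duplicated
  p <- fluxPolytope(Ain = rbind(diag(2), -diag(2), c(1, 0)),
                    bin = c(1, 1, 0, 0, 1))
  pre <- removeRedundantInequalities(p)
  expect_equal(nrow(pre@Ain), 4L)
  expect_length(pre@provenance$removedRows, 1L)

  # loose row x1 + x2 <= 5 strictly dominated
  p <- fluxPolytope(Ain = rbind(diag(2), -diag(2), c(1, 1)),
                    bin = c(1, 1, 0, 0, 5))
  pre <- removeRedundantInequalities(p)
  expect_equal(nrow(pre@Ain), 4L)
  expect_true(5L %in% pre@provenance$removedRows)

  # random 10-row 2-D system: identical feasible set via membership oracle
  poly2 <- random2dPolytope(seed = 11, m = 10)
  p <- fluxPolytope(Ain = ineqMatrix(poly2), bin = ineqBound(poly2))
  pre <- removeRedundantInequalities(p)
  set.seed(99)
  pts <- matrix(stats::runif(2e4, -2, 2), ncol = 2)
  inRaw <- rowSums(pts %*% t(p@Ain) <= matrix(p@bin, nrow(pts), length(p@bin),
                                              byrow = TRUE)) == length(p@bin)
  inPre <- rowSums(pts %*% t(pre@Ain) <= matrix(pre@bin, nrow(pts), length(pre@bin),
                                                byrow = TRUE)) == length(pre@bin)
  expect_identical(inRaw, inPre)

  # idempotence: a second pass removes nothing
  pre2 <- removeRedundantInequalities(pre)
  expect_equal(nrow(pre2@Ain), nrow(pre@Ain))
  expect_length(setdiff(pre2@provenance$removedRows, pre@provenance$removedRows), 0L)
})

test_that("narrow flux ranges are tightened to equalities at the range midpoint", {
  # 0 <= x2 <= 5e-8 collapses to x2 = 2.5e-8
  p <- fluxPolytope(Ain = rbind(diag(2), -diag(2)), bin = c(1, 5e-8, 0, 0))
  tp <- tightenNarrowInequalities(p)
  expect_equal(nrow(tp@Aeq), 1L)
  expect_equal(as.numeric(tp@Aeq), c(0, 1))
  expect_equal(tp@beq, 2.5e-8, tolerance = 1e-12)
  expect_equal(tp@provenance$tightened$fixedAt, 2.5e-8)
  # bound rows on x2 moved out of the inequality system
  expect_equal(nrow(tp@Ain), 2L)

  # 0 <= x2 <= 1e-3 stays untouched
  p <- fluxPolytope(Ain = rbind(diag(2), -diag(2)), bin = c(1, 1e-3, 0, 0))
  tp <- tightenNarrowInequalities(p)
  expect_equal(nrow(tp@Aeq), 0L)
  expect_equal(nrow(tp@Ain), 4L)

  # simplex S_3: all widths are 1, nothing happens
  s3 <- fluxPolytope(Ain = rbind(-diag(3), rep(1, 3)), bin = c(0, 0, 0, 1))
  tp <- tightenNarrowInequalities(s3)
  expect_equal(nrow(tp@Aeq), 0L)
  expect_equal(nrow(tp@Ain), 4L)
})

test_that("null-space basis is orthonormal and spans the kernel", {
  # kernel of a row vector
  K <- nullspaceBasis(matrix(c(1, 1), 1))
  expect_equal(ncol(K), 1L)
  expect_equal(abs(sum(K * c(1, -1) / sqrt(2))), 1, tolerance = 1e-12)

  # trivial kernel
  K <- nullspaceBasis(diag(4))
  expect_equal(ncol(K), 0L)

  # random rank-3 system: SVD oracle properties
  set.seed(5)
  A <- matrix(stats::rnorm(15), 3, 5)
  K <- nullspaceBasis(A)
  expect_equal(ncol(K), 2L)
  expect_lt(max(abs(A %*% K)), 1e-12)
  expect_equal(crossprod(K), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Chebyshev center maximizes the inscribed ball radius", {
  # unit square
  cc <- chebyshevCenter(rbind(diag(2), -diag(2)), c(1, 1, 0, 0))
  expect_equal(cc$center, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(cc$radius, 0.5, tolerance = 1e-9)

  # S_2: all slacks >= r, and r is maximal (analytic value 1/(2 + sqrt(2)))
  A <- rbind(-diag(2), rep(1, 2)); b <- c(0, 0, 1)
  cc <- chebyshevCenter(A, b)
  nr <- sqrt(rowSums(A^2))
  slackDist <- (b - as.numeric(A %*% cc$center)) / nr
  expect_true(all(slackDist >= cc$radius - 1e-9))
  expect_equal(cc$radius, 1 / (2 + sqrt(2)), tolerance = 1e-9)

  # empty interior is refused
  expect_error(chebyshevCenter(rbind(c(1, 0), c(-1, 0), diag(2), -diag(2)),
                               c(0, 0, 1, 1, 1, 1)),
               "empty interior")
})

test_that("dimension reduction reproduces the reduced system and embeds exactly", {
  # 2-D unit box with equality x1 = x2 -> interval of length sqrt(2)
  p <- fluxPolytope(Ain = rbind(diag(2), -diag(2)), bin = c(1, 1, 0, 0),
                    Aeq = matrix(c(1, -1), 1), beq = 0)
  red <- reduceDimension(p)
  expect_equal(effectiveDim(red), 1L)
  bd <- checkBoundedness(red)
  expect_equal(bd$upper - bd$lower, sqrt(2), tolerance = 1e-9)

  # reduced system is A = Ain K, b = bin - Ain nu0 by construction
  expect_equal(red@A, p@Ain %*% red@K, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(red@b, p@bin - as.numeric(p@Ain %*% red@nu0), tolerance = 1e-12)
  # origin strictly feasible
  expect_true(all(red@b > 0))

  # embedding identity: A_eq (K x + nu0) = b_eq for random x
  set.seed(3)
  for (x in stats::runif(5, -1, 1)) {
    nu <- embedFluxes(red, x)
    expect_lt(max(abs(p@Aeq %*% nu - p@beq)), 1e-9)
  }
})

test_that("preprocessing pipeline preserves feasibility and satisfies d + rank = D", {
  set.seed(21)
  # random bounded system in 4-D with one equality and extra sloppy rows
  D <- 4
  Ain <- rbind(diag(D), -diag(D),
               matrix(stats::rnorm(2 * D), 2, D),  # possibly redundant
               diag(D)[2, , drop = FALSE])          # duplicate of a bound row
  bin <- c(rep(1, D), rep(1, D), rep(6, 2), 1)
  Aeq <- matrix(c(1, 1, 0, 0), 1)
  p <- fluxPolytope(Ain = Ain, bin = bin, Aeq = Aeq, beq = 0.3)
  pre <- preprocessPolytope(p)
  red <- reduceDimension(pre)

  expect_equal(effectiveDim(red) + qr(pre@Aeq)$rank, D)

  # 1000 random feasible reduced points satisfy the raw system
  cheb <- chebyshevCenter(red)
  set.seed(22)
  pts <- matrix(stats::rnorm(1000 * effectiveDim(red)), ncol = effectiveDim(red))
  pts <- pts * stats::runif(1000, 0, cheb$radius) / sqrt(rowSums(pts^2))
  pts <- sweep(pts, 2, cheb$center, "+")
  nus <- embedFluxes(red, pts)
  expect_lt(max(nus %*% t(Ain) - matrix(bin, 1000, length(bin), byrow = TRUE)),
            1e-8)
  expect_lt(max(abs(nus %*% t(Aeq) - 0.3)), 1e-8)
})
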