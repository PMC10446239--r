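# rounded polytope with identity transform: the raw inequality system itself
asRounded <- function(poly) {
  buildRounding(new("Ellipsoid", center = rep(0, effectiveDim(poly)),
                    shape = diag(1, effectiveDim(poly))), poly)
}

squareRounded <- function() {
  # unit square [0,1]^2 recentered at its midpoint: sampler coordinates are
  # offsets from (0.5, 0.5)
  poly <- new("ReducedPolytope",
              A = rbind(diag(2), -diag(2)), b = rep(0.5, 4),
              K = diag(1, 2), nu0 = c(0.5, 0.5), fluxNames = c("x1", "x2"))
  asRounded(poly)
}

test_that("chord bounds match box geometry and a bisection oracle", {
  sq <- squareRounded()   # square [-0.5, 0.5]^2 in sampler coordinates
  # state (0.5, 0.5) in [0,1]^2 is the origin here
  expect_equal(chordBounds(sq, c(0, 0), 1), c(dminus = -0.5, dplus = 0.5))
  # state (0.9, 0.5) -> (-0.9, +0.1)
  expect_equal(chordBounds(sq, c(0.4, 0), 1), c(dminus = -0.9, dplus = 0.1),
               tolerance = 1e-12)

  # S_2, interior point, against bisection on the membership oracle
  s2 <- makeSimplex(2)
  rp <- asRounded(s2)
  x <- c(0.2, 0.3) - s2@nu0   # interior point (0.2, 0.3) in simplex coords
  member <- function(p) all(rp@A %*% p <= rp@b)
  bisect <- function(x, k, dir) {
    lo <- 0; hi <- 1
    while (member(x + dir * hi * diag(2)[, k])) hi <- hi * 2
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (member(x + dir * mid * diag(2)[, k])) lo <- mid else hi <- mid
    }
    dir * lo
  }
  cb <- chordBounds(rp, x, 2)
  expect_equal(cb[["dplus"]], bisect(x, 2, +1), tolerance = 1e-10)
  expect_equal(cb[["dminus"]], bisect(x, 2, -1), tolerance = 1e-10)

  # unbounded chord is a contract violation
  open <- new("ReducedPolytope", A = matrix(c(1, 0), 1), b = 1,
              K = diag(1, 2), nu0 = c(0, 0), fluxNames = c("x1", "x2"))
  expect_error(chordBounds(asRounded(open), c(0, 0), 1), "unbounded chord")
})

test_that("a single update on an interval is a uniform draw over the interval", {
  # d = 1 interval [-0.5, 0.5]; one update from the center is U(-0.5, 0.5)
  iv <- new("ReducedPolytope", A = matrix(c(1, -1), 2, 1), b = c(0.5, 0.5),
            K = matrix(1, 1, 1), nu0 = 0.5, fluxNames = "x1")
  rp <- asRounded(iv)
  set.seed(123)
  draws <- replicate(1e5, chrrtUpdate(list(x = 0, i = 0L), rp)$x + 0.5)
  ks <- suppressWarnings(stats::ks.test(draws, "punif"))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("updates are reproducible and leave the polytope invariant", {
  s2 <- makeSimplex(2)
  rp <- buildRounding(computeMVE(s2), s2)
  set.seed(7)
  st1 <- list(x = c(0, 0), i = 0L)
  for (i in 1:50) st1 <- chrrtUpdate(st1, rp)
  set.seed(7)
  st2 <- list(x = c(0, 0), i = 0L)
  for (i in 1:50) st2 <- chrrtUpdate(st2, rp)
  expect_identical(st1$x, st2$x)
  expect_equal(st1$i, 50L)
  expect_true(all(rp@A %*% st1$x <= rp@b + 1e-9))
})

test_that("compiled chain and R-level updates consume the same RNG stream", {
  s2 <- makeSimplex(2)
  rp <- buildRounding(computeMVE(s2), s2)
  cfg <- samplerConfig(N = 40, tau = 1, nChains = 1, seed = 99,
                       storeRounded = TRUE)
  res <- runChain(rp, cfg)
  set.seed(99)
  st <- list(x = c(0, 0), i = 0L)
  manual <- matrix(NA_real_, 40, 2)
  for (i in 1:40) {
    st <- chrrtUpdate(st, rp)
    manual[i, ] <- st$x
  }
  expect_equal(res$rounded, manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("thinning bookkeeping: N stores need exactly N * tau updates", {
  s2 <- makeSimplex(2)
  rp <- buildRounding(computeMVE(s2), s2)
  r1 <- runChain(rp, samplerConfig(N = 10, tau = 1, nChains = 1, seed = 5))
  expect_equal(r1$nUpdates, 10)
  r5 <- runChain(rp, samplerConfig(N = 10, tau = 5, nChains = 1, seed = 5))
  expect_equal(r5$nUpdates, 50)
  expect_equal(nrow(r5$original), 10L)
})

test_that("seed-matched thinned chain equals the subsampled unthinned chain bit for bit", {
  s5 <- makeSimplex(5)
  rp <- buildRounding(computeMVE(s5), s5)
  c1 <- runChain(rp, samplerConfig(N = 250, tau = 1, nChains = 1, seed = 31,
                                   storeRounded = TRUE))
  c5 <- runChain(rp, samplerConfig(N = 50, tau = 5, nChains = 1, seed = 31,
                                   storeRounded = TRUE))
  expect_identical(c5$rounded, c1$rounded[seq(5, 250, by = 5), ])
  expect_identical(c5$original, c1$original[seq(5, 250, by = 5), ])
})

test_that("multiple chains are seed-separated and reduce to a single chain", {
  s2 <- makeSimplex(2)
  rp <- buildRounding(computeMVE(s2), s2)
  cfg1 <- samplerConfig(N = 30, tau = 2, nChains = 1, seed = 17)
  ss <- runChains(rp, cfg1)
  expect_s4_class(ss, "FluxSampleSet")
  expect_identical(ss@samplesOriginal[[1L]],
                   runChain(rp, cfg1)$original)
  cfg4 <- samplerConfig(N = 30, tau = 2, nChains = 4, seed = 17)
  ss4 <- runChains(rp, cfg4)
  expect_length(ss4@samplesOriginal, 4L)
  for (i in 2:4)
    expect_false(identical(ss4@samplesOriginal[[1L]],
                           ss4@samplesOriginal[[i]]))
})

test_that("pooled means on simplices match the Dirichlet(1,..,1) moments", {
  for (d in c(2, 5)) {
    sp <- makeSimplex(d)
    rp <- buildRounding(computeMVE(sp), sp)
    cfg <- samplerConfig(N = 5000, tau = 2 * d, nChains = 4, seed = 2024)
    ss <- runChains(rp, cfg)
    pooled <- do.call(rbind, ss@samplesOriginal)
    nTot <- nrow(pooled)
    sdCoord <- sqrt(d / ((d + 1)^2 * (d + 2)))
    se <- sdCoord / sqrt(nTot)
    expect_true(all(abs(colMeans(pooled) - 1 / (d + 1)) < 4 * se))
    # pairwise covariance of Dirichlet(1,...,1): -1 / ((d+1)^2 (d+2))
    cv <- stats::cov(pooled)
    offDiag <- cv[upper.tri(cv)]
    expect_equal(mean(offDiag), -1 / ((d + 1)^2 * (d + 2)),
                 tolerance = 0.15)
  }
})

test_that("no stored sample violates the rounded or raw system", {
  s3 <- makeSimplex(3)
  rp <- buildRounding(computeMVE(s3), s3)
  cfg <- samplerConfig(N = 2000, tau = 3, nChains = 4, seed = 88,
                       storeRounded = TRUE)
  ss <- runChains(rp, cfg)
  A0 <- rbind(-diag(3), rep(1, 3)); b0 <- c(0, 0, 0, 1)
  for (i in 1:4) {
    Xr <- ss@samplesRounded[[i]]
    expect_lt(max(Xr %*% t(rp@A) - matrix(rp@b, nrow(Xr), length(rp@b),
                                          byrow = TRUE)), 1e-7)
    Xo <- ss@samplesOriginal[[i]]
    expect_lt(max(Xo %*% t(A0) - matrix(b0, nrow(Xo), length(b0),
                                        byrow = TRUE)), 1e-7)
  }
})

test_that("CHRRT output agrees with rejection sampling on a random 2-D polytope", {
  poly <- random2dPolytope(seed = 42, m = 12)
  rp <- buildRounding(computeMVE(poly), poly)
  cfg <- samplerConfig(N = 2500, tau = 4, nChains = 4, seed = 314)
  ss <- runChains(rp, cfg)
  chrr <- do.call(rbind, ss@samplesOriginal)

  bd <- checkBoundedness(poly)
  rej <- rejectionSample(ineqMatrix(poly), ineqBound(poly),
                         bd$lower, bd$upper, n = 10000, seed = 272)

  # 5 x 5 grid-bin chi-square over the bounding box
  bx <- seq(min(bd$lower[1]), max(bd$upper[1]), length.out = 6)
  by <- seq(min(bd$lower[2]), max(bd$upper[2]), length.out = 6)
  binOf <- function(M) {
    ix <- findInterval(M[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
    iy <- findInterval(M[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
    factor(paste(ix, iy), levels = as.vector(outer(1:5, 1:5, paste)))
  }
  t1 <- table(binOf(chrr)); t2 <- table(binOf(rej))
  keep <- (t1 + t2) >= 10
  pval <- suppressWarnings(stats::chisq.test(rbind(t1[keep], t2[keep]))$p.value)
  expect_gt(pval, 0.001)
})
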