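test_that("simplex construction matches its definition and volume", {
  s2 <- makeSimplex(2)
  expect_equal(nrow(s2@A), 3L)
  # rows are -x1 <= 0, -x2 <= 0, x1 + x2 <= 1, shifted by the Chebyshev center
  expect_equal(unname(s2@A), rbind(-diag(2), c(1, 1)))
  expect_equal(s2@nu0, rep(1 / (2 + sqrt(2)), 2))
  expect_equal(s2@b, c(0, 0, 1) - as.numeric(s2@A %*% s2@nu0))
  # Chebyshev center cross-check against the LP
  cc <- chebyshevCenter(rbind(-diag(2), c(1, 1)), c(0, 0, 1))
  expect_equal(cc$center, s2@nu0, tolerance = 1e-9)

  s64 <- makeSimplex(64)
  expect_equal(nrow(s64@A), 65L)
  expect_true(checkBoundedness(s64)$bounded)

  # rejection-sampling volume of S_3 is 1/3! of the unit cube
  set.seed(77)
  pts <- matrix(stats::runif(3 * 2e4), ncol = 3)
  phat <- mean(rowSums(pts) <= 1)
  expect_lt(abs(phat - 1 / 6), 4 * sqrt((1 / 6) * (5 / 6) / 2e4))
})

test_that("anisotropic boxes expose their analytic inscribed ellipsoid", {
  sq <- makeAnisotropicBox(2, aspect = 1)
  expect_equal(sq@b, rep(0.5, 4))
  det4 <- makeAnisotropicBox(2, aspect = 4, details = TRUE)
  expect_equal(det4$sides, c(1, 4))
  expect_equal(det4$mveShape, diag(c(0.5, 2)), ignore_attr = TRUE)
  e <- computeMVE(det4$polytope)
  expect_equal(e@shape, det4$mveShape, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("the SBML reader recovers stoichiometry and bound encoding", {
  poly <- readSBMLModel(toySBMLPath())
  expect_s4_class(poly, "FluxPolytope")
  expect_equal(dim(poly@Aeq), c(3L, 4L))          # 3 metabolites x 4 reactions
  expect_equal(nrow(poly@Ain), 8L)                # 8 bound rows
  expect_equal(poly@beq, rep(0, 3))               # steady state
  expect_equal(poly@fluxNames, c("R_EX_A", "R_AB", "R_BC", "R_EX_C"))
  # stoichiometry of the linear chain
  expect_equal(unname(poly@Aeq["M_A", ]), c(1, -1, 0, 0))
  expect_equal(unname(poly@Aeq["M_B", ]), c(0, 1, -1, 0))
  expect_equal(unname(poly@Aeq["M_C", ]), c(0, 0, 1, -1))
  # reversible R_AB with bounds (-10, 10): v <= 10 and -v <= 10
  j <- which(poly@fluxNames == "R_AB")
  expect_equal(poly@bin[j], 10)                   # +I row
  expect_equal(poly@bin[4 + j], 10)               # -I row encodes -v <= -lb
  # the toy model preprocesses and samples end to end
  red <- reduceDimension(preprocessPolytope(poly))
  expect_equal(effectiveDim(red), 1L)             # one free flux in a chain

  # missing bounds are refused
  bad <- tempfile(fileext = ".xml")
  txt <- readLines(toySBMLPath())
  writeLines(sub(' fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten"',
                 "", txt, fixed = TRUE), bad)
  expect_error(readSBMLModel(bad), "no flux bounds")
})

test_that("polytope exchange directories round-trip all polytope kinds", {
  dir <- tempfile()
  raw <- readSBMLModel(toySBMLPath())
  writePolytope(raw, dir)
  back <- readPolytope(dir)
  expect_equal(back@Aeq, raw@Aeq, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@bin, raw@bin, tolerance = 1e-12)
  expect_identical(back@fluxNames, raw@fluxNames)

  s <- makeSimplex(3)
  dir2 <- tempfile()
  writePolytope(s, dir2)
  s2 <- readPolytope(dir2)
  expect_equal(s2@A, s@A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(s2@nu0, s@nu0, tolerance = 1e-12)

  rp <- buildRounding(computeMVE(s), s)
  dir3 <- tempfile()
  writePolytope(rp, dir3)
  rp2 <- readPolytope(dir3)
  expect_equal(rp2@A, rp@A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rp2@transform@R, rp@transform@R, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rp2@parent@K, rp@parent@K, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(readPolytope(tempfile()), "meta.json")
})

test_that("sample sets round-trip through CSV and the binary container", {
  s <- makeSimplex(4)
  rp <- buildRounding(computeMVE(s), s)
  cfg <- samplerConfig(N = 10, tau = 2, nChains = 4, seed = 3,
                       storeRounded = TRUE)
  ss <- runChains(rp, cfg)

  dirB <- tempfile()
  writeSamples(ss, dirB, format = "rds")
  backB <- readSamples(dirB)
  expect_identical(backB@samplesOriginal, ss@samplesOriginal)  # bit-exact

  dirC <- tempfile()
  writeSamples(ss, dirC, format = "csv")
  backC <- readSamples(dirC)
  for (i in 1:4)
    expect_equal(backC@samplesOriginal[[i]], ss@samplesOriginal[[i]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(backC@config$tau, 2)

  # empty set round-trips
  empty <- new("FluxSampleSet", samplesOriginal = list(),
               samplesRounded = list(), config = list(nChains = 0L),
               timings = data.frame())
  dirE <- tempfile()
  writeSamples(empty, dirE)
  backE <- readSamples(dirE)
  expect_length(backE@samplesOriginal, 0L)
})

test_that("the CLI pipeline runs end to end, deterministically", {
  root <- tempfile(); dir.create(root)
  pdir <- file.path(root, "simplex")
  sdir1 <- file.path(root, "samples1")
  sdir2 <- file.path(root, "samples2")

  expect_equal(suppressMessages(cliMain(c("simplex", "--d", "2", "--out", pdir))), 0L)
  expect_true(file.exists(file.path(pdir, "A.csv")))

  args <- c("sample", "--polytope", pdir, "--n", "50", "--tau", "auto",
            "--kind", "simplex", "--chains", "2", "--seed", "11")
  expect_equal(suppressMessages(cliMain(c(args, "--out", sdir1))), 0L)
  expect_equal(suppressMessages(cliMain(c(args, "--out", sdir2))), 0L)
  # identical invocations with identical seeds produce bit-identical tables
  expect_identical(readLines(file.path(sdir1, "chain_1.csv")),
                   readLines(file.path(sdir2, "chain_1.csv")))
  expect_identical(readLines(file.path(sdir1, "chain_2.csv")),
                   readLines(file.path(sdir2, "chain_2.csv")))

  expect_equal(suppressMessages(cliMain(c("diagnose", "--samples", sdir1))), 0L)
  expect_true(file.exists(file.path(sdir1, "diagnostics.json")))

  out <- utils::capture.output(
    st <- suppressMessages(cliMain(c("tune", "--polytope", pdir,
                                     "--kind", "simplex"))))
  expect_equal(st, 0L)
  expect_match(out, "guideline tau = 4", all = FALSE)

  # missing input directory: nonzero exit, error message
  expect_equal(suppressMessages(cliMain(c("sample", "--polytope",
                                          file.path(root, "nope"),
                                          "--n", "5", "--tau", "1",
                                          "--out", file.path(root, "x")))), 1L)
  expect_equal(suppressMessages(cliMain(c("frobnicate"))), 1L)
})

test_that("the raw-polytope CLI path preprocesses, rounds and samples a model", {
  root <- tempfile(); dir.create(root)
  raw <- readSBMLModel(toySBMLPath())
  rawDir <- file.path(root, "raw")
  writePolytope(raw, rawDir)
  redDir <- file.path(root, "reduced")
  rndDir <- file.path(root, "rounded")
  expect_equal(suppressMessages(cliMain(c("preprocess", "--in", rawDir,
                                          "--out", redDir))), 0L)
  expect_true(file.exists(file.path(redDir, "provenance.json")))
  expect_equal(suppressMessages(cliMain(c("round", "--in", redDir,
                                          "--out", rndDir))), 0L)
  sdir <- file.path(root, "samples")
  expect_equal(suppressMessages(cliMain(c("sample", "--polytope", rndDir,
                                          "--n", "200", "--tau", "2",
                                          "--seed", "4", "--out", sdir))), 0L)
  ss <- readSamples(sdir)
  X <- do.call(rbind, ss@samplesOriginal)
  # all sampled fluxes satisfy the raw system
  expect_lt(max(abs(X %*% t(raw@Aeq))), 1e-7)
  expect_lt(max(X %*% t(raw@Ain) - matrix(raw@bin, nrow(X), length(raw@bin),
                                          byrow = TRUE)), 1e-7)
})
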