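# Deterministic fixtures shared across tests.

# AR(1) chain matrix (n draws x m chains) with per-chain mean shifts.
ar1Chains <- function(n, m, phi, shifts = rep(0, m), seed) {
  set.seed(seed)
  X <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    e <- stats::rnorm(n)
    X[, j] <- as.numeric(stats::filter(e, phi, method = "recursive")) + shifts[j]
  }
  X
}

# family of mixed fixtures for the reference cross-check (index 1..10)
diagFixture <- function(i) {
  phis <- c(0, 0.3, 0.5, 0.7, 0.9, 0.2, 0.4, 0.6, 0.8, 0.95)
  shifts <- if (i %% 3 == 0) c(0, 0.05, 0.1, 0.15) else rep(0, 4)
  ar1Chains(n = 400, m = 4, phi = phis[i], shifts = shifts, seed = 1000 + i)
}

# small random 2-D polytope (bounded, strictly feasible origin)
random2dPolytope <- function(seed = 7, m = 10) {
  set.seed(seed)
  th <- sort(stats::runif(m, 0, 2 * pi))
  A <- cbind(cos(th), sin(th))
  b <- stats::runif(m, 0.5, 1.5)
  new("ReducedPolytope", A = A, b = b, K = diag(1, 2), nu0 = c(0, 0),
      fluxNames = c("x1", "x2"))
}

# rejection sampler over an inequality polytope given a bounding box
rejectionSample <- function(A, b, lower, upper, n, seed = 1) {
  set.seed(seed)
  d <- ncol(A)
  out <- matrix(NA_real_, n, d)
  got <- 0L
  while (got < n) {
    batch <- matrix(stats::runif(1000 * d, rep(lower, each = 1000),
                                 rep(upper, each = 1000)), 1000, d)
    sl <- batch %*% t(A) <= matrix(b, 1000, length(b), byrow = TRUE)
    ok <- which(rowSums(sl) == length(b))
    take <- utils::head(ok, n - got)
    if (length(take)) {
      out[(got + 1L):(got + length(take)), ] <- batch[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

# toy 3-metabolite, 4-reaction chain model fixture (SBML, FBC v2)
toySBMLPath <- function() {
  testthat::test_path("fixtures", "toy_chain_model.xml")
}
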