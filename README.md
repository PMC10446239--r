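# chrrt — uniform flux sampling with coordinate hit-and-run, rounding and thinning

Constraint-based metabolic models confine their reaction rates (fluxes)
ν ∈ R^D to a convex polytope: steady-state mass balances `A_eq ν = b_eq`
and flux bounds `A_in ν < b_in`. Characterizing a model's solution space —
flux ranges, couplings, marginal distributions — requires **uniform samples**
from that polytope, and for genome-scale models only Markov chain Monte Carlo
is feasible. `chrrt` is an R toolkit for this task, aimed at modelers in the
COBRA ecosystem and at anyone who needs uniform samples from a bounded convex
polytope `{x : Ax < b}`.

The pipeline:

1. **Preprocessing** — LP-based boundedness checks, removal of redundant
   inequalities, reformulation of near-degenerate flux ranges (width ≤ 1e-7)
   as equalities, and null-space dimension reduction
   `ν = K x + ν0` to the effective dimension `d = D − rank(A_eq)`.
2. **Rounding** — the maximum-volume ellipsoid `{c + E u : ‖u‖ ≤ 1}` inscribed
   in the reduced polytope (log-det maximization, primal-dual Newton solver)
   defines the affine map `x_round = E⁻¹ (x − c)` that turns the ellipsoid
   into the unit ball, so the rounded system is `A_R = A E`,
   `b_R = b − A c`.
3. **Sampling** — coordinate hit-and-run on the rounded polytope: pick a
   coordinate uniformly, compute the feasible chord from the constraint
   slacks, move to a uniform point on it. Every τ-th state is stored and
   back-transformed to flux space via `ν = (K E) x_round + ν0′` — one dense
   D×d matrix-vector product per stored sample.
4. **Diagnostics** — split-chain rank-normalized effective sample size and
   R-hat per flux (original space), worst-case aggregated, gated at
   `R-hat < 1.01` and `ESS > 400` (four chains × two split-halves × 50).
5. **Tuning** — because the back-transform dominates per-sample cost, thinning
   *raises* efficiency: ESS per wall-clock second, `ESS/t`, peaks at an
   interior τ. Shipped guidelines: `τ̂ = 2d` for simplices and `τ̂ = d²/6` for
   genome-scale models (48× smaller than the older `8d²` rule), plus a
   benchmarking harness (`benchmarkEfficiency`, `measureTimeRatio`,
   `preRunTauRange`) to re-derive τ for new problem classes.

## Worked example

```r
library(chrrt)

s       <- makeSimplex(5)                      # S_5, a known uniform target
rounded <- buildRounding(computeMVE(s), s)
cfg     <- samplerConfig(N = 5000, tau = guidelineTau("simplex", 5),
                         nChains = 4, seed = 1)
ss      <- runChains(rounded, cfg)
ss
#> FluxSampleSet: 4 chains x 5000 samples, D = 5 (tau = 10, seed = 1)

evaluateConvergence(ss)
#> DiagnosticsReport: min ESS = 10262.7, max R-hat = 1.0005 -> converged

round(colMeans(do.call(rbind, ss@samplesOriginal)), 4)
#>     x1     x2     x3     x4     x5
#> 0.1687 0.1676 0.1668 0.1662 0.1641
```

Uniform draws on the standard simplex are Dirichlet(1,…,1), so every
coordinate mean should be 1/(d+1) = 0.1667 — the pooled means above sit within
Monte-Carlo error of that, the worst-case ESS across the five fluxes is about
half the 20,000 stored draws (the chains mix fast at τ = 2d), and the
convergence gate passes.

For a metabolic model, start from SBML instead:

```r
poly    <- readSBMLModel(system.file("extdata", "toy_chain_model.xml",
                                     package = "chrrt"))
red     <- reduceDimension(preprocessPolytope(poly))
rounded <- buildRounding(computeMVE(red), red)
guidelineTau("gem", effectiveDim(red))
```

The thinning guideline is pure arithmetic at any scale, e.g. for the largest
BiGG reconstruction (d = 4861): `guidelineTau("gem", 4861)` → 3,938,220,
versus `priorAdviceTau(4861)` → 189,034,568 — a factor of 48.

A command-line wrapper with subcommands
`simplex | preprocess | round | sample | diagnose | tune | benchmark` is
installed at `inst/cli/chrrt-cli.R`; every stage reads and writes plain
CSV/JSON exchange directories.

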