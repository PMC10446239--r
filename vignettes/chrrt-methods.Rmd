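---
title: "Uniform flux sampling with coordinate hit-and-run, rounding and thinning"
author: "chrrt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniform flux sampling with coordinate hit-and-run, rounding and thinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrrt)
```

## The sampling problem

A constraint-based metabolic model constrains its $D$ reaction rates (fluxes)
$\nu \in \mathbb{R}^D$ by steady-state mass balances
$A_\mathrm{eq}\,\nu = b_\mathrm{eq}$ (the stoichiometric system; under the
standard steady-state convention $b_\mathrm{eq} = 0$) and by linear
inequalities $A_\mathrm{in}\,\nu < b_\mathrm{in}$ encoding flux bounds. The
feasible set is a convex polytope, and many questions about a model — flux
ranges, couplings, the shape of the solution space — are answered by drawing
*uniform* samples from it. Rejection sampling collapses in high dimension, so
the field's workhorse is coordinate hit-and-run with rounding (CHRR): a
Gibbs-style Markov chain that moves along coordinate axes of a geometrically
preconditioned ("rounded") polytope. This package implements the full
pipeline, with *thinning* — storing only every $\tau$-th state — treated as a
first-class tuning parameter rather than a memory afterthought: because every
*stored* sample must be mapped back to flux coordinates by a dense
matrix-vector product, discarding cheap, highly correlated states in exchange
for more updates per stored sample can raise the effective sample size per
second by large factors.

## Preprocessing chain

`preprocessPolytope()` applies, in order:

1. **Boundedness check** (`checkBoundedness`): two LPs per coordinate; an
   unbounded direction makes uniform sampling ill-defined and is a hard error.
2. **Redundancy removal** (`removeRedundantInequalities`): exact scaled
   duplicates are collapsed to the tighter bound, then row $i$ is dropped when
   maximizing $a_i^\top\nu$ over the remaining rows stays below
   $b_i - 10^{-9}$. The tolerance sits below achievable flux precision and
   above LP solver noise. Removing a truly redundant row never changes the
   feasible set, so the sequential sweep is order-independent and idempotent.
3. **Tightening** (`tightenNarrowInequalities`): a flux whose achievable range
   (LP maximum minus minimum) is at most $10^{-7}$ flux units is fixed at the
   range midpoint and moved into the equality system. By default this applies
   to single-flux ranges; `generalRows = TRUE` extends it to arbitrary
   constraint rows (the narrower reading is the default because bound-induced
   degeneracy is what occurs in practice, and general rows are rarer and more
   expensive to scan).

`reduceDimension()` then eliminates the equalities: an orthonormal null-space
basis $K$ of $A_\mathrm{eq}$ (SVD, rank cutoff
$\sigma_\mathrm{max}\,\max(\dim)\,\varepsilon$) and a strictly interior
particular solution $\nu_0$ give the $d$-dimensional inequality-only polytope
$\{x : A x < b\}$ with $A = A_\mathrm{in} K$,
$b = b_\mathrm{in} - A_\mathrm{in}\nu_0$. We place $\nu_0$ at the Chebyshev
center of the *reduced* polytope (computed by LP and mapped back through
$K$): both the reduced-space center and any interior $D$-space point are valid
choices, and the reduced-space center is cheaper to obtain and strictly
interior by construction, so the reduced origin is always a feasible chain
start. Rows whose reduced coefficients vanish (norm $< 10^{-12}$) with slack
$b > 10^{-12}$ are vacuous in the reduced space and are dropped.

All linear programs run on a dense two-phase primal simplex written for this
package (`solveLP`), with a Dantzig rule switching to Bland's rule to break
cycles; it distinguishes infeasible from unbounded outcomes, which the
preprocessing contracts rely on.

## Rounding by the maximum-volume inscribed ellipsoid

Flux polytopes are strongly anisotropic, which throttles coordinate-wise
samplers. `computeMVE()` finds the maximum-volume ellipsoid
$\{c + E u : \lVert u\rVert \le 1\}$ inscribed in the reduced polytope by
maximizing $\log\det E$ subject to
$\lVert E a_i\rVert + a_i^\top c \le b_i$. The solver is a primal-dual Newton
interior-point method on the KKT system of this log-det program, working in
the dual-weight space where the stationarity condition takes the form
$E^2 = (A^\top Y A)^{-1}$; steps are damped with fraction-to-boundary caps and
the barrier parameter is driven to $10^{-14}$. On boxes the computed ellipsoid
matches the analytic inscribed ellipsoid to $\sim 10^{-13}$; the iteration
count is 5–20 for all shipped test families up to $d = 256$.

`buildRounding()` turns the ellipsoid into the affine change of variables
$x_\mathrm{round} = R\,(x - c)$ with $R = E^{-1}$, under which the ellipsoid
becomes the unit ball at the origin. The rounded system is
$A_R = A R^{-1}$ (rows not re-normalized by default; `scaleRows = TRUE` is
available for numerical hygiene), and the back-transform to flux space is the
single affine map
$\nu = K R^{-1} x_\mathrm{round} + \nu_0'$, with the ellipsoid center folded
into the particular solution $\nu_0' = K c + \nu_0$. A note on conventions:
formulations in the literature differ on whether "$R$" names the map
reduced→rounded or its inverse. Here `R` maps reduced to rounded
coordinates (and sends the ellipsoid to the unit sphere), `Rinv` is the SPD
ellipsoid factor $E$ appearing in the two formulas above; tests pin down the
geometry (unit ball inscribed, surface points mapping to norm 1), which is
convention-free. `backTransformOperator()` precomputes the dense $D \times d$
operator so each stored sample costs one matrix-vector product plus an
addition — this cost is exactly why thinning pays.

## The sampler and the thinning convention

One update of the chain draws a coordinate $k$ uniformly from $1..d$, computes
the feasible chord $(d_-, d_+)$ along $e_k$ from the constraint slacks, draws
$\lambda$ uniformly on the chord, and moves. A sample is stored **after every
$\tau$-th update** (the first store happens at update $\tau$), so storing $N$
samples costs exactly $N\tau$ updates plus $N$ back-transforms — the
convention that matches the cost model
$t_{N,\tau} = N(\tau\,t_\mathrm{update} + t_\mathrm{transform})$. The
alternative reading (store at update counter zero) differs by one sample and
would break the exact correspondence; the convention here is fixed and tested
by the bit-exact equivalence between a $\tau$-thinned chain and the
every-$\tau$-th-state subsample of the unthinned chain under a shared seed.

Numerical and design choices:

* slacks are maintained incrementally ($O(n_\mathrm{in})$ per update), clamped
  at zero from below, and recomputed exactly every 4096 updates; the refresh
  schedule depends only on the update counter, so it cannot break the
  thinning-equivalence contract;
* chord coefficients below `zeroTol` $= 10^{-12}$ are treated as zero; a
  missing positive or negative coefficient means an unbounded chord and is a
  contract violation (bounded polytopes cannot produce it);
* $\lambda$ is drawn on the closed interval; the boundary has probability
  zero;
* no burn-in is applied by default (the chain starts at the inscribed-
  ellipsoid center, an excellent starting point); `burninFrac` can discard an
  initial fraction when a user insists;
* with multiple chains, chain 1 starts at the configured start and chains
  $2..M$ are jittered by a short warm run of $d$ updates under their own
  deterministic sub-seed, so chains do not coincide at $t = 0$;
* the RNG is R's global stream; the compiled chain consumes exactly two
  uniforms per update in the same order as the R-level `chrrtUpdate()`, so
  seed-matched compiled and interpreted trajectories agree, and
  reproducibility is exact given (seed, chain index).

## Convergence diagnostics

`ess()` and `rankNormalizedRhat()` implement the split-chain (50/50),
rank-normalized estimators with Geyer's initial-monotone truncation of the
autocorrelation sum; the folded variant is folded into the reported
$\widehat{R}$ (maximum of bulk and folded). On a single chain with
`split = FALSE, rankNormalized = FALSE`, `ess()` reduces to the classical
$N / (1 + 2\sum_t \rho_t)$ with truncated lag sum — the truncation is what
makes that formula computable at all. Both estimators were cross-checked
against an established Python reference implementation on ten seeded fixtures
(frozen into the test suite): agreement is within 0.4% for ESS and
$2\times10^{-4}$ for $\widehat{R}$.

`evaluateConvergence()` computes both quantities per flux **in original flux
space** (the space in which flux statistics are reported), aggregates the
worst case (minimum ESS, maximum $\widehat{R}$), and applies the gate
$\widehat{R} < 1.01$ and $\mathrm{ESS} > 400$. The 400 arises as 4 chains
$\times$ 2 split-halves $\times$ 50 effective draws per part. Fluxes with
pooled variance below $10^{-14}$ (typically fixed by tightening) are excluded
and listed instead of failing the gate. The gate uses bulk-ESS only; tail-ESS
is computed and reported for information. Runs with fewer than four chains
are evaluated but flagged as non-standard.

## Thinning guidelines and benchmarking

`guidelineTau()` returns the ready-to-apply thinning constants
$\hat\tau_\mathrm{simplex} = 2d$ and $\hat\tau_\mathrm{GEM} = d^2/6$
(round-half-up, floored at 1 — the rule is stated as a formula, so the
integerization is a package choice), and `priorAdviceTau()` the older
$8 d^2$ rule for comparison; the two differ by a factor of 48.
`measureTimeRatio()` measures $t_\mathrm{update}$ and $t_\mathrm{transform}$
by averaging wall-clock times over repeated probe runs;
`benchmarkEfficiency()` sweeps thinning constants, recording worst-case ESS
per sampling wall time (updates + transforms only; the one-time costs of
rounding and interior-point computation are excluded, as they are independent
of the number of samples). Unconverged sweep points are retained in the curve
but carry their convergence verdict. `preRunTauRange()` seeds a sweep from a
short pre-run at $\tau = d$, emitting log-spaced candidates bracketing the
estimated integrated autocorrelation time.

## What the synthetic generators emulate — and what they do not

`makeSimplex(d)` builds the standard simplex (the canonical scalable test
problem: non-redundant by construction, no equalities, null-space basis the
identity, particular solution at its Chebyshev center
$\mathbf{1}/(d+\sqrt d)$). Uniform samples on it are Dirichlet$(1,\dots,1)$,
giving exact moment oracles (coordinate means $1/(d{+}1)$, pairwise
covariances $-1/((d{+}1)^2(d{+}2))$). `makeAnisotropicBox()` builds boxes
with geometrically spaced side lengths and a known analytic inscribed
ellipsoid, optionally randomly rotated — the reference family for rounding
tests. The toy SBML fixture is a hand-built 3-metabolite linear chain whose
steady state forces all four fluxes equal ($d = 1$), covering the full
SBML → preprocess → reduce → round → sample → diagnose path.

These generators probe correctness of geometry, uniformity, diagnostics and
the thinning economics. They do *not* reproduce two features of real
genome-scale models: severe row-count asymmetry ($n_\mathrm{in} \gg d$) and
the extreme anisotropy of biological flux bounds spanning many orders of
magnitude. Passing tests therefore demonstrate algorithmic correctness and
the qualitative thinning behavior, not absolute performance figures on any
particular model.

## Problem sizes and what the benchmarks assert

The test suite and the acceptance script run desk-scale configurations chosen
to make the statistical assertions sharp while completing in minutes:
uniformity on $S_2$ and $S_5$ with $4\times10^4$ stored samples at
$\tau = 2d$; ESS calibration on AR(1) chains with $4\times10^4$ draws
(analytic limit $(1-\phi)/(1+\phi)$); efficiency sweeps on $S_{64}$ and
$S_{256}$ with $N = 1000$ per chain over $\tau \in \{1, d/4, 2d, 16d\}$. For
the sweeps only the *ordering* (thinned at $2d$ strictly beats unthinned) and
the rise-then-fall shape of the curve are asserted: absolute speed-ups are
hardware-dependent and grow with dimension, so the desk-scale factors (about
3–5$\times$ here) are far below what large models exhibit, by design of the
problem sizes rather than of the method.

## Known limitations

* The LP solver is a dense tableau simplex: fine for desk-scale and toy-GEM
  systems, not for $10^4$-constraint genome-scale models; an external LP
  backend would slot in behind the same function surface.
* The SBML reader covers Level-3 FBC-v2 bound annotations only; models
  encoding bounds in kinetic-law parameters are rejected with an explicit
  error rather than guessed at. Missing or infinite bounds are errors —
  default bounds are never invented.
* Sampling non-uniform targets, reflective/Riemannian samplers, and
  covariance-based (non-MVE) rounding are out of scope.
* Chains run sequentially; "parallel" refers to statistical independence, not
  threading.
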