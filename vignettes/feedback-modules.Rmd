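---
title: "Product-feedback inhibition and optimal growth: models and numerics"
author: "feedbackmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Product-feedback inhibition and optimal growth: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedbackmod)
```

## The models

Four small metabolic modules are implemented as deterministic ODE systems
in the metabolite pool sizes, each regulated exclusively by product-feedback
inhibition, together with the flux-balance (FBA) optimum that bounds their
steady-state growth from above.

**Rate laws.** Every bounded, regulated flux is its capacity times a
Hill-type attenuation,
$$J = J_{\max}\,\frac{1}{1 + (P/K)^h},$$
so the flux constraint $J \le J_{\max}$ holds identically; the factor is
$1$ at $P=0$ and $1/2$ at $P=K$. $h$ is an *effective* Hill coefficient
(non-integer values allowed): $h=1$ is simple product inhibition, $h>1$
stands in for the ultrasensitivity generated by covalent-modification
cascades or cooperative transcription, which this package deliberately
does not model mechanistically. A knocked-out feedback is an explicit
flag whose factor is exactly 1 — not $K=\infty$ — to avoid overflow in
$(P/K)^h$. Enzymatic conversions saturate in their substrate as
$P^n/(P^n + K_M^n)$ with $n=2$ where two substrate molecules are consumed
per product molecule.

**Growth law.** Growth is the rate of assembling a heteropolymer from
essential monomers,
$$\mu(\{P_i\}) = \frac{\mu_{\max}}{1 + \sum_i \rho_i\,\sigma_i/P_i},$$
which is strictly increasing in every pool, vanishes as any pool empties,
saturates at $\mu_{\max}$, and becomes insensitive to pool $i$ once
$P_i \gg \sigma_i$. The weights $\rho_i$ rescale each pool's effective
contribution; they equal 1 everywhere except the assimilation cycle, where
glutamate and glutamine are consumed in the ratio
$\rho_E : \rho_Q = 0.85 : 0.15$, a literature-informed split of nitrogen
usage between the two carriers. A pool is labelled *growth-limiting* when
$P \le \sigma$ (inclusive boundary — an arbitrary but fixed convention that
affects labels only). Growth efflux is purely stoichiometric consumption
$\rho_i\,\mu$; no dilution term $-\mu P$ is included, so at steady state
input flux equals consumption exactly.

**Units.** All concentrations are measured in units of the
growth-saturating pool size ($\sigma = 1$ by default) and all rates in
units of $\mu_{\max}$; a flux bound of 2 therefore means "twice what
saturated growth consumes".

**Stoichiometries.**

* *Bidirectional:* `J12` denotes the production rate of pool 2 from
  pool 1; each unit produced consumes two units of the source (a
  low-energy by-product is implicitly released), and both directions share
  one capacity `Jc_max`. Under the Full-FI scheme each interconversion is
  additionally inhibited by its *product* pool, which makes the
  flux effectively ratio-sensing; under Min-FI those brackets are 1.
* *Cycle:* nitrogen input consumes one glutamate per glutamine formed
  (saturating in E, inhibited by Q, or by E in the alternative Min-FI
  variant); the conversion flux consumes one glutamine and returns two
  glutamates (saturating in Q, inhibited by E under Full-FI); biosynthesis
  consuming $\rho_Q\mu$ of glutamine credits one glutamate each —
  implemented as $+\rho_Q \mu$ into E.
* *Integration:* the GS/GOGAT-like nitrogen flux spends `carbon_cost`
  (default 1) units of carbon per nitrogen imported and is assumed
  independent of the carbon pool size (high ATP affinity). That
  assumption is singular at $C = 0$; the right-hand side clips negative
  states to zero and the stiff integrator's step control handles the
  boundary, with a diagnostic flag recording whether clipping ever fired.
  The optional first-order leak (`leak`, default 0) applies to the
  nitrogen pool of the feedback-knockout variant, where it is required
  for a finite post-upshift steady state.

**FBA.** For each module, `fba_optimum()` maximizes $\mu$ subject to
exact stationarity of every pool and the linear bounds, in closed
piecewise form; `fba_lp()` solves the same program with a generic simplex
method and is used as an independent oracle in the tests. Among degenerate
optima the representative is chosen lexicographically: maximal $\mu$, then
minimal interconversion/futile flux, then minimal total input — the
deterministic, biologically efficient assignment (for the bidirectional
module it always has $\min(J_{12}, J_{21}) = 0$). When the leak variant is
active the leak enters the LP as a free non-negative drain, which the
optimum sets to zero; the FBA value is therefore unchanged and remains a
valid upper envelope for the leaky kinetics.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `K` (input feedbacks) | pool size at half-inhibition | 100–1000 σ | must far exceed σ so feedback stays silent while the pool is growth-limiting; the growth deficit shrinks as K grows, at the cost of pool ∝ K |
| `h` | effective Hill coefficient | 1 or 4 | 1 = plain product inhibition; 4 = ultrasensitive variant that restricts non-limiting pools (∝ excess$^{1/h}$) and sharpens regime switches |
| `K_M` (interconversion) | Michaelis constant of the outgoing conversion | 100 σ | keeps interconversion off while both pools are near σ (futile-cycle avoidance) |
| interconversion bracket `K` | product-feedback on the conversion | 5 σ | between σ and K_M: shuts the backflow once the receiving pool is non-limiting while barely throttling the wanted direction |
| `K_M` (cycle input) | glutamate affinity of assimilation | 0.1 σ | glutamate should saturate the first step so nitrogen import is maximal |
| `K_N1` vs `K_N2` | GDH vs GS/GOGAT feedback constants | 1000 vs 50 | `K_N1 ≫ K_N2` turns the costly carbon-dependent route on only after the free route saturates (GDH preference under carbon limitation) |
| `rho_E`, `rho_Q` | growth stoichiometries of E and Q | 0.85 / 0.15 | relative glutamate/glutamine usage during biosynthesis |
| `leak` | first-order nitrogen leak (knockout variant) | 0.01 μ_max | small relative to growth; sets the knockout's post-upshift nitrogen pool (~accumulated excess / leak) and its equilibration timescale (~1/leak) |
| `carbon_cost` | carbon per GS/GOGAT nitrogen | 1 | the coupling ratio; exposed because only its positivity, not its value, drives the regime structure |

## The fixture catalog as synthetic study conditions

`fixture()` ships six named parameter sets (`fig1_linear`,
`fig1_bidirectional`, `fig2_cycle`, `fig2_integration`,
`fig3_upshift_wt`, `fig3_upshift_ko`). They are this package's own
synthetic operating points, chosen once to satisfy the ordering rules
above and then frozen; each carries a provenance note saying exactly that.
They emulate the canonical computational experiments — input-flux sweeps
against the FBA envelope, the three-regime stability scan of the cycle,
and a nitrogen upshift from a nitrogen-limited to a growth-saturated
state (both nitrogen bounds raised tenfold at $t=0$, carbon bound fixed)
comparing full regulation against a GS-feedback knockout with a nitrogen
leak.

What they do *not* emulate: real kinetic constants or absolute
concentrations of any organism; transcriptional dynamics, covalent
modification cascades and their time delays (hence no transient overshoot
of the glutamine-like pool, a known signature of delayed feedback);
osmotic or toxicity feedback of large pools on growth; and measurement
noise — the models are deterministic, so passing tests demonstrate the
regulatory logic, not quantitative agreement with any particular dataset.

## Numerics

* **Integration**: `deSolve::lsodar` (stiff, adaptive), relative tolerance
  $10^{-8}$, absolute $10^{-10}$, with a root function that stops once the
  scaled residual $\max_i |\dot P_i| / \max(1, \lVert P\rVert)$ falls
  below $10^{-8}$; the steady state is then confirmed over a further
  10-time-unit window. Trajectories are clipped at zero from below
  (non-negativity is a model property; clipping only absorbs integrator
  round-off and the singular carbon boundary).
* **Steady states**: relaxation by integration over a geometric ladder of
  horizons, followed by a damped Newton polish (finite-difference
  Jacobian, backtracking line search, non-negativity clipping) to
  residuals near machine precision — necessary because at large feedback
  constants the flux-balance function is extremely flat around the root.
  `method = "root"` skips relaxation and Newtons directly from the guess
  (with scaled restarts), which also finds *unstable* roots.
  Non-convergence is a first-class result (`converged = FALSE`), because
  regimes in which a pool grows without bound are a finding, not a
  failure; divergence is declared when the integrator breaks down or a
  pool passes $10^{12}$.
* **Stability**: eigenvalues of the finite-difference Jacobian at the
  steady state; stable iff every real part is below $-10^{-8}$, with
  near-marginal states flagged and reported unstable. The verdict is
  insensitive to the differencing step over $10^{-6}$–$10^{-4}$ relative
  perturbations (tested).
* **Default initial state**: all pools at $0.1\,\sigma$ — small but
  positive, avoiding the absorbing $\mu = 0$ boundary. The cycle's
  stability scan classifies each scheme from this common start:
  `stable`, `unstable` (positive leading eigenvalue), `collapsed`
  (converged with $\mu < 10^{-3}\mu_{\max}$: the cycle stalled, a pool
  shrank to zero), or `diverged` (unbounded pool). Collapse and
  divergence are both failures of regulation in the scan's accounting.
  The Min-FI cycle variants are bistable in parts of parameter space — a
  stable positive root can coexist with the collapse basin — so the scan
  deliberately reports reachability from the standard start rather than
  mere existence of a root.
* **Sweeps**: warm-started continuation along the grid, with cold-start
  spot checks at 10 indices to flag multistability.
* **LP**: `boot::simplex` on problems with 2–5 variables; the
  lexicographic passes re-solve with the previous optimum imposed as a
  constraint (tolerance $10^{-9}$ relative). Degeneracy is detected by
  maximizing, then minimizing, total flux at the optimal $\mu$ and
  comparing. The all-bounds-zero corner is returned directly (the solver
  mishandles it).

## Design choices that were genuinely open

* **Futile-cycle metric**: the index $\min(J_{12},J_{21}) /
  \max(J_{12},J_{21},\varepsilon)$ is 1 *by symmetry* at any
  input-symmetric operating point, however small both fluxes are, and
  blows up near the direction-switch point where the wanted net flux
  vanishes. The package therefore reports, alongside the index, the
  absolute futile flux as a fraction of growth-supporting flux, and the
  tests assert the index bound only where the ratio-sensing mechanism is
  engaged (donor pool above the interconversion feedback constant) while
  bounding the absolute waste everywhere. Suppressing deep-regime
  backflow requires the ultrasensitive ($h=4$) brackets; with $h=1$ the
  $1/(1+P/K)$ tail is too weak once the donor pool saturates its own
  outgoing conversion.
* **Pool-scaling slopes**: inverting the inhibition law at saturated
  growth gives pool $= K\,(J_{\max}/\mu_{\max}-1)^{1/h}$: the pool is
  linear in $K$ for *every* $h$, and the $1/h$ sublinearity lives in the
  input-flux excess. `tradeoff_surface()` fits both slopes, regressing
  the second on $\log(J_{\max}/\mu_{\max}-1)$, where the exponent is
  exact rather than asymptotic.
* **Matched-deficit comparison**: the ultrasensitive pathway's smaller
  pools are demonstrated at equal growth-rate deficit by root-solving for
  the $K$ (at $h=4$) that reproduces the $h=1$ deficit, then comparing
  pools at the same operating point.
* **Upshift summary statistics**: fold changes are normalized to the
  pre-shift steady state; the "peak fold change" of a pool is the
  largest $|\log_2|$ excursion (the carbon-like pool *drops* on a
  nitrogen upshift, so magnitudes are compared); the growth curve is
  cumulative biomass $\exp\int \mu\,dt$ normalized at the shift.
  The simulation horizon (400 time units) covers the knockout's
  leak-limited equilibration.
* **Robustness draws** perturb every flux bound, feedback constant, leak
  and shift value by independent uniform factors in $1\pm0.2$, identically
  for both strains, under one seeded generator (default seed 20100603).

## Known limitations

Only the four fixed topologies are supported — this is a study of
regulatory principles on representative modules, not a general network
simulator. FBA here maximizes growth only (no ATP-yield or
minimal-adjustment objectives). Stability analysis is local
(no bifurcation continuation, no global basins beyond the default-start
scan, no stochastic dynamics). Effective Hill coefficients compress all
ultrasensitivity mechanisms into one exponent, so questions about *how*
ultrasensitivity is implemented — and its time delays, which produce the
overshoots the deterministic model lacks — are out of scope. Problem sizes
throughout (grids of 6–50 points, 50 robustness draws, 100–200 random FBA
cross-checks) were chosen as the package's standard study sizes; all are
arguments and can be scaled up.
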