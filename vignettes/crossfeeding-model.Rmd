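---
title: "A saturating-growth model of a two-strain cross-feeding mutualism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A saturating-growth model of a two-strain cross-feeding mutualism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The model

Two engineered budding-yeast auxotrophs cross-feed: the Trp⁻ strain (density
$X$) overproduces leucine and the Leu⁻ strain (density $Y$) overproduces
tryptophan. Each strain's per-capita growth saturates (Monod form) in the
pool formed by its partner plus the supplemented amino acid, is crowded
logistically against a shared carrying capacity (normalized to 1), and dies
at a rate $\delta$ that stands in for the daily 10× dilution of the
experimental protocol:

$$\frac{dX}{dt} = r_x X \frac{Y + a}{Y + a + \kappa}(1 - X - cY) - \delta X,$$
$$\frac{dY}{dt} = r_y Y \frac{\beta X + a}{\beta X + a + \kappa}(1 - cX - Y) - \delta Y.$$

Tryptophan and leucine are always supplemented at a fixed 1:8 ratio, chosen
to match the strains' intracellular demand, so a single dimensionless
coordinate $a$ describes the condition. Assumptions worth keeping in mind:
the Monod reduction treats the amino-acid pools as fast variables (we do
not implement the resource-explicit version); growth, leakage and uptake
are folded into two effective asymmetry constants; and continuous death
approximates a discrete dilution protocol (see the batch map below for
where that matters).

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `r_x` | 1 | 1/time | Trp⁻ maximum growth rate; defines the time unit |
| `r_y` | 0.925 | 1/time | Leu⁻ maximum growth rate (≈7.5% intrinsic disadvantage) |
| `kappa` | 0.12 | density | Monod constant, shared by both terms because of the 1:8 supplementation ratio |
| `beta` | 2 | — | benefit asymmetry: Trp⁻ contributes more to its partner |
| `delta` | 0.5 | 1/time | death rate representing daily 10× dilution |
| `a` | condition | density | supplemented amino-acid level |
| `c` | 1 | — | niche overlap; `c < 1` weakens inter-strain crowding only in the logistic term, never in the cross-feeding pool |

Time is dimensionless ($r_x = 1$ defines the unit) and not configurable.
The mapping from experimental concentrations to $a$ is not experimentally identifiable; `conc_to_a()` uses a linear convention of 0.1
per µM tryptophan — chosen once so that the experimentally obligate
condition (1 µM) lands in the model's obligate window ($a \approx 0.1$) —
and is overridable everywhere.

## Fixed points, boundaries, classification

`find_equilibria()` returns the origin, the axis (monoculture) points from
their closed form $1 - \delta/(r\,g(a))$, and all interior points. Interior
points are found by eliminating $X$ through the $X$-balance condition and
scanning the residual of the $Y$-balance on a $10^4$-point grid followed by
bisection of every sign change: brute force, but exhaustive at desk scale
and free of basin-of-attraction issues a Newton polish would introduce.
Exact zeros of the residual are only accepted when isolated, because at
$\delta = 0$ the balance conditions degenerate into a continuum (a line
attractor, not isolated fixed points). Stability is decided on the real
parts of the analytic Jacobian's eigenvalues (tolerance $10^{-10}$); the
finite-difference Jacobian appears only as a cross-check in the tests.
Eigen-pairs are ordered slow-first (largest real part).

Two boundaries are located by bisection in $a$ (tolerance $10^{-8}$, far
below any printed precision): the saddle-node point `saddle_node_point()`
where coexistence first exists, and `exclusion_threshold()` where the
interior point leaves through the $X$ axis (a transcritical passage, so
$Y^*$ vanishes continuously there). The monoculture viability thresholds
have closed forms $\delta\kappa/(r - \delta)$ and serve as oracles for the
scan. With the default parameters the four boundaries fall at
$a^* \approx 0.0824$, $a_x = 0.12$, $a_y \approx 0.1412$ and
$a_{excl} \approx 0.7328$.

`classify_regime()` compares the stable co-culture attractor with the two
monoculture equilibria: both monocultures inviable gives collapse (no
interior) or obligatory mutualism (interior); exactly one viable gives the
mixed obligatory/facultative regime; both viable leads to a sign table
(benefit `+`, harm `-`, neutral `0` within a relative band `rel_tol`,
default 1%) distinguishing facultative mutualism, parasitism, amensalism
and competition; no interior attractor with a viable winner is competitive
exclusion. Design choices here:

* **Amensalism is a boundary band.** One strain being exactly unaffected is
  a measure-zero condition; the finite band makes it reportable, which is
  also why `regime_sequence()` by default attributes amensalism intervals
  to their neighbouring boundary when counting distinct regimes. The model
  produces two such bands: at the parasitism/competition crossing (the Leu⁻
  strain neutral — the configuration seen experimentally) and just below
  exclusion, where the survivor's co-culture density converges to its
  monoculture value as $Y^* \to 0$.
* A neutral call whose partner is not strictly harmed is re-resolved by the
  raw sign of the difference, so band artefacts cannot produce labels
  outside the eight-regime taxonomy.
* When an interior attractor coexists with a stable axis attractor the
  interior one defines the label and the bistability is recorded in the
  result's details; genuinely conflicting stable attractors raise a typed
  ambiguity error rather than guessing.
* Extinction means a stable attractor density below $10^{-6}$ on the
  normalized scale.

## Dynamics and the early-warning diagnostics

`integrate_continuous()` uses `deSolve`'s lsoda with relative tolerance
$10^{-9}$, absolute $10^{-12}$, clamping at zero and snapping densities
below $10^{-10}$ to exactly zero to avoid underflow chatter. Terminal fates
are assigned by proximity ($10^{-4}$) to a stable fixed point, except that
an (essentially) empty state is always "extinction": the empty state is
absorbing even in regimes where it is dynamically repelling. Fate grids
default to a 500-time-unit horizon; anything unresolved by then is
labelled, not extended.

`relaxation_diagnostics()` quantifies the anisotropy that provides advance
warning of collapse: the ratio of eigenvalue magnitudes, and the |cosine|
of the slow eigenvector against the radial direction through the
equilibrium (constant strain ratio $f = X/Y$) and against
$(1,-1)/\sqrt{2}$ (constant total density $n = X + Y$). Near the fold the
slow direction is radial (total density is the slow variable; alignment
> 0.99 at $a^* + 0.002$); near exclusion it is the constant-$n$ direction
(the ratio is slow). In between, the eigenvalues are comparable and no
direction dominates dynamically.

## The stochastic model

`gillespie_simulate()` is an exact direct-method simulation of the
birth–death process whose mean-field limit is the ODE, on a lattice of
`omega` individuals at carrying capacity. Births occur at the Monod-
saturating logistic rates with the logistic factor clamped at zero above
carrying capacity (the minimal non-negative rate choice), deaths at
$\delta$ per head; the origin is absorbing. No system size or propensity decomposition is fixed by the underlying
experiments, so this birth/death split is the canonical construction for a
logistic-Monod mean field. The core
is compiled (Rcpp) and draws from R's RNG, so a `set.seed()` gives a
bit-identical event sequence. Default `omega = 10^4` is large enough to
track the ODE yet small enough to show near-fold fluctuations; ensembles
use one derived seed per replicate and refuse duplicated seeds.

## The four-strain invasion extension

`four_strain_rhs()` adds a double producer D (needs no amino acids, grows
slowest) and a non-producer N (needs both pools, grows fastest), all four
strains sharing one carrying capacity. Production weights default to 1.
The biology constrains only the rate ordering
$r_d < r_y < r_x < r_n$; the default magnitudes are this package's
choice, and the obvious "small margins" choice fails: linear invasion
analysis shows the double producer invades the pair equilibrium whenever
$r_d > r_x g_x(Y^* + a)$, and $g_x$ stays below ≈0.86 over the whole
coexistence range, so e.g. $r_d = 0.85$ would invade almost everywhere,
while an $r_n$ barely above 1 postpones non-producer invasion to
supplementation levels far beyond the scanned range. The defaults
$r_d = 0.7$, $r_n = 1.2$ place all three zones inside $a \in (0, 1]$:
D dominates below $a \approx 0.12$, the mutualism repels both invaders up
to $a \approx 0.27$, and N dominates beyond $a \approx 0.3$. Invasion
calls use a 10×-inoculum success / 0.1×-inoculum failure criterion with an
explicit unresolved category.

## The synthetic plate experiment and what it does (not) emulate

`simulate_plate()` emulates the daily protocol: wells are seeded at a
total density `n0`, grown for `t_day` time units with $\delta = 0$
(dilution is the only death process in batch), measured, then diluted
10×. Defaults follow the experimental design: 7 days, 16 conditions from
0 to 200 µM tryptophan (leucine at 8×), monocultures plus co-cultures at
six starting ratios. Measurement noise is multiplicative lognormal on OD
(sd 0.05, a package convention standing in for an instrument model) and a
binomial draw of 10,000 cells for the cytometry fraction; extinct wells
report a detection-floor OD and an *empty* fraction field (a sentinel,
never 0/NaN). `t_day` defaults to $\ln(10)/0.5 \approx 4.61$ so that the
10× dilution corresponds exactly to the continuous model's $\delta = 0.5$;
this makes the batch monoculture viability threshold coincide with the
closed form exactly, and gives a saturated monoculture ≈6.6 doublings per
day, comfortably above the $\log_2 10 = 3.3$ survival minimum.

The generator deliberately does **not** emulate: strain adaptation over
the course of the experiment, instrument drift or well-to-well media
variation, OD nonlinearity at high density, or any resource-explicit
amino-acid dynamics. Passing tests therefore demonstrate that the
estimation pipeline inverts *this* generative model, not that it is robust
to every artefact of real plate data.

A consequence of the batch protocol worth stating explicitly: the iterated
growth–dilution map has slightly different boundary positions from the
continuous model (its within-day densities sweep a range instead of
sitting at equilibrium). The end-to-end agreement check therefore compares
pipeline estimates against `classify_regime_batch()` — the same decision
table fed with the deterministic daily-dilution equilibria — so that a
protocol-level boundary shift is not misread as an estimation failure.
Conditions for that check are chosen mid-regime (and, for amensalism,
exactly at the batch-protocol boundary), with a 15-day noise-free design
so near-threshold transients have settled.

## Estimation procedures

* `relative_fitness()` is the odds-ratio fold change of the Leu⁻ fraction
  over one day, $W = \frac{f_1/(1-f_1)}{f_0/(1-f_0)}$ — a convention
  chosen because it needs only cytometry fractions, is symmetric under
  strain relabeling, and equals the ratio of fold-growths when total
  growth is shared.
* `equilibrium_fraction_bootstrap()` fits $\log W$ against the
  start-of-day fraction (linear, working on the log scale where fitness ratios are additive) and reports the zero crossing with a percentile CI over 2000
  record resamples. Records with no sign change over the observed range
  raise a typed no-equilibrium error — which is itself evidence: a
  materially one-signed drift (|mean log W| > 0.05) is how the pipeline
  recognizes competitive exclusion within a finite experiment, allowing equilibria to be
  estimated from growth trends when a culture has not yet settled.
* `detect_equilibrium()` calls a track converged when OD and fraction
  change by less than 10% per day over a trailing 3-day window; a
  monotone geometric decay is extrapolated to extinction rather than
  averaged, since a culture whose growth cannot balance dilution is fated
  regardless of its current OD.
* `estimate_growth_disadvantage()` inverts per-day fitness into
  $1 - r_y/r_x$ with a first-order composition correction
  ($\rho = (1 - q f_x)/(1 + q(1 - f_x))$, $q = -\overline{\log W}/\ln 10$),
  removing the bias the naive estimator $q$ carries when both strains are
  abundant.

## Problem sizes and numerical conventions

The analysis scripts and test suite run at desk scale by choice: interior
scans at $10^4$ grid points, regime sweeps at $10^{-3}$–$5\times10^{-3}$
steps in $a$, Gillespie ensembles of 20 replicates at $\Omega = 10^5$
(plus 60–100 replicates at $\Omega \le 4000$ for extinction statistics),
100 synthetic replicates for CI-coverage checks, and 7–15 day plates.
Bisection tolerances ($10^{-8}$ in $a$) and integrator tolerances
($10^{-9}/10^{-12}$) are far tighter than any quantity compared against,
so none of the reported brackets depend on them.

## Known limitations

* The µM-to-$a$ mapping is a convention; absolute concentration axes are
  therefore not comparable to experimental figures, only orderings and
  regime structure.
* The classifier's neutrality band makes amensalism's width (and hence
  whether a given coarse grid hits it) a function of `rel_tol`; the
  package treats it as a boundary annotation for exactly this reason.
* Near-threshold monocultures decay arbitrarily slowly; finite plates
  cannot distinguish them from viable ones without the extrapolation rules
  above, and those rules have a resolution limit of roughly 5% decay per
  day.
* No evolutionary dynamics: strain types are fixed, and the invasion
  module asks only about ecological invasibility.
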