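---
title: "The rotation recruitment model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rotation recruitment model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murotation)
```

## The model

Postural (tonic) muscles hold submaximal isometric contractions for hours.
Intramuscular recordings show that their motor units are not recruited in the
fixed smallest-to-largest ("onion skin") order of phasic muscles but in
*rotation*: subsets of units take turns contracting and relaxing, like workers
on shifts. Because a muscle fiber replenishes oxygen, glucose, and ATP mainly
while it is relaxed — contraction compresses the microvascular bed that
supplies it — the ratio of relaxation time to contraction time, $t_r/t_c$, is
a natural index of each unit's opportunity to recover. The energy-crisis
account of myofascial trigger points holds that trouble starts when
consumption outruns replenishment; in a rotating muscle that happens not to a
privileged "Cinderella" subpopulation but to *any* unit whose shifts leave it
too little rest.

`murotation` implements this mechanism as a stochastic simulation with two
deliberately simple ingredients.

**Force balance.** A muscle of $n$ motor units with twitch forces $f_i$
carrying a load $F$ must keep enough units contracted that their forces sum
to the load:

$$F \le \sum_{i \in \text{recruited}} f_i ,$$

with the recruited set kept minimal (recruiting stops as soon as the
inequality holds). The *recruitment ratio* $R$ is the fraction of units
recruited at a given moment.

**Duty cycle.** If a fraction $R$ of units must be contracted at all times
and every unit takes its fair turn, each unit is contracted a fraction $R$ of
the time, so over a long run

$$\frac{t_r}{t_c} = \frac{1 - R}{R}.$$

The ratio is 1 at $R = 0.5$ (a second of rest per second of work), 0 at full
recruitment, and grows without bound as the load vanishes. Everything the
package computes — load sweeps, strength sweeps, thresholds, chronicity
trajectories — follows from how $R$, and through it $t_r/t_c$, responds to
load and to muscle strength. Firing-rate modulation is deliberately outside
the model: during a prolonged isometric contraction of a postural muscle,
force is assumed to be graded by how many units are recruited, not how fast
they fire.

## The simulated muscle

`mu_pool()` builds the muscle as a vector of twitch forces. Unit $i$ of $n$
receives

$$f_i = \rho^{\left((i-1)/(n-1)\right)^{\gamma}},$$

where $\rho$ is `force_range_ratio` (largest over smallest force) and
$\gamma$ is `shape_exponent`. With $\gamma = 1$ this is the classical
exponentially spaced pool of the motor-unit modelling literature: forces span
$[1, \rho]$ with many small units and few large ones (the mean force exceeds
the median for any $n \ge 2$). Defaults are $n = 100$ units and $\rho = 100$,
the typical hundred-fold twitch-force range in pool models; both are
configurable, and an optional lognormal jitter (`jitter_sd`) roughens the
deterministic spacing without destroying the skew. Force units are arbitrary
throughout: every load in the package is expressed as a fraction of a pool's
maximum strength (the sum of its twitch forces), so the units cancel.

## Stochastic shift recruitment

Each shift epoch draws a fresh recruited set. Units are sampled one at a time
without replacement, with selection probabilities proportional to the policy
weights renormalized among the units not yet drawn, and sampling stops the
moment the accumulated twitch force reaches the load. Two policies are
provided, matching the two recruitment distributions of interest: `uniform`
(all units equally likely) and `small_biased`, with weight
$\propto f_i^{-b}$ for bias strength $b \ge 0$. The power-weight family is
the simplest monotone family that contains the uniform policy as the exact
$b = 0$ limit; $b$ defaults to 1.

Internally the sequential draw is realized by the *exponential race*: unit
$i$ receives an arrival time $E_i/w_i$ with $E_i \sim \text{Exp}(1)$, and
sorting arrival times ascending reproduces sequential weighted sampling
without replacement exactly. This makes a shift one vectorizable pass (the
inner loop is compiled C++ using R's own RNG, so every result is reproducible
from an integer seed), and it gives both policies a single code path: with
equal weights the race *is* the uniform draw, which is why `bias_strength =
0` reproduces uniform results bit for bit. The test suite verifies the race
construction against exhaustive enumeration of all sampling orders, with
their exact sequential probabilities, on pools of five units.

Conventions at the edges: a zero load recruits nothing ($R = 0$; the duty
ratio is undefined there and reported as such, never as a large number), a
load above maximum strength raises an infeasibility error, and a load equal
to maximum strength recruits every unit even if floating-point summation of
the permuted forces falls an ulp short.

## Rotation, tallies, and the headline statistic

`simulate_rotation()` runs `n_shifts` epochs (default 1000), redrawing the
recruited set independently each epoch — memoryless rotation, the simplest
stochastic realization of shift-like recruitment. Units in the set accrue one
`shift_duration` of contraction time; all others accrue relaxation time.
`shift_duration` (default 1) is a pure scale factor: all reported ratios are
dimensionless and invariant to it.

The headline statistic is the *mean over units of the per-unit ratio*
$t_r/t_c$, matching how relative relaxation time is plotted against load and
strength. Units never recruited in a finite run have infinite ratio; they are
excluded from the mean and counted separately (`n_never_contracted`). The
pooled alternative — total relaxation time over total contraction time — is
reported alongside as `pooled_ratio`; under uniform rotation the two coincide
at convergence, and the per-unit form is primary because the energy-crisis
argument is about individual units, not muscle-average bookkeeping.

One consequence of whole-unit recruitment is worth stating plainly: because
recruiting stops only when the load is *met or exceeded*, the realized mean
$R$ at a load fraction $x$ sits slightly above $x$ (the crossing unit
overshoots the balance point), so at a 50% load the simulated mean ratio
comes out near 0.98 rather than exactly 1 — the value $(1-R)/R$ would give at
$R$ exactly one half. The effect shrinks as pools grow finer-grained; it is
the discreteness of motor units, not a numerical artifact.

## Sweeps and seeding

`sweep_load()` and `sweep_strength()` reproduce the two central experiments:
ratio versus load fraction for one muscle, and ratio versus maximum strength
under one constant absolute load (20% of a reference muscle's strength by
default). Each grid point runs 100 replicate simulations of 1000 shifts by
default, and error bars are the between-replicate standard deviation of the
per-replicate mean ratio. The default grids — load fractions 0.05–0.95 in
steps of 0.05, strength multipliers 0.2–2.0 in steps of 0.1 — span the
plotted ranges of interest; the replicate count is the stated simulation
count of the original figures, while grids and shifts-per-replicate are this
package's own choices, sized so that within-replicate Monte-Carlo error is
well below the between-replicate spread. Multipliers too weak to carry the
fixed load are flagged infeasible rather than silently dropped.

Replicate $k$ runs under seed `base_seed + k` *at every grid point*. These
common random numbers mean each replicate's recruitment permutations are
identical across loads, so each replicate's ratio curve — and hence the grid
means — is exactly monotone in load (and in strength multiplier), and the
strength sweep at multiplier 1 reproduces the load sweep's matching point
bit for bit. `compare_bias()` reuses the same seeds for both policies, so the
uniform and small-biased curves differ only by policy, and their qualitative
similarity is summarized as trend direction plus Spearman rank correlation
(no hypothesis test: the claim under study is qualitative).

## Thresholds and chronicity

If the energy crisis is a threshold phenomenon — triggered when $t_r/t_c$
falls below some critical value — then each muscle has a *threshold load*
above which its units are underrested. `threshold_load()` finds it by
bisection on the load fraction, seeded identically at every evaluation so the
simulated ratio is exactly non-increasing in load and the bracket shrinks
cleanly; the analytic inverse $R^\ast = 1/(1 + \text{critical ratio})$
initializes the bracket. The default stopping half-width is 0.005 of maximum
strength with 2000 shifts per evaluation. The critical ratio itself is a
required argument with no default: no physiologically established value
exists, and supplying one would present a modelling choice as a measurement.

Because recruitment depends on the load only through the load fraction, the
threshold *fraction* is invariant to pool scaling (the tests verify exact
invariance across multipliers 0.25–4). `simulate_chronicity()` exploits this:
it computes one threshold fraction and propagates it along a declining
strength curve instead of re-running the bisection at every time step.
Strength declines exponentially ($S_0 e^{-rt}$) or linearly
($S_0(1 - rt)$, rejected if it reaches zero within the trajectory) — both
forms are illustrative parameterizations, not fitted models. Day-to-day
loads are i.i.d. lognormal, specified by a mean load fraction (default 0.3
of initial strength) and coefficient of variation (default 0.4) — a
stationary, right-skewed load history for a muscle mostly lightly used with
occasional heavy demands — or any user-supplied load series. A pain episode
is flagged exactly when the applied load exceeds the current threshold; as
strength declines the threshold declines in proportion, episodes become more
frequent, and once everyday loads exceed the threshold every step is an
episode — chronicity.

## What the simulations do and do not show

All data in this package are synthetic by design: the point is whether the
rotation mechanism *can* produce the claimed dependencies, not to fit any
measured muscle. The generator captures a skewed pool, stochastic rotation,
and force balance; it omits firing-rate modulation, fatigue, metabolite
dynamics, recovery between episodes, within-shift force redistribution, and
any hierarchical recruitment component real postural muscles may mix in.
Passing tests therefore demonstrate internal consistency of the mechanism
and its qualitative trends — ratio falling with load, rising with strength,
robust to the recruitment-bias choice — not quantitative agreement with any
in vivo measurement.

Numerical conventions collected in one place: recruitment stops at
accumulated force $\ge$ load (minimal set under the sampling order, whole
units only); $R$ is a count fraction, not a force fraction; ties never need
breaking because stopping is on the force inequality; zero-load ratio is
undefined and flagged, never a large number; time conservation per unit
(contraction plus relaxation equals total simulated time) is exact in the
count domain and remains exact in time units for dyadic shift durations;
never-recruited units are excluded from ratio means and reported; all
randomness descends from user-supplied integer seeds, kept below $2^{31}$.

The test suite runs the full default study conditions (100 replicates of
1000 shifts per grid point, the 19-point load grid and 19-point strength
grid, both policies) for the acceptance checks, and smaller pools (20–50
units, hundreds of shifts) for unit and property tests; the convergence
check of the duty-cycle relation uses 5000 shifts, where each unit's
empirical ratio is compared with $(1-\bar R)/\bar R$ at three delta-method
standard errors.
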