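---
title: "Stochastic resource competition along fitness-inequality gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic resource competition along fitness-inequality gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rstarcomp)
```

## The model

`rstarcomp` simulates two consumer species competing for one mineral
resource in an open, chemostat-like system, in discrete time. The
deterministic skeleton is classical resource-competition (Monod) dynamics:

$$N_i(t+1) = N_i(t) + \mu_i N_i(t)\frac{R(t)}{K_i + R(t)} - D\,N_i(t)$$
$$R(t+1) = R(t) + D\,(I - R(t)) - \sum_i Q_i\,\mu_i N_i(t)\frac{R(t)}{K_i + R(t)}$$

where $N_i$ is the density of species $i$ (individuals/L), $R$ the resource
concentration (µmol/L), $\mu_i$ the maximum growth rate (1/day), $K_i$ the
half-saturation constant (µmol/L), $D$ the dilution rate (1/day), $I$ the
inflow concentration (µmol/L) and $Q_i$ the resource bound into each new
individual (µmol/individual). Setting per-capita growth equal to dilution
gives the break-even resource concentration

$$R^*_i = \frac{D\,K_i}{\mu_i - D},$$

the equilibrium concentration a monoculture of species $i$ drives the
system to. With one limiting resource, equilibrium theory predicts that the
species with the lower $R^*$ excludes the other.

Demographic stochasticity enters through Poisson births and deaths whose
means are the deterministic terms, evaluated at time-$t$ values:

$$N_i(t+1) = N_i(t) + \mathrm{Pois}(G_i) - \min\!\big(\mathrm{Pois}(M_i),\,N_i(t)\big),
\qquad G_i = \mu_i N_i \frac{R}{K_i+R},\quad M_i = D\,N_i.$$

The resource receives no direct noise, but uptake is forced to equal the
births each species actually achieved, $Q_i b_i$, so it inherits the
demographic fluctuations. Populations are integers in stochastic mode; a
population is extinct once it falls below one individual (below 1.0 in the
continuous deterministic mode, where the threshold is applied every step so
extinction is absorbing in both modes).

## The fitness-inequality parameter space

Fitness inequality is manipulated by placing the two species on mirrored
linear $R^*$ gradients: over `n_points` (default 35) grid points species A's
$R^*$ ascends from 1.10 to 1.78 µmol/L while species B's descends over the
same values, so the species swap competitive ranks across the central point
(index 18), where both have $R^* = 1.44$ and inequality is zero. Relative
fitness at a point is the ratio of the competitors' $R^*$ values and
fitness inequality is $|R^*_a/R^*_b - R^*_b/R^*_a|$; one grid step off
equality gives 0.056, and the gradient ends at 1.000.

Two growth regimes share this $R^*$ range. In the *low-growth* regime
($K = 0.072$ µmol/L held, $\mu$ between 0.104 and 0.107 1/day) per-capita
growth barely exceeds dilution even at abundant resource, so dynamics are
slow; in the *high-growth* regime ($K = 4.32$ µmol/L, $\mu$ between 0.343
and 0.493 1/day) initial growth is fast although both regimes equilibrate
at identical $R^*$ values. By default $\mu$ varies along the gradient with
$K$ held; setting `varying = "K"` instead holds $\mu$ at its regime median
(0.105 or 0.4 1/day) and recomputes $K = R^*(\mu - D)/D$. Alternative
dilution rates (0.05, 0.01 1/day) retain the held parameter and recompute
the varying one, so the grid's $R^*$ values are preserved exactly; this is
checked to 1e-12 relative tolerance for every constructed point, along with
the algebraic fixed-point identity $\mu R^*/(K+R^*) = D$.

```{r space}
ps <- build_parameter_space(regime = "high_growth")
round(ps[c(1, 18, 35), c("rstar_a", "rstar_b", "mu_a", "mu_b", "inequality")], 3)
```

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `dilution` (D) | 0.1 | 1/day | loss rate for both species and the resource; sets the timescale of exclusion |
| `inflow` (I) | 10 | µmol/L | resource supply; with `initial_resource = I`, $R(t) \in [0, I]$ always |
| `quota` (Q) | 1e-6 | µmol/individual | converts births to uptake; small Q means single-species equilibria near $(I - R^*)/Q \approx 8.6\times10^6$ individuals |
| `initial_sizes` | 1, 2, 4, …, 512 | individuals | the stochasticity treatment: small founding populations feel demographic noise strongly |
| `horizon` | 20 000 | steps (days) | census time; outcomes are judged only here |
| `n_replicates` | 100 | — | per (point, size) treatment |

These defaults are the stated world of the study the package reimplements —
a parameterization plausible for phytoplankton on a daily timescale — and
are not tuned. Reduced-replication profiles (e.g. 20 replicates) are
first-class configurations for desk-scale testing.

## Outcomes and summaries

Each finished run is classified at the horizon into exactly one of five
categories: `co_persistence` (both extant), `dual_extinction` (both gone),
and single-survivor dominance, split into `more_fit_dominant` /
`less_fit_dominant` by whether the survivor has the lower $R^*$, or
`dominance_at_equality` at the central point where neither label applies.
Dominance is never assessed mid-run: a run whose early leader later dies is
a dual extinction. `summarize_frequencies()` turns the long-format records
into per-cell percentages that sum to 100 by construction, with the
more/less-fit grids structurally zero at the equality point.

## Stochastic implementation choices

**Resource contention.** The model requires uptake not to exceed the
available resource. When $Q_a b_a + Q_b b_b > R(t)$ — essentially never
under the default $Q = 10^{-6}$, $I = 10$ — drawn births are scaled by
$R(t)/(Q_a b_a + Q_b b_b)$, floored, and the remaining capacity is handed
out in order of largest fractional remainder, with a single RNG coin flip
breaking an exact tie. The rule is unbiased between species, conserves
resource, and degenerates to a no-op when resource is ample. Inflow arriving
in the same step is *not* available for uptake (the cap uses $R(t)$ only),
and deaths never refund resource.

**Synchronous updates.** All Poisson means and the uptake use time-$t$
values; the two species are updated simultaneously, so results do not
depend on species order.

**Reproducibility.** Every replicate has its own seed, derived by hashing
(base seed, regime, varying parameter, mode, dilution, point, initial size,
replicate) with 32-bit FNV-1a (`replicate_seed()`). Any single replicate
can therefore be re-run in isolation from the manifest alone, results are
independent of execution order, and rerunning a sweep with the same base
seed reproduces the results CSV byte-for-byte. Seeds live in
$[1, 2^{31}-2]$; distinctness of the underlying Mersenne-Twister streams is
the usual pragmatic assumption, not a cryptographic guarantee.

**Engines.** The 20 000-step loop is implemented twice: readable reference
steppers in R (`deterministic_step()`, `stochastic_step()`) and a compiled
kernel used by `run_trajectory()`. Both consume R's global RNG in the same
draw order (births A, births B, deaths A, deaths B, optional tie coin) and
the test suite asserts bit-identical trajectories, so the fast path is
continuously validated against the reference. Care is taken that floating
point association matches between the two.

**Early exit.** Once both species are extinct the outcome cannot change, so
unrecorded runs may stop early; the final state is reported as at the
horizon. Recorded trajectories always run to the horizon.

## What the generator does and does not emulate

The simulation module is itself the study's synthetic-data generator: it
produces the full replicated experiment (35 points × 10 initial sizes ×
replicates × regimes) from nothing but the configuration. It emulates
demographic stochasticity (Poisson births/deaths) in a well-mixed,
single-resource, two-species system. It does **not** emulate environmental
stochasticity, spatial structure or immigration, resource recycling from
dead individuals, continuous-time (Gillespie) event scheduling, more than
two species or more than one resource. A green test therefore establishes
that the implementation reproduces the stated model's behaviour — e.g.
that dual extinction fades with founding population size, or that
co-persistence extends to moderate inequality only under slow growth — not
that those patterns transfer to systems outside these assumptions.
Co-persistence in particular is censoring at the horizon, not stable
coexistence: the deterministic system excludes one species eventually at
any nonzero inequality.

## Numerical choices

* Parameter conversions are closed-form; round-trips are tested to 1e-10
  relative tolerance and grid realization to 1e-12.
* The central grid pair is made *exactly* equal (bitwise) by mirroring the
  ascending sequence rather than recomputing the descending one, so the
  `"tie"` label and the structural zeros at equality never depend on
  floating-point coincidence.
* The resource is clamped at zero after the update in both modes; in
  stochastic mode the contention rule already guarantees uptake ≤ R(t).
* Deterministic populations below 1.0 are zeroed each step; the one-step
  update is tested against an independently hand-evaluated oracle at 1e-12.
* Percentages are computed from integer counts, so cells sum to exactly
  100.

## Known limitations

* Runtime: a full 100-replicate, two-regime reproduction takes on the order
  of tens of minutes on one CPU; the test suite uses the 20-replicate
  reduced profile (identical grid and horizon).
* The per-point parameter values of the original gradient are reconstructed
  from the printed $R^*$ range and checkpoints; every printed value is
  reproduced, but a point-by-point comparison with the original study's
  supplementary material is not possible from the text alone.
* Grid orientation (species A ascending in $R^*$) is an arbitrary,
  documented convention; all outcome metrics are symmetric under swapping
  the species, which is tested.
* `set.seed`-based replicate streams are heuristically, not provably,
  independent.
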