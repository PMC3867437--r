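---
title: "A fitness model for the evolution of cooperative mothering and male coalitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fitness model for the evolution of cooperative mothering and male coalitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopbreed)
```

## The question and the model

Human mothers reproduce faster than other apes while producing more
expensive offspring, which is only possible because they receive substantial
help. `coopbreed` implements an evolutionary game-theoretic model asking
under what conditions natural selection favors *female* cooperative infant
care versus *male* provisioning within coalition-based monogamy, in a
hominin-like life history.

Three female strategies compete on a frequency simplex:

* **Independent Mother (IM)** — provisions only her own offspring. Each
  reproductive cycle she produces one offspring that survives to breeding
  age with probability $S = \mathrm{clamp}(s_0 + c,\,0,\,1)$ (baseline
  survival $s_0$ plus paternal care $c$), and she survives the $T$-year
  interbirth interval with probability $s_f^{T}$ to begin the next cycle.
  Her expected lifetime fitness is the geometric renewal sum
  $w_{IM} = S/(1 - s_f^{T})$.
* **Cooperative Mother (CM)** — searches for another CM; once paired the two
  reciprocate allo-parental care indefinitely. Allo-care changes offspring
  survival by $b_{allo}$ (which may be negative) and shortens the interbirth
  interval by $\delta$ (shared lactational load), so a cooperative cycle has
  survival payoff $S_{coop} = \mathrm{clamp}(s_0 + b_{allo} + c)$ and
  per-cycle discount $d_2 = s_f^{T-\delta} > d_1 = s_f^{T}$. Meetings with
  an IM cost an ordinary cycle; meetings with an OM resolve by fair coin
  into the *sucker's payoff* — a full allomothering period of $T-\delta$
  years with no own reproduction — or an ordinary cycle. CM fitness solves
  the two-state (Search/Paired) linear system documented in
  `?fitness_cm`.
* **Opportunistic Mother (OM)** — accepts allo-care but never reciprocates:
  on meeting a CM she exploits her with probability 1/2 (gaining
  $S_{allo}$ and the short cycle), otherwise everyone involved behaves
  independently.

Two male strategies compete in parallel. **Coalition Males** partner with
each other, gaining an economy of scale that raises their paternal care to
$b_{coal} \ge b_{non}$ while mutual monitoring lowers their lifetime
extra-pair mating (EPM) extent to $e_{coal} \le e_{non}$. A male's fitness
is his within-pair siring — population paternity certainty
$\Pi = 1 - (q\,e_{coal} + (1-q)\,e_{non})$ times the expected fitness of his
mate, re-evaluated at his care level — plus the extra-pair gain
$e \cdot \bar w_f$, where $\bar w_f$ is mean female fitness (promiscuous
males have equal access to all females, so the gain scales with how
productive females are on average — the "push-pull" that makes paternal
care largely self-defeating for Coalition Males).

Assortment enters in two ways. A *kin-selection* parameter $r$ makes any
individual interact with its own strategy with probability
$r + (1-r)\,f_{own}$; a *male-female assortment* parameter $a$ makes CM
females pair with Coalition Males with probability $a + (1-a)q$, the other
females splitting the residual Coalition-Male mass (clamped, with a
warning, in corners where assortative demand exceeds supply).

## Parameters, units and defaults

Defaults are midpoints of empirically motivated ranges
(`default_ranges()`): offspring survival to breeding age $s_0 \in
[0.5, 0.75]$ (chimpanzee-to-forager span), maternal annual survival
$s_f \in [0.90, 0.99]$, alloparental effect $b_{allo} \in [-0.5, 0.5]$
(deliberately spanning net harm to net benefit), a fixed chimpanzee-like
interbirth interval $T = 5$ years, EPM extents $e_{non} \in [0, 0.2]$,
$e_{coal} \in [0, 0.05]$, and paternal-care effects $b_{non} \in [0, 0.05]$,
$b_{coal} \in [0, 0.1]$. The interbirth-interval reduction $\delta$ has no
published range; we use $[0.5, 2.0]$ years — at most a 40% reduction from
the 5-year baseline, consistent with allo-nursing shortening but not
collapsing the interval — and expose it in every sampling interface.
Assortment strengths default to $[0, 1]$ but the Monte Carlo experiment
drivers fix $r = a = 0$ unless a level is explicitly swept, because the
hypothesized empirical ranges cover only the life-history parameters.

## Dynamics and the basin of attraction

Female strategy frequencies evolve by discrete-time replicator dynamics,
$x'_\sigma = x_\sigma w_\sigma / \bar w$ (`replicator_step()`,
`trajectory()`); the update rule matters only through its fixed points,
which it shares with the continuous-time replicator. On the conservative
edge with no Independent Mothers, the CM and OM vertices are both
attractors in much of parameter space, separated by an unstable equilibrium
$x^*$ where $w_{CM} = w_{OM}$. `cm_om_edge_equilibrium()` locates $x^*$ by
a 200-point sign pre-scan plus bisection (default tolerance $10^{-6}$ in
frequency); the CM *basin of attraction* is $1 - x^*$. Degenerate cases are
classified explicitly (`cm_always`, `om_always`); if several sign changes
occur we report the unstable crossing at the largest $x$ — the smallest,
most conservative CM basin — and set a multiplicity flag.

```{r}
p <- model_params(b_allo = 0.3, delta_ibi = 1.5)
cm_om_edge_equilibrium(p, q_coal = 0.5)
```

## Monte Carlo experiments

`basin_sweep()`, `male_advantage_surface()`, and `male_region_grid()` are
pure compositions of the fitness and dynamics modules. Each fixes the swept
quantity, draws the remaining parameters uniformly from their ranges
(ordering constraints enforced by whole-vector rejection, keeping the
accepted sample uniform on the constrained region), and summarizes with the
mean and empirical 2.5/97.5 percentile band. Design choices worth knowing:

* **Common random numbers.** Per-draw RNG streams are derived from the root
  seed and the draw index, so every grid value reuses the same draws.
  Differences along the grid are then due to the swept parameter alone, and
  results are independent of evaluation order.
* **Population state.** The basin sweeps fix the Coalition-Male frequency at
  0.5 by default (an argument; `NA` draws it uniformly) so that degenerate
  ranges collapse the band to a deterministic value. The advantage surface
  draws female frequencies uniformly on the simplex and $q$ uniformly per
  draw, since its design fixes only $r = a = 0$; the region grids set
  $z_{IM} = 0$, $y_{OM} = 1 - x_{CM}$, the conservative no-IM analysis.
* **Care-versus-EPM comparison.** One unit of survival increment is worth
  more fitness than one unit of EPM extent by construction, so per-unit
  derivatives are not the relevant comparison; we compare the total swing
  of the mean advantage across each difference's hypothesized range
  (care $0$–$0.1$ vs EPM $0$–$0.2$).

The suites run these at reduced scale (200 draws per grid value for basin
sweeps, 1000 for advantage surfaces, a 10x10 grid for the region maps);
`scripts/acceptance.R` reports the same quantities, with the region grids at
the full 100 draws per cell.

## The lifetime oracle

The closed forms are renewal-equation expectations, and every design choice
in them (credit timing, pair dissolution, sucker cost) could silently be
wrong. The package therefore carries a stochastic simulator
(`simulate_lifetime()`, `estimate_fitness()`, `oracle_check()`) that
implements the event rules *directly* — yearly Bernoulli($s_f$) survival
draws (fractional cycle remainders use $s_f^{frac}$), encounter draws from
the assortative meeting distribution, fair-coin defection, independent
partner survival, mate type drawn once per lifetime — with no reference to
the closed forms. Closed form and simulator must agree within Monte Carlo
error at any valid point; the test suite checks 20 random points at
$10^5$ lifetimes each, and the compiled kernel is itself cross-checked
against a pure-R replica of the event rules.

One modeling subtlety follows from the oracle. Offspring survival is
clamped to $[0,1]$, so fitness is not quite linear in paternal care, and
"evaluate at the expected care level" is not the same as "average over the
two realizable care levels" wherever the clamp binds. Because the mate (and
hence the care level, $b_{coal}$ or $b_{non}$) is fixed once per lifetime,
the exact expectation is the two-point mixture, and that is what
`female_profile()` computes; `expected_paternal_care()` still reports the
mean care increment for inspection. Away from the clamp the two coincide.

## Numerical and degenerate-input conventions

An offspring is credited at the start of its cycle and the mother must
survive the cycle to continue; $s_f = 1$ is rejected (infinite horizon).
Pair continuation requires both partners' survival ($d_2$ each,
independent); the survivor re-enters search. Residual pairing probabilities
and the pairing table are clamped with warnings, never silently. Monomorphic
states are replicator fixed points by construction; mean-fitness collapse
($\bar w = 0$) is an error, not a `NaN`. The female-side rare-mutant limits
at $q = 0$ and $q = 1$ use the limiting assortment weights so male fitnesses
remain defined for invasion analysis.

## What the synthetic inputs do and do not emulate

The uniform parameter sampler reproduces a Monte Carlo
parameter-uncertainty design: independent uniform draws over hypothesized
ranges, not a fitted posterior. The lifetime simulator generates individual
histories under the model's own event rules; it validates the algebra, not
the biology. Passing tests therefore demonstrate internal consistency and
the robustness of the qualitative conclusions *within the model's
assumptions* — infinite population, fixed strategies within a lifetime, no
complementary feeding, no lactational physiology, coalition size two, no
feedback from births to strategy frequencies — and say nothing about fit to
primate field data.

## Known limitations

* The basin is computed from the deterministic edge equilibrium; Monte
  Carlo variation reflects parameter uncertainty only. Realized stochastic
  search costs (a CM's luck in finding a partner), which a finite-population
  simulation would add, are averaged out, and with them one reported
  source of basin variability at low maternal survival. In this
  implementation the basin's dispersion instead *grows* with maternal
  survival, because the alloparental-effect draw compounds over longer
  reproductive horizons.
* Male frequencies do not evolve dynamically; the male analysis is a
  fitness comparison at fixed $(x, q)$, as in the original design.
* With strong male-female assortment the pairing construction can
  over-demand Coalition Males; the clamped corners are flagged but the
  joint distribution there is a modeling convention, not derived.
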