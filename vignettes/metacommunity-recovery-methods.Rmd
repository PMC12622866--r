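---
title: "Modelling recovery in host-parasitoid metacommunities: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recovery in host-parasitoid metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarecover)
```

## The model

`metarecover` simulates the recovery of an insect food web spreading over a
network of habitat patches, under the mass-effect metacommunity paradigm:
local birth-death dynamics in every patch, coupled by density-dependent
emigration and immigration along the network's edges.

### Aphid dynamics

Aphid species $i$ in patch $k$ updates once per day:

$$A_{i,k}(t+1) = \max\!\Big(0,\; A_{i,k}(t)\, e^{\,r_i - \sum_j \alpha_{ij} A_{j,k}(t)} \;-\; M_{i,k}(t) \;-\; E_{i,k}(t) \;+\; I_{i,k}(t)\Big)$$

The first factor is the exponential (Ricker) form of logistic growth with
Lotka-Volterra competition. The loss terms are applied *outside* the
exponential: the model treats parasitism mortality, emigration and
immigration as separate daily fluxes with their own functional forms rather
than as modifiers of the growth exponent. A control flag
(`control = list(inside_exp = TRUE)`) moves the growth factor after the
fluxes for sensitivity analysis; all shipped results use the default.

### Parasitism and the larval queue

Attack rates use a piecewise-linear saturating function, a minimal stand-in
for a Type II functional response: per adult parasitoid of species $p$,
daily attacks are $\min(\sum_i a_{pi} A_i,\, h_p)$ — linear search at low
host density, capped by the daily egg load $h_p$ at high density. Realised
attacks are allocated to host species proportionally to $a_{pi} A_i$ and
clipped so no host loses more than its standing abundance (proportional
down-scaling across consumer species).

Parasitised hosts do not become adults instantly: they enter a
development queue and emerge $L$ days later as $c$ adults per host
(conversion below 1 absorbs sex ratio and development mortality).
Hyperparasitoids attack the *standing larval pool* (including the same
day's new cohorts, matching the enqueue-then-attack order of the daily
update) with the same saturating form; an attacked larva switches identity
and restarts development in the hyperparasitoid queue, emerging $L_h$ days
after the attack. Adults of both consumer guilds then balance survival
$(1-d)$, emergence, and dispersal.

### Dispersal

Every species uses the same threshold-linear rule with its own parameters:
$E_k = e\,\max(0, Q_k - \tau)$, capped at $Q_k$. Emigrants split equally
among the patch's network neighbours — strict stepping-stone movement, no
patch-skipping, no dispersal mortality, so $\sum_k E_k = \sum_k I_k$ holds
exactly every day (a property the test suite asserts to machine precision).

### Update order and non-negativity

All fluxes of one day are computed from the state at $t$ (synchronous
update), then applied. Non-negativity is enforced by a final clip; the
per-day ledger stores the *pre-clip* components (`growth_net`,
`parasitism`, `emigration`, `immigration`), so the bookkeeping identity
$\Delta A = G - M - E + I$ is exact wherever the clip did not fire, and
clip events are counted on the returned object. We deliberately do not
rescale emigration when a clip fires: rescaling $E$ after immigration has
been routed would break the exact dispersal mass balance, which we consider
the more important invariant. In practice clips are rare under the default
parameters (`sim$clip_events` reports them).

## Parameters

The fitted parameter values of the original experimental system live in
supplementary material that is not redistributed with this package. The
built-in table (`default_parameter_priors()`) is therefore a **synthetic
reference set**, chosen once on biological grounds and then frozen; it is
shaped exactly like a user-supplied table so any subset can be overridden
from CSV. The reasoning:

| Parameter | Default (focal aphid) | Why |
|---|---|---|
| $r$ (d$^{-1}$) | 0.28–0.33 across aphids | roughly four aphid generations in a 26-day run |
| $\alpha_{ii}$ (d$^{-1}$ ind$^{-1}$) | 0.0011–0.0014 | carrying capacity $r/\alpha \approx$ 200–300 per patch (one plant) |
| $\alpha_{ij}$, $i \ne j$ | 0.0004–0.0011 | competitive hierarchy: the focal aphid weakest, *M. persicae* strongest; products $\alpha_{ij}\alpha_{ji} < \alpha_{ii}\alpha_{jj}$ so competitors coexist over the horizon, as all species persist in the experimental system |
| $a_{pi}$ (d$^{-1}$ ind$^{-1}$) | 0.02–0.10 | host preferences: *D. rapae* attacks the focal aphid hardest, *A. colemani* prefers *M. persicae* |
| $h, k$ (hosts d$^{-1}$) | 8 / 6 | egg-load caps of aphidiine wasps |
| $c$ | 0.5 | emerging females per parasitised host |
| $d$ (d$^{-1}$) | 0.15 | adult lifespan of order one week |
| $L$ (d) | 10 | about two consumer generations in 26 days |
| $e$, $\tau$ (aphids) | 0.10–0.12, 45–50 | aphids disperse when crowded (threshold near $K/4$–$K/5$) |
| $e$, $\tau$ (wasps) | 0.30, 1 | winged consumers are far more mobile |
| $g_{hp}$ | 0.04 vs 0.02 | the hyperparasitoid attacks *D. rapae* larvae at the higher rate |

Each parameter carries lower/upper confidence bounds (roughly $\pm 15\%$,
wider where field estimates vary more). **Replicate stochasticity** enters
the simulation design solely through independent uniform draws between
those bounds (`draw_replicate_parameters()`); dynamics within a replicate
are deterministic. A different mechanism (demographic noise) would be
plausible; the uniform-draw scheme was chosen because the
parameterisation procedure of such systems yields interval estimates, and
it keeps every replicate exactly reproducible from its seed. The defaults
were frozen after one qualitative sanity run (populations persist,
colonisation happens mid-run) and were not adjusted afterwards.

Initial conditions follow the study design: 10 individuals per aphid
species and 1 adult per consumer species in every initially populated
patch, 26 daily steps.

## Landscapes and placements

The 5-patch experimental landscape is a star (hub id 0). The 50-patch
landscape is a preferential-attachment graph grown from a triangle with 2
edges per new patch, giving $2(n-2)+1 = 97$ edges at $n = 50$, a few hubs
and many degree-2 leaves; the construction guarantees connectivity.
"Central" patches are the highest-degree patches (ties broken
deterministically by id); "peripheral" the lowest-degree (ties broken at
random under the placement seed, since e.g. all leaves of a star are
exchangeable). Degree rank rather than betweenness defines centrality
because in these landscapes connectivity is what drives colonisation. In
factorial runs the scale-free landscape is regenerated per replicate from
the cell seed, so results average over network realisations (a fixed-graph
run is available by constructing the landscape once and calling
`simulate_metacommunity()` directly).

## Recovery credit and statistics

The recovery credit is the trapezoidal area under the abundance-vs-time
curve on the daily grid (abundance-days). At the local scale the credit is
averaged over the initially empty (or populated) patch class **before**
the $\ln(1+x)$ transform — the transformed average credit is the quantity
the effect analyses use; `transform_first = TRUE` switches the order.
The metapopulation credit integrates the summed series, which by linearity
equals the sum of per-patch credits (asserted in tests).

Effects are estimated by OLS on
`credit_ln1p ~ number * location * community`. Two model forms match the
two design scales: the experiment-sized design (5 replicates) omits the
three-way interaction (residual df 50 on a 2×2×3 design), the
simulation-sized design (100 replicates) is the full factorial (residual
df 1188). Balanced designs use the standard sequential ANOVA (all types
coincide); unbalanced tables are refused unless `force = TRUE`, which
switches to Type-II sums of squares via `car`. Marginal means are computed
by hand (averaging predicted cell means over a balanced grid, t-based CIs);
`emmeans` is used in the test suite as an independent oracle, never as the
implementation. Percent changes are computed on the transformed scale —
the scale the effect axes use — with a back-transformed variant available.
Post hoc simple effects use Holm adjustment (a deliberately conservative
default; the analysis the package mirrors does not name one).

Degenerate inputs are defined, not errors: a constant response gives
$F = 0$ for every term; a noiseless table with real effects gives
$F = \infty$ for those terms.

## Calibration

`fit_growth()` mirrors how such models are parameterised from single-patch
series: per-capita growth $(\ln N_{t+1} - \ln N_t)/\Delta t$ regressed on
$N_t$, intercept $= r$, $-$slope $= \alpha$, CIs from the regression. The
$\Delta t$ normalisation makes 3- and 4-day census gaps comparable. Note
the regression is exact (zero residuals) only for unit-spaced data;
multi-day gaps introduce a small discretisation bias that shrinks with the
gap. `fit_saturating()` and `fit_emigration()` profile their breakpoint /
threshold over a grid of the observed x-values plus midpoints (each
candidate reduces to a one-parameter regression); ties go to the smaller
candidate, and exact recovery of a generator's parameters requires the
true breakpoint to lie on the grid. All-zero emigrant series return
$(e = 0, \tau = \max A)$, flagged, and purely linear attack data fall back
to an infinite breakpoint, flagged.

## Synthetic data

The generators provide known ground truth for every pipeline stage:
logistic count series on the twice-weekly census grid (days 0, 3, 7, …)
with multiplicative lognormal noise (counts are positive and their spread
grows with the mean — no observation-noise model is prescribed by the
system, so this is the package's choice), and balanced factorial credit
tables with injected effects on the $\ln(1+x)$ scale. They emulate the
*structure* of real observations, not their empirical noise: passing tests
demonstrate that the estimators and the ANOVA stage recover known truth
under the stated noise model, not that the model fits any particular
field system.

## Numerical choices

* Growth exponent capped at $\pm 50$ before exponentiation (overflow guard
  for adversarial parameters).
* Per-cell design seeds are drawn without replacement from the 32-bit
  range under the master seed: unique, reproducible, safe for R's RNG.
* Larval queues are integer-day cohort arrays; ages shift by one row per
  day, and emergence takes the whole terminal row.
* The breakpoint grids of the calibration fits prefer smaller candidates
  on SSE ties (within $10^{-12}$).

## Problem sizes

The shipped test suite and acceptance script run the 5-patch factorial at
the full study size (3 communities × 4 configurations × 100 replicates)
and the 50-patch factorial over all 15 communities at 25 replicates per
cell — a size chosen so the directional effect pattern is resolved well
beyond its Monte-Carlo error while a complete run stays in the minutes
range on one CPU. The ANOVA type-I simulation uses $10^4$ null tables; the
growth-CI coverage check uses 200 seeds at $\sigma = 0.1$ on 9 census
points.

## Known limitations

* Effect *magnitudes* depend on the parameter set; with the synthetic
  reference set the package reproduces the directional structure of
  recovery (positive number-of-introductions effect concentrated in empty
  patches; negative competition and parasitism effects, parasitism
  stronger; positive hyperparasitoid effect; the reversal of the location
  effect between small stars and large scale-free landscapes), and all
  reported magnitudes are whatever the shipped parameterisation produces —
  they are computed at run time, never asserted as constants.
* The unpaired factorial estimate of small effects (notably the
  hyperparasitoid boost) carries replicate-level variance from the
  parameter draws; paired-seed comparisons resolve the same effect with
  far less noise and are used in the trend test.
* Plants are habitat, not a state variable; patches are identical; edges
  are unweighted; there is no long-distance dispersal. These are inherited
  simplifications of the study design, listed there as future work.
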