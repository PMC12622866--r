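# metarecover

Simulation and analysis of ecological recovery in insect host–parasitoid
metacommunities on patch networks.

## The problem

Landscape-scale restoration introduces communities of interacting species
into a few habitat patches and hopes they spread. How fast a focal species
recovers then depends jointly on the *spatial configuration* of the
introductions (how many patches, and whether they are central hubs or
peripheral leaves of the patch network) and on the *food-web complexity* of
the introduced community (competitors, parasitoids, hyperparasitoids).
`metarecover` implements a mass-effect metacommunity model of this process
for a six-species aphid–parasitoid–hyperparasitoid system on radish, a
recovery-credit measure of the resulting trajectories, and the factorial
simulation + ANOVA machinery to decompose the effects.

## The model

Aphid species *i* in patch *k* follows a daily Ricker-type
competition–parasitism–dispersal update:

```
A_ik(t+1) = max(0,  A_ik(t) · exp( r_i − Σ_j α_ij A_jk(t) )  −  M_ik(t)  −  E_ik(t)  +  I_ik(t) )
```

* **Growth / competition** — exponential logistic with intrinsic rate `r_i`
  and competition coefficients `α_ij`.
* **Parasitism `M`** — per parasitoid adult, daily attacks are
  `min(Σ_i a_pi A_i, h_p)`: a piecewise-linear ramp with an egg-load cap
  that mimics a Type II functional response. Attacked hosts enter a larval
  queue and emerge `L` days later as `c` new adults — unless a
  hyperparasitoid attacked the larva first (same functional form), in which
  case a hyperparasitoid emerges instead.
* **Dispersal `E`, `I`** — density-dependent emigration
  `E_k = e · max(0, A_k − τ)`, split equally among the patch's neighbours
  (stepping-stone movement, mass conserved exactly).
* **Consumers** — adults balance survival `(1 − d)`, emergence from the
  larval queue, and the same threshold dispersal rule.

Communities come from a 15-web catalogue (`1A` … `3A-2P-1H`: 1–3 aphids ×
0–2 parasitoids × optional hyperparasitoid); landscapes are a 5-patch star
or a 50-patch scale-free (preferential-attachment) network; placements put
1 or 4 initial communities in central (high-degree) or peripheral
(low-degree) patches (`1C`, `1P`, `4C`, `4P`).

**Recovery credit** is the area under the population-size curve
(trapezoid, abundance·days), computed per patch (averaged over initially
empty or populated patches) and for the metapopulation (summed series),
then `ln(1+x)`-transformed. Effects are decomposed with a three-way ANOVA
(number × location × community) and reported as percent changes between
marginal-mean predictions.

Parameter values ship as a synthetic reference set with confidence bounds
(`default_parameter_priors()`); each simulation replicate draws its
parameters uniformly within the bounds. Any subset can be overridden from a
CSV (`read_parameter_priors()`), and the calibration module re-estimates
the parameters from time series (`fit_growth()`, `fit_saturating()`,
`fit_emigration()`).

## Worked example

```r
library(metarecover)

web <- build_community("2A-1P")     # focal aphid + competitor + parasitoid
web
#> <foodweb> 2A-1P : 3 species, 2 trophic level(s)
#>    Bb -> Le -> Dr

ls  <- star_landscape(4)
pl  <- select_placement(ls, 1, "central")     # configuration 1C
sim <- simulate_metacommunity(web, ls, pl, seed = 42)
sim
#> <metacommunity_sim> 2A-1P on star (5 patches), 1C placement, 26 days
#>   final metapopulation sizes: Bb=71.4, Le=1143.4, Dr=25.5

summarise_credits(sim)                         # focal-aphid recovery credit
#>               scale    credit credit_ln1p
#> 1     empty_patches  110.4647    4.713708
#> 2 populated_patches 1155.9846    7.053572
#> 3    metapopulation 1597.8436    7.377036
```

The focal aphid (`Bb`) is suppressed by its competitor and the parasitoid:
its populated-patch credit (7.05 on the ln scale) far exceeds the credit in
the four initially empty patches (4.71), which are colonised only after the
hub population passes the emigration threshold.

A small factorial run and its effect decomposition:

```r
d   <- enumerate_design(c("1A", "2A", "2A-1P"), replicates = 20, master_seed = 1)
cr  <- run_factorial(d, list(kind = "star"))
fit <- fit_effects_model(cr, scale = "metapopulation", model = "full")
fit
#> <effects_fit> full model on metapopulation scale, 240 observations
#>                       term df_num df_den       F        p
#>                     number      1    228 502.800 1.36e-59
#>                   location      1    228  10.220 1.59e-03
#>                  community      2    228 336.700 8.72e-69
#>            number:location      1    228  32.170 4.25e-08
#>           number:community      2    228   2.200 1.13e-01
#>         location:community      2    228   2.209 1.12e-01
#>  number:location:community      2    228   2.811 6.22e-02

percent_change(fit, "number", "1", "4")       # +12.3%
percent_change(fit, "community", "2A", "2A-1P")  # -8.9%
```

Four introductions instead of one raise metapopulation recovery by ~12%;
adding the parasitoid to the two-aphid community lowers it by ~9%.

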