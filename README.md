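# rxnbo

Closed-loop Bayesian optimization of reaction conditions on constrained
categorical grids, as run by autonomous ("self-driving") laboratories — with
the iodination of terminal alkynes as the built-in application.

## The problem

Iodoalkynes are made either from an iodide salt (KI, NaI, TBAI, NH₄I)
oxidized by chloramine-B, or directly with *N*-iodosuccinimide (NIS),
usually acid-catalyzed. Optimizing the reaction means searching a joint,
chemistry-constrained space — route, reagent equivalents, solvent, catalyst,
temperature — for four aromatic alkyne substrates simultaneously. The
feasible space is a finite grid (the campaign roster has 12 036 candidate
conditions; the default roster, which adds neat CH₃CN, has 13 260), far too
large to screen.

`rxnbo` implements the full closed loop:

* **Grid**: declarative constraint rules (boiling-point temperature caps,
  stoichiometry minima, route exclusions) over eight discrete parameters;
  `build_grid()` enumerates the feasible set deterministically.
* **Objectives**: conversion `1 − C_SM/C_IS` and yield `C_product/C_IS`
  from internal-standard-calibrated HPLC areas, scalarized into the merit
  `m = 0.9·clip(yield) + 0.1·clip(conversion)`.
* **Initial design**: a greedy maximum-coverage heuristic that covers every
  solvent, substrate, iodine source and catalyst in 11 experiments.
* **Surrogate**: one Gaussian process (Matérn-5/2, one length-scale per
  parameter block) over all substrates jointly, on a one-hot/standardized
  encoding.
* **Acquisition**: expected improvement with a constant-liar policy for
  batches of 2, fully seeded and reproducible.
* **Stopping**: a substrate is done once any observation surpasses 80 %
  conversion; its points are then removed from the search space. The
  campaign ends when all four substrates have converged.
* **Desk-scale oracle**: a synthetic reaction landscape with the qualitative
  structure of the real chemistry (broad chloramine optimum in polar
  solvents at ≤ 65 °C; a deceptive NIS+PTSA region with high conversion but
  near-zero yield) so the whole loop is testable without a lab.
* **Interpretability**: exact t-SNE embeddings of the condition space with
  contour maps of true and surrogate-predicted merit, conversion progress
  charts and parallel-coordinates plots.

## Worked example

```r
library(rxnbo)

default_grid("campaign")
#> Feasible reaction grid: 12036 points, 8 parameters
#>   alkyne             categorical (4 levels)
#>   chloramine_eq      ordinal-numeric (4 levels)
#>   solvent            categorical (10 levels)
#>   iodine_source      categorical (5 levels)
#>   iodine_source_eq   ordinal-numeric (4 levels)
#>   catalyst           categorical (3 levels)
#>   catalyst_eq        ordinal-numeric (3 levels)
#>   temperature        ordinal-numeric (8 levels)
#>   constraints: 7 rule(s)

# greedy initial design on the default (11-solvent) roster
g <- default_grid("default")
init <- greedy_diverse_init(g, diversity_config(n_init = 11, seed = 1))
coverage_complete_at(init, grid_space(g))
#> [1] 11
```

All 11 solvents, 4 substrates, 5 iodine sources and 3 catalysts are covered
at exactly the 11th pick (the solvent roster is the binding field). A
simulated campaign against the synthetic landscape:

```r
camp <- run_campaign(make_oracle(), g, campaign_config(seed = 11))
summary(camp)
#> Reaction-optimization campaign: 13 experiments, 2 iterations (converged)
#>   best merit 0.983 at experiment 8
#>   converged substrates: 1-chloro-2-ethynylbenzene, 1-chloro-4-ethynylbenzene, 2-ethynyltoluene, 4-ethynyltoluene
#>
#> Convergence scan (threshold: conversion > 80%, 13 observations)
#>                     alkyne first_surpassing n_before converged
#>           2-ethynyltoluene               13        4      TRUE
#>           4-ethynyltoluene                5        1      TRUE
#>  1-chloro-2-ethynylbenzene                4        0      TRUE
#>  1-chloro-4-ethynylbenzene                1        0      TRUE
#> last substrate converged at experiment 13; campaign stop at 13
```

Here every substrate surpassed 80 % conversion within the first batch after
the diverse initial block (the diverse block alone often finds the polar
chloramine-route region); harder seeds run more rounds. The best conditions
found — chloramine route, aqueous acetonitrile, 2 eq oxidant, no catalyst,
35 °C — sit squarely in the landscape's designed optimum.

Replaying a recorded history (here the synthetic reconstruction of the
first published campaign):

```r
replay_campaign(synthetic_campaign_histories()$light)
#> Convergence scan (threshold: conversion > 80%, 23 observations)
#>                     alkyne first_surpassing n_before converged
#>           2-ethynyltoluene               17        3      TRUE
#>  1-chloro-2-ethynylbenzene               19       10      TRUE
#>           4-ethynyltoluene               20        2      TRUE
#>  1-chloro-4-ethynylbenzene               22        3      TRUE
#> last substrate converged at experiment 22; campaign stop at 23
```

23 experiments out of 12 036 candidates is 0.2 % of the search space.

For maps of the design space, embed any observation set and rasterize a
scalar over it:

```r
pool <- pool_campaign_histories()                      # 49 observations
map  <- embed_points(pool, default_space("campaign"))  # t-SNE, substrate excluded
plot(contour_from_values(map, pool$merit), file = "merit-map.png")
```

A thin command-line front end over the same functions ships in
`inst/scripts/rxnbo-cli.R` (`build-grid`, `init`, `run-sim`, `replay`).

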