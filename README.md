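# plasmidCNC

Multi-scale modelling of the evolution of copy-number control (CNC) among
non-conjugative bacterial plasmids.

Plasmids are vertically transmitted genetic symbionts that replicate
autonomously inside their host cell. Every extra copy improves a plasmid
lineage's odds at cell division but taxes host metabolism, so plasmid
replication sits in a two-level selection conflict: within-cell selection
rewards faster replicators, between-cell selection rewards hosts whose
plasmid load is near the metabolic optimum. Real plasmids resolve this with
copy-number control — rapidly decaying, trans-acting replication inhibitors
whose concentration tracks copy number. This package models that system with
three heritable plasmid traits:

* **selfishness** `alpha` — basal replication rate (cis),
* **policing** `kappa` — inhibitor production rate (trans),
* **obedience** `beta` — binding affinity to the inhibitor (cis),

coupled to a host growth law
`g(n) = g0 + B(1 - exp(-s n)) - c n - c_inh * sum(kappa)` and an inhibited
replication rate `r = alpha / (1 + beta * I)` with quasi-steady-state
inhibitor concentration `I = tau * sum(kappa) / M`.

Two layers share these laws:

1. **Deterministic single-cell layer** — integrates biomass and continuous
   copy number over a cell cycle, builds the parent-to-daughter generation
   map, finds its fixed points (characteristic copy numbers), their
   stability, the fold bifurcation marking the edge of plasmid stability,
   and cell fitness (reciprocal division time).
2. **Stochastic multicellular engine** (compiled) — asynchronous cell
   growth, Poisson plasmid replication with per-replication mutation,
   binomial segregation at division, cell death, neutral population capping,
   and full observable recording. Experiment drivers reproduce the fitness
   landscape over traits, obedience sweeps of copy-number distributions,
   three-trait co-evolution from a non-policing founder, policing-cost
   sweeps, paired comparisons of collective vs individual restraint, and
   invasion analyses.

See the methods vignette (`vignettes/copy-number-control.Rmd`) for the model
assumptions, parameter rationale, numerical choices and limitations.

## Worked example

```r
library(plasmidCNC)
p <- cellParams()                      # reference study conditions

## host growth optimum
optimalCopyNumber(p)
#> [1] 11.51293

## passive control (no policing): narrow stable band, edge at max fitness
findEquilibria(PlasmidGenotype(alpha = 0.35), p)
#> EquilibriumSet for alpha = 0.35, kappa = 0, beta = 0
#>     nStar stable     slope     tDiv
#>  3.154781   TRUE 0.7649224 1.980420
#> 16.935167  FALSE 1.5868969 1.980421
edgeOfStability(0, 0, p, c(0.1, 0.8))
#> [1] 0.4296318

## strong CNC widens stability ~6-fold and makes the optimum interior
edgeOfStability(1, 2, p, c(0.5, 3.5))
#> [1] 2.694986

## stochastic layer at the CNC optimum
set.seed(1)
pop <- population(500, PlasmidGenotype(alpha = 1.7, kappa = 2, beta = 1),
                  n = 8)
res <- runSimulation(pop, p, evolutionParams(mu = 0), cap = 1000,
                     steps = 20000)
res
#> SimulationResult: 401 recording intervals
#>   final: t = 2000, 1000 cells, infected fraction 0.998
#>   counters: divisions = 826096, deaths = 0, segLosses = 986, divisionsInfected = 826017
```

The two fixed points of the generation map are the stable characteristic
copy number (`n* = 3.15`; cells below it over-replicate, cells above it
under-replicate) and the unstable threshold (`n = 16.9`) beyond which
over-replication runs away. At the CNC optimum the population divides about
0.41 times per cell per unit time with segregational loss in ~0.12% of
infected-cell divisions.

Co-evolution from a founder that neither produces nor responds to inhibitors
(`coevolve()`) climbs to maximal obedience and near-maximal policing; see
the vignette for the full experiment set (`fitnessLandscape`,
`obedienceSweep`, `policingCostSweep`, `cncVsNocnc`, `invasion`).

A thin command-line front end is included at `inst/scripts/plasmidcnc`
(subcommands `simulate`, `equilibria`, `bifurcation-scan`, `fitness-scan`,
`landscape`, `sweep-beta`, `coevolve`, `cost-sweep`, `compare`, `invade`;
YAML configs via `loadConfig()`).

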