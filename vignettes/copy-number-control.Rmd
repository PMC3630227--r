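---
title: "Modelling the evolution of plasmid copy-number control"
author: "plasmidCNC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of plasmid copy-number control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidCNC)
```

## The problem

Non-conjugative plasmids are vertically transmitted molecular symbionts of
bacteria: they propagate only when their host divides, yet they replicate
autonomously inside it. Each extra copy raises the chance of being
transmitted to both daughters, but also taxes host metabolism, so plasmid
replication is subject to a conflict between selection *within* cells (which
favours faster replicators) and selection *between* cells (which favours
hosts whose plasmid load sits near the metabolic optimum). Real plasmids
resolve this conflict with copy-number control (CNC): constitutively
produced, rapidly decaying trans-acting inhibitors (in R1, antisense RNAs)
whose concentration tracks copy number and down-regulates replication
initiation.

plasmidCNC models this system at two coupled scales and asks when stable
characteristic copy numbers exist, how the stability region depends on the
plasmid's replication traits, and whether policing (inhibitor production) and
obedience (inhibitor binding) can evolve from scratch under the two-level
selection structure.

## The model

**Host growth.** A cell of biomass $M$ (newborn at $M_0$, dividing at
$2M_0$) grows at the per-biomass rate

$$g(n) = g_0 + B\left(1 - e^{-sn}\right) - c\,n - c_{inh}\sum_j \kappa_j,$$

where $n$ is the plasmid copy number: a chromosomal baseline $g_0$, a
saturating gene-dosage benefit with ceiling $B$ and steepness $s$, a linear
per-copy maintenance cost $c$, and (optionally) a cost $c_{inh}$ per unit of
inhibitor produced. Because the benefit saturates while the cost is linear,
growth is maximised at a finite copy number
$n_{opt} = \log(Bs/c)/s$ and turns negative beyond an upper viability
boundary.

**Plasmid replication.** Each plasmid copy carries three heritable traits:
a basal replication rate $\alpha$ (selfishness, cis-acting), an inhibitor
production rate $\kappa$ (policing, trans-acting), and a binding affinity
$\beta$ to the inhibitor (obedience, cis-acting). The inhibitor decays fast
relative to the cell cycle, so its concentration is treated at quasi-steady
state, proportional to total production and diluted by biomass,
$I = \tau \sum_j \kappa_j / M$. A plasmid's realised replication rate is its
basal rate modulated by quasi-equilibrium binding kinetics,

$$r_i = \frac{\alpha_i}{1 + \beta_i I},$$

(an exponential response $\alpha_i e^{-\beta_i I}$ is available as a toggle;
all qualitative results are insensitive to this choice). For a genotypically
homogeneous cell the dynamics depend on $\beta$ and $\kappa$ only through the
product $\beta\kappa$, which makes the two traits interchangeable in
homogeneous analyses — a symmetry the test suite checks exactly.

**Deterministic single-cell layer.** Treating $n$ as continuous,
$\dot M = Mg(n)$ and $\dot n = n\,r(n, M)$ are integrated over one cell cycle
(adaptive lsoda with event detection on $M = 2M_0$). Equipartition at
division defines the generation map $n_0 \mapsto n_1 = n_{div}/2$ between
the start of a parent's and a daughter's cycle. Fixed points of this map are
characteristic copy numbers; a fixed point is stable when the map slope
magnitude is below 1, in which case cells below it over-replicate and cells
above it under-replicate back towards it. As $\alpha$ rises the stable and
unstable fixed points approach and annihilate at a fold bifurcation — the
edge of plasmid stability — beyond which plasmids over-replicate from any
initial copy number.

**Stochastic multicellular layer.** A population of up to `cap` cells is
updated in discrete steps `dt`: biomass grows by $M \leftarrow M(1 + g\,dt)$;
each plasmid replicates a Poisson($r_i\,dt$) number of times (aggregated into
one cell-level Poisson draw with proportional event assignment, which is
distributionally identical); each new copy mutates with probability $\mu$, in
which case exactly one free trait is perturbed by an additive uniform step
and clipped to its bounds; a cell whose biomass reaches $2M_0$ divides, with
every copy independently assigned to a daughter (binomial segregation, the
source of segregational loss); and the population is regulated by neutral
uniform culling back to the cap. Divisions, deaths, segregational losses and
divisions of infected cells are counted, and trait means, within/between-host
trait SDs and copy-number distribution moments are recorded.

## Reference study conditions

All defaults live in `cellParams()` and `evolutionParams()` and are used by
every experiment unless overridden.

| Parameter | Value | Units | Meaning / rationale |
|---|---|---|---|
| `g0` | 0.1 | 1/time | chromosomal growth baseline; sets the plasmid-free division time $\ln 2/g_0 \approx 6.9$ |
| `B` | 0.5 | 1/time | benefit ceiling; a strongly beneficial plasmid (5x the baseline at saturation) |
| `steepness` | 0.2 | 1/copy | benefit saturates over ~10 copies, typical of gene-dosage effects |
| `c` | 0.01 | 1/(copy·time) | per-copy cost; gives $n_{opt} = 11.5$ and a viability boundary near 60 copies, well clear of the working distributions |
| `cInh` | 0 | per inhibitor unit | policing cost; swept in the cost experiment |
| `M0` | 1 | biomass | newborn biomass; division at 2 |
| `tau` | 0.2 | time | inhibitor lifetime, ~10% of the fastest cell cycle ("short") |
| `dt` | 0.1 | time | step; ≥16 steps per cell cycle everywhere in the stable region |
| bounds | $\alpha \le 2$, $\kappa \le 2$, $\beta \le 1$ | | physiological caps; chosen so maximal CNC is strong (~4-fold inhibition at equilibrium) and the maximal-CNC fitness optimum is interior in $\alpha$ |
| `mu` | 0.02 | per replication | mutation probability |
| `step` | 0.1 | fraction of bound | mutation kernel half-width |

Under these conditions the deterministic layer gives: passive-control
(NO-CNC) stability edge $\alpha_{crit} \approx 0.43$, maximal-CNC edge
$\alpha_{crit} \approx 2.7$, and a maximal-CNC fitness optimum near
$\alpha \approx 1.7$ with characteristic copy number $n^* \approx 7.5$.
Fitness of the equilibrium cycle is maximised when the cycle's span
$[n^*, 2n^*]$ brackets $n_{opt}$, not when $n^* = n_{opt}$.

Two derived-quantity subtleties are worth stating explicitly:

* **Population-mean copy number.** In an asynchronously dividing population
  the stable age distribution weights cells between birth ($n^*$) and
  division ($2n^*$); for exponential copy-number growth the predicted
  population mean is $2\ln 2 \, n^* \approx 1.39\,n^*$.
  `deterministicMeanCopyNumber()` computes this prediction for arbitrary
  genotypes; it — not $n^*$ itself — is the deterministic comparator for the
  stochastic layer's mean copy number over infected cells.
* **Death rule.** With the multiplicative biomass update, biomass cannot
  cross zero while $-1 < g\,dt < 0$, which would leave perpetually shrinking
  cells. Since copy number never decreases within a cell's life, $g$ is
  non-increasing, so shrinking below $M_0/2$ is irreversible: both layers
  treat that as death. The same argument makes the deterministic layer's
  early stopping exact rather than an approximation.

## What the experiments emulate

* `fitnessLandscape()` reproduces the homogeneous-strain net-growth surface
  over $\alpha \times \beta$ at fixed $\kappa$, with outcome labels. One
  stochastic-only regime appears: deep over-replication with no obedience
  drives every infected cell through high copy numbers where plasmid-free
  segregants essentially cannot form ($P \sim 2^{1-n}$), so instead of
  segregant rescue the population either goes extinct or persists in a
  division–death churn with near-zero net growth; both are labelled
  `population-collapse`.
* `obedienceSweep()` fixes $\alpha$ at the value optimal under maximal CNC
  and sweeps $\beta$: the weak-CNC end loses its plasmids, and with rising
  obedience the pooled copy-number distribution tightens (SD), symmetrises
  (skewness) and aligns its mean with $n_{opt}$.
* `coevolve()` starts from a founder that neither produces nor responds to
  inhibitors ($\kappa = \beta = 0$, $\alpha = 0.35$ inside the passive-control
  stable region so the founding strain persists) and lets the free traits
  mutate. The trajectory climbs the net-growth gradient as a ladder of
  selfish ($\alpha$ up, $\beta$ down) and cooperative ($\kappa$, $\beta$ up)
  substitutions, settling at maximal obedience and near-maximal policing.
  Because hosts are founded by single parents and there is no horizontal
  transfer, within-host trait variation stays roughly an order of magnitude
  below between-host variation — the relatedness structure that lets
  inter-cellular selection see trait differences.
* `policingCostSweep()` adds the $c_{inh}$ term. Costs are swept over
  $c_{inh}/c \in \{0, 0.05, 0.1, 0.25\}$ — the regime in which policing is
  eroded but not priced out entirely. (At several-fold higher costs
  $\kappa$ collapses to zero, obedience becomes selectively neutral and
  drifts; that regime is outside the phenomenon of interest.)
* `cncVsNocnc()` compares paired evolutionary runs in which either all three
  traits evolve (CNC) or only $\alpha$ evolves with $\kappa = \beta = 0$
  (NO-CNC, "passive control"), via one-sided rank-sum tests on
  replicate-level window means — replicate means, not pooled time points, to
  avoid autocorrelation pseudo-replication.
* `invasion()` competes a fixed policing-obedient type against an
  inhibitor-insensitive type at matched $\alpha$, mixed within or between
  hosts. Founder cells carry two copies (one of each type under within-host
  mixing): starting from low-copy heterogeneous founders lets binomial
  segregation expose pure types to selection. With larger mixed founder
  complements the insensitive type drives every host to over-replication
  death before assortment, and the whole population dies — a real, if
  degenerate, outcome of the same dynamics.

## Numerical choices

* Cell-cycle integration: `deSolve::lsodar`, relative tolerance $10^{-8}$,
  event roots on $M = 2M_0$ (division) and $M = M_0/2$ (death); horizon 50
  plasmid-free division times, after which a non-dividing cell is classified
  `dies` if shrinking, else `stalls`.
* Generation-map roots: bracketing on a uniform grid (default 200 points up
  to the viability boundary) refined by `uniroot` to $10^{-8}$; stability by
  central-difference map slope with step $10^{-4} n^*$. Brackets never span
  grid gaps where the map is undefined.
* Fold location: bisection on equilibrium existence; for tangency studies
  the search is refocused on a copy-number window around the coalescing pair
  so the shrinking root gap stays resolvable.
* Outcome classification (stochastic): extinction → collapse; final infected
  fraction < 0.25 → plasmid loss (under vs over by whether the mean copy
  number ran below or above its founding value); surviving populations with
  death rate > 30% of division rate → collapse (the churn state); otherwise
  stable-infected. Stochastic/deterministic agreement is assessed away from
  regime boundaries — grid cells whose deterministic label differs from a
  4-neighbour's, or whose $n^* < 2.5$, where the continuum description
  cannot bind (segregation at 1–2 copies is lethal to the lineage).
* Seeds: every experiment derives one stream per replicate from a master
  seed by `seedFor(master, i) = master + 7919 i` (mod $2^{31}-1$); the
  engine uses R's RNG, so runs are bit-reproducible from `set.seed()`.

## Desk-scale sizes

The package's reference experiment sizes are: population cap 1000 (400–600
for grid scans), $1.5\times 10^5$ steps for co-evolution (the trait ladder
reaches quasi-equilibrium by $\sim 1.2\times 10^5$), $8\times 10^3$–$2\times
10^4$ steps for homogeneous runs, and 5–20 replicates per experiment. The
mutation kernel (`mu = 0.02`, step 10% of bound) is deliberately coarse so
the full co-evolutionary transient completes at these sizes; finer kernels
(5% steps, `mu = 0.01`) give the same endpoint roughly four times slower.

## What passing tests do and do not show

The synthetic populations are well-mixed (no spatial structure), plasmids
are non-conjugative (no horizontal transfer), segregation is always binomial
(no active partitioning), and replication control is a single generic
inhibitor species with hyperbolic kinetics (no explicit antisense-RNA/Rep
mechanism, no iterons, no host-growth feedback on replication capacity).
Agreement between the layers and the qualitative reproduction of the
landscape, sweep, co-evolution, cost, comparison and invasion structures
therefore says nothing about molecular detail of any specific replicon — it
shows that the three-trait policing architecture, under two-level selection
with vertical transmission alone, is sufficient for collective restraint to
evolve and persist.

## Session info

```{r}
sessionInfo()
```
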