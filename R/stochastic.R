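## Stochastic multicellular layer. The per-step operations (stepCell,
## divideCell, mutateGenotype, regulatePopulation) are reference R
## implementations of the update rules, exported for direct use and testing;
## runSimulation() drives the compiled engine, which applies the identical
## rules over many cells and steps.

#' Mutate a plasmid genotype
#'
#' Perturbs exactly one trait, chosen uniformly among the traits that are free
#' to evolve, by an additive step drawn uniformly on +/- `step * bound`, and
#' clips the result to `[0, bound]`. All other traits (and the lineage label)
#' are untouched.
#'
#' @param genotype a [PlasmidGenotype].
#' @param ev an [EvolutionParams].
#' @return the mutated [PlasmidGenotype].
#' @export
mutateGenotype <- function(genotype, ev = evolutionParams()) {
    free <- which(ev@free)
    if (length(free) == 0L) return(genotype)
    slotName <- c("alpha", "kappa", "beta")[sample(free, 1L)]
    bound <- ev@bounds[[slotName]]
    v <- slot(genotype, slotName) + stats::runif(1, -1, 1) * ev@step * bound
    slot(genotype, slotName) <- min(max(v, 0), bound)
    genotype
}

.mutateRow <- function(row, ev) {
    free <- which(ev@free)
    if (length(free) == 0L) return(row)
    i <- sample(free, 1L)
    bound <- ev@bounds[[i]]
    row[i] <- min(max(row[i] + stats::runif(1, -1, 1) * ev@step * bound, 0),
                  bound)
    row
}

#' Advance one host cell by one time step
#'
#' Applies the per-step update: (i) biomass grows geometrically,
#' `M <- M * (1 + g*dt)`, with `g` from [growthRate] including the policing
#' cost of the cell's total inhibitor production; (ii) each plasmid replicates
#' a Poisson(`r*dt`) number of times at its own inhibited rate (see
#' [replicationRate]); each new copy inherits its parent's genotype and label
#' and mutates with probability `mu`; (iii) the event emitted is `"death"`
#' when the biomass has shrunk to half the newborn biomass (negative growth
#' is irreversible, because the copy number never falls within a cell's
#' life), `"division"` when it has reached `2*M0`, otherwise `"none"`.
#'
#' @param cell a [HostCell].
#' @param params a [CellParams].
#' @param ev an [EvolutionParams] (set `mu = 0` for mutation-free dynamics).
#' @return list with the updated `cell` and the emitted `event`.
#' @export
stepCell <- function(cell, params = cellParams(), ev = evolutionParams(mu = 0)) {
    stopifnot(is(cell, "HostCell"))
    pm <- cell@plasmids
    n <- nrow(pm)
    sumk <- sum(pm[, "kappa"])
    g <- growthRate(n, sumk, params)
    mass <- cell@biomass * (1 + g * params@dt)
    if (mass > 0 && n > 0) {
        I <- params@tau * sumk / mass
        r <- replicationRate(pm, I)
        reps <- stats::rpois(n, r * params@dt)
        for (j in which(reps > 0)) {
            for (q in seq_len(reps[j])) {
                row <- pm[j, ]
                if (ev@mu > 0 && stats::runif(1) < ev@mu)
                    row[1:3] <- .mutateRow(row[1:3], ev)
                pm <- rbind(pm, row)
            }
        }
        rownames(pm) <- NULL
    }
    cell@biomass <- mass
    cell@plasmids <- pm
    ## a cell below half the newborn biomass has been shrinking (g < 0) and,
    ## since its copy number can only rise, can never recover: it is dead
    event <- if (mass <= 0.5 * params@M0) "death"
             else if (mass >= 2 * params@M0) "division" else "none"
    list(cell = cell, event = event)
}

#' Divide a host cell into two daughters
#'
#' Each daughter receives half the parent biomass; every plasmid copy is
#' assigned to one daughter or the other independently with probability 1/2
#' (binomial segregation), conserving the total count. If the parent carried
#' plasmids and a daughter receives none, a segregational-loss event is
#' reported.
#'
#' @param cell a [HostCell] whose biomass has reached the division threshold.
#' @return list with `daughters` (list of two [HostCell]) and `segLoss`
#'   (logical).
#' @export
divideCell <- function(cell) {
    stopifnot(is(cell, "HostCell"))
    pm <- cell@plasmids
    n <- nrow(pm)
    toA <- stats::runif(n) < 0.5
    a <- new("HostCell", biomass = cell@biomass / 2,
             plasmids = pm[toA, , drop = FALSE])
    b <- new("HostCell", biomass = cell@biomass / 2,
             plasmids = pm[!toA, , drop = FALSE])
    list(daughters = list(a, b),
         segLoss = n > 0 && (sum(toA) == 0L || sum(!toA) == 0L))
}

#' Neutral population regulation
#'
#' When the population exceeds the cap, uniformly random cells are removed
#' until the cap is met. Removal is blind to genotype, copy number and
#' biomass, so regulation exerts no selection.
#'
#' @param pop a [Population].
#' @param cap maximum number of cells (>= 1).
#' @return the regulated [Population].
#' @export
regulatePopulation <- function(pop, cap) {
    stopifnot(is(pop, "Population"), cap >= 1)
    if (length(pop@cells) == 0L)
        stop("population is extinct: simulation terminated")
    if (length(pop@cells) > cap)
        pop@cells <- pop@cells[sort(sample.int(length(pop@cells), cap))]
    pop
}

.popToEngine <- function(pop) {
    mass <- vapply(pop@cells, function(cl) cl@biomass, numeric(1))
    counts <- vapply(pop@cells, function(cl) nrow(cl@plasmids), integer(1))
    pm <- do.call(rbind, c(lapply(pop@cells, function(cl) cl@plasmids),
                           list(matrix(numeric(0), 0, 4))))
    list(mass = mass, plasmids = pm, cellOf = rep(seq_along(counts), counts))
}

.engineToPop <- function(out, time) {
    counts <- tabulate(out$cellOf, nbins = length(out$mass))
    idx <- split(seq_along(out$cellOf), factor(out$cellOf,
                                               levels = seq_along(out$mass)))
    cells <- lapply(seq_along(out$mass), function(i) {
        pm <- out$plasmids[idx[[i]], , drop = FALSE]
        colnames(pm) <- .plasmidCols
        new("HostCell", biomass = out$mass[i], plasmids = pm)
    })
    new("Population", cells = cells, time = time,
        counters = out$counters[.counterNames])
}

#' Run a stochastic multicellular simulation
#'
#' Iterates the per-cell update of [stepCell], division with binomial
#' segregation, death and neutral regulation for all cells over `steps` time
#' steps, recording population observables every `recordEvery` steps. Runs in
#' compiled code; given the same seed (via [set.seed]), configuration and
#' initial population, results are bit-identical.
#'
#' @param init a [Population] (see [population] for construction).
#' @param params a [CellParams].
#' @param ev an [EvolutionParams]; use `mu = 0` for homogeneous (no-mutation)
#'   simulations.
#' @param cap population cap enforced by neutral random culling.
#' @param steps number of time steps.
#' @param recordEvery recording interval, in steps.
#' @param histFrom step index from which copy numbers of infected cells are
#'   pooled into the histogram (burn-in exclusion; default 0).
#' @param histMax largest tracked copy number; larger values pool into the
#'   final bin.
#' @return a [SimulationResult-class].
#' @examples
#' set.seed(1)
#' pop <- population(50, PlasmidGenotype(alpha = 1.7, kappa = 2, beta = 1),
#'                   n = 8)
#' res <- runSimulation(pop, cap = 100, steps = 500)
#' observables(res)[1:3, 1:8]
#' @export
runSimulation <- function(init, params = cellParams(),
                          ev = evolutionParams(mu = 0), cap = 1000L,
                          steps = 10000L, recordEvery = 50L, histFrom = 0L,
                          histMax = 200L) {
    stopifnot(is(init, "Population"), is(params, "CellParams"),
              is(ev, "EvolutionParams"), steps >= 1, cap >= 1)
    st <- .popToEngine(init)
    out <- .engineRun(st$mass, st$plasmids, as.integer(st$cellOf),
                      list(g0 = params@g0, B = params@B,
                           steepness = params@steepness, c = params@c,
                           cInh = params@cInh, M0 = params@M0,
                           tau = params@tau, dt = params@dt),
                      list(mu = ev@mu, step = ev@step,
                           bounds = unname(ev@bounds),
                           free = unname(ev@free)),
                      as.integer(cap), as.integer(steps),
                      as.integer(recordEvery), as.integer(histFrom),
                      as.integer(histMax))
    series <- as.data.frame(out$series)
    hist <- data.frame(n = seq_len(histMax), count = out$hist)
    finalTime <- if (nrow(series)) series$time[nrow(series)] else 0
    new("SimulationResult", series = series,
        hist = hist[hist$count > 0, , drop = FALSE],
        counters = out$counters[.counterNames],
        finalPopulation = .engineToPop(out, finalTime),
        terminated = out$terminated, params = params, evolution = ev)
}

#' Within- and between-host trait variance decomposition
#'
#' For each trait, the within-host component is the standard deviation of the
#' plasmid trait values around their host's mean, averaged across all infected
#' hosts; the between-host component is the standard deviation of the host
#' means around the global mean of host means. Population (1/n) standard
#' deviations are used throughout.
#'
#' @param pop a [Population] with at least one infected host.
#' @return data.frame with columns `trait`, `within`, `between`.
#' @export
varianceDecomposition <- function(pop) {
    stopifnot(is(pop, "Population"))
    infected <- Filter(function(cl) nrow(cl@plasmids) > 0, pop@cells)
    if (length(infected) == 0L)
        stop("no infected hosts: variance decomposition undefined")
    sdPop <- function(x) sqrt(mean((x - mean(x))^2))
    traits <- c("alpha", "kappa", "beta")
    res <- lapply(traits, function(tr) {
        vals <- lapply(infected, function(cl) cl@plasmids[, tr])
        hostMeans <- vapply(vals, mean, numeric(1))
        data.frame(trait = tr,
                   within = mean(vapply(vals, sdPop, numeric(1))),
                   between = sdPop(hostMeans))
    })
    do.call(rbind, res)
}

#' Interval event rates from a recorded series
#'
#' Converts the interval event counts of a [SimulationResult] series into
#' per-cell per-unit-time rates: events divided by (population size at the
#' start of the interval times interval duration). Segregational losses are
#' divided by divisions of infected cells (a per-division frequency), and the
#' infected fraction is reported as recorded.
#'
#' @param result a [SimulationResult-class].
#' @param from discard recording rows with `time < from` (burn-in).
#' @return data.frame with columns `time`, `divisionRate`, `deathRate`,
#'   `netGrowthRate`, `segLossRate`, `infectedFraction`.
#' @export
seriesRates <- function(result, from = 0) {
    s <- observables(result)
    if (nrow(s) < 2L) stop("series too short for rates")
    dtInt <- diff(s$time)
    popAtStart <- s$popSize[-nrow(s)]
    out <- data.frame(
        time = s$time[-1],
        divisionRate = s$divisions[-1] / (popAtStart * dtInt),
        deathRate = s$deaths[-1] / (popAtStart * dtInt),
        segLossRate = ifelse(s$divisionsInfected[-1] > 0,
                             s$segLosses[-1] / s$divisionsInfected[-1], NA),
        infectedFraction = s$infected[-1] / pmax(s$popSize[-1], 1))
    out$netGrowthRate <- out$divisionRate - out$deathRate
    out[out$time >= from & is.finite(out$divisionRate), ]
}
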