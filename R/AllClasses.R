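#' @import methods
NULL

## Central value classes. Trait vectors for whole cells are carried as plain
## numeric matrices (columns alpha, kappa, beta, label) for speed; the S4
## classes are the user-facing containers with validity checking.

#' PlasmidGenotype: the three heritable plasmid replication traits
#'
#' A plasmid genotype is defined by three quantitative traits: `alpha`, the
#' basal (uninhibited) replication rate per plasmid per unit time
#' ("selfishness", cis-acting); `kappa`, the rate of synthesis of the
#' trans-acting replication inhibitor per plasmid per unit time ("policing");
#' and `beta`, the binding affinity of the plasmid's replication target to the
#' inhibitor ("obedience", cis-acting, dimensionless).
#'
#' @slot alpha numeric(1), basal replication rate, >= 0.
#' @slot kappa numeric(1), inhibitor production rate, >= 0.
#' @slot beta numeric(1), binding affinity to the inhibitor, >= 0.
#' @slot label numeric(1), neutral lineage marker inherited at replication;
#'   has no effect on dynamics. Used by competition experiments.
#'
#' @examples
#' gt <- PlasmidGenotype(alpha = 0.3, kappa = 1, beta = 0.8)
#' selfishness(gt); policing(gt); obedience(gt)
#' @export
setClass("PlasmidGenotype",
    representation(alpha = "numeric", kappa = "numeric", beta = "numeric",
                   label = "numeric"),
    prototype(alpha = 0, kappa = 0, beta = 0, label = 0))

setValidity("PlasmidGenotype", function(object) {
    msg <- character()
    for (s in c("alpha", "kappa", "beta")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
        else if (v < 0)
            msg <- c(msg, sprintf("'%s' must be non-negative", s))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname PlasmidGenotype-class
#' @param alpha,kappa,beta,label trait values (see slots).
#' @export
PlasmidGenotype <- function(alpha = 0, kappa = 0, beta = 0, label = 0) {
    new("PlasmidGenotype", alpha = as.numeric(alpha), kappa = as.numeric(kappa),
        beta = as.numeric(beta), label = as.numeric(label))
}

#' CellParams: host-cell growth-law and simulation constants
#'
#' Parameters of the host growth law
#' \deqn{g(n) = g_0 + B(1 - e^{-s n}) - c\,n - c_{inh} \sum_j \kappa_j}
#' together with the biomass thresholds and the time discretisation used by
#' the stochastic layer. A newborn cell has biomass `M0` and divides when its
#' biomass reaches `2*M0`; a cell whose biomass falls below zero dies.
#'
#' @slot g0 basal (chromosomal) growth rate, per unit biomass per unit time.
#' @slot B ceiling of the saturating plasmid benefit to host growth.
#' @slot steepness shape constant `s` of the saturating benefit curve, per copy.
#' @slot c maintenance cost per plasmid copy per unit time.
#' @slot cInh policing cost per unit of inhibitor produced (0 in the baseline).
#' @slot M0 biomass of a newborn cell; division at `2*M0`.
#' @slot tau mean inhibitor lifetime (short relative to the cell cycle).
#' @slot dt time step of the stochastic simulation.
#' @export
setClass("CellParams",
    representation(g0 = "numeric", B = "numeric", steepness = "numeric",
                   c = "numeric", cInh = "numeric", M0 = "numeric",
                   tau = "numeric", dt = "numeric"))

setValidity("CellParams", function(object) {
    msg <- character()
    pos <- c("g0", "M0", "tau", "dt", "steepness")
    nonneg <- c("B", "c", "cInh")
    for (s in c(pos, nonneg)) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v)) {
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
            next
        }
        if (s %in% pos && v <= 0)
            msg <- c(msg, sprintf("'%s' must be positive", s))
        if (s %in% nonneg && v < 0)
            msg <- c(msg, sprintf("'%s' must be non-negative", s))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname CellParams-class
#' @param g0,B,steepness,c,cInh,M0,tau,dt see slots. Defaults are the
#'   package's reference study conditions (see the methods vignette).
#' @export
cellParams <- function(g0 = 0.1, B = 0.5, steepness = 0.2, c = 0.01,
                       cInh = 0, M0 = 1, tau = 0.2, dt = 0.1) {
    new("CellParams", g0 = g0, B = B, steepness = steepness, c = c,
        cInh = cInh, M0 = M0, tau = tau, dt = dt)
}

#' EvolutionParams: mutation model and trait bounds
#'
#' Each plasmid replication event mutates the daughter copy with probability
#' `mu`; a mutation perturbs exactly one trait, chosen uniformly among the
#' `free` traits, by an additive uniform step on +/- `step` times that trait's
#' bound, clipped to `[0, bound]`.
#'
#' @slot mu per-replication mutation probability in [0, 1].
#' @slot step mutation kernel half-width, as a fraction of each trait's bound.
#' @slot bounds named numeric(3): upper bounds `alpha`, `kappa`, `beta`.
#' @slot free named logical(3): which traits are allowed to mutate.
#' @export
setClass("EvolutionParams",
    representation(mu = "numeric", step = "numeric", bounds = "numeric",
                   free = "logical"))

setValidity("EvolutionParams", function(object) {
    msg <- character()
    if (object@mu < 0 || object@mu > 1)
        msg <- c(msg, "'mu' must lie in [0, 1]")
    if (object@step <= 0)
        msg <- c(msg, "'step' must be positive")
    if (!identical(names(object@bounds), c("alpha", "kappa", "beta")))
        msg <- c(msg, "'bounds' must be named alpha, kappa, beta")
    else if (any(object@bounds <= 0))
        msg <- c(msg, "'bounds' must be positive")
    if (!identical(names(object@free), c("alpha", "kappa", "beta")))
        msg <- c(msg, "'free' must be named alpha, kappa, beta")
    if (length(msg)) msg else TRUE
})

#' @rdname EvolutionParams-class
#' @param mu,step,bounds,free see slots.
#' @export
evolutionParams <- function(mu = 0.02, step = 0.1,
                            bounds = c(alpha = 2, kappa = 2, beta = 1),
                            free = c(alpha = TRUE, kappa = TRUE, beta = TRUE)) {
    bounds <- bounds[c("alpha", "kappa", "beta")]
    free <- free[c("alpha", "kappa", "beta")]
    new("EvolutionParams", mu = mu, step = step, bounds = bounds, free = free)
}

#' HostCell: one bacterium with its plasmid complement
#'
#' @slot biomass current biomass, same units as `M0`.
#' @slot plasmids numeric matrix with one row per plasmid copy and columns
#'   `alpha`, `kappa`, `beta`, `label`; the copy number `n` is `nrow(plasmids)`.
#' @export
setClass("HostCell",
    representation(biomass = "numeric", plasmids = "matrix"))

.plasmidCols <- c("alpha", "kappa", "beta", "label")

setValidity("HostCell", function(object) {
    msg <- character()
    if (length(object@biomass) != 1L || !is.finite(object@biomass))
        msg <- c(msg, "'biomass' must be a single finite number")
    pm <- object@plasmids
    if (!is.numeric(pm) || !identical(colnames(pm), .plasmidCols))
        msg <- c(msg, "'plasmids' must be a numeric matrix with columns alpha, kappa, beta, label")
    else if (nrow(pm) && any(pm[, 1:3] < 0))
        msg <- c(msg, "trait values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @rdname HostCell-class
#' @param biomass starting biomass.
#' @param genotype a [PlasmidGenotype] replicated `n` times, or a numeric
#'   matrix of per-copy trait rows.
#' @param n copy number when `genotype` is a single genotype.
#' @export
hostCell <- function(biomass = 1, genotype = PlasmidGenotype(), n = 0L) {
    pm <- genotypeMatrix(genotype, n)
    new("HostCell", biomass = as.numeric(biomass), plasmids = pm)
}

#' Expand genotypes into a per-copy trait matrix
#'
#' @param genotype a [PlasmidGenotype], a list of them, or a ready matrix.
#' @param n number of copies per genotype (recycled).
#' @return numeric matrix with columns alpha, kappa, beta, label.
#' @export
genotypeMatrix <- function(genotype, n = 1L) {
    if (is.matrix(genotype)) {
        stopifnot(identical(colnames(genotype), .plasmidCols))
        return(genotype)
    }
    if (is(genotype, "PlasmidGenotype")) genotype <- list(genotype)
    n <- rep_len(as.integer(n), length(genotype))
    rows <- mapply(function(g, k) {
        matrix(rep(c(g@alpha, g@kappa, g@beta, g@label), each = k),
               nrow = k, ncol = 4L)
    }, genotype, n, SIMPLIFY = FALSE)
    pm <- do.call(rbind, c(rows, list(matrix(numeric(0), 0, 4))))
    colnames(pm) <- .plasmidCols
    pm
}

#' Population: a collection of host cells with event counters
#'
#' @slot cells list of [HostCell].
#' @slot time current simulation time.
#' @slot counters named numeric: cumulative `divisions`, `deaths`,
#'   `segLosses` (plasmid-free daughters of infected parents) and
#'   `divisionsInfected` (divisions of plasmid-carrying cells).
#' @export
setClass("Population",
    representation(cells = "list", time = "numeric", counters = "numeric"))

.counterNames <- c("divisions", "deaths", "segLosses", "divisionsInfected")

setValidity("Population", function(object) {
    msg <- character()
    if (!all(vapply(object@cells, is, logical(1), "HostCell")))
        msg <- c(msg, "'cells' must be a list of HostCell objects")
    if (!identical(names(object@counters), .counterNames))
        msg <- c(msg, paste("'counters' must be named:",
                            paste(.counterNames, collapse = ", ")))
    else {
        if (any(object@counters < 0))
            msg <- c(msg, "counters must be non-negative")
        if (object@counters["segLosses"] > object@counters["divisionsInfected"])
            msg <- c(msg, "segregational losses cannot exceed divisions of infected cells")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname Population-class
#' @param cells list of [HostCell], or an integer number of founder cells.
#' @param genotype,n founder genotype and per-cell copy number, used when
#'   `cells` is an integer count.
#' @param biomass founder biomass (recycled across cells).
#' @export
population <- function(cells, genotype = PlasmidGenotype(), n = 0L,
                       biomass = 1) {
    if (is.numeric(cells) && length(cells) == 1L) {
        cells <- replicate(as.integer(cells),
                           hostCell(biomass = biomass, genotype = genotype,
                                    n = n),
                           simplify = FALSE)
    }
    cnt <- stats::setNames(numeric(4), .counterNames)
    new("Population", cells = cells, time = 0, counters = cnt)
}

#' EquilibriumSet: fixed points of the copy-number generation map
#'
#' @slot equilibria data.frame with columns `nStar` (fixed-point copy number),
#'   `stable` (logical, |map slope| < 1), `slope` (map slope at the root) and
#'   `tDiv` (cell-cycle duration of the equilibrium cycle).
#' @slot genotype the [PlasmidGenotype] analysed.
#' @slot nRange the copy-number interval searched.
#' @export
setClass("EquilibriumSet",
    representation(equilibria = "data.frame", genotype = "PlasmidGenotype",
                   nRange = "numeric"))

#' SimulationResult: recorded observables of a stochastic run
#'
#' @slot series data.frame, one row per recording interval: time, population
#'   size, infected count/fraction, interval event counts (divisions, deaths,
#'   segregational losses, divisions of infected cells), per-trait
#'   plasmid-weighted means and within/between-host SDs, and copy-number
#'   mean/SD/skewness over infected cells.
#' @slot hist data.frame `(n, count)`: pooled copy numbers of all
#'   plasmid-infected cells sampled at every recording interval.
#' @slot counters cumulative event counters at the end of the run.
#' @slot finalPopulation the [Population] at the end of the run.
#' @slot terminated TRUE if the population went extinct before the horizon.
#' @slot params,evolution the [CellParams] and [EvolutionParams] used.
#' @export
setClass("SimulationResult",
    representation(series = "data.frame", hist = "data.frame",
                   counters = "numeric", finalPopulation = "Population",
                   terminated = "logical", params = "CellParams",
                   evolution = "EvolutionParams"))
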