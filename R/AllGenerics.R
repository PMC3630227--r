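#' Trait accessors
#'
#' Accessors for the three plasmid replication traits and for cell/population
#' structure. `selfishness` is the basal replication rate `alpha`, `policing`
#' the inhibitor production rate `kappa`, `obedience` the inhibitor binding
#' affinity `beta`.
#'
#' @param x a [PlasmidGenotype], [HostCell] or [Population].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("selfishness", function(x) standardGeneric("selfishness"))
#' @rdname accessors
#' @export
setGeneric("policing", function(x) standardGeneric("policing"))
#' @rdname accessors
#' @export
setGeneric("obedience", function(x) standardGeneric("obedience"))
#' @rdname accessors
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))
#' @rdname accessors
#' @export
setGeneric("biomass", function(x) standardGeneric("biomass"))
#' @rdname accessors
#' @export
setGeneric("counters", function(x) standardGeneric("counters"))
#' @rdname accessors
#' @export
setGeneric("equilibria", function(x) standardGeneric("equilibria"))
#' @rdname accessors
#' @export
setGeneric("observables", function(x) standardGeneric("observables"))

setMethod("selfishness", "PlasmidGenotype", function(x) x@alpha)
setMethod("policing", "PlasmidGenotype", function(x) x@kappa)
setMethod("obedience", "PlasmidGenotype", function(x) x@beta)

setMethod("selfishness", "HostCell", function(x) unname(x@plasmids[, "alpha"]))
setMethod("policing", "HostCell", function(x) unname(x@plasmids[, "kappa"]))
setMethod("obedience", "HostCell", function(x) unname(x@plasmids[, "beta"]))
setMethod("copyNumber", "HostCell", function(x) nrow(x@plasmids))
setMethod("biomass", "HostCell", function(x) x@biomass)

setMethod("copyNumber", "Population",
          function(x) vapply(x@cells, function(cl) nrow(cl@plasmids), integer(1)))
setMethod("counters", "Population", function(x) x@counters)

setMethod("equilibria", "EquilibriumSet", function(x) x@equilibria)
setMethod("observables", "SimulationResult", function(x) x@series)
setMethod("counters", "SimulationResult", function(x) x@counters)

setMethod("show", "PlasmidGenotype", function(object) {
    cat(sprintf(
        "PlasmidGenotype: alpha (selfishness) = %.4g, kappa (policing) = %.4g, beta (obedience) = %.4g\n",
        object@alpha, object@kappa, object@beta))
})

setMethod("show", "CellParams", function(object) {
    cat("CellParams (host growth law g(n) = g0 + B*(1 - exp(-s*n)) - c*n - cInh*sum(kappa))\n")
    cat(sprintf("  g0 = %.4g  B = %.4g  steepness = %.4g  c = %.4g  cInh = %.4g\n",
                object@g0, object@B, object@steepness, object@c, object@cInh))
    cat(sprintf("  M0 = %.4g (division at %.4g)  tau = %.4g  dt = %.4g\n",
                object@M0, 2 * object@M0, object@tau, object@dt))
})

setMethod("show", "HostCell", function(object) {
    cat(sprintf("HostCell: biomass = %.4g, copy number = %d\n",
                object@biomass, nrow(object@plasmids)))
})

setMethod("show", "Population", function(object) {
    n <- copyNumber(object)
    cat(sprintf("Population of %d cells at t = %.4g (%d plasmid-infected)\n",
                length(object@cells), object@time, sum(n > 0)))
    cat("  counters:",
        paste(sprintf("%s = %g", names(object@counters), object@counters),
              collapse = ", "), "\n")
})

setMethod("show", "EquilibriumSet", function(object) {
    cat("EquilibriumSet for", sprintf(
        "alpha = %.4g, kappa = %.4g, beta = %.4g\n",
        object@genotype@alpha, object@genotype@kappa, object@genotype@beta))
    if (nrow(object@equilibria) == 0L) {
        cat("  no fixed points in [", object@nRange[1], ",", object@nRange[2],
            "] (consistent under- or over-replication)\n")
    } else {
        print(object@equilibria, row.names = FALSE)
    }
})

setMethod("show", "SimulationResult", function(object) {
    s <- object@series
    cat(sprintf("SimulationResult: %d recording intervals%s\n", nrow(s),
                if (object@terminated) " (terminated: extinction)" else ""))
    if (nrow(s)) {
        last <- s[nrow(s), ]
        cat(sprintf("  final: t = %.4g, %d cells, infected fraction %.3f\n",
                    last$time, last$popSize,
                    last$infected / max(last$popSize, 1)))
    }
    cat("  counters:",
        paste(sprintf("%s = %g", names(object@counters), object@counters),
              collapse = ", "), "\n")
})
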