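#' Host-cell growth rate as a function of plasmid copy number
#'
#' The specific growth rate of a host cell (change in biomass per unit biomass
#' per unit time) combines the chromosomal baseline `g0`, a saturating
#' gene-dosage benefit of plasmid carriage, a linear per-copy maintenance cost
#' and (optionally) the cost of inhibitor production:
#' \deqn{g(n) = g_0 + B\,(1 - e^{-s n}) - c\,n - c_{inh} \sum_j \kappa_j .}
#' Because the benefit is bounded by `B` while the cost grows linearly, `g` is
#' eventually decreasing in `n` and admits a finite optimal copy number
#' whenever `B * steepness > c` (see [optimalCopyNumber]).
#'
#' @param n copy number (vectorised); non-negative. Integer in the stochastic
#'   layer, real-valued in the deterministic layer.
#' @param totalKappa summed inhibitor production rate of the cell's plasmids
#'   (only enters through the policing cost `cInh`).
#' @param params a [CellParams].
#' @return growth rate(s), per unit biomass per unit time; may be negative.
#' @examples
#' p <- cellParams()
#' growthRate(0, 0, p)                     # plasmid-free cell: g0
#' growthRate(optimalCopyNumber(p), 0, p)  # maximal growth
#' @export
growthRate <- function(n, totalKappa = 0, params = cellParams()) {
    stopifnot(is(params, "CellParams"))
    if (any(!is.finite(n)) || any(n < 0))
        stop("'n' must be finite and non-negative")
    if (any(!is.finite(totalKappa)) || any(totalKappa < 0))
        stop("'totalKappa' must be finite and non-negative")
    params@g0 + params@B * (1 - exp(-params@steepness * n)) -
        params@c * n - params@cInh * totalKappa
}

#' Copy number that maximises the host growth rate
#'
#' Solves the first-order condition of the growth law: the marginal benefit
#' `B*s*exp(-s*n)` equals the marginal cost `c` at
#' \deqn{n_{opt} = \log(B s / c) / s,}
#' provided `B*s > c`; otherwise every plasmid copy is a net burden, the
#' maximum sits at `n = 0` and the plasmid is a pure parasite.
#'
#' @param params a [CellParams].
#' @return the real-valued optimal copy number, with attribute `parasite`
#'   set to TRUE when the optimum is `n = 0`.
#' @export
optimalCopyNumber <- function(params = cellParams()) {
    stopifnot(is(params, "CellParams"))
    if (params@c == 0)
        stop("'c' = 0: growth is non-decreasing in n, no finite optimum")
    bs <- params@B * params@steepness
    if (bs <= params@c)
        return(structure(0, parasite = TRUE))
    structure(log(bs / params@c) / params@steepness, parasite = FALSE)
}

#' Quasi-steady-state inhibitor concentration in a host cell
#'
#' The trans-acting replication inhibitor is synthesised by every resident
#' plasmid at its own rate `kappa` and decays with short mean lifetime `tau`,
#' so its concentration tracks production at quasi-steady state and is diluted
#' by the cell's biomass:
#' \deqn{I = \tau \sum_j \kappa_j / M .}
#'
#' @param plasmids a [HostCell], a [PlasmidGenotype] (with `n` copies), or a
#'   per-copy trait matrix as returned by [genotypeMatrix].
#' @param biomass current cell biomass `M` (> 0); taken from the cell when
#'   `plasmids` is a [HostCell].
#' @param tau mean inhibitor lifetime.
#' @param n copy count used when `plasmids` is a single genotype.
#' @return inhibitor concentration `I >= 0`.
#' @export
inhibitorConcentration <- function(plasmids, biomass = NULL, tau = 0.2, n = 1L) {
    if (is(plasmids, "HostCell")) {
        if (is.null(biomass)) biomass <- plasmids@biomass
        plasmids <- plasmids@plasmids
    } else if (is(plasmids, "PlasmidGenotype")) {
        plasmids <- genotypeMatrix(plasmids, n)
    }
    if (is.null(biomass) || !is.finite(biomass) || biomass <= 0)
        stop("dead or invalid cell: 'biomass' must be positive")
    tau * sum(plasmids[, "kappa"]) / biomass
}

#' Per-plasmid replication rate under inhibition
#'
#' The basal replication rate `alpha` of a plasmid is modulated by its weighted
#' response `beta * I` to the collectively produced inhibitor, with hyperbolic
#' (quasi-equilibrium binding) kinetics by default:
#' \deqn{r = \alpha / (1 + \beta I)}
#' or, alternatively, an exponential response `r = alpha * exp(-beta*I)`.
#' Either way `r = alpha` when `beta = 0` or `I = 0`, and `r` is strictly
#' decreasing in `beta * I`.
#'
#' @param genotype a [PlasmidGenotype], or a per-copy trait matrix (one rate
#'   per row is returned).
#' @param I inhibitor concentration, >= 0.
#' @param form inhibition response: `"hyperbolic"` (default) or
#'   `"exponential"`.
#' @return replication rate(s), events per plasmid per unit time.
#' @export
replicationRate <- function(genotype, I, form = c("hyperbolic", "exponential")) {
    form <- match.arg(form)
    if (any(!is.finite(I)) || any(I < 0))
        stop("'I' must be finite and non-negative")
    if (is(genotype, "PlasmidGenotype")) {
        a <- genotype@alpha; b <- genotype@beta
    } else {
        a <- genotype[, "alpha"]; b <- genotype[, "beta"]
    }
    switch(form,
        hyperbolic = a / (1 + b * I),
        exponential = a * exp(-b * I))
}
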