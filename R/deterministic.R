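## Deterministic single-cell layer: continuous copy number n and biomass M,
##   dM/dt = M * g(n),   dn/dt = n * alpha / (1 + beta * tau * kappa * n / M),
## integrated over one cell cycle (M: M0 -> 2*M0) with event detection, from
## which the parent->daughter generation map and its fixed points are built.

.cycleDerivs <- function(t, y, parms) {
    M <- y[1]; n <- y[2]
    g <- parms$g0 + parms$B * (1 - exp(-parms$steepness * n)) -
        parms$c * n - parms$cInh * parms$kappa * n
    I <- parms$tau * parms$kappa * n / M
    r <- parms$alpha / (1 + parms$beta * I)
    list(c(M * g, n * r))
}

#' Integrate one deterministic cell cycle
#'
#' Starting from a newborn cell of biomass `M0` carrying `n0` (real-valued)
#' copies of a single plasmid genotype, jointly integrates biomass and copy
#' number until the biomass doubles (division), the horizon elapses, or the
#' cell is shrinking at the horizon (death by negative growth). Integration is
#' adaptive (lsodar) with a root function on `M = 2*M0`.
#'
#' @param n0 initial copy number, >= 0.
#' @param genotype a [PlasmidGenotype].
#' @param params a [CellParams].
#' @param horizon maximum integration time; default 50 plasmid-free division
#'   times, `50*log(2)/g0`.
#' @param rtol,atol integration tolerances.
#' @return a list with `nDivision` (copy number at division, NA if none),
#'   `tDiv` (division time, NA if none) and `outcome` in
#'   `c("divides", "dies", "stalls")`.
#' @examples
#' res <- integrateCellCycle(5, PlasmidGenotype(alpha = 0.2))
#' res$tDiv; res$nDivision
#' @export
integrateCellCycle <- function(n0, genotype, params = cellParams(),
                               horizon = 50 * log(2) / params@g0,
                               rtol = 1e-8, atol = 1e-10) {
    stopifnot(is(genotype, "PlasmidGenotype"), is(params, "CellParams"),
              n0 >= 0)
    parms <- list(g0 = params@g0, B = params@B, steepness = params@steepness,
                  c = params@c, cInh = params@cInh, tau = params@tau,
                  alpha = genotype@alpha, kappa = genotype@kappa,
                  beta = genotype@beta)
    M0 <- params@M0
    ## plasmid-free (or replication-free) cycles have closed forms; also avoids
    ## a degenerate root search when g <= 0 forever
    if (n0 == 0) {
        if (parms$g0 <= 0)
            return(list(nDivision = NA_real_, tDiv = NA_real_, outcome = "stalls"))
        return(list(nDivision = 0, tDiv = log(2) / parms$g0,
                    outcome = "divides"))
    }
    y0 <- c(M = M0, n = n0)
    ## n is non-decreasing and g(n) < 0 only beyond the death boundary, so a
    ## cell that has shrunk to M0/2 can never recover: stop it as dead there
    ## rather than integrating an exploding n to overflow.
    root <- function(t, y, p) c(y[1] - 2 * M0, y[1] - 0.5 * M0)
    sol <- deSolve::lsodar(y = y0, times = c(0, horizon), func = .cycleDerivs,
                           parms = parms, rootfunc = root,
                           rtol = rtol, atol = atol)
    if (any(!is.finite(sol)))
        stop(sprintf(
            "non-finite state integrating cell cycle (n0 = %g, alpha = %g, kappa = %g, beta = %g)",
            n0, parms$alpha, parms$kappa, parms$beta))
    last <- sol[nrow(sol), ]
    tEnd <- last[["time"]]; MEnd <- last[["M"]]; nEnd <- last[["n"]]
    if (MEnd >= 2 * M0 * (1 - 1e-7)) {
        return(list(nDivision = nEnd, tDiv = tEnd, outcome = "divides"))
    }
    if (MEnd <= 0.5 * M0 * (1 + 1e-7)) {
        return(list(nDivision = NA_real_, tDiv = NA_real_, outcome = "dies"))
    }
    gEnd <- growthRate(nEnd, genotype@kappa * nEnd, params)
    list(nDivision = NA_real_, tDiv = NA_real_,
         outcome = if (gEnd < 0) "dies" else "stalls")
}

#' Parent-to-daughter copy-number generation map
#'
#' Maps the copy number `n0` at the start of a parent's cell cycle to the copy
#' number at the start of each daughter's cycle, assuming equipartitioning at
#' division: `n1 = nDivision / 2`. Undefined (NA) where the parent never
#' divides (death or stall).
#'
#' @param n0 initial copy number(s); vectorised.
#' @inheritParams integrateCellCycle
#' @return numeric vector `n1`, NA where the map is undefined.
#' @export
generationMap <- function(n0, genotype, params = cellParams(),
                          horizon = 50 * log(2) / params@g0) {
    vapply(n0, function(x) {
        res <- integrateCellCycle(x, genotype, params, horizon)
        if (res$outcome == "divides") res$nDivision / 2 else NA_real_
    }, numeric(1))
}

.mapSlope <- function(nStar, genotype, params, h = NULL) {
    if (is.null(h)) h <- max(1e-4 * nStar, 1e-6)
    y <- generationMap(c(nStar - h, nStar + h), genotype, params)
    (y[2] - y[1]) / (2 * h)
}

.deathBoundary <- function(params) {
    ## copy number above which growth is negative (upper root of g(n) = 0)
    nopt <- optimalCopyNumber(params)
    if (growthRate(nopt, 0, params) <= 0) return(nopt)
    hi <- max(2 * nopt, 1)
    while (growthRate(hi, 0, params) > 0) hi <- hi * 2
    stats::uniroot(function(n) growthRate(n, 0, params),
                   c(max(nopt, 1e-8), hi), tol = 1e-8)$root
}

#' Fixed points of the generation map and their stability
#'
#' Locates all roots of `generationMap(n) - n` on a grid over `nRange` by
#' sign-change bracketing refined with [stats::uniroot], and classifies each
#' root as stable when the absolute slope of the map at the root is below 1.
#' Around a stable root the map satisfies the over-/under-replication sign
#' structure: cells starting below `nStar` over-replicate (`n1 > n0`), cells
#' starting above under-replicate.
#'
#' @inheritParams integrateCellCycle
#' @param nRange copy-number interval to search; defaults to (0.01, the copy
#'   number at which growth turns negative).
#' @param nGrid number of grid points used for bracketing (default 200).
#' @return an [EquilibriumSet-class].
#' @export
findEquilibria <- function(genotype, params = cellParams(), nRange = NULL,
                           nGrid = 200L) {
    stopifnot(is(genotype, "PlasmidGenotype"))
    if (is.null(nRange)) nRange <- c(0.01, .deathBoundary(params))
    grid <- seq(nRange[1], nRange[2], length.out = nGrid)
    f <- generationMap(grid, genotype, params) - grid
    roots <- numeric(0)
    ok <- which(!is.na(f))
    for (i in seq_along(ok)[-1]) {
        a <- ok[i - 1L]; b <- ok[i]
        if (b - a != 1L) next   # don't bracket across an undefined gap
        if (f[a] == 0) roots <- c(roots, grid[a])
        if (f[a] * f[b] < 0) {
            r <- stats::uniroot(function(n) {
                generationMap(n, genotype, params) - n
            }, c(grid[a], grid[b]), tol = 1e-8)
            roots <- c(roots, r$root)
        }
    }
    if (length(roots)) {
        slopes <- vapply(roots, .mapSlope, numeric(1), genotype = genotype,
                         params = params)
        tdiv <- vapply(roots, function(n)
            integrateCellCycle(n, genotype, params)$tDiv, numeric(1))
        eq <- data.frame(nStar = roots, stable = abs(slopes) < 1,
                         slope = slopes, tDiv = tdiv)
    } else {
        eq <- data.frame(nStar = numeric(0), stable = logical(0),
                         slope = numeric(0), tDiv = numeric(0))
    }
    new("EquilibriumSet", equilibria = eq, genotype = genotype,
        nRange = as.numeric(nRange))
}

#' Cell fitness at the stable characteristic copy number
#'
#' Cell fitness is the reciprocal of the division time of the equilibrium cell
#' cycle, i.e. the cycle that starts at the stable characteristic copy number
#' `nStar`. A plasmid-free cell has fitness `g0/log(2)`.
#'
#' @inheritParams integrateCellCycle
#' @param equilibriumSet optionally, a precomputed [findEquilibria] result.
#' @return fitness `1/tDiv`, with attribute `nStar`; `NA` (with attribute
#'   `reason`) when no stable equilibrium exists.
#' @export
cellFitness <- function(genotype, params = cellParams(),
                        equilibriumSet = NULL) {
    if (is.null(equilibriumSet))
        equilibriumSet <- findEquilibria(genotype, params)
    eq <- equilibriumSet@equilibria
    st <- eq[eq$stable, , drop = FALSE]
    if (nrow(st) == 0L)
        return(structure(NA_real_, reason = "no stable equilibrium"))
    i <- which.max(st$nStar)
    structure(1 / st$tDiv[i], nStar = st$nStar[i])
}

#' Deterministic prediction of the population-mean copy number
#'
#' In an asynchronously dividing population at steady state, cell ages follow
#' the stable age distribution `phi(a) = 2*lambda*exp(-lambda*a)` with
#' `lambda = log(2)/T`. A cell of age `a` on the equilibrium cycle carries
#' `n(a)` plasmids, rising from `nStar` at birth to `2*nStar` at division, so
#' the deterministic layer predicts a population-mean copy number
#' \deqn{\bar n = \int_0^T n(a)\, 2\lambda e^{-\lambda a}\, da}
#' (for exponential copy-number growth this is `2*log(2)*nStar ~ 1.39*nStar`).
#' This is the like-for-like comparator for the mean copy number over infected
#' cells reported by the stochastic layer.
#'
#' @inheritParams integrateCellCycle
#' @param nStar the stable characteristic copy number; located via
#'   [findEquilibria] when NULL.
#' @return the predicted population-mean copy number (attribute `nStar`), or
#'   NA if no stable equilibrium exists.
#' @export
deterministicMeanCopyNumber <- function(genotype, params = cellParams(),
                                        nStar = NULL) {
    if (is.null(nStar)) {
        f <- cellFitness(genotype, params)
        if (is.na(f)) return(structure(NA_real_, nStar = NA_real_))
        nStar <- attr(f, "nStar")
    }
    cyc <- integrateCellCycle(nStar, genotype, params)
    T <- cyc$tDiv
    parms <- list(g0 = params@g0, B = params@B, steepness = params@steepness,
                  c = params@c, cInh = params@cInh, tau = params@tau,
                  alpha = genotype@alpha, kappa = genotype@kappa,
                  beta = genotype@beta)
    times <- seq(0, T, length.out = 201L)
    sol <- deSolve::lsoda(c(M = params@M0, n = nStar), times, .cycleDerivs,
                          parms, rtol = 1e-8, atol = 1e-10)
    lambda <- log(2) / T
    w <- 2 * lambda * exp(-lambda * times)
    nbar <- sum(diff(times) * (utils::head(sol[, "n"] * w, -1) +
                               utils::tail(sol[, "n"] * w, -1)) / 2)
    structure(nbar, nStar = nStar)
}

#' Edge of plasmid stability (fold bifurcation in alpha)
#'
#' As the basal replication rate `alpha` increases, the stable and unstable
#' fixed points of the generation map approach each other and coalesce at a
#' fold bifurcation, `alphaCrit`, where the map becomes tangent to the
#' diagonal; beyond it plasmids over-replicate from any initial copy number.
#' Located by bisection on equilibrium existence over `alphaRange`.
#'
#' @param beta,kappa the obedience and policing traits held fixed.
#' @param params a [CellParams].
#' @param alphaRange interval of basal replication rates to search; must
#'   contain the fold.
#' @param tol bisection tolerance on alpha.
#' @param nGrid grid size passed to [findEquilibria] during the search.
#' @param nRange copy-number search interval passed to [findEquilibria];
#'   focusing it around the fold sharpens detection of the nearly tangent
#'   root pair close to `alphaCrit`.
#' @return `alphaCrit`, with attributes `nFold` (the coalescing copy number)
#'   and `slopeBelow` (map slope at the stable root just below the fold,
#'   which approaches 1 at tangency).
#' @export
edgeOfStability <- function(beta, kappa, params = cellParams(),
                            alphaRange = c(0.01, 1), tol = 1e-5,
                            nGrid = 120L, nRange = NULL) {
    eqAt <- function(a) findEquilibria(
        PlasmidGenotype(alpha = a, kappa = kappa, beta = beta),
        params, nRange = nRange, nGrid = nGrid)
    hasRoots <- function(a) nrow(eqAt(a)@equilibria) > 0L
    coarse <- seq(alphaRange[1], alphaRange[2], length.out = 16L)
    has <- vapply(coarse, hasRoots, logical(1))
    if (!any(has)) {
        gt <- PlasmidGenotype(alpha = mean(alphaRange), kappa = kappa,
                              beta = beta)
        probe <- generationMap(1, gt, params)
        regime <- if (is.na(probe) || probe > 1) "over-replication" else
            "under-replication"
        stop("no equilibria anywhere in alphaRange (entire range in the ",
             regime, " regime)")
    }
    if (has[length(has)])
        stop("equilibria persist at the top of alphaRange; extend the range ",
             "to bracket the fold")
    iLast <- max(which(has))
    lo <- coarse[iLast]; hi <- coarse[iLast + 1L]
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (hasRoots(mid)) lo <- mid else hi <- mid
    }
    eqLo <- eqAt(lo)@equilibria
    stable <- eqLo[eqLo$stable, , drop = FALSE]
    structure((lo + hi) / 2,
              nFold = if (nrow(eqLo)) mean(range(eqLo$nStar)) else NA_real_,
              slopeBelow = if (nrow(stable)) max(stable$slope) else NA_real_)
}
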