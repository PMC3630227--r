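## Scripted experiment drivers over the stochastic engine. Every driver takes
## a master seed and derives one RNG stream per replicate/grid cell by the
## fixed splitting rule seedFor(master, i) = master + 7919*i (7919 = 1000th
## prime), so runs are reproducible and replicates independent.

seedFor <- function(master, i) as.integer((master + 7919 * i) %% .Machine$integer.max)

.lastWindow <- function(x, frac = 0.25) {
    x[x$time >= (1 - frac) * max(x$time), , drop = FALSE]
}

.homogeneousRun <- function(genotype, params, cap, steps, nInit,
                            founders = max(2L, cap %/% 2L),
                            recordEvery = max(1L, steps %/% 200L),
                            histFrom = steps %/% 4L) {
    pop <- population(founders, genotype, n = nInit)
    runSimulation(pop, params, evolutionParams(mu = 0), cap = cap,
                  steps = steps, recordEvery = recordEvery,
                  histFrom = histFrom)
}

## Outcome labels mirror the deterministic regimes, with one stochastic
## subtlety: consistent over-replication at high copy numbers produces no
## plasmid-free segregants (P(empty daughter) ~ 2^(1-n)), so instead of
## plasmid loss the population persists in a division-death churn with net
## growth near zero. That stagnant state is classified population-collapse,
## alongside outright extinction.
.classifyOutcome <- function(res, nInit) {
    if (res@terminated) return("population-collapse")
    s <- observables(res)
    finalInf <- mean(utils::tail(s$infected / pmax(s$popSize, 1), 5))
    if (finalInf < 0.25) {
        mn <- s$meanN[!is.na(s$meanN)]
        return(if (length(mn) && mean(mn) >= nInit) "plasmid-loss-over"
               else "plasmid-loss-under")
    }
    r <- .lastWindow(seriesRates(res), 0.5)
    if (mean(r$deathRate) > 0.3 * mean(r$divisionRate)) "population-collapse"
    else "stable-infected"
}

#' Net-growth-rate landscape over selfishness and obedience
#'
#' For each point of an `alpha x beta` grid at fixed policing `kappa`, runs
#' homogeneous (mutation-free) stochastic simulations and reports the mean net
#' growth rate (division rate minus death rate, per cell per unit time, over
#' the post-burn-in window) together with an outcome classification:
#' `stable-infected`, `plasmid-loss-under` (consistent under-replication
#' dilutes plasmids away), `plasmid-loss-over` (plasmid-free segregants
#' outgrow over-infected cells), or `population-collapse`.
#'
#' @param alphaGrid,betaGrid grid values of the basal replication rate and the
#'   inhibitor binding affinity.
#' @param kappa fixed inhibitor production rate (trans-acting).
#' @param params a [CellParams].
#' @param cap,steps per-run population cap and step count.
#' @param nInit founder copy number per cell (identical across the grid).
#' @param replicates independent runs averaged per grid point.
#' @param seed master seed.
#' @return data.frame: alpha, beta, netGrowthRate, outcome (modal over
#'   replicates), infectedFraction.
#' @export
fitnessLandscape <- function(alphaGrid, betaGrid, kappa = 2,
                             params = cellParams(), cap = 400L,
                             steps = 8000L, nInit = 5L, replicates = 1L,
                             seed = 1L) {
    grid <- expand.grid(alpha = alphaGrid, beta = betaGrid)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        gt <- PlasmidGenotype(alpha = grid$alpha[i], kappa = kappa,
                              beta = grid$beta[i])
        net <- inf <- dv <- dth <- numeric(replicates)
        outc <- character(replicates)
        for (rep in seq_len(replicates)) {
            set.seed(seedFor(seed, (i - 1L) * replicates + rep))
            res <- .homogeneousRun(gt, params, cap, steps, nInit)
            outc[rep] <- .classifyOutcome(res, nInit)
            if (res@terminated) {
                net[rep] <- NA; inf[rep] <- 0; dv[rep] <- NA; dth[rep] <- NA
            } else {
                r <- .lastWindow(seriesRates(res), 0.5)
                net[rep] <- mean(r$netGrowthRate)
                inf[rep] <- mean(r$infectedFraction)
                dv[rep] <- mean(r$divisionRate)
                dth[rep] <- mean(r$deathRate)
            }
        }
        data.frame(alpha = grid$alpha[i], beta = grid$beta[i],
                   netGrowthRate = mean(net),
                   divisionRate = mean(dv), deathRate = mean(dth),
                   outcome = names(which.max(table(outc))),
                   infectedFraction = mean(inf))
    })
    do.call(rbind, rows)
}

#' Deterministic outcome classification on a trait grid
#'
#' The deterministic layer's counterpart of [fitnessLandscape]: for each grid
#' point, `stable-infected` when the generation map has a stable fixed point,
#' otherwise under- or over-replication according to the side of the diagonal
#' the map lies on.
#'
#' @inheritParams fitnessLandscape
#' @param nGrid grid size for [findEquilibria].
#' @return data.frame: alpha, beta, outcome.
#' @export
deterministicOutcomeMap <- function(alphaGrid, betaGrid, kappa = 2,
                                    params = cellParams(), nGrid = 80L) {
    grid <- expand.grid(alpha = alphaGrid, beta = betaGrid)
    res <- lapply(seq_len(nrow(grid)), function(i) {
        gt <- PlasmidGenotype(alpha = grid$alpha[i], kappa = kappa,
                              beta = grid$beta[i])
        eq <- equilibria(findEquilibria(gt, params, nGrid = nGrid))
        if (any(eq$stable))
            return(list("stable-infected", max(eq$nStar[eq$stable])))
        probe <- generationMap(2, gt, params)
        list(if (!is.na(probe) && probe < 2) "plasmid-loss-under"
             else "plasmid-loss-over", NA_real_)
    })
    grid$outcome <- vapply(res, `[[`, character(1), 1L)
    grid$nStar <- vapply(res, `[[`, numeric(1), 2L)
    grid
}

#' Copy-number distributions along an obedience cross-section
#'
#' Fixes the basal replication rate (at the value optimal under maximal CNC on
#' the landscape) and sweeps the binding affinity `beta`, recording the pooled
#' copy-number distribution of all infected cells past burn-in. Reports, per
#' beta: distribution mean, SD, skewness, the discrepancy between mean copy
#' number and the host-optimal copy number, final infected fraction, and
#' whether plasmids were lost.
#'
#' @param betaGrid obedience values swept.
#' @param alpha fixed basal replication rate.
#' @param kappa fixed inhibitor production rate.
#' @inheritParams fitnessLandscape
#' @return list with `summary` (one row per beta x replicate) and `hists`
#'   (pooled histogram per beta, summed over replicates).
#' @export
obedienceSweep <- function(betaGrid, alpha, kappa = 2, params = cellParams(),
                           cap = 600L, steps = 15000L, nInit = 5L,
                           replicates = 3L, seed = 1L) {
    nOpt <- optimalCopyNumber(params)
    out <- list(); hists <- list()
    for (bi in seq_along(betaGrid)) {
        gt <- PlasmidGenotype(alpha = alpha, kappa = kappa,
                              beta = betaGrid[bi])
        hsum <- NULL
        for (rep in seq_len(replicates)) {
            set.seed(seedFor(seed, (bi - 1L) * replicates + rep))
            res <- .homogeneousRun(gt, params, cap, steps, nInit)
            h <- res@hist
            m <- histMoments(h)
            s <- observables(res)
            finalInf <- mean(utils::tail(s$infected / pmax(s$popSize, 1), 5))
            out[[length(out) + 1L]] <- data.frame(
                beta = betaGrid[bi], replicate = rep, meanN = m["mean"],
                sdN = m["sd"], skewN = m["skew"],
                discrepancy = abs(m["mean"] - nOpt),
                infectedFraction = finalInf,
                lost = res@terminated || finalInf < 0.05)
            full <- stats::setNames(numeric(200), 1:200)
            full[as.character(h$n)] <- h$count
            hsum <- if (is.null(hsum)) full else hsum + full
        }
        hists[[as.character(betaGrid[bi])]] <-
            data.frame(n = 1:200, count = unname(hsum))
    }
    list(summary = do.call(rbind, out), hists = hists, nOpt = nOpt)
}

#' Moments of a pooled copy-number histogram
#'
#' @param hist data.frame with columns `n` and `count`.
#' @return named vector: mean, sd (population), skew.
#' @export
histMoments <- function(hist) {
    w <- hist$count / sum(hist$count)
    m <- sum(w * hist$n)
    m2 <- sum(w * (hist$n - m)^2)
    m3 <- sum(w * (hist$n - m)^3)
    c(mean = m, sd = sqrt(m2), skew = if (m2 > 0) m3 / m2^1.5 else NA_real_)
}

#' Co-evolution of selfishness, policing and obedience
#'
#' Evolves a founding plasmid strain under mutation and two-level selection.
#' The default protocol starts from plasmids that neither produce nor respond
#' to inhibitors (`kappa = 0`, `beta = 0`) with a basal replication rate
#' inside the passive-control stable region, and lets the free traits mutate.
#'
#' @param founder founding [PlasmidGenotype].
#' @param free named logical(3): traits allowed to mutate.
#' @param params a [CellParams].
#' @param mu,step mutation probability and kernel width (fraction of bound).
#' @param bounds trait bounds.
#' @param cap,steps population cap and number of steps.
#' @param nInit founder copy number.
#' @param replicates number of independent runs.
#' @param seed master seed.
#' @param recordEvery recording interval (steps).
#' @param windowFrac final fraction of the run treated as quasi-equilibrium.
#' @return list: `trajectories` (replicate x time trait means),
#'   `endpoint` (per-replicate window-averaged trait means and rates),
#'   `varDecomp` (within/between-host trait SDs of each final population),
#'   `excluded` (replicates lost to extinction).
#' @export
coevolve <- function(founder = PlasmidGenotype(alpha = 0.3),
                     free = c(alpha = TRUE, kappa = TRUE, beta = TRUE),
                     params = cellParams(), mu = 0.02, step = 0.1,
                     bounds = c(alpha = 2, kappa = 2, beta = 1),
                     cap = 1000L, steps = 150000L, nInit = 4L,
                     replicates = 10L, seed = 1L, recordEvery = 1000L,
                     windowFrac = 0.2) {
    ev <- evolutionParams(mu = mu, step = step, bounds = bounds, free = free)
    traj <- list(); endp <- list(); vd <- list(); excluded <- integer(0)
    for (rep in seq_len(replicates)) {
        set.seed(seedFor(seed, rep))
        pop <- population(cap %/% 2L, founder, n = nInit)
        res <- runSimulation(pop, params, ev, cap = cap, steps = steps,
                             recordEvery = recordEvery)
        if (res@terminated) {
            excluded <- c(excluded, rep)
            next
        }
        s <- observables(res)
        s$replicate <- rep
        traj[[length(traj) + 1L]] <- s
        w <- .lastWindow(s, windowFrac)
        r <- .lastWindow(seriesRates(res), windowFrac)
        endp[[length(endp) + 1L]] <- data.frame(
            replicate = rep,
            meanAlpha = mean(w$meanAlpha), meanKappa = mean(w$meanKappa),
            meanBeta = mean(w$meanBeta), meanN = mean(w$meanN),
            withinSdAlpha = mean(w$withinSdAlpha, na.rm = TRUE),
            betweenSdAlpha = mean(w$betweenSdAlpha, na.rm = TRUE),
            withinSdKappa = mean(w$withinSdKappa, na.rm = TRUE),
            betweenSdKappa = mean(w$betweenSdKappa, na.rm = TRUE),
            withinSdBeta = mean(w$withinSdBeta, na.rm = TRUE),
            betweenSdBeta = mean(w$betweenSdBeta, na.rm = TRUE),
            divisionRate = mean(r$divisionRate),
            deathRate = mean(r$deathRate),
            netGrowthRate = mean(r$netGrowthRate),
            segLossRate = mean(r$segLossRate, na.rm = TRUE),
            infectedFraction = mean(r$infectedFraction))
        vd[[length(vd) + 1L]] <-
            cbind(replicate = rep, varianceDecomposition(res@finalPopulation))
    }
    list(trajectories = do.call(rbind, traj),
         endpoint = do.call(rbind, endp),
         varDecomp = do.call(rbind, vd),
         excluded = excluded)
}

#' Evolved outcomes across policing costs
#'
#' Runs the [coevolve] protocol at each level of the policing cost `cInh`
#' (cost per unit of inhibitor produced, paid by the host) and summarises the
#' evolved trait means and population performance per cost level.
#'
#' @param cInhGrid policing cost levels.
#' @param ... passed to [coevolve].
#' @param params baseline [CellParams]; `cInh` is overridden per level.
#' @param seed master seed.
#' @return data.frame: one row per (cInh, replicate) with evolved trait means,
#'   division rate, segregational-loss rate and infected fraction.
#' @export
policingCostSweep <- function(cInhGrid, params = cellParams(), seed = 1L, ...) {
    rows <- lapply(seq_along(cInhGrid), function(i) {
        p <- params
        p@cInh <- cInhGrid[i]
        co <- coevolve(params = p, seed = seedFor(seed, 1000L * i), ...)
        if (is.null(co$endpoint)) return(NULL)
        cbind(cInh = cInhGrid[i], co$endpoint)
    })
    do.call(rbind, rows)
}

#' Collective versus individual restraint (CNC vs NO-CNC arms)
#'
#' Pairs of evolutionary simulations sharing a replicate seed: in the CNC arm
#' all three traits evolve from the non-policing founder; in the NO-CNC arm
#' only the basal replication rate evolves while `kappa = beta = 0` (passive
#' control). Host performance (division and death rates) and plasmid
#' performance (segregational-loss rate, infected fraction) are compared by
#' one-sided rank-sum tests on replicate-level window means.
#'
#' @inheritParams coevolve
#' @param nocncFree trait freedom of the comparison arm; the default frees
#'   alpha only. Passing the same freedoms as the CNC arm yields a null
#'   control.
#' @return list: `metrics` (per arm x replicate), `tests` (one-sided
#'   Wilcoxon p-values per metric), `excluded`.
#' @export
cncVsNocnc <- function(founder = PlasmidGenotype(alpha = 0.3),
                       params = cellParams(), mu = 0.02, step = 0.1,
                       bounds = c(alpha = 2, kappa = 2, beta = 1),
                       cap = 1000L, steps = 150000L, nInit = 4L,
                       replicates = 10L, seed = 1L,
                       nocncFree = c(alpha = TRUE, kappa = FALSE,
                                     beta = FALSE),
                       windowFrac = 0.2) {
    runArm <- function(arm, free) {
        co <- coevolve(founder = founder, free = free, params = params,
                       mu = mu, step = step, bounds = bounds, cap = cap,
                       steps = steps, nInit = nInit, replicates = replicates,
                       seed = seed, windowFrac = windowFrac)
        list(metrics = if (!is.null(co$endpoint))
                 cbind(arm = arm, co$endpoint) else NULL,
             excluded = co$excluded)
    }
    cnc <- runArm("CNC", c(alpha = TRUE, kappa = TRUE, beta = TRUE))
    noc <- runArm("NO-CNC", nocncFree)
    metrics <- rbind(cnc$metrics, noc$metrics)
    test <- function(metric, alternative) {
        x <- metrics[metrics$arm == "CNC", metric]
        y <- metrics[metrics$arm == "NO-CNC", metric]
        stats::wilcox.test(x, y, alternative = alternative, exact = FALSE)$p.value
    }
    tests <- data.frame(
        metric = c("divisionRate", "deathRate", "segLossRate",
                   "infectedFraction"),
        alternative = c("greater", "less", "less", "greater"))
    tests$p.value <- mapply(test, tests$metric, tests$alternative)
    list(metrics = metrics, tests = tests,
         excluded = list(CNC = cnc$excluded, `NO-CNC` = noc$excluded))
}

#' Invasion analysis: policing type versus insensitive type
#'
#' Competes two fixed genotypes (no mutation): a CNC type (policing and
#' obedient) against a NO-CNC type insensitive to inhibitors, starting from
#' equal frequencies mixed either within hosts (every founder cell carries
#' both types) or between hosts (each founder cell carries one type). The
#' type frequency is tracked through neutral lineage labels (resident label 1,
#' invader 0).
#'
#' @param resident,invader the two [PlasmidGenotype]s; labels are overwritten
#'   (resident 1, invader 0).
#' @param mixing `"within"` or `"between"` host initial heterogeneity.
#' @param params a [CellParams].
#' @param cap,nInit population cap; total founder copies per cell.
#' @param maxSteps fixation horizon.
#' @param checkEvery steps between fixation checks.
#' @param replicates,seed replication control.
#' @return data.frame per replicate: `winner` (`"resident"`, `"invader"` or
#'   `"coexist"`/`"extinct"`), `fixationTime`, final resident frequency.
#' @export
invasion <- function(resident, invader, mixing = c("within", "between"),
                     params = cellParams(), cap = 500L, nInit = 2L,
                     maxSteps = 40000L, checkEvery = 2000L,
                     replicates = 20L, seed = 1L) {
    mixing <- match.arg(mixing)
    resident@label <- 1; invader@label <- 0
    founders <- max(1L, cap %/% 2L)
    rows <- lapply(seq_len(replicates), function(rep) {
        set.seed(seedFor(seed, rep))
        cells <- if (mixing == "within") {
            replicate(founders, hostCell(1, list(resident, invader),
                                         n = c(nInit %/% 2L,
                                               nInit - nInit %/% 2L)),
                      simplify = FALSE)
        } else {
            c(replicate(founders %/% 2L, hostCell(1, resident, nInit),
                        simplify = FALSE),
              replicate(founders - founders %/% 2L,
                        hostCell(1, invader, nInit), simplify = FALSE))
        }
        pop <- population(cells)
        t <- 0L; winner <- "coexist"; freq <- 0.5; ftime <- NA_real_
        while (t < maxSteps) {
            res <- runSimulation(pop, params, evolutionParams(mu = 0),
                                 cap = cap, steps = checkEvery,
                                 recordEvery = checkEvery)
            t <- t + checkEvery
            if (res@terminated) { winner <- "extinct"; break }
            s <- observables(res)
            freq <- s$meanLabel[nrow(s)]
            if (is.na(freq)) { winner <- "extinct"; break }
            if (freq == 1) { winner <- "resident"; ftime <- t * params@dt; break }
            if (freq == 0) { winner <- "invader"; ftime <- t * params@dt; break }
            pop <- res@finalPopulation
        }
        data.frame(replicate = rep, winner = winner, fixationTime = ftime,
                   residentFreq = freq)
    })
    do.call(rbind, rows)
}
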