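# Single-cell deterministic layer: cell-cycle integration, generation map,
# fixed points, fitness and the fold bifurcation.

# independent fixed-step Euler oracle for one cell cycle
eulerCycle <- function(n0, gt, p, dt = 1e-4, horizon = 400) {
    M <- p@M0; n <- n0; t <- 0
    while (t < horizon) {
        g <- p@g0 + p@B * (1 - exp(-p@steepness * n)) - p@c * n -
            p@cInh * gt@kappa * n
        I <- p@tau * gt@kappa * n / M
        r <- gt@alpha / (1 + gt@beta * I)
        M <- M * (1 + g * dt)
        n <- n * (1 + r * dt)
        t <- t + dt
        if (M >= 2 * p@M0) return(list(tDiv = t, nDivision = n))
        if (M <= 0.5 * p@M0) return(list(tDiv = NA, nDivision = NA))
    }
    list(tDiv = NA, nDivision = NA)
}

test_that("a plasmid-free cell divides after ln(2)/g0 with no plasmids", {
    res <- integrateCellCycle(0, PlasmidGenotype(), refParams)
    expect_identical(res$outcome, "divides")
    expect_equal(res$tDiv, log(2) / refParams@g0, tolerance = 1e-10)
    expect_identical(res$nDivision, 0)
})

test_that("without replication the copy number is frozen while biomass
           doubles", {
    res <- integrateCellCycle(6, PlasmidGenotype(alpha = 0), refParams)
    expect_identical(res$outcome, "divides")
    expect_equal(res$nDivision, 6, tolerance = 1e-6)
    # division time is the closed form for constant copy number
    expect_equal(res$tDiv, log(2) / growthRate(6, 0, refParams),
                 tolerance = 1e-6)
})

test_that("adaptive integration agrees with a fixed-step Euler oracle", {
    set.seed(42)
    for (gt in list(gtNoCncStable, gtCncOpt, randomStableGenotype())) {
        n0 <- 4
        adaptive <- integrateCellCycle(n0, gt, refParams)
        euler <- eulerCycle(n0, gt, refParams)
        expect_identical(adaptive$outcome, "divides")
        expect_equal(adaptive$tDiv, euler$tDiv, tolerance = 1e-3)
        expect_equal(adaptive$nDivision, euler$nDivision, tolerance = 1e-3)
    }
})

test_that("the generation map halves the copy number at division and flags
           non-dividing cells", {
    gt <- gtNoCncStable
    n1 <- generationMap(5, gt, refParams)
    full <- integrateCellCycle(5, gt, refParams)
    expect_equal(n1, full$nDivision / 2)
    # a cell started far beyond the death boundary never divides
    expect_true(is.na(generationMap(80, gt, refParams)))
    expect_identical(integrateCellCycle(80, gt, refParams)$outcome, "dies")
})

test_that("a low-alpha genotype under-replicates from every initial copy
           number", {
    gt <- gtNoCncUnder
    n0 <- seq(0.5, 30, length.out = 15)
    n1 <- generationMap(n0, gt, refParams)
    ok <- !is.na(n1)
    expect_true(any(ok))
    expect_true(all(n1[ok] < n0[ok]))
    # and the map has no fixed points
    expect_identical(nrow(equilibria(findEquilibria(gt, refParams))), 0L)
})

test_that("the generation map is continuous and robust to tighter ODE
           tolerance", {
    gt <- gtCncOpt
    n0 <- seq(1, 25, length.out = 40)
    n1 <- generationMap(n0, gt, refParams)
    expect_true(all(is.finite(n1)))
    # no jumps: successive differences comparable to grid spacing scale
    expect_lt(max(abs(diff(n1))), 5 * max(diff(n0)))
    # re-integration at 10x tighter tolerance reproduces the map
    n1tight <- vapply(n0, function(x)
        integrateCellCycle(x, gt, refParams, rtol = 1e-9,
                           atol = 1e-11)$nDivision / 2, numeric(1))
    expect_equal(n1, n1tight, tolerance = 1e-6)
})

test_that("a mid-stability genotype has one stable and one unstable fixed
           point with the over/under-replication sign structure", {
    eq <- equilibria(findEquilibria(gtNoCncStable, refParams))
    expect_identical(nrow(eq), 2L)
    expect_identical(sum(eq$stable), 1L)
    nStar <- eq$nStar[eq$stable]
    nUnst <- eq$nStar[!eq$stable]
    expect_lt(nStar, nUnst)
    # fixed-point property under independent re-integration
    for (r in eq$nStar)
        expect_equal(generationMap(r, gtNoCncStable, refParams), r,
                     tolerance = 1e-5)
    # below the stable root plasmids over-replicate, above they
    # under-replicate
    d <- 0.05 * nStar
    expect_gt(generationMap(nStar - d, gtNoCncStable, refParams), nStar - d)
    expect_lt(generationMap(nStar + d, gtNoCncStable, refParams), nStar + d)
})

test_that("roots from the bracketing grid match a fine-grid sign-change
           oracle", {
    gt <- gtNoCncStable
    eq <- equilibria(findEquilibria(gt, refParams, nGrid = 200L))
    # independent oracle: dense evaluation + sign changes + uniroot
    grid <- seq(0.5, 40, length.out = 400L)
    f <- generationMap(grid, gt, refParams) - grid
    roots <- c()
    for (i in seq_along(grid)[-1]) {
        if (is.na(f[i - 1]) || is.na(f[i])) next
        if (f[i - 1] * f[i] < 0)
            roots <- c(roots, uniroot(function(n)
                generationMap(n, gt, refParams) - n,
                c(grid[i - 1], grid[i]), tol = 1e-8)$root)
    }
    expect_equal(sort(eq$nStar), sort(roots), tolerance = 1e-5)
})

test_that("cell fitness is 1/T on the equilibrium cycle, with the plasmid-free
           closed form as reference", {
    # plasmid-free reference
    expect_equal(1 / integrateCellCycle(0, PlasmidGenotype(),
                                        refParams)$tDiv,
                 refParams@g0 / log(2), tolerance = 1e-8)
    f <- cellFitness(gtNoCncStable, refParams)
    eq <- equilibria(findEquilibria(gtNoCncStable, refParams))
    expect_equal(as.numeric(f), 1 / eq$tDiv[eq$stable], tolerance = 1e-6)
    # undefined (not zero) outside the stable region
    fBad <- cellFitness(gtNoCncOver, refParams)
    expect_true(is.na(fBad))
    expect_match(attr(fBad, "reason"), "no stable")
})

test_that("cell fitness is continuous in alpha within the stable region", {
    alphas <- seq(0.2, 0.4, length.out = 9)
    fits <- vapply(alphas, function(a)
        as.numeric(cellFitness(PlasmidGenotype(alpha = a), refParams)),
        numeric(1))
    expect_true(all(is.finite(fits)))
    expect_lt(max(abs(diff(fits))), 0.05)
    # passive control: fitness rises with alpha throughout the stable band
    expect_true(all(diff(fits) > 0))
})

test_that("the fold bifurcation separates two-root from zero-root regimes
           and moves out as policing strengthens", {
    ac <- edgeOfStability(0, 0, refParams, c(0.1, 0.8), tol = 1e-4)
    below <- equilibria(findEquilibria(PlasmidGenotype(alpha = ac - 0.02),
                                       refParams))
    above <- equilibria(findEquilibria(PlasmidGenotype(alpha = ac + 0.02),
                                       refParams))
    expect_identical(nrow(below), 2L)
    expect_identical(nrow(above), 0L)
    # near tangency the stable-branch slope approaches 1 from below
    expect_gt(attr(ac, "slopeBelow"), 0.8)
    expect_lt(attr(ac, "slopeBelow"), 1)
    # CNC widens the stability range
    acCnc <- edgeOfStability(0.6, 1.5, refParams, c(0.1, 3), tol = 1e-4)
    expect_gt(acCnc, ac + 0.2)
    expect_error(edgeOfStability(0, 0, refParams, c(0.01, 0.05)),
                 "under-replication")
})

test_that("homogeneous dynamics are symmetric under exchanging policing and
           obedience", {
    a <- PlasmidGenotype(alpha = 1.1, kappa = 1.8, beta = 0.45)
    b <- PlasmidGenotype(alpha = 1.1, kappa = 0.45, beta = 1.8)
    eqA <- equilibria(findEquilibria(a, refParams))
    eqB <- equilibria(findEquilibria(b, refParams))
    expect_equal(eqA, eqB, tolerance = 1e-7)
    n1a <- generationMap(c(2, 6, 12), a, refParams)
    n1b <- generationMap(c(2, 6, 12), b, refParams)
    expect_equal(n1a, n1b, tolerance = 1e-9)
})

test_that("the deterministic population-mean prediction exceeds nStar by the
           age-structure factor", {
    nb <- deterministicMeanCopyNumber(gtNoCncStable, refParams)
    nStar <- attr(nb, "nStar")
    # passive control replicates exponentially: closed form 2*ln2*nStar
    expect_equal(as.numeric(nb), 2 * log(2) * nStar, tolerance = 0.01)
    # undefined without a stable equilibrium
    expect_true(is.na(deterministicMeanCopyNumber(gtNoCncOver, refParams)))
})
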