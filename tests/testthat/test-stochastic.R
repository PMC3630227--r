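# Stochastic layer: per-cell update rules (reference R implementations) and
# the compiled multicellular engine.

test_that("a plasmid-free cell grows geometrically and divides on schedule", {
    p <- refParams
    cell <- hostCell(1, PlasmidGenotype(), n = 0L)
    g <- p@g0
    expected <- ceiling(log(2) / log1p(g * p@dt))
    ev <- evolutionParams(mu = 0)
    for (k in seq_len(expected)) {
        out <- stepCell(cell, p, ev)
        cell <- out$cell
    }
    expect_identical(out$event, "division")
    expect_equal(biomass(cell), (1 + g * p@dt)^expected)
})

test_that("without mutation every offspring plasmid is genotypically
           identical to its parent", {
    set.seed(1)
    cell <- hostCell(1, PlasmidGenotype(alpha = 1.7, kappa = 2, beta = 1),
                     n = 8L)
    for (k in 1:50) cell <- stepCell(cell, refParams,
                                     evolutionParams(mu = 0))$cell
    expect_gt(copyNumber(cell), 8L)   # some replication happened
    pm <- cell@plasmids
    expect_true(all(pm[, "alpha"] == 1.7))
    expect_true(all(pm[, "kappa"] == 2))
    expect_true(all(pm[, "beta"] == 1))
})

test_that("replication counts are Poisson with mean r*dt", {
    set.seed(2)
    p <- refParams
    gt <- PlasmidGenotype(alpha = 1.2, kappa = 2, beta = 0.8)
    draws <- 20000L
    # single-plasmid cell at fixed biomass: analytic per-step rate
    M <- 1.4
    I <- p@tau * 2 / (M * (1 + growthRate(1, 2, p) * p@dt))
    r <- replicationRate(gt, I)
    counts <- vapply(seq_len(draws), function(i) {
        cell <- new("HostCell", biomass = M,
                    plasmids = genotypeMatrix(gt, 1L))
        copyNumber(stepCell(cell, p, evolutionParams(mu = 0))$cell) - 1L
    }, integer(1))
    se <- sqrt(r * p@dt / draws)
    expect_lt(abs(mean(counts) - r * p@dt), 3 * se)
})

test_that("division conserves plasmids and biomass and flags segregational
           loss", {
    set.seed(3)
    # no plasmids: no loss event
    d0 <- divideCell(hostCell(2.1, PlasmidGenotype(), 0L))
    expect_false(d0$segLoss)
    expect_equal(copyNumber(d0$daughters[[1]]), 0L)
    for (k in 1:40) {
        n <- sample(1:12, 1)
        cell <- hostCell(2 + runif(1, 0, 0.05), randomStableGenotype(), n)
        d <- divideCell(cell)
        ns <- vapply(d$daughters, copyNumber, integer(1))
        expect_identical(sum(ns), n)
        expect_equal(sum(vapply(d$daughters, biomass, numeric(1))),
                     biomass(cell))
        expect_identical(d$segLoss, any(ns == 0L))
    }
})

test_that("the plasmid-free daughter frequency matches the binomial closed
           form", {
    set.seed(8)
    n <- 5L
    reps <- 40000L
    cell <- hostCell(2, PlasmidGenotype(alpha = 1), n)
    losses <- sum(vapply(seq_len(reps), function(i)
        divideCell(cell)$segLoss, logical(1)))
    pLoss <- 2 * 0.5^n
    se <- sqrt(pLoss * (1 - pLoss) / reps)
    expect_lt(abs(losses / reps - pLoss), 3 * se)
})

test_that("mutation perturbs exactly one free trait, uniformly chosen, and
           respects bounds", {
    set.seed(5)
    ev <- evolutionParams(mu = 1, step = 0.1)
    gt <- PlasmidGenotype(alpha = 1, kappa = 1, beta = 0.5)
    draws <- 30000L
    nChanged <- integer(draws)
    picks <- integer(3)
    for (k in seq_len(draws)) {
        m <- mutateGenotype(gt, ev)
        changed <- which(c(m@alpha != gt@alpha, m@kappa != gt@kappa,
                           m@beta != gt@beta))
        nChanged[k] <- length(changed)
        picks[changed] <- picks[changed] + 1L
    }
    expect_true(all(nChanged == 1L))
    se <- sqrt(1 / 3 * 2 / 3 / draws)
    expect_true(all(abs(picks / draws - 1 / 3) < 4 * se))
    # trait at its bound stays inside under repeated mutation
    atBound <- PlasmidGenotype(alpha = 2, kappa = 2, beta = 1)
    muts <- replicate(300, {
        m <- mutateGenotype(atBound, ev)
        c(m@alpha, m@kappa, m@beta)
    })
    expect_true(all(muts >= 0) &&
                all(muts <= c(2, 2, 1)))   # column recycling by trait
})

test_that("a frozen trait never mutates in restricted-evolution mode", {
    set.seed(6)
    ev <- evolutionParams(mu = 1, step = 0.1,
                          free = c(alpha = TRUE, kappa = FALSE, beta = TRUE))
    gt <- PlasmidGenotype(alpha = 1, kappa = 1.3, beta = 0.5)
    ks <- replicate(2000, policing(mutateGenotype(gt, ev)))
    expect_true(all(ks == 1.3))
    # engine route: evolve with kappa frozen, kappa stays put population-wide
    pop <- population(30, PlasmidGenotype(alpha = 0.35, kappa = 0.8,
                                          beta = 0.2), n = 4)
    res <- runSimulation(pop, refParams,
                         evolutionParams(mu = 0.05, step = 0.1, free = ev@free),
                         cap = 60, steps = 2000, recordEvery = 500)
    s <- observables(res)
    expect_true(all(abs(s$meanKappa - 0.8) < 1e-12, na.rm = TRUE))
})

test_that("population regulation is a neutral uniform cull", {
    pop <- population(10, PlasmidGenotype(), n = 0L)
    expect_identical(length(regulatePopulation(pop, 20)@cells), 10L)
    expect_identical(length(regulatePopulation(pop, 4)@cells), 4L)
    expect_error(regulatePopulation(population(list()), 5), "extinct")
    # neutrality: two labelled, dynamically identical subpopulations keep
    # expected frequency 1/2 under heavy regulation
    set.seed(7)
    gt1 <- PlasmidGenotype(alpha = 0.35, label = 1)
    gt0 <- PlasmidGenotype(alpha = 0.35, label = 0)
    freqs <- vapply(1:30, function(i) {
        cells <- c(replicate(50, hostCell(1, gt1, 3), simplify = FALSE),
                   replicate(50, hostCell(1, gt0, 3), simplify = FALSE))
        res <- runSimulation(population(cells), refParams,
                             evolutionParams(mu = 0), cap = 100,
                             steps = 400, recordEvery = 400)
        s <- observables(res)
        s$meanLabel[nrow(s)]
    }, numeric(1))
    se <- sd(freqs) / sqrt(length(freqs))
    expect_lt(abs(mean(freqs) - 0.5), 3 * se + 0.02)
})

test_that("identical seeds give bit-identical runs and mu=0 keeps traits
           exactly constant", {
    gt <- gtCncOpt
    run <- function() {
        set.seed(99)
        pop <- population(40, gt, n = 6)
        runSimulation(pop, refParams, evolutionParams(mu = 0), cap = 80,
                      steps = 1500, recordEvery = 100)
    }
    a <- run(); b <- run()
    expect_identical(counters(a), counters(b))
    expect_identical(observables(a), observables(b))
    s <- observables(a)
    expect_true(all(abs(s$meanAlpha - selfishness(gt)) < 1e-12, na.rm = TRUE))
    expect_true(all(s$withinSdBeta == 0, na.rm = TRUE))
})

test_that("homogeneous stochastic trajectories are invariant under the
           policing/obedience exchange", {
    mk <- function(kappa, beta) {
        set.seed(123)
        pop <- population(40, PlasmidGenotype(alpha = 1.1, kappa = kappa,
                                              beta = beta), n = 5)
        runSimulation(pop, refParams, evolutionParams(mu = 0), cap = 80,
                      steps = 2000, recordEvery = 200)
    }
    a <- mk(1.8, 0.45); b <- mk(0.45, 1.8)
    expect_identical(counters(a), counters(b))
    expect_identical(observables(a)$meanN, observables(b)$meanN)
})

test_that("the compiled engine and the R reference update agree on the
           one-step offspring distribution", {
    p <- refParams
    gt <- PlasmidGenotype(alpha = 1.5, kappa = 2, beta = 0.7)
    nCells <- 400L
    engineDraw <- function() {
        pop <- population(nCells, gt, n = 3L)
        res <- runSimulation(pop, p, evolutionParams(mu = 0), cap = 10000L,
                             steps = 1L, recordEvery = 1L)
        copyNumber(res@finalPopulation) - 3L
    }
    refDraw <- function() {
        vapply(seq_len(nCells), function(i) {
            out <- stepCell(hostCell(1, gt, 3L), p, evolutionParams(mu = 0))
            copyNumber(out$cell) - 3L
        }, integer(1))
    }
    set.seed(11); eng <- c(engineDraw(), engineDraw(), engineDraw())
    set.seed(12); ref <- c(refDraw(), refDraw(), refDraw())
    # equal Poisson means within Monte-Carlo error
    seDiff <- sqrt(var(eng) / length(eng) + var(ref) / length(ref))
    expect_lt(abs(mean(eng) - mean(ref)), 4 * seDiff)
})

test_that("engine counters respect the segregational-loss bound and
           monotonicity", {
    set.seed(13)
    pop <- population(100, gtNoCncStable, n = 3)
    res <- runSimulation(pop, refParams, evolutionParams(mu = 0), cap = 200,
                         steps = 4000, recordEvery = 200)
    ct <- counters(res)
    expect_lte(ct[["segLosses"]], ct[["divisionsInfected"]])
    expect_lte(ct[["divisionsInfected"]], ct[["divisions"]])
    s <- observables(res)
    expect_true(all(s$divisions >= 0))
    expect_equal(sum(s$divisions), ct[["divisions"]])
})

test_that("variance decomposition matches a direct two-level computation", {
    # degenerate cases
    popHom <- population(5, PlasmidGenotype(alpha = 1, kappa = 0.5,
                                            beta = 0.2), n = 3)
    vd <- varianceDecomposition(popHom)
    expect_true(all(vd$within == 0) && all(vd$between == 0))
    cells <- list(hostCell(1, PlasmidGenotype(alpha = 0.5), 4L),
                  hostCell(1, PlasmidGenotype(alpha = 1.5), 4L))
    vd2 <- varianceDecomposition(population(cells))
    expect_equal(vd2$within[vd2$trait == "alpha"], 0)
    expect_equal(vd2$between[vd2$trait == "alpha"], 0.5)
    expect_error(varianceDecomposition(population(3, n = 0L)), "no infected")
    # random population vs independent summation oracle
    set.seed(14)
    cells <- lapply(1:12, function(i)
        hostCell(1, genotypeMatrix(replicate(sample(1:6, 1),
            PlasmidGenotype(runif(1, 0, 2), runif(1, 0, 2), runif(1)),
            simplify = FALSE)))
    )
    pop <- population(cells)
    vd3 <- varianceDecomposition(pop)
    for (tr in c("alpha", "kappa", "beta")) {
        vals <- lapply(pop@cells, function(cl) cl@plasmids[, tr])
        expect_equal(vd3$within[vd3$trait == tr],
                     mean(vapply(vals, popSd, numeric(1))))
        expect_equal(vd3$between[vd3$trait == tr],
                     popSd(vapply(vals, mean, numeric(1))))
    }
})

test_that("extinction terminates the run with a truncated series", {
    set.seed(15)
    # far over-replicating genotype: every infected cell dies
    pop <- population(30, PlasmidGenotype(alpha = 2), n = 20)
    res <- runSimulation(pop, refParams, evolutionParams(mu = 0), cap = 60,
                         steps = 5000, recordEvery = 100)
    expect_true(res@terminated)
    expect_identical(length(res@finalPopulation@cells), 0L)
    expect_lt(max(observables(res)$time), 5000 * refParams@dt)
})
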