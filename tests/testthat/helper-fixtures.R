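# Shared fixtures: the package's reference study conditions and a few
# genotypes sitting in known dynamical regimes (located with the
# deterministic layer; see the methods vignette for the regime map).

refParams <- cellParams()                         # g0 .1, B .5, s .2, c .01

gtNoCncStable <- PlasmidGenotype(alpha = 0.35)    # passive control, n* ~ 3.2
gtNoCncUnder <- PlasmidGenotype(alpha = 0.08)     # below g0: always dilutes
gtNoCncOver <- PlasmidGenotype(alpha = 0.9)       # far beyond the fold
gtCncOpt <- PlasmidGenotype(alpha = 1.7, kappa = 2, beta = 1)  # CNC optimum

# random genotypes drawn from the deterministically stable region:
# passive-control alpha plus enough policing/obedience to stay stable
randomStableGenotype <- function() {
    beta <- runif(1, 0.6, 1)
    kappa <- runif(1, 1, 2)
    # keep alpha between the regimes: lower edge ~g0's basin, upper edge
    # grows with beta*kappa; conservative interior band
    alpha <- runif(1, 0.45, 0.45 + 0.8 * beta * kappa)
    PlasmidGenotype(alpha = alpha, kappa = kappa, beta = beta)
}

# population-moment helpers used by oracles
popSd <- function(x) sqrt(mean((x - mean(x))^2))
popSkew <- function(x) {
    m2 <- mean((x - mean(x))^2)
    mean((x - mean(x))^3) / m2^1.5
}
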