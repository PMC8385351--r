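test_that("a closed two-species system relaxes to its analytic equilibrium", {
    net <- abNetwork(KA = 2, KB = 1, kappa = 1)
    net <- setAmounts(net, c(A = 1.2, B = 0.8))
    tr <- simulateNetwork(net, tEnd = 50, untilSteady = TRUE)
    expect_true(tr@steady)
    n <- length(tr@time)
    total <- 2.0
    # equilibrium: KA xA = KB xB with the total amount conserved
    expect_equal(unname(tr@x[n, "A"]), total * 1 / (2 + 1),
                 tolerance = 1e-7)
    expect_equal(unname(tr@x[n, "B"]), total * 2 / (2 + 1),
                 tolerance = 1e-7)
    expect_equal(unname(rowSums(tr@x)), rep(total, n), tolerance = 1e-8)
})

test_that("closed networks reach detailed balance with all flows vanishing", {
    for (seed in 1:3) {
        net <- randomNetwork(4, 5, maxCoeff = 2, seed = seed)
        net <- setSpeciesConstants(net, stats::setNames(
            runif(4, 0.3, 3), speciesIds(net)))
        net <- setMassAction(net, stats::setNames(
            runif(5, 0.3, 2), reactionIds(net)))
        net <- setAmounts(net, stats::setNames(runif(4, 0.5, 2),
                                               speciesIds(net)))
        tr <- simulateNetwork(net, tEnd = 100, untilSteady = TRUE,
                              tMax = 1e6)
        n <- length(tr@time)
        expect_true(tr@steady)
        expect_lt(max(abs(tr@f[n, ])), 1e-6)
    }
})

test_that("chemostats hold amounts and flowstats hold flows", {
    par <- glypppParameterized()
    chem <- c(G6P = 2, ATP = 1.5, ADP = 1, H = 1)
    tr <- simulateNetwork(par$network, chemostats = chem,
                          flowstats = "GAPD", tEnd = 5, nGrid = 50)
    for (s in names(chem))
        expect_equal(unname(tr@x[, s]), rep(chem[[s]], 51))
    expect_equal(unname(tr@f[, "GAPD"]), rep(0, 51))
    # a nonzero flowstat is held too
    tr2 <- simulateNetwork(par$network, chemostats = chem,
                           flowstats = c(GAPD = 0.25), tEnd = 1, nGrid = 10)
    expect_equal(unname(tr2@f[, "GAPD"]), rep(0.25, 11))
    expect_error(simulateNetwork(par$network, flowstats = "NOPE"),
                 "unknown flowstat")
})

test_that("missing rate parameters are reported by reaction id", {
    net <- stoichiometricNetwork(list(rr = c(A = -1, B = 1)))
    net <- setSpeciesConstants(net, c(A = 1, B = 1))
    expect_error(simulateNetwork(net, tEnd = 1), "rr")
    net2 <- stoichiometricNetwork(list(rr = c(A = -1, B = 1)))
    expect_error(reactionFlows(setMassAction(net2, c(rr = 1))), "A")
})

test_that("steady-state chemostat-flow ratios equal pathway stoichiometry", {
    par <- glypppParameterized()
    net <- par$network
    base <- baseChemostats(par$presets, net)
    chem <- stats::setNames(rep(1, length(base)), base)
    chem["G6P"] <- 5; chem["NADP"] <- 3
    chem["NADPH"] <- 0.2; chem["H"] <- 0.5

    # pathway iii (NADPH generation): NADPH:G6P = 12, no R5P export
    tr3 <- simulateNetwork(net, chemostats = chem, flowstats = "GAPD",
                           tEnd = 100, untilSteady = TRUE, tMax = 1e6)
    n <- length(tr3@time)
    expect_true(tr3@steady)
    expect_equal(fluxRatios(tr3, "NADPH", "G6P")[n], 12, tolerance = 1e-6)
    expect_lt(abs(tr3@exchange[n, "R5P"] / tr3@exchange[n, "G6P"]), 1e-6)

    # pathway i (R5P + NADPH generation): ratios 1 and 2
    chem1 <- c(chem, R5P = 0.2)
    tr1 <- simulateNetwork(net, chemostats = chem1,
                           flowstats = c("PGI", "TKT2"),
                           tEnd = 100, untilSteady = TRUE, tMax = 1e6)
    n1 <- length(tr1@time)
    expect_equal(fluxRatios(tr1, "R5P", "G6P")[n1], 1, tolerance = 1e-6)
    expect_equal(fluxRatios(tr1, "NADPH", "G6P")[n1], 2, tolerance = 1e-6)

    # pathway ii (R5P generation): |R5P:G6P| = 6/5
    tr2 <- simulateNetwork(net, chemostats = chem1,
                           flowstats = c("GAPD", "G6PDH2R"),
                           tEnd = 100, untilSteady = TRUE, tMax = 1e6)
    n2 <- length(tr2@time)
    expect_equal(fluxRatios(tr2, "R5P", "G6P")[n2], 6 / 5,
                 tolerance = 1e-6)
    # identical numerator and denominator
    expect_equal(fluxRatios(tr2, "G6P", "G6P")[n2], 1)

    # the steady-state flux vector lies in span(Kp)
    pd <- decomposePathways(net, chemostats = names(chem),
                            flowstats = "GAPD")
    fss <- tr3@f[n, ]
    proj <- estimatePathwayFlows(pd@Kp, fss)
    expect_lt(sqrt(sum((fss - proj$fhat)^2)) / sqrt(sum(fss^2)), 1e-4)
})

test_that("energy audits close and dissipation is nonnegative", {
    # closed system: internal residual at floating tolerance
    net <- abNetwork(KA = 2, KB = 1)
    net <- setAmounts(net, c(A = 1.2, B = 0.8))
    tr <- simulateNetwork(net, tEnd = 20, nGrid = 100)
    au <- energyAudit(tr, net)
    expect_lt(max(abs(au$internal)), 1e-8)
    expect_equal(au$boundary, rep(0, 101))

    # open system: internal balance equals minus the boundary power
    chain <- stoichiometricNetwork(list(r1 = c(A = -1, B = 1),
                                        r2 = c(B = -1, C = 1)))
    chain <- setSpeciesConstants(chain, c(A = 4, B = 1, C = 0.25))
    chain <- setMassAction(chain, c(r1 = 1, r2 = 1))
    tro <- simulateNetwork(chain, chemostats = c(A = 1, C = 1), tEnd = 30,
                           untilSteady = TRUE)
    auo <- energyAudit(tro, chain)
    expect_equal(auo$internal, -auo$boundary, tolerance = 1e-10)
    expect_gt(max(abs(auo$boundary)), 0)

    # second law: total dissipation Phi' f >= 0 along every trajectory
    diss <- rowSums(tro@Phi * tro@f)
    expect_true(all(diss >= -1e-12))
    # all flows zero -> zero residual
    eq <- simulateNetwork(setAmounts(abNetwork(KA = 1, KB = 1),
                                     c(A = 1, B = 1)), tEnd = 1)
    expect_lt(max(abs(energyAudit(eq, net)$internal)), 1e-14)
})

test_that("mass-action and Michaelis-Menten reach the same steady state", {
    # lumped MM rate law vs the expanded two-step mass-action module,
    # simulated on a driven two-reaction chain
    fmax <- 1.5; rho <- 0.3; KC <- 0.8; KE <- 1.2; e0 <- 1
    ma <- mmToMassAction(fmax, rho, KC, e0)

    lumped <- stoichiometricNetwork(list(rx = c(A = -1, B = 1),
                                         out = c(B = -1, C = 1)))
    lumped <- setSpeciesConstants(lumped, c(A = 5, B = 1, C = 0.2))
    lumped <- setMassAction(lumped, c(out = 0.7))
    # Kf of the lumped law equals KC/KE of the expanded module
    lumped <- setMichaelisMenten(lumped, fmax = c(rx = fmax),
                                 Kf = c(rx = KC / KE),
                                 rho = c(rx = rho))
    trL <- simulateNetwork(lumped, chemostats = c(A = 1, C = 1),
                           tEnd = 200, untilSteady = TRUE, tMax = 1e6)

    expanded <- stoichiometricNetwork(list(rx = c(A = -1, B = 1),
                                           out = c(B = -1, C = 1)))
    expanded <- setSpeciesConstants(expanded, c(A = 5, B = 1, C = 0.2))
    expanded <- setMassAction(expanded, c(rx = 1, out = 0.7))
    expanded <- expandEnzyme(expanded, "rx", KC = KC, KE = KE, e0 = e0,
                             kappa1 = ma$kappa1, kappa2 = ma$kappa2)
    trE <- simulateNetwork(expanded, chemostats = c(A = 1, C = 1),
                           tEnd = 200, untilSteady = TRUE, tMax = 1e6)

    nL <- length(trL@time); nE <- length(trE@time)
    expect_true(trL@steady && trE@steady)
    expect_equal(unname(trE@f[nE, "out"]), unname(trL@f[nL, "out"]),
                 tolerance = 1e-6)
    expect_equal(unname(trE@x[nE, "B"]), unname(trL@x[nL, "B"]),
                 tolerance = 1e-5)
})
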