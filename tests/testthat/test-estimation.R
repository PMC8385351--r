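test_that("reactions partition into known/unknown column blocks", {
    N <- stoichMatrix(makeFixture("glycolysis_ppp")$network)
    mask <- !(colnames(N) %in% c("G6PDH2R", "PGL"))
    part <- partitionReactions(N, mask)
    expect_equal(ncol(part$N0), 11)
    expect_equal(colnames(part$N1), c("G6PDH2R", "PGL"))
    expect_equal(cbind(part$N0, part$N1)[, colnames(N)], N)

    all.known <- partitionReactions(N, rep(TRUE, ncol(N)))
    expect_equal(ncol(all.known$N1), 0)
    none <- partitionReactions(N, rep(FALSE, ncol(N)))
    expect_equal(ncol(none$N0), 0)
    expect_error(estimatePotentials(none$N0, none$N1, numeric(0)),
                 "impossible")
    expect_error(partitionReactions(N, TRUE), "length")
})

test_that("potential QP reproduces consistent measurements", {
    set.seed(11)
    net <- makeFixture("tca")$network
    N <- stoichMatrix(net)
    phiTrue <- rnorm(nrow(N), sd = 30)
    Phi <- reactionPotentials(N, phiTrue)$Phi
    part <- partitionReactions(N, rep(TRUE, ncol(N)))
    pe <- estimatePotentials(part$N0, part$N1, Phi, lambda = 1e-10,
                             delta = 0)
    expect_lt(max(abs(pe@Phi0hat - Phi)), 1e-6)
    expect_lt(pe@kkt, 1e-8)

    # N1 empty, square invertible N0, lambda = 0: exact inverse
    N0 <- matrix(c(-1, 1, 0, -1, 2, -1, 0, 0, 1), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("r1", "r2", "r3")))
    Phi0 <- c(5, -3, 8)
    pe2 <- estimatePotentials(N0, N0[, 0], Phi0, lambda = 0, delta = 0)
    expect_equal(unname(pe2@phi), unname(drop(-solve(t(N0)) %*% Phi0)))
})

test_that("sign constraints activate for infeasible unknown potentials", {
    # A -r1-> B (known, Phi = 10), B -r2-> C with C touched only by the
    # unknown reaction: unconstrained minimum-norm estimation would give a
    # negative potential for r2; the QP pushes it onto the delta bound
    # without degrading the fit of the known reaction.
    N <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
                dimnames = list(c("A", "B", "C"), c("r1", "r2")))
    pe <- estimatePotentials(N[, 1, drop = FALSE], N[, 2, drop = FALSE],
                             Phi0 = 10, lambda = 1e-6, delta = 1)
    expect_equal(unname(pe@Phi0hat), 10, tolerance = 1e-4)
    expect_true(pe@active["r2"])
    expect_equal(unname(pe@Phi1hat["r2"]), 1, tolerance = 1e-6)
    # without the constraint the estimate would indeed be negative
    peFree <- estimatePotentials(N[, 1, drop = FALSE],
                                 N[, 2, drop = FALSE][, 0, drop = FALSE],
                                 Phi0 = 10, lambda = 1e-6, delta = 0)
    PhiFree <- reactionPotentials(N, peFree@phi)$Phi
    expect_lt(PhiFree["r2"], 0)
})

test_that("pathway flows solve the measured-row least squares", {
    fx <- makeFixture("glycolysis_ppp")
    pd <- decomposePathways(fx$network,
                            chemostats = fx$presets$estimation_chemostats)
    Kp <- pd@Kp
    fpTrue <- c(2, 0.7, 0.3)
    f <- drop(Kp %*% fpTrue)
    names(f) <- rownames(Kp)

    est <- estimatePathwayFlows(Kp, f)
    expect_equal(unname(est$fp), fpTrue)
    expect_equal(est$fhat, f)

    # noisy fluxes: explicit normal-equations solution, orthogonal residual
    set.seed(12)
    fn <- f + rnorm(length(f), sd = 0.05)
    est2 <- estimatePathwayFlows(Kp, fn)
    expect_equal(est2$fp, drop(solve(crossprod(Kp), crossprod(Kp, fn))))
    expect_equal(drop(crossprod(Kp, fn - est2$fhat)), rep(0, 3),
                 tolerance = 1e-10)

    # deleting one measured flow still recovers the three pathway flows
    fm <- f
    fm["TKT1"] <- NA
    est3 <- estimatePathwayFlows(Kp, fm, N = stoichMatrix(fx$network))
    expect_equal(unname(est3$fp), fpTrue)
    expect_equal(est3$fhat[["TKT1"]], f[["TKT1"]])
    # chemostat flows are reported via N fhat
    expect_equal(est3$exchange,
                 speciesRate(stoichMatrix(fx$network), est3$fhat))

    # rank deficiency after deletion is an error
    half <- f
    half[rowSums(Kp != 0) > 0] <- NA
    expect_error(estimatePathwayFlows(Kp, half), "unidentifiable")
})

test_that("mass-action constants follow kappa = f / f0", {
    pN <- thermalPotential()
    Nf <- matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "r1"))
    Nr <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), "r1"))
    phi <- c(pN * log(2), 0)
    tab <- estimateKappa(1, phi, Nf, Nr)
    expect_equal(tab$f0, 1)
    expect_equal(tab$kappa, 1)
    # definitional round trip through the rate law
    expect_equal(reFlowMassAction(tab$kappa, pN * log(2), 0), 1)

    # equilibrium reactions are flagged, not divided by zero
    tab0 <- estimateKappa(0, c(0, 0), Nf, Nr)
    expect_false(tab0$identifiable)
    expect_true(is.na(tab0$kappa))
})

test_that("Michaelis-Menten estimation recovers the truth", {
    pN <- thermalPotential()
    fmax <- 2; Kf <- 0.3; rho <- 0.35
    Phif <- c(30, 55, 12, 70)
    Phir <- c(5, 20, -10, 40)
    f <- reFlowMM(fmax, Kf, rho, Phif, Phir)
    f0p <- exp(Phif / pN); f0m <- exp(Phir / pN)

    # the linear-in-parameters form is an identity on exact data
    fit <- estimateMMParams(f, f0p, f0m, lambda = 1e-12)
    expect_equal(fit$fmax, fmax, tolerance = 1e-6)
    expect_equal(fit$rho, rho, tolerance = 1e-6)
    expect_equal(fit$Kf, Kf, tolerance = 1e-6)
    expect_lt(max(abs(fit$residual)), 1e-8)
    expect_equal(drop(fit$X %*% c(fmax, rho, Kf)), fit$y)

    # single steady state with Kf and rho fixed by equality constraints
    Aec <- rbind(c(0, 1, 0), c(0, 0, 1))
    fit1 <- estimateMMParams(f[1], f0p[1], f0m[1], Aec = Aec,
                             bec = c(rho, Kf), lambda = 1e-12)
    expect_equal(fit1$fmax, fmax, tolerance = 1e-6)

    # fewer than three states without constraints is rejected
    expect_error(estimateMMParams(f[1:2], f0p[1:2], f0m[1:2]),
                 "three steady states")

    # truth near the positivity boundary stays positive
    fb <- reFlowMM(1, 0.2, 1e-3, Phif, Phir)
    fitb <- estimateMMParams(fb, f0p, f0m, lambda = 1e-12)
    expect_gt(fitb$rho, 0)
    expect_gt(fitb$fmax, 0)
    expect_gt(fitb$Kf, 0)
})

test_that("species constants reproduce potentials at the measured state", {
    expect_equal(unname(dynamicalConstants(c(A = 0), c(A = 1))), 1)
    pN <- thermalPotential()
    expect_equal(unname(dynamicalConstants(c(A = pN), c(A = 1))), exp(1))
    phi <- c(A = -12.4, B = 31, C = 4)
    conc <- c(A = 0.3, B = 2.5, C = NA)
    K <- dynamicalConstants(phi, conc)
    expect_true(is.na(K["C"]))
    expect_equal(cePotential(K[c("A", "B")], conc[c("A", "B")]),
                 phi[c("A", "B")], ignore_attr = TRUE)
    expect_error(dynamicalConstants(c(A = 1), c(A = -1)), "positive")
})

test_that("normalization uses the reference concentration and flow", {
    cRaw <- c(G6P = 7.88, F6P = 2.1)
    fRaw <- c(PGI = 59.52, PFK = 30)   # mM/min
    nz <- normalizeData(cRaw, fRaw, "G6P", "PGI")
    expect_equal(nz$c0, 7.88)
    expect_equal(nz$f0, 0.992)
    expect_equal(nz$t0, 7.88 / 0.992)
    expect_equal(unname(nz$c["G6P"]), 1)
    expect_equal(unname(nz$f["PGI"]), 1)
    # un-normalizing recovers the raw data
    expect_equal(nz$c * nz$c0, cRaw)
    expect_equal(nz$f * nz$f0 * 60, fRaw)
    expect_error(normalizeData(cRaw, fRaw, "XYZ", "PGI"), "XYZ")
})

test_that("pipeline recovers kappa and K exactly on an identifiable network", {
    # three reactions over three species give N' full column rank, so the
    # potential QP pins down phi itself and kappa/K are fully identifiable
    net <- stoichiometricNetwork(list(r1 = c(A = -1, B = 1),
                                      r2 = c(A = -1, B = 2),
                                      r3 = c(B = -1, C = 1)))
    Ktrue <- c(A = 3, B = 1, C = 0.5)
    kapTrue <- c(r1 = 0.8, r2 = 1.3, r3 = 2)
    gd <- generateDataset(net, Ktrue, kapTrue, chemostats = c(A = 2, C = 1),
                          noiseSd = 0, seed = 3)
    ps <- estimateParameters(net, gd$data, chemostats = c("A", "C"),
                             lambda = 1e-10, delta = 0)
    expect_lt(max(abs(ps@kappa - kapTrue) / kapTrue), 1e-6)
    expect_lt(max(abs(ps@K - Ktrue) / Ktrue), 1e-6)
})

test_that("estimated parameters reproduce the steady state and improve with less noise", {
    par <- glypppParameterized()
    net <- par$network
    chem <- par$presets$estimation_chemostats
    chemAmt <- stats::setNames(rep(1, length(chem)), chem)
    kapTrue <- stats::setNames(net@reactions$kappa, reactionIds(net))

    fluxError <- function(noiseSd, seed) {
        gd <- generateDataset(net, par$K, kapTrue, chemostats = chemAmt,
                              noiseSd = noiseSd, seed = seed)
        ps <- estimateParameters(net, gd$data, chemostats = chem,
                                 lambda = 1e-10, delta = 0)
        ok <- !is.na(ps@kappa)
        m <- setSpeciesConstants(net, ps@K)
        m <- setMassAction(m, ps@kappa[ok])
        m <- setAmounts(m, gd$data@c)
        m@reactions$flowstat[!ok] <- TRUE   # equilibrium reactions: no flow
        max(abs(reactionFlows(m) - gd$truth$f)) / max(abs(gd$truth$f))
    }

    # noiseless: the estimated (kappa, K) reproduce the steady-state fluxes
    expect_lt(fluxError(0, 1), 1e-4)

    # thermodynamic safety: every emitted parameter is positive
    gd <- generateDataset(net, par$K, kapTrue, chemostats = chemAmt,
                          noiseSd = 0.05, seed = 2)
    ps <- estimateParameters(net, gd$data, chemostats = chem, delta = 0)
    expect_true(all(ps@kappa[!is.na(ps@kappa)] > 0))
    expect_true(all(ps@K[!is.na(ps@K)] > 0))

    # bias decreases as the noise shrinks (averaged over seeds)
    seeds <- 1:3
    errs <- vapply(c(0.1, 0.02, 0),
                   function(sd) mean(vapply(seeds, function(s)
                       fluxError(sd, s), numeric(1))), numeric(1))
    expect_true(all(diff(errs) < 0))
})

test_that("unknown-potential partition matches the measurement campaign shape", {
    par <- glypppParameterized()
    net <- par$network
    chem <- par$presets$estimation_chemostats
    kapTrue <- stats::setNames(net@reactions$kappa, reactionIds(net))
    gd <- generateDataset(net, par$K, kapTrue,
                          chemostats = stats::setNames(rep(1, length(chem)),
                                                       chem),
                          unknownPhi = c("G6PDH2R", "PGL"), seed = 5)
    expect_true(all(is.na(gd$data@Phi[c("G6PDH2R", "PGL")])))
    expect_equal(sum(is.na(gd$data@Phi)), 2)
    # estimation still runs, with the unknown potentials bounded below
    ps <- estimateParameters(net, gd$data, chemostats = chem,
                             delta = 1e-3)
    expect_true(all(!is.na(ps@kappa[c("PGI", "PFK", "GND")])))
})
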