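# Small networks and parameterized fixtures shared across test files.

# A <-> B with chosen constants
abNetwork <- function(KA = 2, KB = 1, kappa = 1) {
    net <- stoichiometricNetwork(list(r1 = c(A = -1, B = 1)))
    net <- setSpeciesConstants(net, c(A = KA, B = KB))
    setMassAction(net, c(r1 = kappa))
}

# closed 3-species loop A -> B -> C -> A
cycleNetwork <- function() {
    stoichiometricNetwork(list(r1 = c(A = -1, B = 1),
                               r2 = c(B = -1, C = 1),
                               r3 = c(C = -1, A = 1)))
}

# glycolysis + pentose phosphate fixture with generic driving parameters:
# G6P/ATP/NADP held at high potential, products low, so flux runs forward
glypppParameterized <- function() {
    fx <- makeFixture("glycolysis_ppp")
    net <- fx$network
    sid <- speciesIds(net)
    K <- stats::setNames(rep(1, length(sid)), sid)
    K[c("G6P", "ATP", "NADP")] <- c(6, 4, 3)
    K[c("NADPH", "R5P", "G3P", "ADP")] <- c(0.3, 0.5, 0.4, 0.5)
    net <- setSpeciesConstants(net, K)
    net <- setMassAction(net, stats::setNames(
        seq(0.5, 1.7, length.out = nReactions(net)), reactionIds(net)))
    list(network = net, presets = fx$presets, K = K)
}

baseChemostats <- function(fx, net) {
    intersect(fx$base_chemostats, speciesIds(net))
}

# do two integer matrices span the same column space?
sameSpan <- function(A, B, tol = 1e-9) {
    qr(A, tol = tol)$rank == qr(B, tol = tol)$rank &&
        qr(cbind(A, B), tol = tol)$rank == qr(A, tol = tol)$rank
}

# net pathway reaction string for the single pathway of a configuration,
# oriented so that `orientTo` is consumed
renderSinglePathway <- function(net, chemostats, flowstats, orientTo) {
    pd <- decomposePathways(net, chemostats = chemostats,
                            flowstats = flowstats)
    stopifnot(ncol(pd@Kp) == 1)
    np <- pd@Np[, 1]
    if (np[orientTo] > 0) np <- -np
    renderPathway(np)
}
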