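#' Constitutive law of an energy-storing species component
#'
#' \eqn{\phi = \phi_N \ln(K x)}: the potential of a species with constant
#' `K` at amount `x`.
#'
#' @param K species constant (> 0).
#' @param x species amount (> 0).
#' @param temperature kelvin, passed to [thermalPotential()].
#' @return potential in mV.
#' @examples
#' cePotential(1, exp(1))  # one thermal potential, ~26.7 mV
#' @export
cePotential <- function(K, x, temperature = 310) {
    stopifnot(all(K > 0))
    if (any(x <= 0))
        stop("species amount must be positive to evaluate a potential")
    thermalPotential(temperature) * log(K * x)
}

#' Species constant from a reference potential
#'
#' \eqn{K = \exp(\phi^\circ/\phi_N) / x^\circ}: inverts [cePotential()] at
#' the reference state, so `cePotential(K, xref) == phiref`.
#'
#' @param phiref reference potential (mV).
#' @param xref reference amount (> 0).
#' @inheritParams cePotential
#' @return species constant `K` (> 0 by construction).
#' @export
speciesConstant <- function(phiref, xref, temperature = 310) {
    if (any(xref <= 0)) stop("reference amount must be positive")
    exp(phiref / thermalPotential(temperature)) / xref
}

#' Reaction flow: mass action (Marcelin-de Donder)
#'
#' \eqn{f = \kappa (e^{\Phi^f/\phi_N} - e^{\Phi^r/\phi_N})}. The flow
#' always has the sign of \eqn{\Phi = \Phi^f - \Phi^r}, so the dissipation
#' \eqn{f \Phi \ge 0} holds for any positive \eqn{\kappa}.
#'
#' @param kappa reaction constant (> 0).
#' @param Phif,Phir forward and reverse reaction potentials (mV).
#' @inheritParams cePotential
#' @return reaction flow.
#' @export
reFlowMassAction <- function(kappa, Phif, Phir, temperature = 310) {
    stopifnot(all(kappa > 0))
    pN <- thermalPotential(temperature)
    kappa * (exp(Phif / pN) - exp(Phir / pN))
}

#' Reaction flow: reversible Michaelis-Menten
#'
#' Same Marcelin-de Donder form with a state-dependent
#' \eqn{\kappa = f_{max} / (K_f + (1-\rho) e^{\Phi^f/\phi_N} +
#' \rho e^{\Phi^r/\phi_N})}; the flow keeps the sign of
#' \eqn{\Phi^f - \Phi^r} and saturates at \eqn{f_{max}/(1-\rho)}.
#'
#' @param fmax,Kf positive rate-law constants; `rho` in (0, 1).
#' @param rho kinetic asymmetry parameter.
#' @inheritParams reFlowMassAction
#' @return reaction flow.
#' @export
reFlowMM <- function(fmax, Kf, rho, Phif, Phir, temperature = 310) {
    stopifnot(all(fmax > 0), all(Kf > 0), all(rho > 0), all(rho < 1))
    pN <- thermalPotential(temperature)
    ef <- exp(Phif / pN)
    er <- exp(Phir / pN)
    fmax / (Kf + (1 - rho) * ef + rho * er) * (ef - er)
}

#' Map Michaelis-Menten constants to the two-step mass-action pair
#'
#' The enzyme-catalysed reaction `A + E <-> C`, `C <-> B + E` with
#' mass-action constants \eqn{\kappa_1, \kappa_2} has, at steady state of
#' the enzyme cycle, exactly the reversible Michaelis-Menten flow with
#' \eqn{f_{max} = e_0 K_C \kappa_1\kappa_2/(\kappa_1+\kappa_2)},
#' \eqn{\rho = \kappa_2/(\kappa_1+\kappa_2)} and \eqn{K_f = K_C/K_E}.
#' `mmToMassAction()` inverts this:
#' \eqn{\bar\kappa = f_{max}/(K_C e_0)}, \eqn{\kappa_1 = \bar\kappa/\rho},
#' \eqn{\kappa_2 = \bar\kappa/(1-\rho)}.
#'
#' @param fmax,rho Michaelis-Menten constants (`rho` strictly inside
#'   (0, 1)).
#' @param KC complex species constant.
#' @param e0 total enzyme amount.
#' @return list with `kbar`, `kappa1`, `kappa2`.
#' @examples
#' mmToMassAction(1, 0.5, 1, 1)  # kappa1 = kappa2 = 2
#' @export
mmToMassAction <- function(fmax, rho, KC, e0) {
    stopifnot(all(fmax > 0), all(KC > 0), all(e0 > 0))
    if (any(rho <= 0) || any(rho >= 1))
        stop("rho must lie strictly between 0 and 1")
    kbar <- fmax / (KC * e0)
    list(kbar = kbar, kappa1 = kbar / rho, kappa2 = kbar / (1 - rho))
}

#' @rdname mmToMassAction
#' @param kappa1,kappa2 two-step mass-action constants.
#' @param KE enzyme species constant.
#' @return `massActionToMM()`: list with `fmax`, `rho`, `Kf`.
#' @export
massActionToMM <- function(kappa1, kappa2, KC, KE, e0) {
    stopifnot(all(kappa1 > 0), all(kappa2 > 0), all(KC > 0), all(KE > 0),
              all(e0 > 0))
    list(fmax = e0 * KC * kappa1 * kappa2 / (kappa1 + kappa2),
         rho = kappa2 / (kappa1 + kappa2),
         Kf = KC / KE)
}

#' Expand a reaction into its two-step enzyme module
#'
#' Replaces the single reaction with the pair `substrates + E <-> C`,
#' `C <-> products + E`, introducing the enzyme species `<rxn>_E` (constant
#' `KE`, initial amount `e0`) and the complex `<rxn>_C` (constant `KC`,
#' initial amounts splitting `e0` almost entirely onto the free enzyme so
#' that every potential is defined at t = 0; the closed enzyme cycle
#' conserves
#' `x_E + x_C = e0`). The two reactions are named `<rxn>_1`, `<rxn>_2`
#' with mass-action constants `kappa1`, `kappa2`.
#'
#' @param net a [StoichiometricNetwork-class].
#' @param reaction reaction id to expand.
#' @param KC,KE,e0,kappa1,kappa2 positive enzyme-module constants.
#' @return The expanded network (species constants of the original species
#'   are preserved).
#' @export
expandEnzyme <- function(net, reaction, KC, KE, e0, kappa1, kappa2) {
    stopifnot(KC > 0, KE > 0, e0 > 0, kappa1 > 0, kappa2 > 0)
    j <- match(reaction, reactionIds(net))
    if (is.na(j)) stop("unknown reaction: ", reaction)
    eid <- paste0(reaction, "_E")
    cid <- paste0(reaction, "_C")
    if (any(c(eid, cid) %in% speciesIds(net)))
        stop("generated species id collides with existing species: ",
             eid, " / ", cid)
    N <- stoichMatrix(net)
    st <- N[, j]
    r1 <- c(st[st < 0], stats::setNames(c(-1, 1), c(eid, cid)))
    r2 <- c(st[st > 0], stats::setNames(c(1, -1), c(eid, cid)))
    rx <- stats::setNames(
        lapply(colnames(N), function(id) { v <- N[, id]; v[v != 0] }),
        colnames(N))
    pos <- match(reaction, names(rx))
    newrx <- c(rx[seq_len(pos - 1)],
               stats::setNames(list(r1, r2),
                               paste0(reaction, c("_1", "_2"))),
               rx[-seq_len(pos)])
    out <- stoichiometricNetwork(newrx,
                                 species = c(speciesIds(net), eid, cid))
    # carry over parameters
    keep <- match(speciesIds(net), out@species$id)
    out@species$K[keep] <- net@species$K
    out@species$x0[keep] <- net@species$x0
    out@species$chemostat[keep] <- net@species$chemostat
    out@species$K[match(c(eid, cid), out@species$id)] <- c(KE, KC)
    # split e0 with a token amount of complex so potentials are defined at t0
    out@species$x0[match(c(eid, cid), out@species$id)] <-
        c(e0 * (1 - 1e-6), e0 * 1e-6)
    old <- match(setdiff(reactionIds(net), reaction), out@reactions$id)
    src <- match(setdiff(reactionIds(net), reaction), net@reactions$id)
    for (colnm in c("kinetics", "kappa", "fmax", "Kf", "rho", "flowstat",
                    "flowstatValue"))
        out@reactions[[colnm]][old] <- net@reactions[[colnm]][src]
    out@reactions$kappa[match(paste0(reaction, c("_1", "_2")),
                              out@reactions$id)] <- c(kappa1, kappa2)
    validObject(out)
    out
}
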