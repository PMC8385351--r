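#' Reaction flows at a given state
#'
#' Evaluates every reaction's rate law at species amounts `x`. The
#' exponentials of the forward/reverse potentials are evaluated in product
#' form \eqn{e^{\Phi^f/\phi_N} = \prod_i (K_i x_i)^{N^f_{ij}}}, which is a
#' polynomial in the amounts (integer stoichiometry), so flows remain
#' defined as amounts pass through zero. Flowstatted reactions return their
#' fixed flow.
#'
#' @param net a [StoichiometricNetwork-class] with species constants and
#'   rate-law parameters assigned.
#' @param x named species amounts (defaults to the stored `x0`).
#' @param temperature kelvin.
#' @return named vector of reaction flows.
#' @export
reactionFlows <- function(net, x = NULL, temperature = 310) {
    ff <- .flowEvaluator(net, temperature)
    if (is.null(x)) x <- stats::setNames(net@species$x0, net@species$id)
    ff(x[speciesIds(net)])
}

# returns function(x) -> named flows; precomputes index structure
.flowEvaluator <- function(net, temperature = 310) {
    N <- stoichMatrix(net)
    d <- decomposeStoichiometry(N)
    K <- net@species$K
    if (anyNA(K))
        stop("missing species constant K for: ",
             paste(utils::head(net@species$id[is.na(K)], 5), collapse = ", "))
    rx <- net@reactions
    for (j in seq_len(nrow(rx))) {
        if (rx$flowstat[j]) next
        if (rx$kinetics[j] == "mass_action" && is.na(rx$kappa[j]))
            stop("missing mass-action constant kappa for reaction ",
                 rx$id[j])
        if (rx$kinetics[j] == "michaelis_menten" &&
            (is.na(rx$fmax[j]) || is.na(rx$Kf[j]) || is.na(rx$rho[j])))
            stop("missing Michaelis-Menten parameters for reaction ",
                 rx$id[j])
    }
    fidx <- lapply(seq_len(ncol(N)), function(j) which(d$Nf[, j] != 0))
    ridx <- lapply(seq_len(ncol(N)), function(j) which(d$Nr[, j] != 0))
    fpow <- lapply(seq_len(ncol(N)), function(j) d$Nf[fidx[[j]], j])
    rpow <- lapply(seq_len(ncol(N)), function(j) d$Nr[ridx[[j]], j])
    function(x) {
        z <- K * x
        f <- numeric(ncol(N))
        for (j in seq_len(ncol(N))) {
            if (rx$flowstat[j]) { f[j] <- rx$flowstatValue[j]; next }
            ef <- prod(z[fidx[[j]]]^fpow[[j]])
            er <- prod(z[ridx[[j]]]^rpow[[j]])
            f[j] <- if (rx$kinetics[j] == "mass_action") {
                rx$kappa[j] * (ef - er)
            } else {
                rx$fmax[j] / (rx$Kf[j] + (1 - rx$rho[j]) * ef +
                              rx$rho[j] * er) * (ef - er)
            }
        }
        stats::setNames(f, colnames(N))
    }
}

#' Simulate network dynamics under chemostats and flowstats
#'
#' Integrates \eqn{\dot x = N^{cd} f(x)} with a stiff-capable implicit
#' integrator (`deSolve::lsoda`). Chemostatted species are held at their
#' initial amount (their row of `N` is zeroed and the balancing external
#' flow is reported in the `exchange` slot); flowstatted reactions carry a
#' fixed flow. With `untilSteady = TRUE` the integration is extended in
#' doubling chunks until \eqn{\|\dot x\|_\infty} falls below `steadyTol`
#' or `tMax` is reached.
#'
#' @param net a parameterized [StoichiometricNetwork-class].
#' @param chemostats character vector of species ids (amounts taken from
#'   `x0`/`x0` override), or a named numeric vector of fixed amounts.
#' @param flowstats character vector of reaction ids (flow 0), or a named
#'   numeric vector of fixed flows.
#' @param x0 optional named amounts overriding the stored `x0`.
#' @param tEnd end of the reported time grid (normalized time units).
#' @param nGrid number of output points.
#' @param rtol,atol integrator tolerances.
#' @param steadyTol steady-state threshold on the amount derivatives.
#' @param untilSteady extend integration until steady state (up to `tMax`).
#' @param tMax cap for `untilSteady`.
#' @param temperature kelvin.
#' @return A [Trajectory-class].
#' @export
simulateNetwork <- function(net, chemostats = character(),
                            flowstats = character(), x0 = NULL,
                            tEnd = 100, nGrid = 200, rtol = 1e-8,
                            atol = 1e-10, steadyTol = 1e-9,
                            untilSteady = FALSE, tMax = 1e6,
                            temperature = 310) {
    sid <- speciesIds(net)
    rid <- reactionIds(net)
    xinit <- stats::setNames(net@species$x0, sid)
    if (!is.null(x0)) xinit[names(x0)] <- x0
    if (is.numeric(chemostats)) {
        xinit[names(chemostats)] <- chemostats
        chemostats <- names(chemostats)
    }
    if (is.numeric(flowstats)) {
        j <- match(names(flowstats), rid)
        if (anyNA(j)) stop("unknown flowstat reaction")
        net@reactions$flowstat[j] <- TRUE
        net@reactions$flowstatValue[j] <- unname(flowstats)
        flowstats <- names(flowstats)
    } else if (length(flowstats)) {
        j <- match(flowstats, rid)
        if (anyNA(j)) stop("unknown flowstat reaction")
        net@reactions$flowstat[j] <- TRUE
    }
    if (any(xinit <= 0 & !(sid %in% chemostats)))
        stop("all initial amounts must be positive")
    N <- stoichMatrix(net)
    Ncd <- applyStats(N, chemostats, flowstats)
    flow <- .flowEvaluator(net, temperature)
    deriv <- function(t, x, parms) {
        f <- flow(x)
        list(drop(Ncd %*% f))
    }
    times <- seq(0, tEnd, length.out = nGrid + 1)
    out <- deSolve::lsoda(xinit, times, deriv, NULL, rtol = rtol,
                          atol = atol)
    if (attr(out, "istate")[1] < 0)
        stop("integration failed near t = ", max(out[, 1]))
    steady <- function(x) max(abs(drop(Ncd %*% flow(x)))) < steadyTol
    if (untilSteady) {
        t1 <- tEnd
        while (!steady(out[nrow(out), -1]) && t1 < tMax) {
            xlast <- out[nrow(out), -1]
            tseg <- seq(t1, min(2 * t1, tMax), length.out = 32)
            seg <- deSolve::lsoda(xlast, tseg, deriv, NULL, rtol = rtol,
                                  atol = atol)
            if (attr(seg, "istate")[1] < 0)
                stop("integration failed near t = ", max(seg[, 1]))
            out <- rbind(out, seg[-1, ])
            t1 <- min(2 * t1, tMax)
        }
    }
    tgrid <- out[, 1]
    X <- out[, -1, drop = FALSE]
    colnames(X) <- sid
    Fm <- t(apply(X, 1, flow))
    if (length(rid) == 1) Fm <- matrix(Fm, ncol = 1)
    colnames(Fm) <- rid
    Ex <- Fm %*% t(N)
    colnames(Ex) <- sid
    pN <- thermalPotential(temperature)
    Phim <- matrix(NA_real_, nrow(X), length(sid),
                   dimnames = list(NULL, sid))
    pos <- X > 0
    Kv <- matrix(net@species$K, nrow(X), length(sid), byrow = TRUE)
    Phim[pos] <- pN * log(Kv[pos] * X[pos])
    PhiR <- -Phim %*% N
    colnames(PhiR) <- rid
    new("Trajectory", time = tgrid, x = X, f = Fm, exchange = Ex,
        phi = Phim, Phi = PhiR,
        steady = steady(X[nrow(X), ]),
        chemostats = as.character(chemostats),
        flowstats = as.character(flowstats))
}

#' Ratio of chemostat exchange flows
#'
#' The exchange flow of a species is its internal production rate
#' \eqn{(N f)_i}, i.e. the flow an external reservoir must remove to hold a
#' chemostat steady. The ratio reported is the magnitude
#' \eqn{|(N f)_{num} / (N f)_{den}|}; values where the denominator flow is
#' below `tol` are `NA`. At steady state the ratio equals the ratio of the
#' corresponding net-pathway coefficients.
#'
#' @param traj a [Trajectory-class].
#' @param numerator,denominator species ids.
#' @param tol denominator masking threshold.
#' @return numeric time series.
#' @export
fluxRatios <- function(traj, numerator, denominator, tol = 1e-12) {
    ex <- traj@exchange
    stopifnot(numerator %in% colnames(ex), denominator %in% colnames(ex))
    den <- ex[, denominator]
    out <- abs(ex[, numerator] / den)
    out[abs(den) < tol] <- NA_real_
    out
}

#' Energy audit along a trajectory
#'
#' Computes the internal power balance \eqn{\phi^T \dot x + \Phi^T f}
#' (with \eqn{\dot x = N^{cd} f}) and the boundary power absorbed by the
#' chemostats/flowstats, \eqn{\phi^T (N - N^{cd}) f}. For a closed system
#' the internal residual is zero to integration tolerance; for open systems
#' internal + boundary = 0 identically, so the internal residual equals
#' minus the boundary power.
#'
#' @param traj a [Trajectory-class].
#' @param net the simulated network (for `N`).
#' @return data.frame with columns `time`, `internal`, `boundary`.
#' @export
energyAudit <- function(traj, net) {
    N <- stoichMatrix(net)
    Ncd <- applyStats(N, traj@chemostats, traj@flowstats)
    xdot <- traj@f %*% t(Ncd)
    boundary <- rowSums(traj@phi * (traj@f %*% t(N - Ncd)))
    internal <- rowSums(traj@phi * xdot) + rowSums(traj@Phi * traj@f)
    data.frame(time = traj@time, internal = internal, boundary = boundary)
}

setMethod("show", "Trajectory", function(object) {
    n <- length(object@time)
    cat("Trajectory:", n, "time points over [0,",
        format(object@time[n]), "];",
        ncol(object@x), "species,", ncol(object@f), "reactions;",
        if (object@steady) "steady state reached" else "not steady", "\n")
    invisible(NULL)
})
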