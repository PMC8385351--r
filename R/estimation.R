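#' Partition reactions into known and unknown potential sets
#'
#' Splits the columns of `N` into `N0` (reactions with measured potentials)
#' and `N1` (unknown), keeping the original column order within each part.
#'
#' @param N stoichiometric matrix.
#' @param knownMask logical vector over reactions (TRUE = potential known).
#' @return list with `N0`, `N1`, and the id vectors `known`, `unknown`.
#' @export
partitionReactions <- function(N, knownMask) {
    if (is(N, "StoichiometricNetwork")) N <- stoichMatrix(N)
    if (length(knownMask) != ncol(N))
        stop("mask length must equal the number of reactions")
    list(N0 = N[, knownMask, drop = FALSE],
         N1 = N[, !knownMask, drop = FALSE],
         known = colnames(N)[knownMask],
         unknown = colnames(N)[!knownMask])
}

# shared QP wrapper: min 1/2 x'Cx + d'x s.t. Ax <= b, Aeq x = beq, x >= lb
.solveQP <- function(C, d, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                     lb = NULL) {
    if (is.null(A) && is.null(Aeq) && is.null(lb))
        return(list(x = drop(-solve(C, d)), active = logical(0)))
    sol <- pracma::quadprog(C, d, A = A, b = b, Aeq = Aeq, beq = beq,
                            lb = lb)
    if (sol$eflag != 1)
        stop("quadratic program did not converge (flag ", sol$eflag, ")")
    x <- sol$xmin
    active <- logical(0)
    if (!is.null(A))
        active <- abs(drop(A %*% x) - b) < 1e-7 * (1 + abs(b))
    list(x = x, active = active)
}

# KKT stationarity residual given the active inequality rows (and equality
# rows): least-squares multipliers for grad + Act' mu = 0
.kktResidual <- function(C, d, x, Act = NULL) {
    g <- drop(C %*% x) + d
    if (is.null(Act) || nrow(Act) == 0) return(max(abs(g)))
    mu <- qr.solve(t(Act), -g)
    max(abs(g + drop(t(Act) %*% mu)))
}

#' Estimate species potentials from measured reaction potentials
#'
#' Solves the quadratic program
#' \deqn{\min_\phi \tfrac12 \phi^T (N_0 N_0^T + \lambda I)\phi +
#'   (N_0 \Phi_0)^T \phi \quad \mathrm{s.t.}\; -N_1^T \phi \ge \delta,}
#' i.e. least-squares fitting of the measured potentials
#' (\eqn{\hat\Phi_0 = -N_0^T\hat\phi \approx \Phi_0}) with a minimum-norm
#' ridge (`lambda`) resolving the null directions, subject to the
#' thermodynamic sign constraint that every unknown reaction potential be at
#' least `delta` (all measured flows positive). Reactions whose constraint
#' is active are flagged.
#'
#' @param N0,N1 known/unknown column partitions of `N` (see
#'   [partitionReactions()]).
#' @param Phi0 measured reaction potentials for the known columns (mV).
#' @param lambda small ridge weight (> 0).
#' @param delta lower bound on unknown reaction potentials (mV).
#' @return A [PotentialEstimate-class].
#' @export
estimatePotentials <- function(N0, N1, Phi0, lambda = 1e-6, delta = 1) {
    stopifnot(lambda >= 0, delta >= 0)
    if (ncol(N0) == 0)
        stop("no measured reaction potentials: estimation is impossible")
    if (length(Phi0) != ncol(N0))
        stop("Phi0 length must match the known reactions")
    n <- nrow(N0)
    P <- N0 %*% t(N0) + lambda * diag(n)
    q <- drop(N0 %*% Phi0)
    if (ncol(N1) == 0) {
        sol <- .solveQP(P, q)
        act <- logical(0)
        kkt <- .kktResidual(P, q, sol$x)
    } else {
        A <- t(N1)                       # -N1' phi >= delta  <=>  N1' phi <= -delta
        b <- rep(-delta, ncol(N1))
        sol <- .solveQP(P, q, A = A, b = b)
        act <- sol$active
        kkt <- .kktResidual(P, q, sol$x, Act = A[act, , drop = FALSE])
    }
    phi <- stats::setNames(sol$x, rownames(N0))
    Phi0hat <- stats::setNames(drop(-crossprod(N0, phi)), colnames(N0))
    Phi1hat <- stats::setNames(drop(-crossprod(N1, phi)), colnames(N1))
    new("PotentialEstimate", phi = phi, Phi0hat = Phi0hat,
        Phi1hat = Phi1hat,
        residual = Phi0hat - Phi0,
        active = stats::setNames(act, colnames(N1)),
        kkt = kkt)
}

setMethod("show", "PotentialEstimate", function(object) {
    cat("PotentialEstimate:", length(object@phi), "species potentials;",
        "max |residual| =", format(max(abs(object@residual))), "mV;",
        sum(object@active), "active constraint(s)\n")
    invisible(NULL)
})

#' Estimate pathway flows from measured reaction fluxes
#'
#' Least squares on the measured rows of `Kp`:
#' \eqn{(K_p^T K_p)\hat f_p = K_p^T f} (rows with missing fluxes are
#' deleted before solving). All reaction flows, including missing ones, are
#' then imputed as \eqn{\hat f = K_p \hat f_p}; when `N` is supplied, the
#' chemostat exchange flows \eqn{N \hat f} are reported too.
#'
#' @param Kp pathway basis (reactions x pathways, named rows).
#' @param f measured fluxes with `NA` for missing values.
#' @param N optional full stoichiometric matrix for exchange flows.
#' @return list with `fp`, `fhat`, and (optionally) `exchange`.
#' @export
estimatePathwayFlows <- function(Kp, f, N = NULL) {
    if (length(f) != nrow(Kp))
        stop("flux vector must cover every reaction (use NA for missing)")
    keep <- !is.na(f)
    Kred <- Kp[keep, , drop = FALSE]
    qrK <- qr(Kred)
    if (qrK$rank < ncol(Kp)) {
        bad <- setdiff(seq_len(ncol(Kp)), qrK$pivot[seq_len(qrK$rank)])
        stop("pathways unidentifiable after deleting unmeasured rows: ",
             paste(bad, collapse = ", "))
    }
    fp <- drop(solve(crossprod(Kred), crossprod(Kred, f[keep])))
    fhat <- stats::setNames(drop(Kp %*% fp), rownames(Kp))
    out <- list(fp = fp, fhat = fhat)
    if (!is.null(N)) out$exchange <- speciesRate(N, fhat)
    out
}

#' Estimate mass-action reaction constants
#'
#' Given estimated fluxes and species potentials,
#' \eqn{\hat f_0^+ = e^{\hat\Phi^f/\phi_N}},
#' \eqn{\hat f_0^- = e^{\hat\Phi^r/\phi_N}},
#' \eqn{\hat f_0 = \hat f_0^+ - \hat f_0^-} and
#' \eqn{\hat\kappa = \hat f / \hat f_0}. Equilibrium reactions
#' (\eqn{\hat f_0 = 0}) are flagged unidentifiable. When the upstream QP
#' sign constraint holds, every \eqn{\hat\kappa} is positive, hence
#' thermodynamically safe.
#'
#' @param fhat estimated reaction fluxes.
#' @param phi estimated species potentials (mV).
#' @param Nf,Nr forward/reverse stoichiometric parts.
#' @param temperature kelvin.
#' @param tol threshold on `|f0|` (and on `|fhat|`) below which the
#'   reaction is effectively at equilibrium and kappa is unidentifiable.
#' @return data.frame with columns `id`, `f0plus`, `f0minus`, `f0`,
#'   `kappa`, `identifiable`.
#' @export
estimateKappa <- function(fhat, phi, Nf, Nr, temperature = 310,
                          tol = 1e-9) {
    pN <- thermalPotential(temperature)
    Phif <- drop(crossprod(Nf, phi))
    Phir <- drop(crossprod(Nr, phi))
    f0p <- exp(Phif / pN)
    f0m <- exp(Phir / pN)
    f0 <- f0p - f0m
    ok <- abs(f0) > tol & abs(fhat) > tol
    kappa <- ifelse(ok, fhat / f0, NA_real_)
    data.frame(id = colnames(Nf), f0plus = f0p, f0minus = f0m, f0 = f0,
               kappa = kappa, identifiable = ok,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate reversible Michaelis-Menten parameters
#'
#' Fits \eqn{\theta = (f_{max}, \rho, K_f)} from one or more steady states
#' using the linear-in-parameters rearrangement of the rate law:
#' per steady state, \eqn{X = (1, \hat f, -\hat f/\hat f_0)} and
#' \eqn{y = \hat f \hat f_0^+ / \hat f_0}, solved as the quadratic program
#' \deqn{\min_\theta \tfrac12\theta^T(X^TX+\lambda I)\theta - (X^Ty)^T\theta
#'   \quad \mathrm{s.t.}\; \theta \ge \theta_{min},\; A_{ec}\theta = b_{ec}.}
#' With fewer than three steady states the equality constraints must fix
#' the deficient directions (e.g. known `Kf` and `rho` leave `fmax`
#' determined by a single state).
#'
#' @param fhat,f0plus,f0minus vectors over steady states for one reaction.
#' @param Aec,bec optional equality constraints on `(fmax, rho, Kf)`.
#' @param lambda ridge weight.
#' @param thetaMin strictly positive lower bound implementing `theta > 0`.
#' @param temperature unused placeholder for interface symmetry.
#' @return list with `fmax`, `rho`, `Kf`, `residual` (per steady state)
#'   and the design pair `X`, `y`.
#' @export
estimateMMParams <- function(fhat, f0plus, f0minus, Aec = NULL, bec = NULL,
                             lambda = 1e-6, thetaMin = 1e-9,
                             temperature = 310) {
    stopifnot(length(fhat) == length(f0plus),
              length(fhat) == length(f0minus))
    f0 <- f0plus - f0minus
    if (any(abs(f0) < 1e-12))
        stop("equilibrium steady state: rate-law parameters unidentifiable")
    X <- cbind(1, fhat, -fhat / f0)
    y <- fhat * f0plus / f0
    nec <- if (is.null(Aec)) 0L else nrow(Aec)
    if (length(fhat) + nec < 3)
        stop("at least three steady states (or equality constraints ",
             "fixing the deficient directions) are required")
    C <- crossprod(X) + lambda * diag(3)
    d <- -drop(crossprod(X, y))
    sol <- .solveQP(C, d, Aeq = Aec, beq = bec, lb = rep(thetaMin, 3))
    theta <- sol$x
    list(fmax = theta[1], rho = theta[2], Kf = theta[3],
         residual = drop(y - X %*% theta), X = X, y = y)
}

#' Species constants at the measured steady state
#'
#' With amounts expressed per unit volume, the reference amount equals the
#' steady-state concentration, so \eqn{K = e^{\hat\phi/\phi_N}/c} and
#' `cePotential(K, c)` returns `phi` exactly. Species with missing
#' concentrations get `NA`.
#'
#' @param phi estimated species potentials (mV, named).
#' @param conc steady-state concentrations (normalized; `NA` = missing).
#' @param temperature kelvin.
#' @return named vector of species constants.
#' @export
dynamicalConstants <- function(phi, conc, temperature = 310) {
    stopifnot(length(phi) == length(conc))
    if (any(!is.na(conc) & conc <= 0))
        stop("concentrations must be positive")
    K <- ifelse(is.na(conc), NA_real_,
                exp(phi / thermalPotential(temperature)) / conc)
    stats::setNames(K, names(phi))
}

#' Normalize raw concentration and flow data
#'
#' Scales concentrations by the reference species concentration `c0` (mM)
#' and flows by the reference reaction flow `f0` (converted from mM/min to
#' mM/s); the induced time unit is `t0 = c0/f0` seconds. The normalized
#' reference concentration and flow are 1.
#'
#' @param cRaw named concentrations (mM).
#' @param fRaw named flows (mM/min).
#' @param refSpecies,refReaction reference ids.
#' @return list with `c`, `f` (normalized), `c0`, `f0`, `t0`.
#' @export
normalizeData <- function(cRaw, fRaw, refSpecies, refReaction) {
    if (!refSpecies %in% names(cRaw) || is.na(cRaw[refSpecies]))
        stop("missing reference concentration: ", refSpecies)
    if (!refReaction %in% names(fRaw) || is.na(fRaw[refReaction]))
        stop("missing reference flow: ", refReaction)
    c0 <- unname(cRaw[refSpecies])
    f0 <- unname(fRaw[refReaction]) / 60
    if (c0 <= 0 || f0 <= 0) stop("reference values must be positive")
    list(c = cRaw / c0, f = (fRaw / 60) / f0, c0 = c0, f0 = f0,
         t0 = c0 / f0)
}

#' Bundle steady-state measurements
#'
#' @param Phi named reaction potentials (mV), `NA` = unknown.
#' @param f named normalized fluxes, `NA` = missing.
#' @param conc named normalized concentrations, `NA` = missing.
#' @param normalization list with `c0`, `f0`, `t0` (see
#'   [normalizeData()]).
#' @return A [SteadyStateData-class].
#' @export
steadyStateData <- function(Phi, f, conc,
                            normalization = list(c0 = 1, f0 = 1, t0 = 1)) {
    new("SteadyStateData", Phi = Phi, f = f, c = conc,
        normalization = normalization)
}

#' Full thermodynamically safe parameter estimation pipeline
#'
#' Runs the estimation chain on one steady state: potential QP, pathway
#' flow least squares under the given chemostats/flowstats, mass-action
#' constants, and species constants; optionally the Michaelis-Menten
#' equivalents with `Kf` and `rho` fixed by equality constraint (their
#' mass-action pair `kappa1`, `kappa2` uses the convention `e0 = 1`,
#' `KE = 1`, hence `KC = Kf`). Every emitted parameter is positive by
#' construction.
#'
#' @param net a [StoichiometricNetwork-class].
#' @param data a [SteadyStateData-class].
#' @param chemostats,flowstats boundary conditions defining the pathway
#'   space.
#' @param lambda,delta QP settings (see [estimatePotentials()]).
#' @param mm fit Michaelis-Menten equivalents.
#' @param fixKf,fixRho fixed values used when `mm = TRUE`.
#' @param temperature kelvin.
#' @return A [ParameterSet-class].
#' @export
estimateParameters <- function(net, data, chemostats = character(),
                               flowstats = character(), lambda = 1e-6,
                               delta = 1, mm = FALSE, fixKf = 0.1,
                               fixRho = 0.2, temperature = 310) {
    N <- stoichMatrix(net)
    known <- !is.na(data@Phi[colnames(N)])
    part <- partitionReactions(N, known)
    pe <- estimatePotentials(part$N0, part$N1,
                             data@Phi[part$known], lambda = lambda,
                             delta = delta)
    pd <- decomposePathways(net, chemostats, flowstats)
    pf <- estimatePathwayFlows(pd@Kp, data@f[colnames(N)], N = N)
    d <- decomposeStoichiometry(N)
    kap <- estimateKappa(pf$fhat, pe@phi, d$Nf, d$Nr,
                         temperature = temperature)
    K <- dynamicalConstants(pe@phi, data@c[rownames(N)],
                            temperature = temperature)
    mmTab <- NULL
    if (mm) {
        Aec <- rbind(c(0, 1, 0), c(0, 0, 1))
        bec <- c(fixRho, fixKf)
        rows <- lapply(seq_len(ncol(N)), function(j) {
            if (!kap$identifiable[j])
                return(data.frame(id = kap$id[j], fmax = NA_real_,
                                  rho = NA_real_, Kf = NA_real_,
                                  kappa1 = NA_real_, kappa2 = NA_real_))
            fit <- estimateMMParams(pf$fhat[j], kap$f0plus[j],
                                    kap$f0minus[j], Aec = Aec, bec = bec,
                                    lambda = lambda)
            ma <- mmToMassAction(fit$fmax, fit$rho, KC = fit$Kf, e0 = 1)
            data.frame(id = kap$id[j], fmax = fit$fmax, rho = fit$rho,
                       Kf = fit$Kf, kappa1 = ma$kappa1, kappa2 = ma$kappa2)
        })
        mmTab <- do.call(rbind, rows)
    }
    new("ParameterSet",
        phi = pe@phi,
        K = K,
        kappa = stats::setNames(kap$kappa, kap$id),
        f = pf$fhat,
        fp = pf$fp,
        mm = mmTab)
}

setMethod("show", "ParameterSet", function(object) {
    cat("ParameterSet:", length(object@phi), "species potentials,",
        sum(!is.na(object@kappa)), "mass-action constants,",
        length(object@fp), "pathway flows",
        if (!is.null(object@mm)) "(+ Michaelis-Menten equivalents)", "\n")
    invisible(NULL)
})
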