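#' Apply chemostat and flowstat boundary conditions to N
#'
#' Returns `Ncd`: the stoichiometric matrix with chemostatted species
#' *rows* and flowstatted reaction *columns* set to zero. `N` itself is
#' untouched. Chemostats hold species amounts fixed (an implied external
#' flow balances their internal flow); zero-flow flowstats isolate
#' reactions, akin to removing the enzyme.
#'
#' @param N stoichiometric matrix with dimnames, or a
#'   [StoichiometricNetwork-class].
#' @param chemostats species ids to chemostat.
#' @param flowstats reaction ids to flowstat.
#' @return The constrained matrix `Ncd`.
#' @export
applyStats <- function(N, chemostats = character(),
                       flowstats = character()) {
    if (is(N, "StoichiometricNetwork")) N <- stoichMatrix(N)
    unknown <- setdiff(chemostats, rownames(N))
    if (length(unknown))
        stop("unknown chemostat species: ", paste(unknown, collapse = ", "))
    unknown <- setdiff(flowstats, colnames(N))
    if (length(unknown))
        stop("unknown flowstat reaction: ", paste(unknown, collapse = ", "))
    Ncd <- N
    Ncd[rownames(N) %in% chemostats, ] <- 0
    Ncd[, colnames(N) %in% flowstats] <- 0
    Ncd
}

#' Integer pathway basis of a constrained network
#'
#' Columns of `Kp` form an exact integer basis of the right null space of
#' `Ncd`, canonicalized as in [integerNullspace()]. Flowstatted reactions
#' carry a *fixed* flow, not a free pathway flow: although zeroing their
#' column makes each unit vector a trivial null vector, those directions are
#' excluded, so `Kp` has zero rows at flowstatted reactions and spans only
#' the free steady-state flux patterns.
#'
#' @param Ncd constrained stoichiometric matrix (see [applyStats()]).
#' @param flowstats reaction ids (or column indices) whose columns were
#'   zeroed by flowstats.
#' @return Integer matrix `Kp` (reactions x pathways).
#' @export
pathwayBasis <- function(Ncd, flowstats = character()) {
    Ncd <- as.matrix(Ncd)
    if (is.character(flowstats)) {
        fidx <- match(flowstats, colnames(Ncd))
        if (anyNA(fidx)) stop("unknown flowstat reaction")
    } else fidx <- as.integer(flowstats)
    keep <- setdiff(seq_len(ncol(Ncd)), fidx)
    Kred <- integerNullspace(Ncd[, keep, drop = FALSE])
    Kp <- matrix(0, ncol(Ncd), ncol(Kred),
                 dimnames = list(colnames(Ncd), NULL))
    Kp[keep, ] <- Kred
    Kp
}

#' Pathway stoichiometry
#'
#' `Np = N Kp`: each column is the net reaction of one pathway.
#'
#' @param N full (unconstrained) stoichiometric matrix.
#' @param Kp pathway basis.
#' @return Integer matrix `Np` (species x pathways).
#' @export
pathwayStoichiometry <- function(N, Kp) {
    if (is(N, "StoichiometricNetwork")) N <- stoichMatrix(N)
    N %*% Kp
}

#' Render the net reaction of a pathway
#'
#' @param np one column of `Np` (named by species).
#' @param arrow arrow token.
#' @return Reaction string; an all-zero column renders with empty sides.
#' @export
renderPathway <- function(np, arrow = "<->") {
    renderReaction(np[np != 0], arrow = arrow)
}

#' Classify pathways by the species in their net reactions
#'
#' Type I pathways touch at least one primary metabolite; type II touch
#' currency metabolites only (futile cycles); type III have an empty net
#' reaction.
#'
#' @param Np pathway stoichiometry (species x pathways, named rows).
#' @param currency currency metabolite ids (see [currencyMetabolites()]).
#' @param primary primary metabolite ids; defaults to all species not in
#'   `currency`.
#' @return Character vector of labels `"I"`, `"II"`, `"III"`.
#' @export
classifyPathways <- function(Np, currency = currencyMetabolites(),
                             primary = NULL) {
    if (is.null(primary)) primary <- setdiff(rownames(Np), currency)
    if (length(intersect(primary, currency)))
        stop("primary and currency sets must be disjoint")
    vapply(seq_len(ncol(Np)), function(j) {
        sp <- rownames(Np)[Np[, j] != 0]
        if (!length(sp)) return("III")
        outside <- setdiff(sp, union(primary, currency))
        if (length(outside))
            stop("species in neither primary nor currency set: ",
                 paste(outside, collapse = ", "))
        if (any(sp %in% primary)) "I" else "II"
    }, character(1))
}

#' Default currency metabolite set
#'
#' Ubiquitous cofactors distinguished from primary metabolites when
#' classifying pathways; override per analysis as needed.
#'
#' @return character vector of ids.
#' @export
currencyMetabolites <- function() {
    c("ATP", "ADP", "PI", "H", "H2O", "NAD", "NADH", "NADP", "NADPH",
      "CO2", "O2", "Q8", "Q8H2", "HE", "FOR")
}

#' Pathway reaction potentials
#'
#' \eqn{\Phi_p = -N_p^T \phi}; equivalently `t(Kp) %*% Phi`.
#'
#' @param Np pathway stoichiometry.
#' @param phi species potentials (mV).
#' @return numeric vector of pathway potentials (mV).
#' @export
pathwayPotentials <- function(Np, phi) {
    if (length(phi) != nrow(Np))
        stop("phi has length ", length(phi), " but Np has ", nrow(Np),
             " rows")
    drop(-crossprod(Np, phi))
}

#' Full pathway decomposition of a network
#'
#' Convenience wrapper: applies the boundary conditions, computes the
#' integer pathway basis, the pathway stoichiometry, and the type labels.
#'
#' @param net a [StoichiometricNetwork-class].
#' @param chemostats,flowstats boundary-condition id sets.
#' @inheritParams classifyPathways
#' @return A [PathwayDecomposition-class].
#' @export
decomposePathways <- function(net, chemostats = character(),
                              flowstats = character(),
                              currency = currencyMetabolites(),
                              primary = NULL) {
    N <- stoichMatrix(net)
    Ncd <- applyStats(N, chemostats, flowstats)
    Kp <- pathwayBasis(Ncd, flowstats)
    Np <- pathwayStoichiometry(N, Kp)
    types <- tryCatch(
        classifyPathways(Np, currency = currency, primary = primary),
        error = function(e) rep(NA_character_, ncol(Np)))
    new("PathwayDecomposition", chemostats = as.character(chemostats),
        flowstats = as.character(flowstats), Ncd = Ncd, Kp = Kp, Np = Np,
        types = types, fp = NULL)
}

setMethod("show", "PathwayDecomposition", function(object) {
    np <- ncol(object@Kp)
    cat("PathwayDecomposition:", np, "pathway(s);",
        length(object@chemostats), "chemostats,",
        length(object@flowstats), "flowstats\n")
    for (j in seq_len(np)) {
        v <- object@Kp[, j]
        terms <- paste0(ifelse(v[v != 0] > 0, "+", "-"),
                        ifelse(abs(v[v != 0]) == 1, "",
                               paste0(abs(v[v != 0]), " ")),
                        names(v)[v != 0], collapse = " ")
        cat(sprintf("  [%d] type %s: %s\n      %s\n", j, object@types[j],
                    terms, renderPathway(object@Np[, j])))
    }
    invisible(NULL)
})

#' Energy balance analysis of a flux/potential pair
#'
#' Checks the two thermodynamic feasibility constraints that the bond-graph
#' formulation satisfies by construction: the sign constraint
#' \eqn{f_i \Phi_i \ge 0} (positive flux resistances
#' \eqn{r_i = \Phi_i / f_i}) and the cycle constraint \eqn{K^T \Phi = 0}
#' over the right null space `K` of the full `N`. When pathway flows `fp`
#' for a chemostatted configuration are supplied, the residual of
#' \eqn{K^T R K_p f_p = 0} is reported as well.
#'
#' @param f reaction flows.
#' @param Phi reaction potentials (mV).
#' @param N full stoichiometric matrix.
#' @param Kp optional pathway basis of the open system.
#' @param fp optional pathway flows.
#' @return An [EbaReport-class].
#' @export
ebaCheck <- function(f, Phi, N, Kp = NULL, fp = NULL) {
    if (is(N, "StoichiometricNetwork")) N <- stoichMatrix(N)
    stopifnot(length(f) == ncol(N), length(Phi) == ncol(N))
    r <- ifelse(f == 0, ifelse(Phi == 0, NA_real_, Inf), Phi / f)
    viol <- which(f * Phi < 0)
    K <- integerNullspace(N)
    cyc <- if (ncol(K)) max(abs(crossprod(K, Phi))) else 0
    pres <- NA_real_
    if (!is.null(Kp) && !is.null(fp) && ncol(K)) {
        rr <- r
        rr[!is.finite(rr)] <- 0   # zero-flow reactions carry no pathway flow
        pres <- max(abs(crossprod(K, rr * drop(Kp %*% fp))))
    }
    ids <- colnames(N)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(N)))
    new("EbaReport", r = stats::setNames(r, ids), cycleResidual = cyc,
        pathwayResidual = pres,
        violations = ids[viol])
}

setMethod("show", "EbaReport", function(object) {
    cat("EbaReport: cycle residual ", format(object@cycleResidual),
        "; ", length(object@violations), " sign violation(s)",
        if (length(object@violations))
            paste0(" [", paste(object@violations, collapse = ", "), "]"),
        "\n", sep = "")
    invisible(NULL)
})
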