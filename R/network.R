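#' Construct a stoichiometric network
#'
#' @param reactions named list: each element is a named numeric vector of
#'   signed stoichiometric coefficients (negative = reactant, positive =
#'   product), names are species ids; the list names are the reaction ids.
#' @param species optional character vector fixing the species order; by
#'   default species appear in order of first occurrence.
#' @param names optional named character vector of free-text species names.
#' @return A [StoichiometricNetwork-class].
#' @examples
#' net <- stoichiometricNetwork(list(r1 = c(A = -1, B = 2)))
#' stoichMatrix(net)
#' @export
stoichiometricNetwork <- function(reactions, species = NULL, names = NULL) {
    stopifnot(is.list(reactions))
    rids <- base::names(reactions)
    if (length(reactions) == 0) rids <- character()
    if (is.null(rids) || any(rids == ""))
        stop("every reaction must be named")
    seen <- character()
    for (st in reactions) seen <- c(seen, setdiff(base::names(st), seen))
    sids <- if (is.null(species)) seen else species
    if (!all(seen %in% sids))
        stop("species order vector omits species used by reactions")
    N <- matrix(0, length(sids), length(reactions),
                dimnames = list(sids, rids))
    for (j in seq_along(reactions)) {
        st <- reactions[[j]]
        if (!length(st) || all(st == 0))
            stop("reaction ", rids[j], " has empty stoichiometry")
        N[base::names(st), j] <- st
    }
    spnm <- sids
    if (!is.null(names)) {
        hit <- sids %in% base::names(names)
        spnm[hit] <- unname(names[sids[hit]])
    }
    ns <- length(sids); nr <- length(rids)
    sp <- data.frame(id = sids, name = spnm, K = rep(NA_real_, ns),
                     x0 = rep(1, ns), chemostat = rep(FALSE, ns),
                     stringsAsFactors = FALSE)
    rx <- data.frame(id = rids, kinetics = rep("mass_action", nr),
                     kappa = rep(NA_real_, nr), fmax = rep(NA_real_, nr),
                     Kf = rep(NA_real_, nr), rho = rep(NA_real_, nr),
                     flowstat = rep(FALSE, nr), flowstatValue = rep(0, nr),
                     stringsAsFactors = FALSE)
    new("StoichiometricNetwork", species = sp, reactions = rx, stoich = N)
}

.emptyNetwork <- function() {
    stoichiometricNetwork(stats::setNames(list(), character()))
}

#' Accessors for StoichiometricNetwork
#'
#' @param object a [StoichiometricNetwork-class].
#' @return `stoichMatrix()` the integer matrix `N`; `speciesIds()`,
#'   `reactionIds()` character vectors; `speciesTable()`,
#'   `reactionTable()` the underlying data.frames; `nSpecies()`,
#'   `nReactions()` counts.
#' @name network-accessors
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname network-accessors
#' @export
setMethod("stoichMatrix", "StoichiometricNetwork",
          function(object) object@stoich)

#' @rdname network-accessors
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))

#' @rdname network-accessors
#' @export
setMethod("speciesIds", "StoichiometricNetwork",
          function(object) object@species$id)

#' @rdname network-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname network-accessors
#' @export
setMethod("reactionIds", "StoichiometricNetwork",
          function(object) object@reactions$id)

#' @rdname network-accessors
#' @export
setGeneric("speciesTable", function(object) standardGeneric("speciesTable"))

#' @rdname network-accessors
#' @export
setMethod("speciesTable", "StoichiometricNetwork",
          function(object) object@species)

#' @rdname network-accessors
#' @export
setGeneric("reactionTable", function(object) standardGeneric("reactionTable"))

#' @rdname network-accessors
#' @export
setMethod("reactionTable", "StoichiometricNetwork",
          function(object) object@reactions)

#' @rdname network-accessors
#' @export
nSpecies <- function(object) nrow(object@species)

#' @rdname network-accessors
#' @export
nReactions <- function(object) nrow(object@reactions)

#' Set species constants, amounts or reaction parameters
#'
#' `setSpeciesConstants()` and `setAmounts()` update the per-species `K`
#' and `x0` columns; `setMassAction()` assigns mass-action constants;
#' `setMichaelisMenten()` switches reactions to the reversible
#' Michaelis-Menten rate law with the given triples.
#'
#' @param net a [StoichiometricNetwork-class].
#' @param K,x0,kappa named numeric vectors (names are species/reaction ids;
#'   unnamed vectors of full length are matched by position).
#' @param fmax,Kf,rho named numeric vectors over the reactions to switch.
#' @return The updated network.
#' @name network-setters
#' @export
setSpeciesConstants <- function(net, K) {
    net@species$K <- .matchAssign(net@species$K, K, net@species$id, "species")
    validObject(net)
    net
}

#' @rdname network-setters
#' @export
setAmounts <- function(net, x0) {
    net@species$x0 <- .matchAssign(net@species$x0, x0, net@species$id,
                                   "species")
    validObject(net)
    net
}

#' @rdname network-setters
#' @export
setMassAction <- function(net, kappa) {
    net@reactions$kappa <- .matchAssign(net@reactions$kappa, kappa,
                                        net@reactions$id, "reaction")
    idx <- if (is.null(names(kappa))) seq_len(nReactions(net)) else
        match(names(kappa), net@reactions$id)
    net@reactions$kinetics[idx] <- "mass_action"
    validObject(net)
    net
}

#' @rdname network-setters
#' @export
setMichaelisMenten <- function(net, fmax, Kf, rho) {
    ids <- names(fmax)
    if (is.null(ids)) stop("fmax must be named by reaction id")
    idx <- match(ids, net@reactions$id)
    if (anyNA(idx)) stop("unknown reaction: ", ids[is.na(idx)][1])
    net@reactions$fmax[idx] <- unname(fmax)
    net@reactions$Kf[idx] <- unname(Kf[ids])
    net@reactions$rho[idx] <- unname(rho[ids])
    net@reactions$kinetics[idx] <- "michaelis_menten"
    validObject(net)
    net
}

.matchAssign <- function(current, value, ids, what) {
    if (is.null(names(value))) {
        if (length(value) != length(current))
            stop("unnamed vector must cover every ", what)
        return(as.numeric(value))
    }
    idx <- match(names(value), ids)
    if (anyNA(idx))
        stop("unknown ", what, ": ", names(value)[is.na(idx)][1])
    current[idx] <- unname(value)
    current
}

setMethod("show", "StoichiometricNetwork", function(object) {
    cat("StoichiometricNetwork:", nSpecies(object), "species,",
        nReactions(object), "reactions\n")
    if (nReactions(object)) {
        shown <- utils::head(reactionIds(object), 6)
        for (id in shown)
            cat("  ", renderReaction(object@stoich[, id], arrow = "<->",
                                     id = id), "\n", sep = "")
        if (nReactions(object) > 6)
            cat("  ... and", nReactions(object) - 6, "more\n")
    }
    invisible(NULL)
})

#' Render a signed stoichiometry as a reaction string
#'
#' Negative coefficients are listed as reactants, positive as products;
#' unit coefficients are omitted. An all-zero column renders as an empty
#' reaction (`" <-> "` sides blank).
#'
#' @param stoich named numeric vector of signed coefficients.
#' @param arrow arrow token, default `"<->"`.
#' @param id optional reaction id prefix (`"id: ..."`).
#' @return A single string.
#' @examples
#' renderReaction(c(A = -1, B = 2))
#' @export
renderReaction <- function(stoich, arrow = "<->", id = NULL) {
    side <- function(v) {
        if (!length(v)) return("")
        paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
    }
    lhs <- -stoich[stoich < 0]
    rhs <- stoich[stoich > 0]
    out <- trimws(paste(side(lhs), arrow, side(rhs)))
    if (!is.null(id)) out <- paste0(id, ": ", out)
    out
}
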