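#' Create a network module
#'
#' @param network a [StoichiometricNetwork-class].
#' @param name module name (used to prefix private species on collision).
#' @param exposed species ids initially exposed as ports.
#' @return A [NetworkModule-class].
#' @export
networkModule <- function(network, name, exposed = character()) {
    new("NetworkModule", name = name, network = network,
        exposed = as.character(exposed))
}

#' Expose species of a module as ports
#'
#' Exposing is idempotent and does not alter the wrapped network; only
#' exposed species may be unified during [composeModules()].
#'
#' @param module a [NetworkModule-class].
#' @param speciesIds ids to expose.
#' @return The module with its exposed set extended.
#' @export
exposeSpecies <- function(module, speciesIds) {
    unknown <- setdiff(speciesIds, module@network@species$id)
    if (length(unknown))
        stop("cannot expose unknown species: ",
             paste(unknown, collapse = ", "))
    module@exposed <- union(module@exposed, speciesIds)
    module
}

#' Compose modules by unifying common species
#'
#' Common species (ports shared by name, or via a synonym table mapping
#' module-local ids to unified ids) become a single species row; private
#' species stay distinct and are prefixed with `<module>.` when their ids
#' collide across modules. Reaction columns are the union of all module
#' reactions, in module order. Every common species must be exposed in each
#' module that contains it.
#'
#' Species constants and amounts of a common species must agree across
#' modules (or be NA in all but one); disagreement is an error, not a
#' silent overwrite.
#'
#' @param modules list of [NetworkModule-class].
#' @param common character vector of unified species ids to share.
#' @param synonyms optional named character vector mapping module-local
#'   species ids to unified ids (applied before matching).
#' @return The composed [StoichiometricNetwork-class].
#' @export
composeModules <- function(modules, common = character(),
                           synonyms = character()) {
    stopifnot(all(vapply(modules, is, logical(1), "NetworkModule")))
    nms <- vapply(modules, function(m) m@name, character(1))
    if (anyDuplicated(nms)) stop("module names must be unique")
    rename <- function(ids) {
        hit <- ids %in% names(synonyms)
        ids[hit] <- unname(synonyms[ids[hit]])
        ids
    }
    # per-module: unified species ids and exposure check
    uids <- lapply(modules, function(m) rename(m@network@species$id))
    for (k in seq_along(modules)) {
        present <- intersect(common, uids[[k]])
        exposed <- rename(modules[[k]]@exposed)
        miss <- setdiff(present, exposed)
        if (length(miss))
            stop("module '", nms[k], "': common species not exposed: ",
                 paste(miss, collapse = ", "))
    }
    # resolve private-species collisions by module prefixing
    priv <- lapply(seq_along(modules),
                   function(k) setdiff(uids[[k]], common))
    privAll <- unlist(priv)
    dup <- unique(privAll[duplicated(privAll)])
    finalIds <- uids
    for (k in seq_along(modules)) {
        clash <- finalIds[[k]] %in% dup & !(finalIds[[k]] %in% common)
        finalIds[[k]][clash] <- paste0(nms[k], ".", finalIds[[k]][clash])
    }
    # assemble reactions
    rx <- list()
    for (k in seq_along(modules)) {
        net <- modules[[k]]@network
        N <- stoichMatrix(net)
        map <- stats::setNames(finalIds[[k]], net@species$id)
        for (id in reactionIds(net)) {
            rid <- if (id %in% names(rx)) paste0(nms[k], ".", id) else id
            st <- N[, id]
            st <- st[st != 0]
            names(st) <- unname(map[names(st)])
            rx[[rid]] <- st
        }
    }
    order.sp <- unique(unlist(finalIds))
    out <- stoichiometricNetwork(rx, species = order.sp)
    # merge species metadata, checking agreement on common species
    K <- stats::setNames(rep(NA_real_, length(order.sp)), order.sp)
    x0 <- stats::setNames(rep(NA_real_, length(order.sp)), order.sp)
    for (k in seq_along(modules)) {
        sp <- modules[[k]]@network@species
        for (i in seq_len(nrow(sp))) {
            uid <- finalIds[[k]][i]
            for (field in c("K", "x0")) {
                val <- sp[[field]][i]
                cur <- if (field == "K") K[uid] else x0[uid]
                if (is.na(val)) next
                if (!is.na(cur) && uid %in% common &&
                    abs(cur - val) > 1e-12)
                    stop("common species '", uid, "': modules disagree on ",
                         field, " (", cur, " vs ", val, ")")
                if (field == "K") K[uid] <- val else x0[uid] <- val
            }
        }
    }
    out@species$K <- unname(K)
    out@species$x0 <- ifelse(is.na(x0), 1, unname(x0))
    # carry reaction parameters
    pos <- 0L
    for (k in seq_along(modules)) {
        net <- modules[[k]]@network
        idx <- pos + seq_len(nReactions(net))
        for (colnm in c("kinetics", "kappa", "fmax", "Kf", "rho",
                        "flowstat", "flowstatValue"))
            out@reactions[[colnm]][idx] <- net@reactions[[colnm]]
        pos <- pos + nReactions(net)
    }
    validObject(out)
    out
}
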