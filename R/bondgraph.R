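#' Build a bond graph from a stoichiometric network
#'
#' For every species, a `Ce` component bonded to its own `0` junction; for
#' every reaction, an `Re` component with a `1` junction on the forward
#' port and another on the reverse port. Each negative entry `N[i, j]`
#' contributes a bond of weight `|N[i, j]|` from the species' `0` junction
#' into the forward `1` junction of reaction `j`; each positive entry a
#' bond of weight `N[i, j]` from the reverse `1` junction back to the
#' species' `0` junction. Coefficients above one are stored as integer bond
#' weights (multiplicity), not duplicated bond records.
#'
#' @param net a [StoichiometricNetwork-class] (integer stoichiometry).
#' @return A [BondGraph-class].
#' @examples
#' bg <- buildBondGraph(stoichiometricNetwork(list(r1 = c(A = -1, B = 2))))
#' bondCount(bg)  # 7 = 2 Ce bonds + 2 Re port bonds + 1 + 2 stoichiometry
#' @export
buildBondGraph <- function(net) {
    N <- stoichMatrix(net)
    sid <- speciesIds(net)
    rid <- reactionIds(net)
    cmpOf <- function(prefix, type, refs)
        data.frame(id = paste0(prefix, refs, recycle0 = TRUE),
                   type = rep(type, length(refs)),
                   ref = refs, stringsAsFactors = FALSE)
    cmp <- rbind(
        cmpOf("Ce:", "Ce", sid),
        cmpOf("0:", "J0", sid),
        cmpOf("Re:", "Re", rid),
        cmpOf("1f:", "J1", rid),
        cmpOf("1r:", "J1", rid))
    bondOf <- function(tail, head, port, n)
        data.frame(tail = tail, head = head, weight = rep(1L, n),
                   port = rep(port, n), stringsAsFactors = FALSE)
    bonds <- list(
        bondOf(paste0("0:", sid, recycle0 = TRUE),
               paste0("Ce:", sid, recycle0 = TRUE),
               NA_character_, length(sid)),
        bondOf(paste0("1f:", rid, recycle0 = TRUE),
               paste0("Re:", rid, recycle0 = TRUE), "f", length(rid)),
        bondOf(paste0("Re:", rid, recycle0 = TRUE),
               paste0("1r:", rid, recycle0 = TRUE), "r", length(rid)))
    nz <- which(N != 0, arr.ind = TRUE)
    if (nrow(nz)) {
        val <- N[nz]
        bonds <- c(bonds, list(data.frame(
            tail = ifelse(val < 0, paste0("0:", sid[nz[, 1]]),
                          paste0("1r:", rid[nz[, 2]])),
            head = ifelse(val < 0, paste0("1f:", rid[nz[, 2]]),
                          paste0("0:", sid[nz[, 1]])),
            weight = as.integer(abs(val)),
            port = NA_character_)))
    }
    bnd <- do.call(rbind, bonds)
    rownames(bnd) <- NULL
    new("BondGraph", components = cmp, bonds = bnd,
        species = net@species, reactions = net@reactions)
}

#' Bond and component counts
#'
#' `bondCount()` counts bonds with multiplicity (a weight-w bond counts w
#' times), matching the per-coefficient construction; `componentCounts()`
#' tabulates component types.
#'
#' @param bg a [BondGraph-class].
#' @return integer (count) or named integer vector (per type).
#' @export
bondCount <- function(bg) {
    sum(bg@bonds$weight)
}

#' @rdname bondCount
#' @export
componentCounts <- function(bg) {
    table(factor(bg@components$type, levels = c("Ce", "Re", "J0", "J1")))
}

#' Recover the stoichiometric network from a bond graph
#'
#' Exact inverse of [buildBondGraph()]: reads the weighted bonds between
#' `0` junctions and the forward/reverse `1` junctions back into the signed
#' integer matrix, and restores the species/reaction parameter tables.
#'
#' @param bg a [BondGraph-class].
#' @return A [StoichiometricNetwork-class].
#' @export
stoichiometryFromBondGraph <- function(bg) {
    cmp <- bg@components
    bnd <- bg@bonds
    sid <- cmp$ref[cmp$type == "Ce"]
    rid <- cmp$ref[cmp$type == "Re"]
    # every Re must have both port bonds
    for (id in rid) {
        hasf <- any(bnd$port == "f" & bnd$head == paste0("Re:", id),
                    na.rm = TRUE)
        hasr <- any(bnd$port == "r" & bnd$tail == paste0("Re:", id),
                    na.rm = TRUE)
        if (!hasf || !hasr)
            stop("malformed bond graph: Re component '", id,
                 "' is missing a port bond")
    }
    N <- matrix(0, length(sid), length(rid), dimnames = list(sid, rid))
    stoichBonds <- bnd[is.na(bnd$port) &
                       !(grepl("^0:", bnd$tail) & grepl("^Ce:", bnd$head)), ,
                       drop = FALSE]
    for (k in seq_len(nrow(stoichBonds))) {
        b <- stoichBonds[k, ]
        if (grepl("^0:", b$tail)) {        # species -> forward junction
            sp <- sub("^0:", "", b$tail)
            rx <- sub("^1f:", "", b$head)
            N[sp, rx] <- N[sp, rx] - b$weight
        } else {                           # reverse junction -> species
            sp <- sub("^0:", "", b$head)
            rx <- sub("^1r:", "", b$tail)
            N[sp, rx] <- N[sp, rx] + b$weight
        }
    }
    new("StoichiometricNetwork", species = bg@species,
        reactions = bg@reactions, stoich = N)
}

setMethod("show", "BondGraph", function(object) {
    cc <- componentCounts(object)
    cat("BondGraph:", paste(cc, names(cc), collapse = ", "),
        "|", bondCount(object), "bonds\n")
    invisible(NULL)
})
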