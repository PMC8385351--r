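#' Read and write stoichiometric models
#'
#' `loadModel()` dispatches on `format` (or guesses from the file
#' extension): `"reaction_list"` (the plain-text dialect below), `"sbml"`
#' (SBML Level 3 core, read with xml2) or `"cobra_json"` (COBRA-style JSON).
#' Species and reactions keep their file order; nothing is sorted, so the
#' stoichiometric matrix is reproducible.
#'
#' The reaction-list dialect has one reaction per line,
#' `id: 2 A + B <-> C`, with `<->` mandatory (every reaction is treated as
#' reversible -- direction is a property of the state, not the network).
#' Blank lines and `#` comments are ignored. Species tokens may start with a
#' digit (`13DPG`); a coefficient is a standalone numeric token.
#'
#' Fractional stoichiometries are rejected by default, naming the reaction;
#' with `scaleFractions = TRUE` each offending reaction is scaled by the
#' least common denominator (denominators above `maxDenominator` are still
#' rejected).
#'
#' @param path file path.
#' @param format one of `"reaction_list"`, `"sbml"`, `"cobra_json"`, or
#'   `NULL` to guess from the extension.
#' @param scaleFractions scale reactions with fractional coefficients to
#'   integers instead of rejecting them.
#' @param maxDenominator largest denominator accepted when scaling.
#' @return A [StoichiometricNetwork-class].
#' @export
loadModel <- function(path, format = NULL, scaleFractions = FALSE,
                      maxDenominator = 12L) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(format)) {
        format <- switch(tolower(tools::file_ext(path)),
                         xml = , sbml = "sbml",
                         json = "cobra_json",
                         "reaction_list")
    }
    raw <- switch(format,
        reaction_list = .readReactionList(path),
        sbml = .readSBML(path),
        cobra_json = .readCobraJSON(path),
        stop("unknown format: ", format))
    .finishModel(raw, scaleFractions, maxDenominator)
}

#' @rdname loadModel
#' @param net network to write.
#' @export
writeModel <- function(net, path) {
    N <- stoichMatrix(net)
    lines <- vapply(reactionIds(net), function(id) {
        st <- N[, id]
        renderReaction(st[st != 0], id = id)
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

.finishModel <- function(raw, scaleFractions, maxDenominator) {
    # raw: list(reactions = named list of named numeric, names = named chr)
    rx <- raw$reactions
    for (id in names(rx)) {
        st <- rx[[id]]
        if (any(st != round(st))) {
            dens <- vapply(st, .denominator, numeric(1),
                           maxDenominator = maxDenominator)
            if (anyNA(dens))
                stop("reaction ", id, ": non-integer stoichiometry beyond ",
                     "denominator bound ", maxDenominator)
            if (!scaleFractions)
                stop("reaction ", id, ": fractional stoichiometry ",
                     "(set scaleFractions = TRUE to scale)")
            l <- 1
            for (d in unique(dens)) l <- l / .gcd2(l, d) * d
            rx[[id]] <- st * l
        }
    }
    net <- stoichiometricNetwork(rx, species = raw$species,
                                 names = raw$names)
    net
}

.denominator <- function(x, maxDenominator) {
    for (d in seq_len(maxDenominator))
        if (abs(x * d - round(x * d)) < 1e-9) return(d)
    NA_real_
}

.readReactionList <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    rx <- list()
    for (ln in lines) {
        parts <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
        if (length(parts) != 2)
            stop("malformed reaction line (missing 'id:'): ", ln)
        id <- trimws(parts[1])
        body <- parts[2]
        if (id %in% names(rx)) stop("duplicate reaction id: ", id)
        sides <- strsplit(body, "<->", fixed = TRUE)[[1]]
        if (length(sides) != 2)
            stop("reaction ", id, ": '<->' is mandatory")
        st <- c(.parseSide(sides[1], -1, id), .parseSide(sides[2], +1, id))
        rx[[id]] <- .aggregateStoich(st)
    }
    list(reactions = rx, species = NULL, names = NULL)
}

.parseSide <- function(side, sign, id) {
    side <- trimws(side)
    if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
    out <- numeric(0)
    for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
        if (!nzchar(term)) stop("reaction ", id, ": empty term")
        toks <- strsplit(term, "[[:space:]]+")[[1]]
        if (length(toks) == 1) {
            coef <- 1; spid <- toks
        } else if (length(toks) == 2 &&
                   grepl("^[0-9]*\\.?[0-9]+$", toks[1])) {
            coef <- as.numeric(toks[1]); spid <- toks[2]
        } else stop("reaction ", id, ": cannot parse term '", term, "'")
        out <- c(out, stats::setNames(sign * coef, spid))
    }
    out
}

.readCobraJSON <- function(path) {
    m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    sids <- vapply(m$metabolites, function(s) s$id, character(1))
    snames <- vapply(m$metabolites,
                     function(s) if (!is.null(s$name)) s$name else s$id,
                     character(1))
    if (anyDuplicated(sids)) stop("duplicate species ids in ", path)
    rx <- list()
    for (r in m$reactions) {
        if (r$id %in% names(rx)) stop("duplicate reaction id: ", r$id)
        st <- unlist(r$metabolites)
        rx[[r$id]] <- st
    }
    list(reactions = rx, species = sids,
         names = stats::setNames(snames, sids))
}

.readSBML <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    spnodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
    sids <- xml2::xml_attr(spnodes, "id")
    snames <- xml2::xml_attr(spnodes, "name")
    snames[is.na(snames)] <- sids[is.na(snames)]
    if (anyDuplicated(sids)) stop("duplicate species ids in ", path)
    rxnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
    rx <- list()
    for (node in rxnodes) {
        id <- xml2::xml_attr(node, "id")
        if (id %in% names(rx)) stop("duplicate reaction id: ", id)
        st <- numeric(0)
        for (side in c("listOfReactants", "listOfProducts")) {
            refs <- xml2::xml_find_all(
                node, paste0("./", side, "/speciesReference"))
            if (!length(refs)) next
            sp <- xml2::xml_attr(refs, "species")
            co <- xml2::xml_attr(refs, "stoichiometry")
            co <- ifelse(is.na(co), 1, as.numeric(co))
            if (side == "listOfReactants") co <- -co
            st <- c(st, stats::setNames(co, sp))
        }
        rx[[id]] <- .aggregateStoich(st)
    }
    list(reactions = rx, species = sids,
         names = stats::setNames(snames, sids))
}

#' Serialize a bond graph to JSON
#'
#' Writes the component and bond tables plus the species/reaction parameter
#' tables as a single JSON document.
#'
#' @param bg a [BondGraph-class].
#' @param path output file, or `NULL` to return the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
writeBondGraphJSON <- function(bg, path = NULL) {
    doc <- list(components = bg@components, bonds = bg@bonds,
                species = bg@species, reactions = bg@reactions)
    js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
    if (is.null(path)) return(as.character(js))
    writeLines(js, path)
    invisible(path)
}

# sum repeated species mentions, preserving first-occurrence order
.aggregateStoich <- function(st) {
    ids <- unique(names(st))
    stats::setNames(vapply(ids, function(s) sum(st[names(st) == s]),
                           numeric(1)), ids)
}
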