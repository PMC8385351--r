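#' Split a stoichiometric matrix into forward and reverse parts
#'
#' `N = Nr - Nf`, where `Nf` holds the reactant coefficients (the negated
#' negative entries of `N`) and `Nr` the product coefficients (the positive
#' entries). Both are nonnegative integer matrices with disjoint support.
#'
#' @param N integer stoichiometric matrix.
#' @return list with elements `Nf` and `Nr`.
#' @examples
#' decomposeStoichiometry(matrix(c(-1, 2), 2, 1))
#' @export
decomposeStoichiometry <- function(N) {
    N <- as.matrix(N)
    off <- which(N != round(N), arr.ind = TRUE)
    if (nrow(off))
        stop("non-integer stoichiometry at [", off[1, 1], ",", off[1, 2],
             "]: ", N[off[1, 1], off[1, 2]])
    list(Nf = pmax(-N, 0), Nr = pmax(N, 0))
}

#' Reaction potentials from species potentials
#'
#' Computes the forward and reverse reaction potentials
#' \eqn{\Phi^f = (N^f)^T \phi}, \eqn{\Phi^r = (N^r)^T \phi} and the net
#' reaction potential \eqn{\Phi = -N^T \phi = \Phi^f - \Phi^r}.
#'
#' @param N integer stoichiometric matrix (species x reactions).
#' @param phi species potentials (mV), length `nrow(N)`.
#' @return list with elements `Phi`, `Phif`, `Phir` (mV, length
#'   `ncol(N)`).
#' @export
reactionPotentials <- function(N, phi) {
    N <- as.matrix(N)
    if (length(phi) != nrow(N))
        stop("phi has length ", length(phi), " but N has ", nrow(N), " rows")
    d <- decomposeStoichiometry(N)
    Phif <- drop(crossprod(d$Nf, phi))
    Phir <- drop(crossprod(d$Nr, phi))
    nm <- colnames(N)
    out <- list(Phi = stats::setNames(Phif - Phir, nm),
                Phif = stats::setNames(Phif, nm),
                Phir = stats::setNames(Phir, nm))
    out
}

#' Species rate of change from reaction flows
#'
#' \eqn{\dot x = N f}.
#'
#' @param N stoichiometric matrix.
#' @param f reaction flows, length `ncol(N)`.
#' @return numeric vector of length `nrow(N)`.
#' @export
speciesRate <- function(N, f) {
    N <- as.matrix(N)
    if (length(f) != ncol(N))
        stop("f has length ", length(f), " but N has ", ncol(N), " columns")
    stats::setNames(drop(N %*% f), rownames(N))
}
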