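# Exact integer right null space via rational Gauss-Jordan elimination.
#
# Entries are kept as exact integer numerator/denominator pairs stored in
# doubles (all values arising from small stoichiometric matrices stay far
# below 2^53, and every step reduces by the gcd), so the reduced row echelon
# form and the resulting basis are exact, not floating approximations.

.gcd2 <- function(a, b) {
    a <- abs(a); b <- abs(b)
    while (b > 0.5) { t <- b; b <- a %% b; a <- t }
    a
}

.gcdv <- function(v) {
    g <- 0
    for (x in v) {
        g <- .gcd2(g, x)
        if (g == 1) break
    }
    g
}

#' Integer basis of the right null space
#'
#' Computes an exact integer basis of \eqn{\{v : M v = 0\}} for an
#' integer-valued matrix `M`, by rational reduced-row-echelon elimination.
#' Each basis column is scaled to coprime integer entries and its sign is
#' fixed so that the first nonzero entry (in row order) is positive; columns
#' are ordered by the row index of their first nonzero entry.
#'
#' @param M integer-valued matrix.
#' @return integer matrix with `ncol(M)` rows, one column per null-space
#'   dimension (zero columns when the null space is trivial: the matrix then
#'   has 0 columns).
#' @examples
#' cyc <- cbind(c(-1, 1, 0), c(0, -1, 1), c(1, 0, -1))
#' integerNullspace(cyc)  # the (1,1,1) loop
#' @export
integerNullspace <- function(M) {
    M <- as.matrix(M)
    if (any(M != round(M))) stop("matrix must be integer-valued")
    m <- nrow(M); n <- ncol(M)
    num <- M; den <- matrix(1, m, n)
    pivots <- integer(0)       # pivot column per pivot row
    r <- 1L
    for (col in seq_len(n)) {
        if (r > m) break
        # partial pivot: first row >= r with nonzero entry in this column
        hit <- which(num[r:m, col] != 0)
        if (!length(hit)) next
        p <- r + hit[1] - 1L
        if (p != r) {
            num[c(r, p), ] <- num[c(p, r), ]
            den[c(r, p), ] <- den[c(p, r), ]
        }
        # scale pivot row to make pivot exactly 1
        pn <- num[r, col]; pd <- den[r, col]
        for (j in seq_len(n)) {
            a <- num[r, j] * pd; b <- den[r, j] * pn
            if (a == 0) { num[r, j] <- 0; den[r, j] <- 1 }
            else {
                s <- sign(b); a <- a * s; b <- b * s
                g <- .gcd2(a, b)
                num[r, j] <- a / g; den[r, j] <- b / g
            }
        }
        # eliminate the column from every other row
        for (i in seq_len(m)) {
            if (i == r || num[i, col] == 0) next
            fn <- num[i, col]; fd <- den[i, col]
            for (j in seq_len(n)) {
                if (num[r, j] == 0) next
                a <- num[i, j] * fd * den[r, j] - fn * num[r, j] * den[i, j]
                b <- den[i, j] * fd * den[r, j]
                if (a == 0) { num[i, j] <- 0; den[i, j] <- 1 }
                else {
                    s <- sign(b); a <- a * s; b <- b * s
                    g <- .gcd2(a, b)
                    num[i, j] <- a / g; den[i, j] <- b / g
                }
            }
        }
        pivots <- c(pivots, col)
        r <- r + 1L
    }
    free <- setdiff(seq_len(n), pivots)
    K <- matrix(0, n, length(free))
    for (k in seq_along(free)) {
        fcol <- free[k]
        vn <- numeric(n); vd <- rep(1, n)
        vn[fcol] <- 1
        for (pr in seq_along(pivots)) {
            vn[pivots[pr]] <- -num[pr, fcol]
            vd[pivots[pr]] <- den[pr, fcol]
        }
        # clear denominators (lcm) then reduce to coprime integers
        l <- 1
        for (d in unique(vd)) l <- l / .gcd2(l, d) * d
        v <- vn * (l / vd)
        g <- .gcdv(v)
        if (g > 1) v <- v / g
        nz <- which(v != 0)[1]
        if (!is.na(nz) && v[nz] < 0) v <- -v
        K[, k] <- v
    }
    if (ncol(K) > 1) {
        first <- apply(K, 2, function(v) which(v != 0)[1])
        K <- K[, order(first), drop = FALSE]
    }
    rownames(K) <- colnames(M)
    storage.mode(K) <- "double"
    stopifnot(all(M %*% K == 0))
    K
}
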