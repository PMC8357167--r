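# Independent brute-force oracles: plain double loops over offsets, no
# shared code with the package internals.

bruteDiscCount <- function(radius) {
    m <- floor(radius)
    sum(outer((-m:m)^2, (-m:m)^2, "+") <= radius^2)
}

bruteDiscOffsets <- function(radius) {
    m <- floor(radius)
    g <- expand.grid(dr = -m:m, dc = -m:m)
    g[g$dr^2 + g$dc^2 <= radius^2, ]
}

bruteSums <- function(cells, s) {
    nr <- nrow(cells); nc <- ncol(cells)
    m <- floor(2 * s)
    N1 <- N2 <- matrix(0L, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        for (dr in -m:m) for (dc in -m:m) {
            d2 <- dr * dr + dc * dc
            if (d2 <= 4 * s * s) {
                v <- cells[(r - 1 + dr) %% nr + 1, (c - 1 + dc) %% nc + 1]
                N2[r, c] <- N2[r, c] + v
                if (d2 <= s * s) N1[r, c] <- N1[r, c] + v
            }
        }
    }
    list(N1 = N1, N2 = N2)
}

bruteEdges <- function(cells, connectivity = 4) {
    nr <- nrow(cells); nc <- ncol(cells)
    offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    if (connectivity == 8)
        offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    bpos <- wpos <- matrix(integer(0), 0, 2)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        nb <- vapply(offs, function(o)
            cells[(r - 1 + o[1]) %% nr + 1, (c - 1 + o[2]) %% nc + 1], 0L)
        if (cells[r, c] == 1L && any(nb == 0L)) bpos <- rbind(bpos, c(r, c))
        if (cells[r, c] == 0L && any(nb == 1L)) wpos <- rbind(wpos, c(r, c))
    }
    list(black = bpos, white = wpos)
}

randCells <- function(nr, nc, p = 0.5) {
    matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}

posKey <- function(pos) sort(paste(pos[, 1], pos[, 2]))

# toroidal shift used by equivariance checks: entry (r, c) of the result
# is m[(r + dr) mod nr, (c + dc) mod nc]
shiftOracle <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[(seq_len(nr) - 1 + dr) %% nr + 1, (seq_len(nc) - 1 + dc) %% nc + 1,
      drop = FALSE]
}
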