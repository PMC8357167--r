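# Seeded pattern fixtures: every stochastic one is reproducible from its
# seed, so tests and demos need no stored data.

#' Random Bernoulli grid
#'
#' @param rows,cols grid shape.
#' @param density probability a cell is black.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return A \linkS4class{BinaryGrid}.
#' @export
randomGrid <- function(rows = 40L, cols = 40L, density = 0.5, seed = NULL) {
    if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
        density < 0 || density > 1)
        invalidParameter("density must lie in [0, 1]")
    rows <- as.integer(rows); cols <- as.integer(cols)
    cells <- .withSeed(seed,
        matrix(as.integer(stats::runif(rows * cols) < density), rows, cols))
    new("BinaryGrid", cells = cells)
}

#' Checkerboard grid
#'
#' Alternating block x block tiles, black tile at the origin. A
#' checkerboard is the canonical pattern the automaton cannot reproduce:
#' its alternation is faster than any disc filter can track.
#'
#' @param rows,cols grid shape; \code{block} must divide both.
#' @param block tile side length.
#' @return A \linkS4class{BinaryGrid}.
#' @export
checkerboardGrid <- function(rows, cols, block = 1L) {
    rows <- as.integer(rows); cols <- as.integer(cols)
    block <- as.integer(block)
    if (is.na(block) || block < 1L)
        invalidParameter("block must be a positive integer")
    if (rows %% block != 0L || cols %% block != 0L)
        invalidParameter("block must divide both rows and cols")
    tr <- (seq_len(rows) - 1L) %/% block
    tc <- (seq_len(cols) - 1L) %/% block
    BinaryGrid(outer(tr, tc, function(a, b) as.integer((a + b) %% 2L == 0L)))
}

#' Striped grid
#'
#' Alternating bands of width ceiling(period/2), black band first, along
#' the chosen axis: \code{"vertical"} stripes vary across columns,
#' \code{"horizontal"} across rows.
#'
#' @param rows,cols grid shape.
#' @param period full period of the stripes (>= 2).
#' @param orientation \code{"vertical"} or \code{"horizontal"}.
#' @return A \linkS4class{BinaryGrid}.
#' @export
stripeGrid <- function(rows, cols, period, orientation = c("vertical", "horizontal")) {
    orientation <- match.arg(orientation)
    rows <- as.integer(rows); cols <- as.integer(cols)
    period <- as.integer(period)
    if (is.na(period) || period < 2L)
        invalidParameter("period must be an integer >= 2")
    band <- function(n) as.integer((seq_len(n) - 1L) %% period < ceiling(period / 2))
    cells <- if (orientation == "vertical")
        matrix(band(cols), rows, cols, byrow = TRUE)
    else
        matrix(band(rows), rows, cols)
    BinaryGrid(cells)
}
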