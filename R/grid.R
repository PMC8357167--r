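#' Construct a BinaryGrid
#'
#' Wraps a 0/1 matrix (logical matrices are accepted and coerced) into a
#' \linkS4class{BinaryGrid}. State 1 is black, state 0 white; the lattice is
#' a torus: both axes wrap.
#'
#' @param cells matrix of 0/1 (or logical) cell states.
#' @return A \linkS4class{BinaryGrid}.
#' @examples
#' g <- BinaryGrid(matrix(c(0, 1, 1, 0), 2, 2))
#' blackFraction(g)
#' @export
BinaryGrid <- function(cells) {
    if (is.logical(cells)) storage.mode(cells) <- "integer"
    if (!is.matrix(cells))
        invalidParameter("cells must be a matrix")
    if (is.double(cells)) {
        if (anyNA(cells) || any(cells != round(cells)))
            invalidParameter("cell states must be whole numbers 0 or 1")
        storage.mode(cells) <- "integer"
    }
    if (!is.integer(cells))
        invalidParameter("cell states must be numeric or logical")
    new("BinaryGrid", cells = cells)
}

#' @describeIn BinaryGrid grid dimensions, c(rows, cols).
#' @param x a BinaryGrid.
#' @export
setMethod("dim", "BinaryGrid", function(x) dim(x@cells))

#' @export
setMethod("show", "BinaryGrid", function(object) {
    d <- dim(object@cells)
    cat(sprintf("BinaryGrid: %d x %d torus, black fraction %.3f\n",
        d[1L], d[2L], mean(object@cells)))
    if (all(d <= 24L)) {
        glyph <- c("0" = ".", "1" = "#")
        apply(object@cells, 1L, function(r)
            cat(" ", paste(glyph[as.character(r)], collapse = ""), "\n",
                sep = ""))
    }
    invisible(NULL)
})

#' @export
setMethod("as.matrix", "BinaryGrid", function(x, ...) x@cells)

#' Cell-state matrix of a grid
#'
#' @param x a \linkS4class{BinaryGrid}.
#' @return Integer matrix of 0/1 states.
#' @export
gridCells <- function(x) {
    stopifnot(is(x, "BinaryGrid"))
    x@cells
}

#' Fraction of black (state-1) cells
#'
#' @param x a \linkS4class{BinaryGrid}.
#' @return A number in [0, 1].
#' @export
setGeneric("blackFraction", function(x) standardGeneric("blackFraction"))

#' @rdname blackFraction
#' @export
setMethod("blackFraction", "BinaryGrid", function(x) mean(x@cells))

#' Cyclically translate a grid on the torus
#'
#' Shifts every cell by (dr, dc) with wraparound; the cell at (r, c) moves
#' to ((r + dr) mod rows, (c + dc) mod cols).
#'
#' @param x a \linkS4class{BinaryGrid}.
#' @param dr,dc integer shifts along rows and columns.
#' @return The translated \linkS4class{BinaryGrid}.
#' @export
translateGrid <- function(x, dr = 0L, dc = 0L) {
    stopifnot(is(x, "BinaryGrid"))
    m <- x@cells
    nr <- nrow(m); nc <- ncol(m)
    ri <- (seq_len(nr) - 1L - dr) %% nr + 1L
    ci <- (seq_len(nc) - 1L - dc) %% nc + 1L
    BinaryGrid(m[ri, ci, drop = FALSE])
}

# toroidal shift of a raw matrix: entry (r, c) of the result is
# m[(r + dr) mod nr, (c + dc) mod nc] -- the neighbor at offset (dr, dc)
.shiftMat <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[(seq_len(nr) - 1L + dr) %% nr + 1L,
      (seq_len(nc) - 1L + dc) %% nc + 1L, drop = FALSE]
}

.componentStats <- function(cells, value, connectivity = 4L) {
    idx <- which(cells == value)
    if (length(idx) == 0L)
        return(list(n = 0L, sizes = integer(0), elongation = numeric(0)))
    nr <- nrow(cells); nc <- ncol(cells)
    vid <- integer(nr * nc)
    vid[idx] <- seq_along(idx)
    offs <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8L)
        offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    edges <- integer(0)
    for (o in offs) {
        r2 <- (rows - 1L + o[1L]) %% nr + 1L
        c2 <- (cols - 1L + o[2L]) %% nc + 1L
        j <- (c2 - 1L) * nr + r2
        keep <- cells[j] == value
        if (any(keep))
            edges <- c(edges, rbind(vid[idx[keep]], vid[j[keep]]))
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
    sizes <- as.integer(tabulate(memb))
    # boundary length of each component: black-white 4-adjacencies
    perim <- numeric(max(memb))
    for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        r2 <- (rows - 1L + o[1L]) %% nr + 1L
        c2 <- (cols - 1L + o[2L]) %% nc + 1L
        j <- (c2 - 1L) * nr + r2
        opp <- cells[j] != value
        if (any(opp)) {
            tab <- tapply(opp, memb, sum)
            perim[as.integer(names(tab))] <-
                perim[as.integer(names(tab))] + unname(tab)
        }
    }
    list(n = as.integer(max(memb)), sizes = sizes,
        elongation = perim^2 / (4 * pi * sizes))
}

#' Summarize a binary pattern
#'
#' Reports the black fraction, the number and mean size of 4-connected
#' components of each color on the torus, and a crude shape class. The class
#' uses the isoperimetric ratio P^2 / (4 pi A) of the minority-color
#' components (about 1.3-1.7 for rasterized discs; >= 2.5 for bands long
#' enough to wrap the torus): \code{"spots"} when the area-weighted mean
#' ratio is below 2, \code{"stripes"} otherwise; uniform grids are
#' \code{"uniform"}.
#'
#' @param x a \linkS4class{BinaryGrid}.
#' @param connectivity 4 (default) or 8.
#' @return A list with elements \code{blackFraction}, \code{blackComponents},
#'   \code{whiteComponents}, \code{meanBlackSize}, \code{meanWhiteSize},
#'   \code{class}.
#' @export
setGeneric("patternSummary", function(x, ...) standardGeneric("patternSummary"))

#' @rdname patternSummary
#' @param ... passed to methods.
#' @export
setMethod("patternSummary", "BinaryGrid", function(x, connectivity = 4L) {
    cells <- x@cells
    black <- .componentStats(cells, 1L, connectivity)
    white <- .componentStats(cells, 0L, connectivity)
    bf <- mean(cells)
    cls <- if (bf %in% c(0, 1)) {
        "uniform"
    } else {
        minority <- if (bf <= 0.5) black else white
        el <- sum(minority$elongation * minority$sizes) / sum(minority$sizes)
        if (el < 2) "spots" else "stripes"
    }
    list(blackFraction = bf,
        blackComponents = black$n,
        whiteComponents = white$n,
        meanBlackSize = if (black$n) mean(black$sizes) else 0,
        meanWhiteSize = if (white$n) mean(white$sizes) else 0,
        class = cls)
})
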