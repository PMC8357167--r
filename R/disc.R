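.discOffsets <- function(radius) {
    m <- floor(radius)
    g <- as.matrix(expand.grid(dr = -m:m, dc = -m:m, KEEP.OUT.ATTRS = FALSE))
    storage.mode(g) <- "integer"
    g[g[, 1L]^2 + g[, 2L]^2 <= radius^2, , drop = FALSE]
}

#' Build the paired disc filter for a radius
#'
#' The inner disc collects all integer offsets (dr, dc) with
#' dr^2 + dc^2 <= s^2, the outer disc those with dr^2 + dc^2 <= (2s)^2
#' (inclusive Euclidean membership, so fractional radii such as 4.5 work
#' naturally). By default the outer region is the full disc -- the inner
#' cells are part of it -- and the focal cell (0, 0) belongs to both.
#'
#' @param s inner radius, >= 1; the outer radius is fixed at 2s.
#' @param includeFocal if FALSE, drop the (0, 0) offset from both discs.
#' @param outer \code{"disc"} (default: the outer sum runs over the whole
#'   2s disc) or \code{"annulus"} (outer offsets strictly beyond radius s
#'   only), provided for sensitivity checks.
#' @return A \linkS4class{DiscPair}.
#' @examples
#' d <- discPair(3)
#' innerSize(d)  # 29
#' outerSize(d)  # 113
#' @export
discPair <- function(s, includeFocal = TRUE, outer = c("disc", "annulus")) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s))
        invalidParameter("s must be a single number")
    if (s < 1)
        invalidParameter("s must be >= 1: smaller radii leave edge-cell ratios ill-defined")
    outer <- match.arg(outer)
    inner <- .discOffsets(s)
    out <- .discOffsets(2 * s)
    if (outer == "annulus")
        out <- out[out[, 1L]^2 + out[, 2L]^2 > s^2, , drop = FALSE]
    if (!includeFocal) {
        inner <- inner[inner[, 1L] != 0L | inner[, 2L] != 0L, , drop = FALSE]
        out <- out[out[, 1L] != 0L | out[, 2L] != 0L, , drop = FALSE]
    }
    new("DiscPair", s = s, inner = inner, outer = out)
}

#' @describeIn discPair number of cells in the inner disc (S1).
#' @param x a DiscPair.
#' @export
innerSize <- function(x) nrow(x@inner)

#' @describeIn discPair number of cells in the outer region (S2).
#' @export
outerSize <- function(x) nrow(x@outer)

#' @describeIn discPair inner radius s.
#' @export
discRadius <- function(x) x@s

#' @export
setMethod("show", "DiscPair", function(object) {
    cat(sprintf("DiscPair: s = %g (outer radius %g), S1 = %d, S2 = %d\n",
        object@s, 2 * object@s, nrow(object@inner), nrow(object@outer)))
    invisible(NULL)
})

# accumulate offsets (mod grid shape) into a kernel matrix; offsets that
# wrap onto the same cell of a small grid add up, matching a direct count
.offsetKernel <- function(off, nr, nc) {
    r <- off[, 1L] %% nr
    c <- off[, 2L] %% nc
    matrix(tabulate(c * nr + r + 1L, nbins = nr * nc), nr, nc)
}

# circular convolution by FFT: exact periodic wrap; the disc kernels are
# symmetric under negation, so convolution equals the wanted correlation;
# counts are integers, so rounding removes FFT noise
.circularSum <- function(cells, kernel) {
    n <- length(cells)
    v <- round(Re(stats::fft(stats::fft(cells) * stats::fft(kernel),
        inverse = TRUE)) / n)
    storage.mode(v) <- "integer"
    v
}

#' Per-cell neighborhood sums under periodic wrap
#'
#' For every cell of the grid, counts the black (state-1) cells within the
#' inner disc (N1) and within the outer region (N2) of the filter, with both
#' axes wrapping. Equivalent to circular convolution of the state matrix
#' with the disc indicator, and computed that way (via FFT).
#'
#' @param x a \linkS4class{BinaryGrid}.
#' @param disc a \linkS4class{DiscPair}.
#' @return A \linkS4class{SumField}.
#' @export
setGeneric("neighborhoodSums", function(x, disc) standardGeneric("neighborhoodSums"))

#' @rdname neighborhoodSums
#' @export
setMethod("neighborhoodSums", signature("BinaryGrid", "DiscPair"),
    function(x, disc) {
        m <- x@cells
        nr <- nrow(m); nc <- ncol(m)
        n1 <- .circularSum(m, .offsetKernel(disc@inner, nr, nc))
        n2 <- .circularSum(m, .offsetKernel(disc@outer, nr, nc))
        new("SumField", inner = n1, outer = n2, s = disc@s)
    })

#' @describeIn neighborhoodSums matrix of inner-disc counts N1.
#' @export
innerSums <- function(x) x@inner

#' @describeIn neighborhoodSums matrix of outer-disc counts N2.
#' @export
outerSums <- function(x) x@outer

#' @export
setMethod("show", "SumField", function(object) {
    cat(sprintf("SumField: %d x %d, s = %g, N1 in [%d, %d], N2 in [%d, %d]\n",
        nrow(object@inner), ncol(object@inner), object@s,
        min(object@inner), max(object@inner),
        min(object@outer), max(object@outer)))
    invisible(NULL)
})
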