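#' Census of pattern-boundary cells
#'
#' Black edge cells are state-1 cells with at least one state-0 neighbor on
#' the torus; white edge cells are state-0 cells touching a state-1 cell.
#' The default adjacency is 4-connectivity (minimal contact); 8-connectivity
#' is available for sensitivity checks. A uniform grid yields an empty
#' census (operations downstream then raise a degenerate-input error).
#'
#' @param x a \linkS4class{BinaryGrid}.
#' @param connectivity 4 (default) or 8.
#' @return An \linkS4class{EdgeCensus}.
#' @export
setGeneric("boundaryCells", function(x, ...) standardGeneric("boundaryCells"))

#' @rdname boundaryCells
#' @param ... passed to methods.
#' @export
setMethod("boundaryCells", "BinaryGrid", function(x, connectivity = 4L) {
    if (!connectivity %in% c(4L, 8L))
        invalidParameter("connectivity must be 4 or 8")
    m <- x@cells
    offs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
    if (connectivity == 8L)
        offs <- c(offs, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
    hasWhiteNbr <- hasBlackNbr <- matrix(FALSE, nrow(m), ncol(m))
    for (o in offs) {
        nbr <- .shiftMat(m, o[1L], o[2L])
        hasWhiteNbr <- hasWhiteNbr | nbr == 0L
        hasBlackNbr <- hasBlackNbr | nbr == 1L
    }
    new("EdgeCensus",
        black = which(m == 1L & hasWhiteNbr, arr.ind = TRUE),
        white = which(m == 0L & hasBlackNbr, arr.ind = TRUE),
        gridDim = dim(m))
})

#' @describeIn boundaryCells number of black edge cells (alpha_t).
#' @export
alphaT <- function(x) nrow(x@black)

#' @describeIn boundaryCells number of white edge cells (beta_t).
#' @export
betaT <- function(x) nrow(x@white)

#' @export
setMethod("show", "EdgeCensus", function(object) {
    cat(sprintf("EdgeCensus: %d black and %d white edge cells on a %d x %d torus\n",
        nrow(object@black), nrow(object@white),
        object@gridDim[1L], object@gridDim[2L]))
    invisible(NULL)
})

#' Per-edge-cell N1/N2 ratios
#'
#' On the boundary between the two colors the update rule balances,
#' N1 = w N2, so the ratio N1/N2 at an edge cell is a local estimate of w.
#' Returns one row per edge cell with its position, color, sums and ratio.
#' With the default filter every edge cell has N1 >= 1 (it sees at least
#' one black cell within distance 1 <= s), so ratios lie in (0, 1].
#'
#' @param grid a \linkS4class{BinaryGrid}.
#' @param disc a \linkS4class{DiscPair} for the candidate radius.
#' @param census the grid's \linkS4class{EdgeCensus} (recomputed if omitted;
#'   edges do not depend on s, so compute it once per grid when scanning).
#' @return data.frame with columns row, col, state, n1, n2, ratio.
#' @export
edgeRatios <- function(grid, disc, census = boundaryCells(grid)) {
    stopifnot(is(grid, "BinaryGrid"), is(disc, "DiscPair"),
        is(census, "EdgeCensus"))
    sums <- neighborhoodSums(grid, disc)
    pos <- rbind(census@black, census@white)
    if (nrow(pos) == 0L)
        degenerateInput("uniform grid: no pattern edges, parameters unidentifiable")
    n1 <- sums@inner[pos]
    n2 <- sums@outer[pos]
    if (any(n2 == 0L))
        internalError("edge cell with empty outer disc (N2 = 0)")
    data.frame(row = pos[, 1L], col = pos[, 2L],
        state = rep(c(1L, 0L), c(nrow(census@black), nrow(census@white))),
        n1 = n1, n2 = n2, ratio = n1 / n2)
}

#' Pool edge ratios into a single w estimate
#'
#' The unweighted grand mean of N1/N2 over all edge cells of both colors
#' (the default); \code{"classMeans"} instead averages the black-edge mean
#' and the white-edge mean, weighting the two classes equally.
#'
#' @param ratios data.frame from \code{\link{edgeRatios}}.
#' @param method \code{"grand"} or \code{"classMeans"}.
#' @return The pooled w estimate.
#' @export
estimateW <- function(ratios, method = c("grand", "classMeans")) {
    method <- match.arg(method)
    if (nrow(ratios) == 0L)
        degenerateInput("no edge cells to average")
    if (method == "grand") mean(ratios$ratio)
    else mean(tapply(ratios$ratio, ratios$state, mean))
}

#' Edge-consistency index of a candidate (s, w)
#'
#' alpha counts black edge cells whose ratio N1/N2 strictly exceeds w, beta
#' counts white edge cells whose ratio is strictly below w; cells at exact
#' equality count toward neither (mirroring the unchanged band of the
#' forward rule). The index alpha/alpha_t + beta/beta_t lies in [0, 2] and
#' reaches 2 exactly when w strictly separates the black-edge from the
#' white-edge ratios -- the signature of the radius the pattern was made
#' with.
#'
#' @param ratios data.frame from \code{\link{edgeRatios}}.
#' @param w the candidate inhibition weight.
#' @return One-row data.frame with columns wHat (= w as passed), alpha,
#'   alphaT, beta, betaT, index.
#' @export
edgeIndex <- function(ratios, w) {
    black <- ratios$ratio[ratios$state == 1L]
    white <- ratios$ratio[ratios$state == 0L]
    if (length(black) == 0L || length(white) == 0L)
        degenerateInput("index needs edge cells of both colors")
    alpha <- sum(black > w)
    beta <- sum(white < w)
    data.frame(wHat = w, alpha = alpha, alphaT = length(black),
        beta = beta, betaT = length(white),
        index = alpha / length(black) + beta / length(white))
}

#' Jointly estimate (s, w) by a decreasing-radius scan
#'
#' For each candidate radius (scanned from large to small), pools the edge
#' ratios into a w estimate and scores the pair with the edge-consistency
#' index; the estimate is the candidate maximizing the index, ties resolved
#' to the larger radius (the first encountered). The edge census is
#' computed once: edges do not depend on s.
#'
#' @param grid a non-uniform \linkS4class{BinaryGrid}.
#' @param sValues candidate radii, all >= 1 (default 8 down to 2 in steps
#'   of 0.5); sorted descending internally.
#' @param connectivity edge adjacency, 4 (default) or 8.
#' @param wMethod ratio pooling, see \code{\link{estimateW}}.
#' @param includeFocal,outer filter variants, see \code{\link{discPair}}.
#' @return A \linkS4class{TuringScan}.
#' @examples
#' pat <- generatePattern(params = modelParams(5, 0.25), seed = 7)
#' est <- scanRadii(pat@final)
#' est@bestS
#' @export
scanRadii <- function(grid, sValues = seq(8, 2, by = -0.5),
        connectivity = 4L, wMethod = c("grand", "classMeans"),
        includeFocal = TRUE, outer = c("disc", "annulus")) {
    stopifnot(is(grid, "BinaryGrid"))
    wMethod <- match.arg(wMethod)
    outer <- match.arg(outer)
    if (length(sValues) == 0L || any(is.na(sValues)) || any(sValues < 1))
        invalidParameter("sValues must be non-empty with every candidate >= 1")
    sValues <- sort(unique(as.numeric(sValues)), decreasing = TRUE)
    census <- boundaryCells(grid, connectivity)
    if (nrow(census@black) == 0L || nrow(census@white) == 0L)
        degenerateInput("uniform grid: no pattern edges, parameters unidentifiable")
    rows <- lapply(sValues, function(s) {
        disc <- discPair(s, includeFocal = includeFocal, outer = outer)
        ratios <- edgeRatios(grid, disc, census)
        wHat <- estimateW(ratios, wMethod)
        cbind(s = s, edgeIndex(ratios, wHat))
    })
    tab <- do.call(rbind, rows)
    best <- which.max(tab$index)   # first max = largest s on ties
    new("TuringScan", bestS = tab$s[best], bestW = tab$wHat[best],
        table = tab)
}

#' @describeIn scanRadii estimated radius of a scan result.
#' @param x a TuringScan.
#' @export
bestS <- function(x) x@bestS

#' @describeIn scanRadii estimated inhibition weight of a scan result.
#' @export
bestW <- function(x) x@bestW

#' @describeIn scanRadii full scan table (one row per candidate radius).
#' @export
scanTable <- function(x) x@table

#' @export
setMethod("show", "TuringScan", function(object) {
    cat(sprintf("TuringScan: best s = %g, best w = %.4f over %d candidates\n",
        object@bestS, object@bestW, nrow(object@table)))
    print(object@table, row.names = FALSE, digits = 4)
    invisible(NULL)
})

#' Mimicry round trip: estimate parameters, regenerate the pattern
#'
#' Runs the radius scan on an observed pattern, then generates a fresh
#' pattern from a seeded random start using the estimated (s, w). The
#' regenerated pattern is statistically similar to the input -- not a
#' cell-by-cell copy -- when the input really is a pattern this automaton
#' can produce; on out-of-family inputs (a checkerboard, say) the round
#' trip completes but the output differs grossly.
#'
#' @param grid observed non-uniform \linkS4class{BinaryGrid}.
#' @param sValues candidate radii for the scan.
#' @param rows,cols shape of the regenerated grid (default: input shape).
#' @param initDensity initial black density of the random start.
#' @param seed seed for the random start.
#' @param maxSteps update budget for the regeneration.
#' @param ... further arguments for \code{\link{scanRadii}}.
#' @return List with elements \code{estimate} (\linkS4class{TuringScan})
#'   and \code{run} (\linkS4class{RunResult}).
#' @export
mimicPattern <- function(grid, sValues = seq(8, 2, by = -0.5),
        rows = nrow(gridCells(grid)), cols = ncol(gridCells(grid)),
        initDensity = 0.5, seed = NULL, maxSteps = 50L, ...) {
    est <- scanRadii(grid, sValues, ...)
    run <- generatePattern(rows, cols,
        modelParams(s = est@bestS, w = est@bestW),
        initDensity = initDensity, seed = seed, maxSteps = maxSteps)
    list(estimate = est, run = run)
}
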