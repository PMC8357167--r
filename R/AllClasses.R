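#' @import methods
NULL

.isWholeNumberMatrix <- function(m) {
    is.matrix(m) && (is.integer(m) || (is.numeric(m) && all(m == round(m))))
}

#' BinaryGrid: a toroidal lattice of black/white cell states
#'
#' The central data container of the package: a rows x cols matrix of cell
#' states in \{0, 1\} (1 = black, 0 = white) with toroidal topology -- both
#' axes wrap, so every cell has a full neighborhood. Indexing follows R
#' convention: 1-based \code{(row, col)}.
#'
#' @slot cells integer matrix of 0/1 states.
#' @aliases BinaryGrid-class
#' @exportClass BinaryGrid
setClass("BinaryGrid", slots = c(cells = "matrix"), validity = function(object) {
    m <- object@cells
    if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L)
        return("cells must be a non-empty matrix")
    if (!is.integer(m))
        return("cells must have integer storage mode")
    if (anyNA(m) || !all(m == 0L | m == 1L))
        return("every cell state must be exactly 0 or 1")
    TRUE
})

#' DiscPair: the paired disc convolution filter
#'
#' Holds the integer offsets of the inner (activating) disc of radius s and
#' the outer (inhibiting) disc of radius 2s, by inclusive Euclidean
#' membership dr^2 + dc^2 <= s^2 and <= (2s)^2. The filter is circular and
#' symmetric under negation of offsets and under axis swap.
#'
#' @slot s positive radius of the inner disc (outer radius is 2s).
#' @slot inner integer matrix, one (dr, dc) offset per row.
#' @slot outer integer matrix, one (dr, dc) offset per row.
#' @aliases DiscPair-class
#' @exportClass DiscPair
setClass("DiscPair",
    slots = c(s = "numeric", inner = "matrix", outer = "matrix"),
    validity = function(object) {
        if (length(object@s) != 1L || is.na(object@s) || object@s < 1)
            return("s must be a single number >= 1")
        for (nm in c("inner", "outer")) {
            off <- slot(object, nm)
            if (!.isWholeNumberMatrix(off) || ncol(off) != 2L || nrow(off) < 1L)
                return(sprintf("%s must be a non-empty two-column integer matrix", nm))
            key <- paste(off[, 1L], off[, 2L])
            if (anyDuplicated(key))
                return(sprintf("%s offsets must be unique", nm))
            if (!setequal(key, paste(-off[, 1L], -off[, 2L])))
                return(sprintf("%s offsets must be symmetric under negation", nm))
        }
        TRUE
    })

#' SumField: per-cell neighborhood sums
#'
#' For every cell of a grid, the count of black cells within the inner disc
#' (N1) and within the outer disc (N2) of a \linkS4class{DiscPair}, computed
#' under periodic wrap.
#'
#' @slot inner integer matrix of N1 values (same shape as the grid).
#' @slot outer integer matrix of N2 values.
#' @slot s the inner-disc radius used.
#' @aliases SumField-class
#' @exportClass SumField
setClass("SumField",
    slots = c(inner = "matrix", outer = "matrix", s = "numeric"),
    validity = function(object) {
        if (!identical(dim(object@inner), dim(object@outer)))
            return("inner and outer sum fields must have identical shape")
        if (anyNA(object@inner) || any(object@inner < 0))
            return("sums must be non-negative")
        TRUE
    })

#' ModelParams: the two pattern parameters plus the unchanged-band halfwidth
#'
#' s is the activation radius (in cells, >= 1, need not be an integer), w the
#' inhibition weight in (0, 1). band is the halfwidth b of the "unchanged"
#' band of the update rule: a cell keeps its state when
#' |N1 - w N2| <= b. The default b = 0 is the standard rule; b = 2 blurs the
#' pattern boundaries.
#'
#' @slot s activation radius.
#' @slot w inhibition weight.
#' @slot band unchanged-band halfwidth.
#' @aliases ModelParams-class
#' @exportClass ModelParams
setClass("ModelParams",
    slots = c(s = "numeric", w = "numeric", band = "numeric"),
    validity = function(object) {
        if (length(object@s) != 1L || is.na(object@s) || object@s < 1)
            return("s must be a single number >= 1")
        if (length(object@w) != 1L || is.na(object@w) ||
            object@w <= 0 || object@w >= 1)
            return("w must lie strictly between 0 and 1")
        if (length(object@band) != 1L || is.na(object@band) || object@band < 0)
            return("band must be non-negative")
        TRUE
    })

#' RunResult: outcome of iterating the automaton
#'
#' @slot final the terminal \linkS4class{BinaryGrid}.
#' @slot steps number of synchronous updates applied before termination
#'   (a grid that is already a fixed point reports 1: one update is performed
#'   to verify it).
#' @slot status one of \code{"fixed_point"}, \code{"cycle2"},
#'   \code{"max_steps"}.
#' @aliases RunResult-class
#' @exportClass RunResult
setClass("RunResult",
    slots = c(final = "BinaryGrid", steps = "integer", status = "character"),
    validity = function(object) {
        if (!object@status %in% c("fixed_point", "cycle2", "max_steps"))
            return("unknown status")
        if (length(object@steps) != 1L || object@steps < 0L)
            return("steps must be a single non-negative integer")
        TRUE
    })

#' EdgeCensus: pattern-boundary cells of both colors
#'
#' Black edge cells are state-1 cells with at least one state-0 neighbor
#' (4-connectivity on the torus by default); white edge cells are the
#' mirror image. Their counts are the alpha_t and beta_t denominators of
#' the edge-consistency index.
#'
#' @slot black two-column integer matrix of (row, col) positions.
#' @slot white two-column integer matrix of (row, col) positions.
#' @slot gridDim dimensions of the censused grid.
#' @aliases EdgeCensus-class
#' @exportClass EdgeCensus
setClass("EdgeCensus",
    slots = c(black = "matrix", white = "matrix", gridDim = "integer"))

#' TuringScan: result of the decreasing-s parameter scan
#'
#' One row per candidate radius, ordered by descending s, with the mean edge
#' ratio (the w estimate at that s), the alpha/beta counts and the
#' edge-consistency index; bestS/bestW belong to the index-maximizing row
#' (ties resolved to the larger s, the first encountered in the scan).
#'
#' @slot bestS estimated activation radius.
#' @slot bestW estimated inhibition weight.
#' @slot table data.frame with columns s, wHat, alpha, alphaT, beta, betaT,
#'   index.
#' @aliases TuringScan-class
#' @exportClass TuringScan
setClass("TuringScan",
    slots = c(bestS = "numeric", bestW = "numeric", table = "data.frame"))
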