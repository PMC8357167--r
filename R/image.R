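# Readers and writers for the supported formats, and the photograph ->
# model-grid preprocessing chain. Rendering convention throughout: state 1
# (black) <-> pixel 0, state 0 (white) <-> pixel 255. PBM follows its own
# convention (bit 1 = black), which coincides with the cell states.

.formatFromPath <- function(path) {
    switch(tolower(tools::file_ext(path)),
        txt = "text", pbm = "pbm", pgm = "pgm", png = "png",
        invalidParameter(sprintf(
            "cannot infer format from '%s' (use .txt, .pbm, .pgm or .png)",
            basename(path))))
}

# whitespace/comment-aware tokenizer shared by the PNM text formats
.pnmTokens <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    toks <- unlist(strsplit(paste(lines, collapse = " "), "[ \t\r]+"))
    toks[nzchar(toks)]
}

.readPBM <- function(path) {
    toks <- .pnmTokens(path)
    if (length(toks) < 3L || toks[1L] != "P1")
        invalidParameter("not a plain PBM (P1) file")
    w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
    bits <- unlist(strsplit(paste(toks[-(1:3)], collapse = ""), ""))
    if (length(bits) != w * h || !all(bits %in% c("0", "1")))
        invalidParameter("PBM raster does not match its dimensions")
    matrix(as.integer(bits), nrow = h, ncol = w, byrow = TRUE)
}

.writePBM <- function(cells, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P1", paste(ncol(cells), nrow(cells))), con)
    writeLines(apply(cells, 1L, paste, collapse = " "), con)
}

.readPGM <- function(path) {
    toks <- .pnmTokens(path)
    if (length(toks) < 4L || toks[1L] != "P2")
        invalidParameter("not a plain PGM (P2) file")
    w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
    maxval <- as.integer(toks[4L])
    px <- as.integer(toks[-(1:4)])
    if (length(px) != w * h || anyNA(px) || any(px < 0L | px > maxval))
        invalidParameter("PGM raster does not match its header")
    if (maxval != 255L)  # rescale to the 8-bit range the model expects
        px <- as.integer(round(px * 255 / maxval))
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

.writePGM <- function(pixels, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), "255"), con)
    writeLines(apply(pixels, 1L, paste, collapse = " "), con)
}

# PNG arrays from png::readPNG are [0,1] with 1-4 channels; collapse to
# 8-bit gray by integer luma for color inputs
.pngToGray <- function(a) {
    if (length(dim(a)) == 3L) {
        ch <- dim(a)[3L]
        a <- if (ch >= 3L)
            0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
        else a[, , 1L]
    }
    matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Read a grayscale image
#'
#' Supports 8-bit PGM (plain, P2) and PNG (color inputs are collapsed to
#' gray by integer luma 0.299 R + 0.587 G + 0.114 B).
#'
#' @param path file path; format inferred from the extension.
#' @return Integer matrix of brightness values 0-255.
#' @export
readGrayImage <- function(path) {
    switch(.formatFromPath(path),
        pgm = .readPGM(path),
        png = .pngToGray(png::readPNG(path)),
        invalidParameter("grayscale images must be .pgm or .png"))
}

#' Read a binary pattern grid
#'
#' Formats: plain text (one row per line, characters 0/1, trailing
#' whitespace tolerated), PBM (P1), PGM (P2) and PNG. For the grayscale
#' formats, dark pixels (< 128) map to state 1.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of \code{"text"}, \code{"pbm"}, \code{"pgm"},
#'   \code{"png"}.
#' @return A \linkS4class{BinaryGrid}.
#' @export
readGrid <- function(path, format = .formatFromPath(path)) {
    cells <- switch(format,
        text = {
            lines <- sub("[ \t\r]+$", "", readLines(path, warn = FALSE))
            lines <- lines[nzchar(lines)]
            if (length(lines) == 0L)
                invalidParameter("empty grid file")
            chars <- strsplit(lines, "")
            if (length(unique(lengths(chars))) != 1L)
                invalidParameter("ragged rows in text grid")
            if (!all(unlist(chars) %in% c("0", "1")))
                invalidParameter("text grid must contain only 0 and 1")
            do.call(rbind, lapply(chars, as.integer))
        },
        pbm = .readPBM(path),
        pgm = {
            g <- .readPGM(path)
            matrix(as.integer(g < 128L), nrow(g), ncol(g))
        },
        png = {
            g <- .pngToGray(png::readPNG(path))
            matrix(as.integer(g < 128L), nrow(g), ncol(g))
        },
        invalidParameter("unknown grid format"))
    BinaryGrid(cells)
}

#' Write a binary pattern grid
#'
#' @param grid a \linkS4class{BinaryGrid}.
#' @param path output path; format inferred from the extension unless given.
#' @param format one of \code{"text"}, \code{"pbm"}, \code{"pgm"},
#'   \code{"png"}.
#' @return \code{path}, invisibly.
#' @export
writeGrid <- function(grid, path, format = .formatFromPath(path)) {
    stopifnot(is(grid, "BinaryGrid"))
    cells <- grid@cells
    switch(format,
        text = writeLines(apply(cells, 1L, paste, collapse = ""), path),
        pbm = .writePBM(cells, path),
        pgm = .writePGM((1L - cells) * 255L, path),
        png = png::writePNG((1 - cells), path),
        invalidParameter("unknown grid format"))
    invisible(path)
}

#' Threshold a grayscale image to black and white
#'
#' A pixel becomes state 1 (black) exactly when its brightness is below the
#' threshold. Lowering the threshold therefore never adds black cells;
#' thresholds 100 and 25 give a permissive and a strict figure mask.
#'
#' @param image integer matrix of brightness values 0-255.
#' @param threshold cut in [0, 255].
#' @return A \linkS4class{BinaryGrid} at the image's full resolution.
#' @export
binarizeImage <- function(image, threshold) {
    if (!is.matrix(image) || anyNA(image) ||
        any(image < 0L) || any(image > 255L))
        invalidParameter("image must be a matrix of brightness values 0-255")
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 255)
        invalidParameter("threshold must lie in [0, 255]")
    BinaryGrid(matrix(as.integer(image < threshold), nrow(image), ncol(image)))
}

#' Downsample a binary image to a model grid
#'
#' Partitions the image into rows x cols area-proportional blocks (block
#' boundaries by rounding) and sets each cell to the majority state of its
#' block, ties going to black.
#'
#' @param grid full-resolution \linkS4class{BinaryGrid} (at least rows x
#'   cols).
#' @param rows,cols target mesh (default 40 x 40).
#' @return A rows x cols \linkS4class{BinaryGrid}.
#' @export
resampleToGrid <- function(grid, rows = 40L, cols = 40L) {
    stopifnot(is(grid, "BinaryGrid"))
    m <- grid@cells
    rows <- as.integer(rows); cols <- as.integer(cols)
    if (nrow(m) < rows || ncol(m) < cols)
        invalidParameter("image is smaller than the target mesh")
    rb <- round(seq(0, nrow(m), length.out = rows + 1L))
    cb <- round(seq(0, ncol(m), length.out = cols + 1L))
    out <- matrix(0L, rows, cols)
    for (i in seq_len(rows)) {
        ri <- (rb[i] + 1L):rb[i + 1L]
        for (j in seq_len(cols)) {
            blk <- m[ri, (cb[j] + 1L):cb[j + 1L], drop = FALSE]
            out[i, j] <- as.integer(mean(blk) >= 0.5)
        }
    }
    BinaryGrid(out)
}

#' Photograph to model grid
#'
#' The full preprocessing chain: read a grayscale image, threshold it, and
#' downsample to the model mesh.
#'
#' @param path image path (.pgm or .png).
#' @param threshold brightness cut in [0, 255].
#' @param rows,cols target mesh (default 40 x 40).
#' @return A \linkS4class{BinaryGrid}.
#' @export
preprocessImage <- function(path, threshold, rows = 40L, cols = 40L) {
    resampleToGrid(binarizeImage(readGrayImage(path), threshold), rows, cols)
}
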