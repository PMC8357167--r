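test_that("boundary census matches hand counts and the brute-force loop", {
    expect_identical(alphaT(boundaryCells(BinaryGrid(matrix(1L, 6, 6)))), 0L)
    expect_identical(betaT(boundaryCells(BinaryGrid(matrix(1L, 6, 6)))), 0L)

    single <- matrix(0L, 9, 9)
    single[5, 5] <- 1L
    cen <- boundaryCells(BinaryGrid(single))
    expect_identical(alphaT(cen), 1L)
    expect_identical(betaT(cen), 4L)
    expect_identical(betaT(boundaryCells(BinaryGrid(single),
        connectivity = 8)), 8L)

    # half-black field split by a vertical line: the torus makes two
    # boundaries, 40 black and 40 white cells along each
    half <- stripeGrid(40, 40, 40, "vertical")
    cenH <- boundaryCells(half)
    expect_identical(alphaT(cenH), 80L)
    expect_identical(betaT(cenH), 80L)

    set.seed(41)
    for (conn in c(4L, 8L)) {
        cells <- randCells(12, 14, 0.35)
        b <- bruteEdges(cells, conn)
        cen2 <- boundaryCells(BinaryGrid(cells), connectivity = conn)
        expect_identical(posKey(cen2@black), posKey(b$black))
        expect_identical(posKey(cen2@white), posKey(b$white))
    }
})

test_that("edge ratios are in (0, 1], translation-invariant, and 1 for an isolated cell", {
    single <- matrix(0L, 9, 9)
    single[5, 5] <- 1L
    g <- BinaryGrid(single)
    r <- edgeRatios(g, discPair(1))
    expect_identical(nrow(r), 5L)
    expect_true(all(r$ratio == 1))
    expect_equal(estimateW(r), 1)

    set.seed(42)
    g2 <- BinaryGrid(randCells(15, 15, 0.4))
    d <- discPair(3)
    r2 <- edgeRatios(g2, d)
    expect_true(all(r2$ratio > 0 & r2$ratio <= 1))
    r3 <- edgeRatios(translateGrid(g2, 3, 8), d)
    expect_equal(sort(r3$ratio), sort(r2$ratio))
})

test_that("alpha/beta counts match a brute-force loop and bound the index", {
    set.seed(43)
    for (rep in 1:3) {
        cells <- randCells(16, 16, 0.45)
        g <- BinaryGrid(cells)
        if (blackFraction(g) %in% c(0, 1)) next
        d <- discPair(2)
        r <- edgeRatios(g, d)
        w <- estimateW(r)
        row <- edgeIndex(r, w)
        # independent recount from brute-force sums and edges
        b <- bruteSums(cells, 2)
        e <- bruteEdges(cells)
        ratios <- b$N1 / b$N2
        expect_identical(row$alpha, sum(ratios[e$black] > w))
        expect_identical(row$beta, sum(ratios[e$white] < w))
        expect_identical(row$alphaT, nrow(e$black))
        expect_identical(row$betaT, nrow(e$white))
        expect_gte(row$index, 0)
        expect_lte(row$index, 2)
    }
})

test_that("index limits behave as the separability score demands", {
    set.seed(44)
    g <- BinaryGrid(randCells(20, 20, 0.4))
    r <- edgeRatios(g, discPair(3))
    # w = 0: every black-edge ratio exceeds it, no white-edge ratio is below
    expect_equal(edgeIndex(r, 0)$index, 1)
    # w = 1: equality cells (ratio exactly 1) count toward neither side
    expect_lte(edgeIndex(r, 1)$index, 1)
    # a strictly separating w scores 2
    blackR <- r$ratio[r$state == 1]
    whiteR <- r$ratio[r$state == 0]
    if (min(blackR) > max(whiteR)) {
        mid <- (min(blackR) + max(whiteR)) / 2
        expect_equal(edgeIndex(r, mid)$index, 2)
    }
})

test_that("the decreasing-radius scan recovers the generating parameters", {
    hits <- 0L
    for (i in 1:10) {
        g <- generatePattern(params = modelParams(5, 0.25), seed = i)@final
        est <- scanRadii(g, seq(7.5, 3, by = -0.5))
        if (bestS(est) == 5) {
            hits <- hits + 1L
            expect_lt(abs(bestW(est) - 0.25), 0.03)
        }
    }
    expect_gte(hits, 9L)
})

test_that("recovery holds across the sustainable parameter grid", {
    for (w in c(0.25, 0.30)) for (s in 3:6) {
        hits <- 0L
        for (i in 1:5) {
            g <- generatePattern(params = modelParams(s, w),
                seed = 1000 * s + i)@final
            est <- scanRadii(g)
            if (bestS(est) == s) {
                hits <- hits + 1L
                expect_lte(abs(bestW(est) - w), 0.05)
            }
        }
        expect_gte(hits, 4L)
    }
    # large radii relative to the 40-cell domain: patterns still form at
    # w = 0.25 and the scan finds them most of the time
    for (s in 7:8) {
        hits <- sum(vapply(1:5, function(i) {
            g <- generatePattern(params = modelParams(s, 0.25),
                seed = 2000 * s + i)@final
            bestS(scanRadii(g)) == s
        }, NA))
        expect_gte(hits, 3L)
    }
})

test_that("scan handles single candidates, ties, and degenerate grids", {
    g <- generatePattern(params = modelParams(5, 0.25), seed = 3)@final
    one <- scanRadii(g, sValues = 5)
    expect_identical(nrow(scanTable(one)), 1L)
    expect_identical(bestS(one), 5)

    # an isolated cell gives index 0 at every radius; the tie resolves to
    # the largest candidate, first encountered in the descending scan
    single <- matrix(0L, 20, 20)
    single[5, 5] <- 1L
    tie <- scanRadii(BinaryGrid(single), sValues = c(1, 2, 3))
    expect_true(all(scanTable(tie)$index == scanTable(tie)$index[1]))
    expect_identical(bestS(tie), 3)

    expect_error(scanRadii(BinaryGrid(matrix(1L, 10, 10))),
        class = "degenerateInputError")
    expect_error(scanRadii(g, sValues = numeric(0)),
        class = "invalidParameterError")
})

test_that("the full scan of a 40x40 grid runs in interactive time", {
    g <- generatePattern(params = modelParams(5, 0.25), seed = 8)@final
    elapsed <- system.time(scanRadii(g))["elapsed"]
    expect_lt(elapsed, 60)
})

test_that("the mimicry round trip reproduces pattern statistics", {
    for (i in 1:2) {
        g <- generatePattern(params = modelParams(5, 0.25), seed = i)@final
        mm <- mimicPattern(g, seq(7.5, 3, by = -0.5), seed = i + 100)
        expect_identical(bestS(mm$estimate), 5)
        expect_lt(abs(blackFraction(mm$run@final) - blackFraction(g)), 0.1)
        expect_identical(patternSummary(mm$run@final)$class,
            patternSummary(g)$class)
    }
})
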