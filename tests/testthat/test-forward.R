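test_that("the update rule follows the activation/inhibition balance", {
    allOne <- BinaryGrid(matrix(1L, 40, 40))
    # 29 > 0.2 * 113 = 22.6: saturated black field is stable
    expect_identical(
        gridCells(turingStep(allOne, modelParams(3, 0.2))),
        gridCells(allOne))
    # 29 < 0.3 * 113 = 33.9: saturated black field bleaches entirely
    expect_true(all(gridCells(turingStep(allOne, modelParams(3, 0.3))) == 0L))
})

test_that("cells at exact balance keep their state", {
    # engineered neighborhood with N1 = 1, N2 = 4 at the center for s = 1:
    # one black cell at distance 1, three more at distance 2
    cells <- matrix(0L, 9, 9)
    cells[5, 6] <- 1L
    cells[5, 3] <- cells[3, 5] <- cells[7, 5] <- 1L
    sf <- neighborhoodSums(BinaryGrid(cells), discPair(1))
    expect_identical(innerSums(sf)[5, 5], 1L)
    expect_identical(outerSums(sf)[5, 5], 4L)
    # w = 0.25: 1 == 4 * 0.25, the unchanged branch; the white center stays
    nxt <- turingStep(BinaryGrid(cells), modelParams(1, 0.25))
    expect_identical(gridCells(nxt)[5, 5], 0L)
    # same sums with a black center: N1 = 2, N2 = 5, 2 > 1.25, stays black
    cells2 <- cells; cells2[5, 5] <- 1L
    nxt2 <- turingStep(BinaryGrid(cells2), modelParams(1, 0.25))
    expect_identical(gridCells(nxt2)[5, 5], 1L)
})

test_that("a wide unchanged band freezes any grid", {
    set.seed(31)
    g <- BinaryGrid(randCells(20, 20))
    d <- discPair(3)
    frozen <- turingStep(g, modelParams(3, 0.25, band = outerSize(d)), d)
    expect_identical(gridCells(frozen), gridCells(g))
})

test_that("run termination distinguishes fixed points, 2-cycles and budget", {
    allOne <- BinaryGrid(matrix(1L, 40, 40))
    r <- runToSteady(allOne, modelParams(3, 0.2))
    expect_identical(r@status, "fixed_point")
    expect_identical(r@steps, 1L)   # one update performed to verify

    r2 <- runToSteady(allOne, modelParams(3, 0.3))
    expect_identical(r2@status, "fixed_point")
    expect_lte(r2@steps, 3L)
    expect_true(all(gridCells(r2@final) == 0L))

    # 2x2 checkerboard at s = 1, w = 0.3 alternates with its complement
    cb <- checkerboardGrid(2, 2, 1)
    r3 <- runToSteady(cb, modelParams(1, 0.3))
    expect_identical(r3@status, "cycle2")
    flip <- turingStep(cb, modelParams(1, 0.3))
    expect_identical(gridCells(flip), 1L - gridCells(cb))

    r4 <- runToSteady(BinaryGrid(randCells(30, 30)), modelParams(5, 0.25),
        maxSteps = 1L)
    expect_identical(r4@status, "max_steps")
    expect_identical(r4@steps, 1L)
})

test_that("seeded generation is reproducible and validates inputs", {
    p <- modelParams(5, 0.3)
    a <- generatePattern(20, 20, p, seed = 99)
    b <- generatePattern(20, 20, p, seed = 99)
    expect_identical(gridCells(a@final), gridCells(b@final))
    c <- generatePattern(20, 20, p, seed = 100)
    expect_false(identical(gridCells(a@final), gridCells(c@final)))

    # generation does not disturb the caller's RNG stream
    set.seed(5); before <- runif(3)
    set.seed(5); invisible(generatePattern(10, 10, p, seed = 1))
    expect_identical(runif(3), before)

    z <- generatePattern(15, 15, p, initDensity = 0, seed = 1)
    expect_true(all(gridCells(z@final) == 0L))
    expect_identical(z@steps, 1L)
    o <- generatePattern(15, 15, p, initDensity = 1, seed = 1)
    expect_true(all(gridCells(o@final) %in% c(0L, 1L)))

    expect_error(generatePattern(10, 10, p, initDensity = 1.2),
        class = "invalidParameterError")
    expect_error(modelParams(5, 1.1), class = "invalidParameterError")
    expect_error(modelParams(0.5, 0.3), class = "invalidParameterError")
})

test_that("small w saturates the field black; larger w leaves white cells", {
    bf15 <- vapply(1:10, function(i)
        blackFraction(generatePattern(params = modelParams(5, 0.15),
            seed = i)@final), 0)
    expect_true(all(bf15 == 1))
    bf30 <- vapply(1:10, function(i)
        blackFraction(generatePattern(params = modelParams(5, 0.30),
            seed = i)@final), 0)
    expect_true(all(bf30 < 1))
})

test_that("doubling the radius scales up the pattern features", {
    sizeAt <- function(s, i) patternSummary(
        generatePattern(params = modelParams(s, 0.3), seed = i)@final
    )$meanBlackSize
    m3 <- vapply(1:10, function(i) sizeAt(3, i), 0)
    m6 <- vapply(1:10, function(i) sizeAt(6, i), 0)
    expect_gt(mean(m6), mean(m3))
})

test_that("continuation tracks the patterned branch into the bistable regime", {
    r <- annealPattern(s = 5, wTarget = 0.2, seed = 4)
    bf <- blackFraction(r@final)
    expect_gt(bf, 0.5)
    expect_lt(bf, 1)
    expect_error(annealPattern(s = 5, wTarget = 0.4, wStart = 0.3),
        class = "invalidParameterError")
})
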