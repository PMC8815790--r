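tr <- function(start, end) data.frame(start = start, end = end,
                                      peak = start)

test_that("transient distances count overlapped frames, negated", {
    A <- tr(c(0, 3), c(2, 10))
    B <- tr(c(5, 8), c(6, 12))
    D <- transientDistanceMatrix(A, B)
    expect_equal(D[1, ], c(0, 0))
    expect_equal(D[2, 1], -2)                 # frames 5,6
    expect_equal(D[2, 2], -3)                 # frames 8,9,10
    expect_equal(transientDistanceMatrix(tr(1, 7), tr(1, 7))[1, 1], -7)
    expect_equal(dim(transientDistanceMatrix(A, A[0, ])), c(2, 0))
})

test_that("transient matching keeps only truly overlapping pairs", {
    A <- tr(c(0, 10, 30), c(5, 20, 40))
    expect_equal(matchTransients(A, A)$tp, 3)
    B <- tr(c(100, 200), c(105, 205))
    expect_equal(matchTransients(A, B)$tp, 0)
    # 3x3 overlap puzzle against exhaustive enumeration
    set.seed(61)
    for (i in 1:20) {
        X <- tr(sort(sample(0:50, 3)) * 2, sort(sample(0:50, 3)) * 2 + 8)
        Y <- tr(sort(sample(0:50, 3)) * 2, sort(sample(0:50, 3)) * 2 + 8)
        D <- transientDistanceMatrix(X, Y)
        expect_equal(sum(D[cbind(matchTransients(X, Y)$pairs$a,
                                 matchTransients(X, Y)$pairs$b)]) -
                     0 * nrow(D),
                     bruteAssignmentCost(D),
                     tolerance = 1e-12)
    }
})

test_that("precision, recall and F1 follow the harmonic-mean formula", {
    s <- precisionRecallF1(10, 10, 10)
    expect_equal(s$f1, 1)
    s2 <- precisionRecallF1(5, 5, 10)
    expect_equal(s2$precision, 1)
    expect_equal(s2$recall, 0.5)
    expect_equal(s2$f1, 2 / 3)
    expect_equal(precisionRecallF1(0, 5, 5)$f1, 0)
    e <- precisionRecallF1(0, 0, 0)
    expect_equal(e$f1, 1)
    expect_true(e$empty)
    expect_equal(precisionRecallF1(0, 0, 4)$f1, 0)
})

test_that("IoU counts pixels and the Dist rule gates mask matches", {
    m <- matrix(FALSE, 4, 4)
    a <- m; a[1, 1:2] <- TRUE
    b <- m; b[1, 2:3] <- TRUE
    expect_equal(maskIoU(a, a), 1)
    expect_equal(maskIoU(a, b), 1 / 3)
    c2 <- m; c2[4, 4] <- TRUE
    expect_equal(maskIoU(a, c2), 0)
    expect_error(maskIoU(m, m), "empty")

    h <- 20; w <- 20
    A <- list(testDisk(c(5, 5), 3, h, w), testDisk(c(14, 14), 3, h, w))
    sameRes <- matchMasks(A, A)
    expect_equal(nrow(sameRes$pairs), 2)
    expect_equal(sameRes$pairs$iou, c(1, 1))
    # IoU 0.6 pair matches with Dist 0.4; IoU < 0.5 does not match
    big <- testDisk(c(5, 5), 3, h, w)
    shifted1 <- testDisk(c(5, 6), 3, h, w)
    iou1 <- maskIoU(big, shifted1)
    res1 <- matchMasks(list(big), list(shifted1))
    if (iou1 >= 0.5) expect_equal(nrow(res1$pairs), 1)
    shifted4 <- testDisk(c(5, 10), 3, h, w)
    expect_lt(maskIoU(big, shifted4), 0.5)
    res4 <- matchMasks(list(big), list(shifted4))
    expect_equal(nrow(res4$pairs), 0)
    expect_equal(res4$unmatchedA, 1L)
    expect_equal(res4$unmatchedB, 1L)
    # symmetry
    B <- list(testDisk(c(5, 6), 3, h, w), testDisk(c(14, 13), 3, h, w))
    ab <- matchMasks(A, B)$pairs
    ba <- matchMasks(B, A)$pairs
    expect_equal(ab[order(ab$a), c("a", "b")],
                 ba[order(ba$b), c("b", "a")],
                 ignore_attr = TRUE)
})

test_that("Hungarian assignment equals brute force on random instances", {
    set.seed(62)
    for (i in 1:30) {
        n <- sample(2:6, 1); m <- sample(2:6, 1)
        cost <- matrix(round(runif(n * m, -10, 10), 2), n, m)
        expect_equal(hungarianCost(cost), bruteAssignmentCost(cost),
                     tolerance = 1e-9)
    }
})

test_that("leave-one-out cross-validation picks dominating grid points", {
    # 1-point grids: parameters forced
    one <- lapply(1:3, function(v)
        matrix(v / 10, 1, 1, dimnames = list("1", "5")))
    cv1 <- looCrossValidate(one)
    expect_equal(nrow(cv1$folds), 3)
    expect_equal(cv1$folds$alpha, rep(1, 3))
    expect_equal(cv1$folds$testF1, c(0.1, 0.2, 0.3))
    expect_equal(cv1$meanTestF1, 0.2)

    # one point strictly dominates on every video
    set.seed(63)
    mats <- lapply(1:4, function(v) {
        m <- matrix(runif(6, 0, 0.5), 2, 3,
                    dimnames = list(c("0.5", "1"), c("4", "6", "8")))
        m[2, 2] <- 0.9 + runif(1, 0, 0.05)
        m
    })
    cv <- looCrossValidate(mats)
    expect_equal(nrow(cv$folds), 4)
    expect_true(all(cv$folds$alpha == 1))
    expect_true(all(cv$folds$thSnr == 6))
    # ties break toward the smaller alpha, then the smaller threshold
    flat <- lapply(1:2, function(v)
        matrix(0.5, 2, 2, dimnames = list(c("1", "2"), c("3", "4"))))
    cvf <- looCrossValidate(flat)
    expect_true(all(cvf$folds$alpha == 1))
    expect_true(all(cvf$folds$thSnr == 3))
    expect_error(looCrossValidate(mats[1]), "at least 2")
})
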