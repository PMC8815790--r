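test_that("input normalization scales by the target row and shifts to zero min", {
    set.seed(21)
    m <- rbind(abs(rnorm(100)) + seq(0, 1, length.out = 100),
               abs(rnorm(100)))
    m <- m / quantileStd(m[1, ])               # unit target scale
    m <- m - min(m)                            # zero global minimum
    n1 <- normalizeInput(m)
    expect_equal(n1$values, m, tolerance = 1e-12)   # identity case
    expect_equal(min(n1$values), 0)
    n3 <- normalizeInput(m * 3)
    expect_equal(n3$scale, 3 * n1$scale, tolerance = 1e-12)
    expect_equal(n3$values, n1$values, tolerance = 1e-10)
    set.seed(22)
    r <- matrix(rnorm(60), 3, 20)
    expect_equal(min(normalizeInput(r)$values), 0)
    expect_error(normalizeInput(matrix(1, 2, 30)), "flat target trace")
})

test_that("the cost function reproduces the printed half-norm conventions", {
    expect_equal(nmfCost(matrix(2), matrix(1), matrix(1), alpha = 0), 0.25)
    M <- diag(2); F <- matrix(runif(8), 2, 4)
    expect_equal(nmfCost(M %*% F, M, F, alpha = 0), 0)
    base <- nmfCost(M %*% F, M, F, alpha = 1)
    doub <- nmfCost(M %*% F, M, F, alpha = 2)
    expect_equal(doub, 2 * base, tolerance = 1e-12)
    expect_error(nmfCost(matrix(1, 2, 3), diag(2), matrix(1, 3, 3), 1),
                 "shape")
})

test_that("the factorization reconstructs orthogonal sources and is seeded", {
    F <- rbind(c(rep(1, 10), rep(0, 20)),
               c(rep(0, 10), rep(1, 10), rep(0, 10)),
               c(rep(0, 20), rep(1, 10)))
    X <- diag(c(2, 1, 3)) %*% F
    dec <- nmfDecompose(X, alpha = 0, seed = 2)
    err <- norm(X - dec$M %*% dec$Fsep, "F") / norm(X, "F")
    expect_lt(err, 1e-3)
    dec2 <- nmfDecompose(X, alpha = 0, seed = 2)
    expect_identical(dec$M, dec2$M)
    expect_identical(dec$Fsep, dec2$Fsep)
    expect_error(nmfDecompose(matrix(c(1, NA, 1, 1), 2, 2), 1),
                 "non-finite")
})

test_that("stronger regularization shrinks the factor mass", {
    fx <- snr10Fixture(3, T = 1500L)
    n <- normalizeInput(fx$Fmeas)
    mass <- vapply(c(0.1, 0.5, 1, 5, 20), function(a) {
        dec <- nmfDecompose(n$values, a, seed = 3)
        0.5 * (sum(abs(dec$M)) + sum(abs(dec$Fsep))) +
            0.5 * (sum(dec$M^2) + sum(dec$Fsep^2))
    }, numeric(1))
    expect_true(all(diff(mass) <= 0.01 * mass[-length(mass)]))
})

test_that("component matching is product-preserving with a unit diagonal", {
    # diagonal-dominant raw factors stay unpermuted
    M <- diag(3) + 0.05
    F <- matrix(runif(30), 3, 10)
    mm <- matchComponents(M, F)
    expect_equal(diag(mm$M), rep(1, 3))
    expect_equal(mm$M %*% mm$Fsep, M %*% F, tolerance = 1e-12)
    expect_equal(order(apply(mm$Fsep, 1, function(r)
        which.max(abs(cor(t(F), r))))), 1:3)

    # 2x2 anti-diagonal case
    M2 <- matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2)
    F2 <- rbind(c(1, 0, 1, 0), c(0, 2, 0, 2))
    mm2 <- matchComponents(M2, F2)
    expect_equal(mm2$M %*% mm2$Fsep, M2 %*% F2, tolerance = 1e-12)
    # the permutation must swap: output row 1 now carries old row 2
    expect_equal(mm2$Fsep[1, ] > 0, F2[2, ] > 0)

    set.seed(23)
    for (i in 1:20) {
        n <- sample(3:6, 1)
        f <- randomFactors(n)
        mm <- matchComponents(f$M, f$F)
        expect_lt(max(abs(mm$M %*% mm$Fsep - f$M %*% f$F)), 1e-10)
        expect_identical(diag(mm$M), rep(1, n))
    }
    bad <- diag(3); bad[, 2] <- 0
    expect_error(matchComponents(bad, matrix(1, 3, 4)), "degenerate")
})

test_that("greedy matching finds the dominant permutation on 3x3 instances", {
    set.seed(24)
    for (i in 1:25) {
        perm <- sample(3)
        P0 <- diag(3)[perm, ]
        # column-normalized matrix dominant under permutation perm
        M <- t(P0) %*% diag(runif(3, 0.6, 0.9)) +
            matrix(runif(9, 0, 0.15), 3, 3)
        F <- matrix(runif(15, 0.1, 1), 3, 5)
        mm <- matchComponents(M, F)
        # brute force: the permutation that maximizes the product of the
        # (column-normalized) selected entries row-by-row
        cn <- sweep(M, 2, colSums(M), "/")
        perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                      c(3,1,2), c(3,2,1))
        scores <- vapply(perms, function(p)
            sum(log(cn[cbind(1:3, p)])), numeric(1))
        best <- perms[[which.max(scores)]]
        # row i of matched Fsep must be old row best[i] (up to scale)
        for (r in 1:3) {
            cors <- abs(cor(mm$Fsep[r, ], F[best[r], ]))
            expect_gt(cors, 0.999)
        }
    }
})

test_that("floating alpha halves until no output trace is identically zero", {
    fx <- snr10Fixture(6, T = 1200L)
    cfg <- runConfig(seed = 6)
    res <- floatingAlphaUnmix(fx$Fmeas, alpha0 = 1, config = cfg)
    expect_equal(alphaFinal(res), 1)           # small alpha: single pass
    expect_true(all(apply(abs(separatedTraces(res)), 1, max) > 1e-9))

    res100 <- floatingAlphaUnmix(fx$Fmeas, alpha0 = 100, config = cfg)
    expect_lt(alphaFinal(res100), 100)
    expect_true(all(apply(abs(separatedTraces(res100)), 1, max) > 1e-9))
    # the single pass at alpha 100 must indeed collapse a component
    n <- normalizeInput(fx$Fmeas)
    single <- nmfDecompose(n$values, 100, seed = 6)
    expect_true(any(apply(abs(single$Fsep), 1, max) < 1e-9) ||
                any(colSums(single$M) == 0))

    res0 <- floatingAlphaUnmix(fx$Fmeas, alpha0 = 0, config = cfg)
    expect_equal(alphaFinal(res0), 0)
    expect_error(floatingAlphaUnmix(fx$Fmeas, alpha0 = -1), ">= 0")
})

test_that("rescaling restores amplitudes and aligns medians exactly", {
    fx <- snr10Fixture(8, T = 1000L)
    res <- floatingAlphaUnmix(fx$Fmeas, 1, runConfig(seed = 8))
    final <- finalTraces(res)
    expect_equal(apply(final, 1, median), apply(fx$Fmeas, 1, median),
                 tolerance = 1e-10)
    # robust scale of the fluctuations grows linearly with the input scale
    res3 <- floatingAlphaUnmix(fx$Fmeas * 3, 1, runConfig(seed = 8))
    expect_equal(quantileStd(finalTraces(res3)[1, ]),
                 3 * quantileStd(final[1, ]), tolerance = 1e-6)
})

test_that("downsampling ratio 1 is the direct path and extremes error", {
    fx <- snr10Fixture(9, T = 800L)
    cfg <- runConfig(seed = 9)
    direct <- floatingAlphaUnmix(fx$Fmeas, 1, cfg)
    ds1 <- downsampleUnmix(fx$Fmeas, 1L, 1, cfg)
    expect_identical(finalTraces(ds1), finalTraces(direct))
    expect_identical(mixingMatrix(ds1), mixingMatrix(direct))
    expect_error(downsampleUnmix(fx$Fmeas, ncol(fx$Fmeas), 1, cfg), "ratio")
})

test_that("downsampled unmixing recovers the same events on clean mixtures", {
    cfg <- synthConfig(T = 1600L, nComponents = 4L, amplitude = 1,
                       noiseSigma = 0, baseline = 0, spikeRate = 0.1,
                       crosstalkRange = c(0.2, 0.5), seed = 14L)
    fx <- simulateTraces(cfg)
    rc <- runConfig(seed = 14)
    d1 <- downsampleUnmix(fx$Fmeas, 1L, 1, rc)
    d4 <- downsampleUnmix(fx$Fmeas, 4L, 1, rc)
    # noiseless, unit-height events: threshold at half the known height
    t1 <- detectTransients(finalTraces(d1)[1, ], 0.5)
    t4 <- detectTransients(finalTraces(d4)[1, ], 0.5)
    expect_gt(nrow(t1), 0)
    expect_equal(nrow(t1), nrow(t4))
    expect_equal(t1$peak, t4$peak)
    expect_true(all(abs(t1$start - t4$start) <= 1))
    expect_true(all(abs(t1$end - t4$end) <= 1))
})

test_that("whole-video unmixing is deterministic and isolates failures", {
    sim <- simulateVideo(synthConfig(H = 36L, W = 36L, T = 400L,
        nNeurons = 4L, neuronRadiusPx = 3.5, minCentroidDistancePx = 9,
        spikeRate = 0.5, nDendrites = 0L, backgroundAmplitude = 0,
        noiseSigma = 3, seed = 5L))
    cfg <- runConfig(seed = 5)
    run1 <- unmixVideo(sim$video, sim$masks, cfg)
    expect_true(all(is.na(run1$errors)))
    cfg2 <- cfg; cfg2$workers <- 2L
    run2 <- unmixVideo(sim$video, sim$masks, cfg2)
    expect_identical(lapply(run1$results, finalTraces),
                     lapply(run2$results, finalTraces))

    # a neuron whose background-subtracted trace is flat fails alone:
    # clamp a corner block so both the mask and its background disk are
    # constant over time
    d <- videoData(sim$video)
    flat <- matrix(FALSE, 36, 36); flat[3:5, 3:5] <- TRUE
    for (t in seq_len(dim(d)[1])) d[t, 1:14, 1:14] <- 7
    masks2 <- NeuronMasks(c(lapply(seq_len(nMasks(sim$masks)), function(i)
        getMask(sim$masks, i)), list(flat)))
    run3 <- unmixVideo(VideoStack(d, frameRate = 30), masks2, cfg)
    expect_true(is.na(run3$errors[5]) == FALSE)
    expect_match(run3$errors[5], "flat target trace")
    expect_true(all(is.na(run3$errors[1:4])))
})
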