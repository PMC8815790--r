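test_that("homomorphic filter is inert on uniform frames and very wide kernels", {
    v <- constantVideo(value = 50, T = 2, H = 16, W = 16)
    out <- homomorphicFilter(v, spatialFwhmUm = 8, pixelSizeUm = 1)
    expect_equal(videoData(out), videoData(v), tolerance = 1e-10)

    set.seed(2)
    d <- array(runif(2 * 16 * 16, 0, 200), c(2, 16, 16))
    v2 <- VideoStack(d, frameRate = 30)
    wide <- homomorphicFilter(v2, spatialFwhmUm = 10 * 16, pixelSizeUm = 1)
    expect_equal(videoData(wide), d, tolerance = 1e-6)
})

test_that("homomorphic filter removes a broad multiplicative gradient", {
    h <- 48; w <- 48
    disk <- testDisk(c(23, 23), 4, h, w)
    base <- matrix(100, h, w)
    base[disk] <- 400
    gradient <- matrix(rep(seq(0.5, 1.5, length.out = w), each = h), h, w)
    mk <- function(frame) VideoStack(array(frame, c(1, h, w)), 30)
    ref <- videoData(homomorphicFilter(mk(base), 20, 1))[1, , ]
    out <- videoData(homomorphicFilter(mk(base * gradient), 20, 1))[1, , ]
    contrastRef <- mean(ref[disk]) / mean(ref[!disk])
    contrastOut <- mean(out[disk]) / mean(out[!disk])
    expect_equal(contrastOut, contrastRef, tolerance = 0.05)
    # away from the border the filtered frame matches the gradient-free
    # reference: the broad gradient is removed
    interior <- matrix(FALSE, h, w); interior[9:40, 9:40] <- TRUE
    expect_lt(mean(abs(out - ref)[interior] / ref[interior]), 0.05)
})

test_that("homomorphic filter rejects invalid inputs", {
    v <- constantVideo()
    expect_error(homomorphicFilter(v, -1), "positive")
    expect_error(homomorphicFilter(v, 0.5, pixelSizeUm = 1), "exceed")
    snr <- VideoStack(array(0, c(2, 4, 4)), kind = "snr")
    expect_error(homomorphicFilter(snr, 5), "raw-kind")
})

test_that("matched kernel is a unit-norm reversed transient template", {
    k <- buildMatchedKernel(0.2, 0, 30)
    expect_equal(sum(k$taps^2), 1, tolerance = 1e-12)
    tpl <- rev(k$taps)
    expect_true(all(diff(tpl) < 0))          # pure decay: monotone
    expect_true(all(k$taps >= 0))
    k2 <- buildMatchedKernel(0.2, 0, 60)
    expect_equal(length(k2$taps), 2 * length(k$taps), tolerance = 0.1)
    expect_error(buildMatchedKernel(-0.1), "positive")
})

test_that("matched filtering peaks at the template onset", {
    k <- buildMatchedKernel(0.2, 0, 30)
    tpl <- rev(k$taps)
    x <- numeric(300)
    t0 <- 100
    x[t0:(t0 + length(tpl) - 1)] <- tpl
    y <- applyMatchedFilter(x, k)
    expect_equal(which.max(y), t0)
})

test_that("whitening maps quiescent pixels to zero and is scale invariant", {
    set.seed(9)
    d <- array(100 + rnorm(200 * 5 * 5, 0, 3), c(200, 5, 5))
    d[, 1, 1] <- 42                 # dead pixel
    v <- VideoStack(d, 30)
    wh <- whitenPixels(v)
    expect_equal(videoKind(wh), "snr")
    expect_equal(videoData(wh)[, 1, 1], rep(0, 200))
    # baseline maps to ~0: per-pixel median of output is exactly 0
    expect_equal(max(abs(apply(videoData(wh), c(2, 3), median))), 0)
    v10 <- VideoStack(10 * d, 30)
    expect_equal(videoData(whitenPixels(v10)), videoData(wh),
                 tolerance = 1e-6)
})

test_that("SNR conversion whitens noise and highlights a transient", {
    set.seed(31)
    T <- 400; h <- 12; w <- 12
    noise <- array(100 + rnorm(T * h * w, 0, 5), c(T, h, w))
    snr <- generateSnrVideo(VideoStack(noise, 30), spatialFwhmUm = 6)
    expect_equal(videoKind(snr), "snr")
    d <- videoData(snr)
    dim(d) <- c(T, h * w)
    q <- apply(d, 2, quantileStd)
    expect_true(all(abs(q - 1) < 1e-6))
    expect_lt(abs(mean(d)), 0.2)

    # add one transient on a small neuron
    mask <- testDisk(c(6, 6), 2, h, w)
    sig <- noise
    wf <- 40 * exp(-(0:20) / 6)
    for (i in seq_along(wf)) sig[200 + i - 1, , ][mask] <-
        sig[200 + i - 1, , ][mask] + wf[i]
    snr2 <- generateSnrVideo(VideoStack(sig, 30), spatialFwhmUm = 6)
    d2 <- videoData(snr2)
    dim(d2) <- c(T, h * w)
    win <- 190:230
    peakNeuron <- max(d2[win, as.vector(mask)])
    far <- !mask & !testDisk(c(6, 6), 4, h, w)
    peakBg <- max(d2[win, as.vector(far)])
    expect_gt(peakNeuron, peakBg + 3)
})
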