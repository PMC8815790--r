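# Shared fixture builders and independent oracles for the test suite.

# Tiny constant video.
constantVideo <- function(value = 1, T = 3, H = 4, W = 4, frameRate = 30,
                          kind = "raw") {
    VideoStack(array(value, c(T, H, W)), frameRate = frameRate, kind = kind)
}

# Disk mask helper independent of the package's region code.
testDisk <- function(center, radius, h, w) {
    rows <- matrix(0:(h - 1L), h, w)
    cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
    (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
}

# A standard unit-SNR-10 trace fixture used across unmixing tests:
# amplitude 1, noise sd 0.1, static baseline 1 protecting the zero-clip,
# dense crosstalk in [0.2, 0.5].
snr10Fixture <- function(seed, T = 2000L, nComponents = 4L,
                         crosstalk = c(0.2, 0.5), noise = 0.1) {
    simulateTraces(synthConfig(T = T, nComponents = nComponents,
        amplitude = 1, noiseSigma = noise, baseline = 1,
        crosstalkRange = crosstalk, seed = seed))
}

# Brute-force minimum-cost assignment by permutation enumeration (n <= 7).
# Returns the minimum total cost over all ways of assigning each row of
# the smaller side to a distinct column.
bruteAssignmentCost <- function(cost) {
    flip <- nrow(cost) > ncol(cost)
    if (flip) cost <- t(cost)
    n <- nrow(cost)
    m <- ncol(cost)
    perms <- function(v) {
        if (length(v) == 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
        out
    }
    best <- Inf
    for (cols in utils::combn(m, n, simplify = FALSE))
        for (p in perms(cols))
            best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    best
}

# Assignment cost achieved by the package's Hungarian wrapper.
hungarianCost <- function(cost) {
    pairs <- caUnmix:::solveAssignment(cost)
    sum(cost[pairs])
}

# F1 of detected-vs-gt transients on a single trace.
traceF1 <- function(trace, gt, thSnr, frameRate = 30) {
    snr <- snrNormalizeTrace(trace, frameRate = frameRate)
    d <- detectTransients(snr, thSnr)
    precisionRecallF1(matchTransients(d, gt)$tp, nrow(d), nrow(gt))$f1
}

# Random non-degenerate mixing factors for matching tests: strictly
# positive entries avoid zero columns.
randomFactors <- function(n, T = 40L) {
    M <- matrix(runif(n * n, 0.05, 1), n, n)
    F <- matrix(runif(n * T, 0, 1), n, T)
    list(M = M, F = F)
}
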