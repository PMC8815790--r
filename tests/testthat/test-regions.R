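rectMask <- function(h, w, r0, c0, nr, nc) {
    m <- matrix(FALSE, h, w)
    m[r0:(r0 + nr - 1), c0:(c0 + nc - 1)] <- TRUE
    m
}

test_that("average neuron radius follows the closed form", {
    h <- 40; w <- 40
    m78 <- rectMask(h, w, 10, 10, 6, 13)          # 78 px
    expect_equal(averageNeuronRadius(NeuronMasks(list(m78))),
                 sqrt(78 / pi), tolerance = 1e-12)
    expect_equal(sqrt(78 / pi), 4.98, tolerance = 0.01)
    m50 <- rectMask(h, w, 2, 2, 5, 10)
    m150 <- rectMask(h, w, 20, 20, 10, 15)
    expect_equal(averageNeuronRadius(NeuronMasks(list(m50, m150))),
                 sqrt(100 / pi), tolerance = 1e-12)
    single <- rectMask(h, w, 5, 5, 1, 1)
    expect_equal(averageNeuronRadius(NeuronMasks(list(single, single))),
                 sqrt(1 / pi), tolerance = 1e-12)
})

test_that("background disk uses the 2.5x rule and pixel-count area", {
    h <- 60; w <- 60
    mask <- testDisk(c(30, 30), 5, h, w)       # area ~ 78-81 px
    masks <- NeuronMasks(list(mask))
    bg <- backgroundMask(masks, 1)
    r <- 2.5 * sqrt(sum(mask) / pi)
    expect_equal(bg$radius, r, tolerance = 1e-12)
    # pixel-count oracle: area within a perimeter-sized band of pi r^2
    expect_lt(abs(sum(bg$mask) - pi * r^2), 4 * pi * r)
    # corner neuron: clipped disk still contains the centroid
    cm <- rectMask(h, w, 1, 1, 4, 4)
    masks2 <- NeuronMasks(list(cm))
    bg2 <- backgroundMask(masks2, 1)
    ctr <- round(bg2$centroid) + 1
    expect_true(bg2$mask[ctr[1], ctr[2]])
    expect_lt(sum(bg2$mask), pi * bg2$radius^2)  # clipped
})

test_that("neighbors are decided by centroid distance against the disk radius", {
    h <- 60; w <- 60
    # two 78-px rectangles -> avg radius ~ 4.98, disk radius ~ 12.46
    mk <- function(dist) {
        a <- rectMask(h, w, 20, 10, 6, 13)
        b <- rectMask(h, w, 20 + dist, 10, 6, 13)
        NeuronMasks(list(a, b))
    }
    near <- mk(10)
    bgN <- backgroundMask(near, 1)
    expect_equal(neighborIds(near, 1, bgN), 1L)     # id of the second mask
    far <- mk(13)
    bgF <- backgroundMask(far, 1)
    expect_length(neighborIds(far, 1, bgF), 0)
    lone <- NeuronMasks(list(rectMask(h, w, 20, 10, 6, 13)))
    expect_length(neighborIds(lone, 1), 0)
})

test_that("outside mask grows by the stated one-pixel rule when crowded", {
    h <- 70; w <- 70
    target <- testDisk(c(35, 35), 5, h, w)
    masks1 <- NeuronMasks(list(target))
    bg <- backgroundMask(masks1, 1)
    os <- outsideMask(masks1, 1, bg)
    expect_equal(sum(os$mask), sum(bg$mask & !target))   # simple set algebra
    expect_equal(os$radius, bg$radius)                    # no growth needed
    expect_false(any(os$mask & target))

    # crowd the field: many small masks tile a ring around the target so
    # the small background disk is fully occupied and must grow past them
    h2 <- 40; w2 <- 40
    tgt <- testDisk(c(20, 20), 3, h2, w2)
    ring <- testDisk(c(20, 20), 10, h2, w2) & !tgt
    idx <- which(ring, arr.ind = TRUE)
    grp <- (seq_len(nrow(idx)) %% 32) + 1
    tiles <- lapply(1:32, function(g) {
        m <- matrix(FALSE, h2, w2)
        m[idx[grp == g, , drop = FALSE]] <- TRUE
        m
    })
    masks2 <- NeuronMasks(c(list(tgt), tiles))
    bg2 <- backgroundMask(masks2, 1)
    os2 <- outsideMask(masks2, 1, bg2)
    areas <- apply(maskArray(masks2), 1, sum)
    thr <- mean(areas) / 2
    expect_gte(sum(os2$mask), thr)
    expect_gt(os2$radius, bg2$radius)
    # oracle: iterate the stated rule independently
    anyN <- apply(maskArray(masks2), c(2, 3), any)
    r <- bg2$radius
    repeat {
        m <- testDisk(bg2$centroid, r, h2, w2) & !anyN
        if (sum(m) >= thr) break
        r <- r + 1
    }
    expect_equal(os2$radius, r)
    expect_equal(os2$mask, m)
})

test_that("region construction satisfies its invariants on random fields", {
    set.seed(77)
    for (rep in 1:8) {
        h <- 50; w <- 50
        n <- sample(2:6, 1)
        centers <- cbind(runif(n, 8, h - 9), runif(n, 8, w - 9))
        masks <- NeuronMasks(lapply(seq_len(n), function(i)
            testDisk(centers[i, ], runif(1, 2, 5), h, w)))
        regs <- buildRegions(masks)
        allNeurons <- apply(maskArray(masks), c(2, 3), any)
        meanArea <- mean(apply(maskArray(masks), 1, sum))
        for (i in seq_len(n)) {
            expect_false(any(regs[[i]]@outsideMask & allNeurons))
            expect_gte(sum(regs[[i]]@outsideMask), meanArea / 2)
            ctr <- round(centers[i, ]) + 1
            expect_true(regs[[i]]@backgroundMask[ctr[1], ctr[2]])
            expect_false((i - 1L) %in% regs[[i]]@neighborIds)
        }
        # determinism
        expect_identical(lapply(buildRegions(masks), function(r) r@outsideMask),
                         lapply(regs, function(r) r@outsideMask))
    }
})

test_that("adjacent neurons list each other symmetrically", {
    h <- 50; w <- 50
    a <- testDisk(c(20, 20), 4, h, w)
    b <- testDisk(c(20, 28), 4, h, w)
    regs <- buildRegions(NeuronMasks(list(a, b)))
    expect_equal(regs[[1]]@neighborIds, 1L)
    expect_equal(regs[[2]]@neighborIds, 0L)
})
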