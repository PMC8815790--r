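#' Distance matrix between two transient sets
#'
#' `D[a, b]` is the negative of the number of frames shared by transient
#' `a` of set A and transient `b` of set B (inclusive frame ranges), so
#' the best overlaps are the most negative entries.
#'
#' @param A,B transient data.frames with `start` and `end` columns
#'   (inclusive, any common frame base).
#' @return `nrow(A) x nrow(B)` numeric matrix (0 x 0 when either set is
#'   empty).
#' @export
transientDistanceMatrix <- function(A, B) {
    if (nrow(A) == 0L || nrow(B) == 0L)
        return(matrix(0, nrow(A), nrow(B)))
    ov <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j)
        pmax(0, pmin(A$end[i], B$end[j]) - pmax(A$start[i], B$start[j]) + 1))
    -ov
}

# Minimum-cost rectangular assignment (Hungarian algorithm via
# clue::solve_LSAP).  Every row of the smaller side is assigned; a
# constant shift makes the costs non-negative without changing the
# optimum.  Returns a 2-column matrix of (row, col) pairs.
solveAssignment <- function(cost) {
    if (nrow(cost) == 0L || ncol(cost) == 0L)
        return(matrix(integer(0L), 0L, 2L))
    flip <- nrow(cost) > ncol(cost)
    if (flip) cost <- t(cost)
    sol <- clue::solve_LSAP(cost - min(cost))
    pairs <- cbind(seq_len(nrow(cost)), as.integer(sol))
    if (flip) pairs <- pairs[, 2:1, drop = FALSE]
    pairs
}

#' Match detected transients to ground-truth transients
#'
#' Solves the linear assignment problem on the negative-overlap distance
#' matrix with the Hungarian algorithm; matched pairs that do not actually
#' overlap (distance 0) are discarded. The retained pairs are the true
#' positives.
#'
#' @param A detected transients (data.frame with `start`, `end`).
#' @param B ground-truth transients.
#' @return List with `pairs` (data.frame `a`, `b`, `overlap`) and `tp`.
#' @export
matchTransients <- function(A, B) {
    D <- transientDistanceMatrix(A, B)
    pairs <- solveAssignment(D)
    if (nrow(pairs)) {
        ov <- -D[pairs]
        keep <- ov >= 1
        pairs <- data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
                            overlap = ov[keep])
    } else {
        pairs <- data.frame(a = integer(0L), b = integer(0L),
                            overlap = numeric(0L))
    }
    list(pairs = pairs, tp = nrow(pairs))
}

#' Precision, recall and F1 from matched counts
#'
#' `precision = tp / nDetected`, `recall = tp / nGt`,
#' `F1 = 2 / (recall^-1 + precision^-1)`. With no detections and no
#' ground truth the score is defined as 1 (perfect agreement on nothing)
#' and flagged via `empty = TRUE`; with `tp = 0` but a non-empty side the
#' score is 0.
#'
#' @param tp true-positive count, `tp <= min(nDetected, nGt)`.
#' @param nDetected number of detected transients.
#' @param nGt number of ground-truth transients.
#' @return List with `precision`, `recall`, `f1`, `tp`, `nDetected`,
#'   `nGt`, `empty`.
#' @export
precisionRecallF1 <- function(tp, nDetected, nGt) {
    stopifnot(tp <= min(nDetected, nGt) || (nDetected == 0L && nGt == 0L))
    if (nDetected == 0L && nGt == 0L)
        return(list(precision = 1, recall = 1, f1 = 1, tp = 0L,
                    nDetected = 0L, nGt = 0L, empty = TRUE))
    precision <- if (nDetected > 0L) tp / nDetected else 0
    recall <- if (nGt > 0L) tp / nGt else 0
    f1 <- if (tp == 0L) 0 else 2 / (1 / recall + 1 / precision)
    list(precision = precision, recall = recall, f1 = f1, tp = tp,
         nDetected = nDetected, nGt = nGt, empty = FALSE)
}

#' Pooled transient F1 over the neurons of a video
#'
#' Matches detected to ground-truth transients neuron by neuron and pools
#' the counts (true positives, detections, ground truth) over all neurons
#' before forming the ratios, so the score weights every transient in the
#' video equally.
#'
#' @param detected list of transient data.frames, one per neuron.
#' @param gt list of ground-truth transient data.frames, same order.
#' @return An evaluation list as from [precisionRecallF1()].
#' @export
videoF1 <- function(detected, gt) {
    stopifnot(length(detected) == length(gt))
    tp <- 0L; nd <- 0L; ng <- 0L
    for (i in seq_along(detected)) {
        m <- matchTransients(detected[[i]], gt[[i]])
        tp <- tp + m$tp
        nd <- nd + nrow(detected[[i]])
        ng <- ng + nrow(gt[[i]])
    }
    precisionRecallF1(tp, nd, ng)
}

#' Intersection over union of two binary masks
#'
#' @param m1,m2 logical matrices of identical shape, not both empty.
#' @return Scalar in `[0, 1]`.
#' @export
maskIoU <- function(m1, m2) {
    u <- sum(m1 | m2)
    if (u == 0L) stop("both masks are empty")
    sum(m1 & m2) / u
}

#' Match two mask sets by intersection over union
#'
#' Pairwise distances are `1 - IoU` when `IoU >= 0.5` and 2 otherwise
#' (2 marks pairs that cannot be matched); the Hungarian algorithm finds
#' the minimum-cost one-to-one assignment and pairs with distance below 2
#' are the matches.
#'
#' @param A,B [NeuronMasks-class] objects (or lists of logical matrices)
#'   on the same grid.
#' @return List with `pairs` (data.frame `a`, `b` 1-based indices, `iou`),
#'   `unmatchedA`, `unmatchedB` (indices).
#' @export
matchMasks <- function(A, B) {
    listA <- if (is(A, "NeuronMasks"))
        lapply(seq_len(nMasks(A)), function(i) getMask(A, i)) else A
    listB <- if (is(B, "NeuronMasks"))
        lapply(seq_len(nMasks(B)), function(i) getMask(B, i)) else B
    na <- length(listA); nb <- length(listB)
    iou <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j)
        maskIoU(listA[[i]], listB[[j]])))
    iou <- matrix(iou, na, nb)
    d <- ifelse(iou >= 0.5, 1 - iou, 2)
    pairs <- solveAssignment(d)
    if (nrow(pairs)) {
        keep <- d[pairs] < 2
        pairs <- pairs[keep, , drop = FALSE]
    }
    pdf <- data.frame(a = pairs[, 1L], b = pairs[, 2L],
                      iou = if (nrow(pairs)) iou[pairs] else numeric(0L))
    list(pairs = pdf,
         unmatchedA = setdiff(seq_len(na), pdf$a),
         unmatchedB = setdiff(seq_len(nb), pdf$b))
}

#' Leave-one-out cross-validation over the parameter grid
#'
#' Takes one F1 matrix per video (rows = regularization weights
#' ascending, columns = detection thresholds ascending, as produced by
#' scoring each grid point on that video). Each fold holds one video out,
#' picks the grid point maximizing the mean F1 over the training videos
#' (ties break to the smaller regularization weight, then the smaller
#' threshold), and reports the held-out video's F1 at that point. The
#' final metric is the mean test F1 over folds.
#'
#' @param f1PerVideo list (length n >= 2) of numeric matrices with
#'   identical dimnames: rownames = alpha grid, colnames = threshold
#'   grid.
#' @return List with `folds` (data.frame `video`, `alpha`, `thSnr`,
#'   `trainF1`, `testF1`) and `meanTestF1`.
#' @export
looCrossValidate <- function(f1PerVideo) {
    n <- length(f1PerVideo)
    if (n < 2L) stop("cross-validation needs at least 2 videos")
    dims <- dim(f1PerVideo[[1L]])
    stopifnot(all(vapply(f1PerVideo, function(m)
        identical(dim(m), dims), logical(1L))))
    if (prod(dims) == 0L) stop("empty parameter grid")
    alphas <- as.numeric(rownames(f1PerVideo[[1L]]))
    ths <- as.numeric(colnames(f1PerVideo[[1L]]))
    folds <- lapply(seq_len(n), function(v) {
        train <- Reduce(`+`, f1PerVideo[-v]) / (n - 1L)
        best <- max(train)
        hits <- which(train == best, arr.ind = TRUE)
        hits <- hits[order(alphas[hits[, 1L]], ths[hits[, 2L]]), ,
                     drop = FALSE]
        i <- hits[1L, 1L]; j <- hits[1L, 2L]
        data.frame(video = v, alpha = alphas[i], thSnr = ths[j],
                   trainF1 = best, testF1 = f1PerVideo[[v]][i, j])
    })
    folds <- do.call(rbind, folds)
    list(folds = folds, meanTestF1 = mean(folds$testF1))
}
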