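#' @useDynLib caUnmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Normalize the measured trace matrix for factorization
#'
#' Divides every row by the quantile-based standard deviation of the first
#' row (so the target neuron's trace has unit robust scale) and then
#' subtracts the global minimum of the scaled matrix so all entries are
#' non-negative. A noiseless trace with sparse transients can have zero
#' quantile-based spread while being far from constant; for such rows the
#' plain standard deviation is used as the scale instead. A truly constant
#' first row is an error.
#'
#' @param Fmeas a [TraceMatrix-class] or a numeric matrix whose first row
#'   is the target-neuron trace.
#' @return List with `values` (normalized non-negative matrix), `scale`
#'   and `offset`.
#' @export
normalizeInput <- function(Fmeas) {
    v <- if (is(Fmeas, "TraceMatrix")) traceValues(Fmeas) else Fmeas
    sc <- quantileStd(v[1L, ])
    if (sc <= 0) sc <- sd(v[1L, ])
    if (sc <= 0) stop("flat target trace")
    v <- v / sc
    off <- min(v)
    list(values = v - off, scale = sc, offset = off)
}

#' Cost function of the regularized factorization
#'
#' `E = 1/2 ||Fmeas - M Fsep||_Fro^2 + alpha * reg(M, Fsep)` with
#' `reg = l1 ||M||_1 + l1 ||Fsep||_1 + (1-l1) ||M||_Fro^2 +
#' (1-l1) ||Fsep||_Fro^2`, using the half-sum norm conventions
#' `||A||_Fro^2 = 1/2 sum A^2` and `||A||_1 = 1/2 sum |A|`. The solver
#' minimizes an equivalent objective (exactly `2 E`), so minimizers
#' coincide.
#'
#' @param Fmeas,M,Fsep shape-compatible numeric matrices.
#' @param alpha regularization weight, >= 0.
#' @param l1 L1/L2 balance in `[0, 1]`.
#' @return Scalar cost `E`.
#' @export
nmfCost <- function(Fmeas, M, Fsep, alpha, l1 = 0.5) {
    if (ncol(M) != nrow(Fsep) || nrow(M) != nrow(Fmeas) ||
        ncol(Fsep) != ncol(Fmeas))
        stop("shape mismatch")
    froH <- function(a) 0.5 * sum(a^2)
    l1H <- function(a) 0.5 * sum(abs(a))
    0.5 * froH(Fmeas - M %*% Fsep) +
        alpha * (l1 * l1H(M) + l1 * l1H(Fsep) +
                 (1 - l1) * froH(M) + (1 - l1) * froH(Fsep))
}

# Non-negative double SVD initialization (zeros replaced by small random
# values drawn uniformly on [0, mean(X)/100]; seeded).
nndsvdInit <- function(X, seed = 1L) {
    n <- nrow(X)
    r <- n
    s <- svd(X, nu = r, nv = r)
    W <- matrix(0, n, r)
    H <- matrix(0, r, ncol(X))
    W[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
    H[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
    for (j in seq_len(r)[-1L]) {
        u <- s$u[, j]; v <- s$v[, j]
        up <- pmax(u, 0); un <- pmax(-u, 0)
        vp <- pmax(v, 0); vn <- pmax(-v, 0)
        nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
        nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
        mp <- nup * nvp; mn <- nun * nvn
        if (mp >= mn && mp > 0) {
            W[, j] <- sqrt(s$d[j] * mp) * up / nup
            H[j, ] <- sqrt(s$d[j] * mp) * vp / nvp
        } else if (mn > 0) {
            W[, j] <- sqrt(s$d[j] * mn) * un / nun
            H[j, ] <- sqrt(s$d[j] * mn) * vn / nvn
        }
    }
    avg <- mean(X)
    withSeed(seed, {
        zw <- W == 0
        W[zw] <- runif(sum(zw), 0, avg / 100)
        zh <- H == 0
        H[zh] <- runif(sum(zh), 0, avg / 100)
    })
    list(W = W, H = H)
}

#' Run the regularized non-negative factorization
#'
#' Factorizes the normalized trace matrix into a square mixing matrix and
#' separated traces by coordinate descent, with non-negative double SVD
#' initialization (zeros replaced by small seeded random values). The
#' component count equals the row count of the input: no dimensionality
#' reduction is performed because every input trace is tied to a physical
#' region. Deterministic given `seed`.
#'
#' @param Fnorm non-negative numeric matrix (output of
#'   [normalizeInput()]).
#' @param alpha regularization weight, >= 0.
#' @param l1 L1/L2 balance (default 0.5).
#' @param maxIter iteration cap (default 20000).
#' @param tol relative tolerance on the objective decrease (default 1e-4).
#' @param seed integer seed for the initialization fill-in.
#' @return List with `M` (raw left factor), `Fsep` (raw right factor),
#'   `nIterations`, `converged`.
#' @export
nmfDecompose <- function(Fnorm, alpha, l1 = 0.5, maxIter = 20000L,
                         tol = 1e-4, seed = 1L) {
    if (!all(is.finite(Fnorm))) stop("non-finite input")
    if (any(Fnorm < 0)) stop("negative input to the factorization")
    init <- nndsvdInit(Fnorm, seed = seed)
    fit <- nmf_hals(Fnorm, init$W, init$H, alpha, l1,
                    as.integer(maxIter), tol)
    list(M = fit$W, Fsep = fit$H,
         nIterations = as.integer(fit$iterations),
         converged = fit$converged)
}

#' Match separated components to the measured traces
#'
#' The factorization does not order its components, so the separated
#' traces are matched to the measured rows by their relative
#' contributions, in five product-preserving steps: (1) normalize each
#' column of `M` to unit sum, compensating the rows of `Fsep`; (2)
#' initialize a working copy `M0` and an indicator `P` of zeros; (3)
#' repeatedly take the largest element `m0[i, j]`, set `P[i, j] = 1`, zero
#' row `i` and column `j` of `M0`, and re-normalize the remaining non-zero
#' columns, until `M0` is all zero; (4) permute: `M <- M P^T`,
#' `Fsep <- P Fsep`; (5) scale each column of `M` by its diagonal element
#' (compensating the `Fsep` rows) so the diagonal is exactly 1. Ties in
#' step (3) break to the smallest row index, then the smallest column
#' index.
#'
#' @param Mraw square non-negative matrix from [nmfDecompose()].
#' @param FsepRaw matching right factor.
#' @return List with matched `M` (unit diagonal) and `Fsep`;
#'   `M %*% Fsep` is unchanged to numerical precision.
#' @export
matchComponents <- function(Mraw, FsepRaw) {
    n <- nrow(Mraw)
    stopifnot(ncol(Mraw) == n, nrow(FsepRaw) == n)
    s <- colSums(Mraw)
    if (any(s == 0)) stop("degenerate component: all-zero column in M")
    M <- sweep(Mraw, 2L, s, "/")
    Fsep <- sweep(FsepRaw, 1L, s, "*")

    M0 <- M
    P <- matrix(0, n, n)
    repeat {
        mx <- max(M0)
        if (mx <= 0) break
        hits <- which(M0 == mx, arr.ind = TRUE)
        hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
        i <- hits[1L, 1L]; j <- hits[1L, 2L]
        P[i, j] <- 1
        M0[i, ] <- 0
        M0[, j] <- 0
        cs <- colSums(M0)
        nz <- cs > 0
        if (any(nz)) M0[, nz] <- sweep(M0[, nz, drop = FALSE], 2L, cs[nz], "/")
    }
    # pair any leftover rows/columns (possible only in degenerate inputs)
    freeR <- which(rowSums(P) == 0)
    freeC <- which(colSums(P) == 0)
    if (length(freeR)) P[cbind(freeR, freeC)] <- 1

    M <- M %*% t(P)
    Fsep <- P %*% Fsep
    d <- diag(M)
    if (any(d == 0)) stop("degenerate component: zero diagonal after matching")
    M <- sweep(M, 2L, d, "/")
    Fsep <- sweep(Fsep, 1L, d, "*")
    list(M = M, Fsep = Fsep)
}

#' Rescale matched output traces to the input amplitude
#'
#' Multiplies every separated trace by the quantile-based standard
#' deviation of the first measured row (undoing the input normalization)
#' and then shifts each row so its median equals the median of the
#' corresponding background-subtracted input row. Row 1 of the result is
#' the decontaminated target-neuron trace.
#'
#' @param result an [UnmixResult-class] (or a list with an `Fsep`
#'   matrix).
#' @param Fmeas the original [TraceMatrix-class] or matrix.
#' @param scale the `scale` returned by [normalizeInput()].
#' @return Numeric matrix of final traces, same shape as `Fmeas`.
#' @export
rescaleOutput <- function(result, Fmeas, scale) {
    Fsep <- if (is(result, "UnmixResult")) separatedTraces(result)
            else result$Fsep
    v <- if (is(Fmeas, "TraceMatrix")) traceValues(Fmeas) else Fmeas
    out <- Fsep * scale
    shift <- apply(v, 1L, median) - apply(out, 1L, median)
    out + shift
}

# One normalized floating-alpha pass: decompose, test for collapsed
# components, and either accept (matched) or report degeneracy.
unmixPass <- function(Fn, alpha, config, epsZero) {
    dec <- nmfDecompose(Fn, alpha, l1 = config$l1Ratio,
                        maxIter = config$maxIter, tol = config$tol,
                        seed = config$seed)
    zeroRow <- apply(abs(dec$Fsep), 1L, max) < epsZero
    zeroCol <- colSums(dec$M) == 0
    if (any(zeroRow) || any(zeroCol))
        return(list(ok = FALSE, dec = dec))
    matched <- tryCatch(matchComponents(dec$M, dec$Fsep),
                        error = function(e) NULL)
    if (is.null(matched))
        return(list(ok = FALSE, dec = dec))
    zeroRow <- apply(abs(matched$Fsep), 1L, max) < epsZero
    if (any(zeroRow))
        return(list(ok = FALSE, dec = dec))
    list(ok = TRUE, dec = dec, matched = matched)
}

#' Unmix one measured trace matrix with the floating-alpha strategy
#'
#' Runs normalize, factorize, match. A separated trace is "identically
#' zero" when its largest absolute value is below `1e-9` times the robust
#' scale of the normalized target row; over-regularization producing such
#' a trace (or an all-zero mixing column) triggers halving of `alpha` and
#' a re-run, until every component survives. If `alpha` falls below
#' `config$alphaFloor` the trace set is unmixed once without
#' regularization and that result is accepted.
#'
#' @param Fmeas a [TraceMatrix-class] or numeric matrix (target row
#'   first).
#' @param alpha0 initial regularization weight, >= 0.
#' @param config a [runConfig()] list (solver settings and seed).
#' @return An [UnmixResult-class]; `finalTraces` holds the rescaled,
#'   median-aligned traces.
#' @export
floatingAlphaUnmix <- function(Fmeas, alpha0 = 1, config = runConfig()) {
    if (alpha0 < 0) stop("alpha0 must be >= 0")
    norm <- normalizeInput(Fmeas)
    epsZero <- 1e-9 * quantileStd(norm$values[1L, ])
    alpha <- alpha0
    repeat {
        pass <- unmixPass(norm$values, alpha, config, epsZero)
        if (pass$ok || alpha == 0) break
        alpha <- alpha / 2
        if (alpha < config$alphaFloor) alpha <- 0
    }
    if (!pass$ok) {
        # alpha reached zero and a component still collapsed; match what
        # is matchable to keep row order (degenerate input)
        pass$matched <- matchComponents(pass$dec$M, pass$dec$Fsep)
    }
    buildUnmixResult(pass, Fmeas, norm, alpha0, alpha)
}

buildUnmixResult <- function(pass, Fmeas, norm, alpha0, alphaFinal) {
    labels <- if (is(Fmeas, "TraceMatrix")) rowLabels(Fmeas)
              else sprintf("row_%d", seq_len(nrow(pass$matched$Fsep)))
    final <- rescaleOutput(pass$matched, Fmeas, norm$scale)
    new("UnmixResult",
        Fsep = pass$matched$Fsep, M = pass$matched$M,
        finalTraces = final,
        alphaInitial = alpha0, alphaFinal = alphaFinal,
        nIterations = pass$dec$nIterations,
        converged = isTRUE(pass$dec$converged),
        rowLabels = labels)
}

#' Unmix with temporal downsampling of the mixing-matrix estimate
#'
#' Estimates the mixing matrix from every `ratio`-th frame of the
#' normalized input (the mixing weights are nearly independent of the
#' sampling rate), then recovers the separated traces at full temporal
#' resolution by solving, for each frame, the non-negative least-squares
#' problem `Fmeas[, t] ~ M' Fsep[, t]`, and finally rescales and
#' median-aligns as in the direct path. `ratio = 1` is exactly the direct
#' path.
#'
#' @param Fmeas a [TraceMatrix-class] or numeric matrix.
#' @param ratio positive integer decimation factor, `1 <= ratio < T`.
#' @param alpha0 initial regularization weight.
#' @param config a [runConfig()] list.
#' @return An [UnmixResult-class] at full temporal resolution.
#' @export
downsampleUnmix <- function(Fmeas, ratio = 1L, alpha0 = 1,
                            config = runConfig()) {
    v <- if (is(Fmeas, "TraceMatrix")) traceValues(Fmeas) else Fmeas
    ratio <- as.integer(ratio)
    if (ratio < 1L || ratio >= ncol(v))
        stop("ratio must satisfy 1 <= ratio < T")
    if (ratio == 1L)
        return(floatingAlphaUnmix(Fmeas, alpha0, config))
    norm <- normalizeInput(Fmeas)
    Fn <- norm$values
    sub <- Fn[, seq(1L, ncol(Fn), by = ratio), drop = FALSE]
    epsZero <- 1e-9 * quantileStd(Fn[1L, ])
    alpha <- alpha0
    repeat {
        pass <- unmixPass(sub, alpha, config, epsZero)
        if (pass$ok || alpha == 0) break
        alpha <- alpha / 2
        if (alpha < config$alphaFloor) alpha <- 0
    }
    if (!pass$ok)
        pass$matched <- matchComponents(pass$dec$M, pass$dec$Fsep)
    Mp <- pass$matched$M
    rec <- vapply(seq_len(ncol(Fn)), function(t)
        pracma::lsqnonneg(Mp, Fn[, t])$x, numeric(nrow(Fn)))
    pass$matched$Fsep <- matrix(rec, nrow = nrow(Fn))
    buildUnmixResult(pass, Fmeas, norm, alpha0, alpha)
}

#' Unmix every neuron of a video
#'
#' Full pipeline: optional SNR-video conversion, auxiliary region
#' construction, trace extraction and background subtraction, and
#' per-neuron floating-alpha unmixing (with optional temporal
#' downsampling). Neurons are processed independently — optionally in
#' parallel — with a per-neuron solver seed (`config$seed` offset by the
#' neuron id), so results do not depend on the worker count. A failure on
#' one neuron is recorded and the remaining neurons are still processed.
#'
#' @param video a [VideoStack-class].
#' @param masks a [NeuronMasks-class] on the same grid.
#' @param config a [runConfig()] list.
#' @return List of class `"UnmixRun"` with elements `neuronIds`,
#'   `results` (per-neuron [UnmixResult-class] or `NULL`), `errors`
#'   (message or `NA` per neuron), `traceMatrices`, `regions`, `bundles`,
#'   `config`.
#' @export
unmixVideo <- function(video, masks, config = runConfig()) {
    stopifnot(is(video, "VideoStack"), is(masks, "NeuronMasks"))
    if (!identical(dim(videoData(video))[2:3], dim(maskArray(masks))[2:3]))
        stop("masks and video grids differ")
    if (config$useSnrVideo && videoKind(video) == "raw")
        video <- generateSnrVideo(video)
    regions <- buildRegions(masks)
    n <- nMasks(masks)
    bundles <- lapply(seq_len(n), function(i)
        traceBundle(video, masks, regions, i))
    fms <- lapply(seq_len(n), function(i)
        assembleFmeas(video, masks, regions, i, bundles = bundles))
    ids <- maskIds(masks)
    worker <- function(i) {
        cfg <- config
        cfg$seed <- config$seed + ids[i]
        tryCatch(
            list(res = downsampleUnmix(fms[[i]], config$downsampleRatio,
                                       config$alphaInitial, cfg),
                 err = NA_character_),
            error = function(e) list(res = NULL, err = conditionMessage(e)))
    }
    out <- if (config$workers > 1L) {
        parallel::mclapply(seq_len(n), worker, mc.cores = config$workers)
    } else {
        lapply(seq_len(n), worker)
    }
    structure(list(neuronIds = ids,
                   results = lapply(out, `[[`, "res"),
                   errors = vapply(out, `[[`, character(1L), "err"),
                   traceMatrices = fms,
                   regions = regions,
                   bundles = bundles,
                   config = config),
              class = "UnmixRun")
}
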