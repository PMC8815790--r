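# Local maxima of a trace, plateau-aware: a run of equal values is a peak
# if it is strictly above both flanking values; the leftmost frame of the
# run is reported. Trace endpoints are never peaks.
localMaxima <- function(x) {
    r <- rle(x)
    v <- r$values
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(v)
    if (k < 3L) return(integer(0L))
    idx <- 2:(k - 1L)
    isPk <- v[idx] > v[idx - 1L] & v[idx] > v[idx + 1L]
    starts[idx][isPk]
}

# Topographic prominence of each peak: drop from the peak to the higher of
# the two key saddles (the lowest point on the path toward the nearest
# higher terrain, or toward the trace boundary).
peakProminence <- function(x, peaks) {
    vapply(peaks, function(p) {
        h <- x[p]
        i <- p
        minL <- h
        while (i > 1L) {
            i <- i - 1L
            if (x[i] > h) break
            if (x[i] < minL) minL <- x[i]
        }
        i <- p
        minR <- h
        n <- length(x)
        while (i < n) {
            i <- i + 1L
            if (x[i] > h) break
            if (x[i] < minR) minR <- x[i]
        }
        h - max(minL, minR)
    }, numeric(1L))
}

# Leftmost argmin of x over the (1-based, inclusive) window [a, b].
leftmostArgmin <- function(x, a, b) {
    w <- x[a:b]
    a + which.min(w) - 1L
}

# Shared active-period machinery: threshold, group consecutive active
# frames, screen prominent peaks, split multi-peak periods at the local
# minima between prominent peaks (the minimum frame belongs to neither
# transient). Frames in/out are 1-based; the exported tables are 0-based.
detectEventsCore <- function(x, th, promMin) {
    active <- x > th
    if (!any(active)) return(emptyTransients())
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    pks <- localMaxima(x)
    prom <- peakProminence(x, pks)
    prominent <- pks[prom >= promMin]
    out <- list()
    for (k in seq_len(nrow(runs))) {
        s <- runs[k, 1L]; e <- runs[k, 2L]
        inRun <- prominent[prominent >= s & prominent <= e]
        if (length(inRun) == 0L) next
        if (length(inRun) == 1L) {
            out[[length(out) + 1L]] <- c(s, e, inRun)
        } else {
            bounds <- vapply(seq_len(length(inRun) - 1L), function(m)
                leftmostArgmin(x, inRun[m], inRun[m + 1L]), integer(1L))
            segStarts <- c(s, bounds + 1L)
            segEnds <- c(bounds - 1L, e)
            for (m in seq_along(inRun))
                out[[length(out) + 1L]] <-
                    c(segStarts[m], segEnds[m], inRun[m])
        }
    }
    if (length(out) == 0L) return(emptyTransients())
    m <- do.call(rbind, out)
    data.frame(start = m[, 1L] - 1L, end = m[, 2L] - 1L,
               peak = m[, 3L] - 1L)
}

emptyTransients <- function() {
    data.frame(start = integer(0L), end = integer(0L), peak = integer(0L))
}

#' Normalize a trace to SNR units for transient detection
#'
#' Traces extracted from raw videos are first enhanced with the matched
#' temporal filter; traces from SNR videos were already filtered during
#' video conversion, so no additional filtering is applied. The
#' (optionally filtered) trace is then centered on its baseline — the peak
#' of the kernel density of its values — and divided by the noise level.
#' The noise is estimated from the high-frequency power spectral density
#' of the unfiltered trace: the matched kernel has unit L2 norm, so white
#' noise keeps its standard deviation through the filter, and the
#' unfiltered series is the one in the white-noise regime the estimator
#' assumes.
#'
#' @param trace numeric vector, length >= 16.
#' @param frameRate frames per second (used to build the matched kernel).
#' @param applyTemporalFilter TRUE for traces from raw videos.
#' @param decayS,riseS matched-filter template time constants (seconds).
#' @param kernel optional prebuilt `"FilterKernel"` overriding
#'   `decayS`/`riseS`.
#' @param eps noise floor guarding against division by zero.
#' @return Numeric SNR trace of the same length.
#' @export
snrNormalizeTrace <- function(trace, frameRate = 30,
                              applyTemporalFilter = TRUE,
                              decayS = 0.2, riseS = 0, kernel = NULL,
                              eps = 1e-9) {
    if (length(trace) < 16L) stop("trace too short")
    y <- trace
    if (applyTemporalFilter) {
        if (is.null(kernel))
            kernel <- buildMatchedKernel(decayS, riseS, frameRate)
        y <- applyMatchedFilter(trace, kernel)
    }
    noise <- psdNoise(trace)
    (y - kdeBaseline(y)) / max(noise, eps)
}

#' Detect calcium transients in an SNR trace
#'
#' A frame is active when the SNR trace is strictly above `thSnr`.
#' Consecutive active frames form candidate periods; periods keep only
#' peaks whose topographic prominence is at least
#' `thSnr * prominenceFactor`. Periods without a prominent peak are
#' discarded; a period with one prominent peak becomes one transient
#' spanning the period; a period with several prominent peaks is split at
#' the local minima between them, the frame before a boundary minimum
#' ending the preceding transient and the frame after it starting the
#' next.
#'
#' @param snrTrace numeric SNR trace (see [snrNormalizeTrace()]).
#' @param thSnr activity threshold in SNR units (> 0).
#' @param prominenceFactor minimum peak prominence as a fraction of
#'   `thSnr` (default 1/3).
#' @return data.frame with 0-based inclusive `start`, `end`, `peak`
#'   frames, ordered and disjoint.
#' @export
detectTransients <- function(snrTrace, thSnr, prominenceFactor = 1 / 3) {
    stopifnot(thSnr > 0)
    detectEventsCore(snrTrace, thSnr, thSnr * prominenceFactor)
}

#' Ground-truth transients from a clean simulated trace
#'
#' Noiseless simulated traces have stereotyped single-event heights, so
#' the activity threshold can be derived from the trace itself: the trace
#' is matched-filtered like an experimental trace, peaks with prominence
#' of at least the filtered trace's standard deviation are screened, the
#' typical single-transient height is the peak of the kernel density of
#' those peak heights, and half that height serves as both the activity
#' threshold and the minimum prominence for the usual period/peak/split
#' processing.
#'
#' @param gtTrace noiseless numeric trace.
#' @param frameRate frames per second.
#' @param decayS,riseS matched-filter template time constants (seconds).
#' @param kernel optional prebuilt `"FilterKernel"`.
#' @return data.frame of 0-based `start`, `end`, `peak` frames (empty when
#'   the trace has no peaks).
#' @export
gtTransientsFromCleanTrace <- function(gtTrace, frameRate = 30,
                                       decayS = 0.2, riseS = 0,
                                       kernel = NULL) {
    if (is.null(kernel))
        kernel <- buildMatchedKernel(decayS, riseS, frameRate)
    y <- applyMatchedFilter(gtTrace, kernel)
    pks <- localMaxima(y)
    if (length(pks) == 0L) return(emptyTransients())
    prom <- peakProminence(y, pks)
    pks <- pks[prom >= sd(y)]
    if (length(pks) == 0L) return(emptyTransients())
    heights <- y[pks]
    hHat <- if (length(heights) >= 2L) kdeBaseline(heights) else heights[1L]
    detectEventsCore(y, hHat / 2, hHat / 2)
}
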