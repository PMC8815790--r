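#' Configuration for the synthetic video and trace generator
#'
#' Defaults mirror typical video-rate two-photon recordings of a fast
#' calcium indicator at desk scale: a 90 x 90 pixel field, 3000 frames at
#' 30 Hz, 20 disk-like neurons of average radius 5.9 px kept at least
#' 12 px apart, a sparse spiking rate of 0.05 events/s per source, fast
#' rise (0.05 s) and exponential decay (0.2 s) transients, a spatially
#' broad fluctuating background, and additive Gaussian noise.
#'
#' @param H,W,T field height, width (pixels) and frame count.
#' @param frameRate frames per second.
#' @param nNeurons number of disk neurons.
#' @param neuronRadiusPx mean neuron radius (pixels).
#' @param radiusJitterPx uniform radius jitter (pixels).
#' @param minCentroidDistancePx minimum centroid separation (pixels).
#' @param spikeRate Poisson event rate per source (events/s).
#' @param riseS,decayS transient rise/decay time constants (seconds).
#' @param amplitude single-transient peak amplitude (intensity units for
#'   videos; arbitrary units for trace fixtures).
#' @param baseline static fluorescence level added to every video pixel.
#' @param nDendrites number of thin elongated processes with independent
#'   activity.
#' @param dendriteAmplitude transient amplitude of dendrites.
#' @param backgroundFwhmPx spatial FWHM of the broad background blobs.
#' @param backgroundAmplitude temporal standard deviation of each blob's
#'   slowly fluctuating amplitude.
#' @param noiseSigma per-pixel (video) or per-trace (fixture) Gaussian
#'   noise standard deviation.
#' @param crosstalkRange range the off-diagonal mixing coefficients of the
#'   trace fixture are drawn from.
#' @param nComponents number of source traces in the trace fixture
#'   (target + neighbors + outside-like source).
#' @param seed integer seed fixing all randomness.
#' @return A named list of class `"SynthConfig"`.
#' @export
synthConfig <- function(H = 90L, W = 90L, T = 3000L, frameRate = 30,
                        nNeurons = 20L, neuronRadiusPx = 5.9,
                        radiusJitterPx = 0.6,
                        minCentroidDistancePx = 12,
                        spikeRate = 0.05, riseS = 0.05, decayS = 0.2,
                        amplitude = 50, baseline = 100,
                        nDendrites = 4L, dendriteAmplitude = 30,
                        backgroundFwhmPx = 40, backgroundAmplitude = 20,
                        noiseSigma = 10,
                        crosstalkRange = c(0.2, 0.5),
                        nComponents = 4L, seed = 1L) {
    stopifnot(H >= 1, W >= 1, T >= 1, frameRate > 0, spikeRate >= 0,
              decayS > 0, riseS >= 0, length(crosstalkRange) == 2L,
              all(crosstalkRange >= 0), diff(crosstalkRange) >= 0)
    structure(as.list(environment()), class = "SynthConfig")
}

# Transient waveform sampled at the frame rate, peak-normalized to 1,
# truncated at 1% of the peak.
transientWaveform <- function(decayS, riseS, frameRate) {
    t <- seq(0, 10 * decayS + 10 * riseS, by = 1 / frameRate)
    h <- exp(-t / decayS)
    if (riseS > 0) h <- h - exp(-t / riseS)
    h <- h / max(h)
    h[seq_len(max(which(h >= 0.01)))]
}

# Poisson spike train (frame indices, 1-based) with at least one event:
# every simulated source is an active source, so a train that happens to
# draw zero events is redrawn from the continuing RNG stream.
spikeFrames <- function(T, ratePerFrame) {
    for (attempt in seq_len(1000L)) {
        fr <- which(runif(T) < ratePerFrame)
        if (length(fr)) return(fr)
    }
    # rate effectively zero: place a single event deterministically
    max(1L, T %/% 2L)
}

# Convolve a spike train with the waveform, truncated to T frames.
spikesToTrace <- function(spikes, wf, T, amplitude) {
    x <- numeric(T)
    for (s in spikes) {
        idx <- s:min(T, s + length(wf) - 1L)
        x[idx] <- x[idx] + amplitude * wf[seq_along(idx)]
    }
    x
}

# Ground-truth transient table (0-based) from the spike frames used:
# each event spans the frames where its own waveform is at least half the
# peak; overlapping events are merged.
spikesToGtTransients <- function(spikes, wf, T) {
    half <- max(which(wf >= 0.5))
    pk <- which.max(wf)
    ev <- data.frame(start = spikes, end = pmin(spikes + half - 1L, T),
                     peak = pmin(spikes + pk - 1L, T))
    ev <- ev[order(ev$start), , drop = FALSE]
    merged <- ev[1L, , drop = FALSE]
    for (i in seq_len(nrow(ev))[-1L]) {
        last <- nrow(merged)
        if (ev$start[i] <= merged$end[last] + 1L) {
            merged$end[last] <- max(merged$end[last], ev$end[i])
        } else {
            merged <- rbind(merged, ev[i, ])
        }
    }
    data.frame(start = merged$start - 1L, end = merged$end - 1L,
               peak = merged$peak - 1L)
}

#' Generate a linear-mixing trace fixture with known ground truth
#'
#' Draws `nComponents` sparse non-negative source traces (Poisson spike
#' trains convolved with the transient waveform), a mixing matrix
#' `M_true = I + crosstalk`, and the measured matrix
#' `F_meas = M_true F_true + baseline + noise` clipped at zero (the
#' static baseline keeps the clip from truncating the noise, as in real
#' recordings where fluorescence rides on a resting level). The
#' contamination is targeted the way neighboring sources contaminate a
#' neuron of interest: the coefficients mixing every other source into
#' the first (target) row are drawn uniformly from `crosstalkRange`,
#' while the remaining off-diagonal entries get a weaker reciprocal
#' bleed, uniform on `[0, min(max(crosstalkRange), 0.1)]`. Ground-truth
#' transients are recorded from the spike times used, not re-detected.
#'
#' @param cfg a [synthConfig()] list.
#' @return List with `Ftrue`, `Mtrue`, `Fmeas` (matrices) and
#'   `gtTransients` (list of 0-based transient data.frames per
#'   component).
#' @export
simulateTraces <- function(cfg = synthConfig()) {
    withSeed(cfg$seed, {
        n <- cfg$nComponents
        T <- cfg$T
        wf <- transientWaveform(cfg$decayS, cfg$riseS, cfg$frameRate)
        rate <- cfg$spikeRate / cfg$frameRate
        spikes <- lapply(seq_len(n), function(i) spikeFrames(T, rate))
        Ftrue <- do.call(rbind, lapply(spikes, function(s)
            spikesToTrace(s, wf, T, cfg$amplitude)))
        gt <- lapply(spikes, spikesToGtTransients, wf = wf, T = T)
        Mtrue <- diag(n)
        Mtrue[1L, -1L] <- runif(n - 1L, cfg$crosstalkRange[1L],
                                cfg$crosstalkRange[2L])
        weak <- min(cfg$crosstalkRange[2L], 0.1)
        for (i in seq_len(n)[-1L])
            Mtrue[i, -i] <- runif(n - 1L, 0, weak)
        Fmeas <- Mtrue %*% Ftrue + cfg$baseline
        if (cfg$noiseSigma > 0)
            Fmeas <- Fmeas + matrix(rnorm(n * T, 0, cfg$noiseSigma), n, T)
        Fmeas <- pmax(Fmeas, 0)
        list(Ftrue = Ftrue, Mtrue = Mtrue, Fmeas = Fmeas,
             gtTransients = gt)
    })
}

# Disk footprint (logical H x W) at a 0-based center.
diskFootprint <- function(center, radius, h, w) {
    diskMask(center, radius, h, w)
}

# Thin dendrite-like segment footprint.
segmentFootprint <- function(p0, angle, len, h, w) {
    steps <- seq(0, len, by = 0.5)
    rows <- round(p0[1L] + steps * sin(angle))
    cols <- round(p0[2L] + steps * cos(angle))
    keep <- rows >= 0 & rows < h & cols >= 0 & cols < w
    m <- matrix(FALSE, h, w)
    m[cbind(rows[keep] + 1L, cols[keep] + 1L)] <- TRUE
    m
}

#' Generate a synthetic fluorescence video with known ground truth
#'
#' Places disk-like neurons with jittered radii by rejection sampling
#' (centroids at least `minCentroidDistancePx` apart), adds thin
#' dendrite-like segments with independent activity, a spatially broad
#' background made of three Gaussian blobs whose amplitudes follow
#' independent slow random walks, a static baseline and per-pixel
#' Gaussian noise, clipping at zero. Every source's clean trace and
#' spike-derived transients are exported as ground truth.
#'
#' @param cfg a [synthConfig()] list.
#' @return List with `video` ([VideoStack-class]), `masks`
#'   ([NeuronMasks-class]), `cleanTraces` (nNeurons x T matrix),
#'   `gtTransients` (list per neuron), `backgroundField` (blob amplitude
#'   matrix, 3 x T), `dendriteMasks`.
#' @export
simulateVideo <- function(cfg = synthConfig()) {
    withSeed(cfg$seed, {
        h <- cfg$H; w <- cfg$W; T <- cfg$T
        margin <- cfg$neuronRadiusPx + cfg$radiusJitterPx + 1
        centers <- matrix(numeric(0L), 0L, 2L)
        attempts <- 0L
        while (nrow(centers) < cfg$nNeurons) {
            attempts <- attempts + 1L
            if (attempts > 1e4L) stop("too dense")
            cand <- c(runif(1L, margin, h - 1 - margin),
                      runif(1L, margin, w - 1 - margin))
            if (nrow(centers) == 0L ||
                min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) >=
                    cfg$minCentroidDistancePx)
                centers <- rbind(centers, cand)
        }
        radii <- cfg$neuronRadiusPx +
            runif(cfg$nNeurons, -cfg$radiusJitterPx, cfg$radiusJitterPx)
        foot <- lapply(seq_len(cfg$nNeurons), function(i)
            diskFootprint(centers[i, ], radii[i], h, w))
        wf <- transientWaveform(cfg$decayS, cfg$riseS, cfg$frameRate)
        rate <- cfg$spikeRate / cfg$frameRate
        spikes <- lapply(seq_len(cfg$nNeurons), function(i)
            spikeFrames(T, rate))
        clean <- do.call(rbind, lapply(spikes, function(s)
            spikesToTrace(s, wf, T, cfg$amplitude)))
        gt <- lapply(spikes, spikesToGtTransients, wf = wf, T = T)

        dFoot <- list(); dTraces <- NULL
        if (cfg$nDendrites > 0L) {
            dFoot <- lapply(seq_len(cfg$nDendrites), function(i)
                segmentFootprint(c(runif(1L, 0, h - 1), runif(1L, 0, w - 1)),
                                 runif(1L, 0, 2 * pi),
                                 runif(1L, 15, 35), h, w))
            dTraces <- do.call(rbind, lapply(seq_len(cfg$nDendrites),
                function(i) spikesToTrace(spikeFrames(T, rate), wf, T,
                                          cfg$dendriteAmplitude)))
        }

        nBlobs <- 3L
        sig <- cfg$backgroundFwhmPx / (2 * sqrt(2 * log(2)))
        rows <- matrix(0:(h - 1L), h, w)
        cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
        blobs <- lapply(seq_len(nBlobs), function(k) {
            c0 <- c(runif(1L, 0, h - 1), runif(1L, 0, w - 1))
            exp(-((rows - c0[1L])^2 + (cols - c0[2L])^2) / (2 * sig^2))
        })
        bgAmp <- do.call(rbind, lapply(seq_len(nBlobs), function(k) {
            rw <- cumsum(rnorm(T))
            if (sd(rw) > 0) rw <- (rw - mean(rw)) / sd(rw)
            rw * cfg$backgroundAmplitude
        }))

        # compose frames: pixels x T intensity matrix
        px <- matrix(cfg$baseline, h * w, T)
        for (i in seq_len(cfg$nNeurons))
            px[as.vector(foot[[i]]), ] <-
                px[as.vector(foot[[i]]), , drop = FALSE] +
                matrix(clean[i, ], sum(foot[[i]]), T, byrow = TRUE)
        for (i in seq_along(dFoot))
            if (any(dFoot[[i]]))
                px[as.vector(dFoot[[i]]), ] <-
                    px[as.vector(dFoot[[i]]), , drop = FALSE] +
                    matrix(dTraces[i, ], sum(dFoot[[i]]), T, byrow = TRUE)
        for (k in seq_len(nBlobs))
            px <- px + as.vector(blobs[[k]]) %o% bgAmp[k, ]
        if (cfg$noiseSigma > 0)
            px <- px + matrix(rnorm(length(px), 0, cfg$noiseSigma),
                              nrow(px), ncol(px))
        px <- pmax(px, 0)
        vid <- array(0, c(T, h, w))
        for (t in seq_len(T)) vid[t, , ] <- matrix(px[, t], h, w)

        list(video = VideoStack(vid, frameRate = cfg$frameRate,
                                kind = "raw"),
             masks = NeuronMasks(foot),
             cleanTraces = clean,
             gtTransients = gt,
             backgroundField = bgAmp,
             dendriteMasks = dFoot)
    })
}
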