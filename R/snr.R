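#' Spatial homomorphic filtering of a raw video
#'
#' Removes multiplicative, spatially broad background (uneven illumination,
#' out-of-focus fluorescence) from each frame: the frame is log-transformed,
#' a Gaussian low-pass of the log image is subtracted, the mean log level is
#' added back, and the result is exponentiated. Structure smaller than the
#' filter scale (neurons, processes) is preserved; gradients broader than
#' the FWHM are flattened.
#'
#' @param video a raw-kind [VideoStack-class].
#' @param spatialFwhmUm full width at half maximum of the Gaussian low-pass,
#'   in micrometers; must exceed the pixel size.
#' @param pixelSizeUm pixel pitch in micrometers per pixel.
#' @param logOffset intensity added before the log to handle zeros
#'   (default 1).
#' @return A raw-kind [VideoStack-class] with non-negative values.
#' @export
homomorphicFilter <- function(video, spatialFwhmUm, pixelSizeUm = 1,
                              logOffset = 1) {
    stopifnot(is(video, "VideoStack"))
    if (videoKind(video) != "raw")
        stop("homomorphicFilter expects a raw-kind video")
    if (spatialFwhmUm <= 0)
        stop("spatialFwhmUm must be positive")
    if (spatialFwhmUm <= pixelSizeUm)
        stop("spatialFwhmUm must exceed the pixel size")
    sigmaPx <- (spatialFwhmUm / pixelSizeUm) / (2 * sqrt(2 * log(2)))
    d <- videoData(video)
    out <- array(0, dim(d))
    for (t in seq_len(dim(d)[1L])) {
        L <- log(d[t, , ] + logOffset)
        lp <- gaussLowpass2d(L, sigmaPx)
        out[t, , ] <- pmax(exp(L - lp + mean(lp)) - logOffset, 0)
    }
    VideoStack(out, frameRate = frameRate(video), kind = "raw")
}

# Gaussian low-pass via FFT on an even (mirror) extension of the image;
# mirroring avoids wrap-around artifacts at the borders, and the transfer
# function exp(-2 pi^2 sigma^2 f^2) sends every non-DC component to zero as
# sigma grows, so very wide filters reduce exactly to the image mean.
gaussLowpass2d <- function(img, sigma) {
    h <- nrow(img); w <- ncol(img)
    big <- img[c(seq_len(h), rev(seq_len(h))), c(seq_len(w), rev(seq_len(w)))]
    n1 <- 2L * h; n2 <- 2L * w
    f1 <- c(0:(n1 %/% 2L), -((n1 - n1 %/% 2L - 1L):1L)) / n1
    f2 <- c(0:(n2 %/% 2L), -((n2 - n2 %/% 2L - 1L):1L)) / n2
    g1 <- exp(-2 * pi^2 * sigma^2 * f1^2)
    g2 <- exp(-2 * pi^2 * sigma^2 * f2^2)
    sm <- Re(fft(fft(big) * outer(g1, g2), inverse = TRUE)) / (n1 * n2)
    sm[seq_len(h), seq_len(w)]
}

#' Build a matched temporal filter for calcium transients
#'
#' The template is a difference-of-exponentials transient (instant or finite
#' rise, exponential decay) sampled at the frame rate, truncated where its
#' amplitude falls below 1% of the peak. The taps are the time-reversed
#' template normalized to unit L2 norm, so that filtering white noise of
#' standard deviation `sigma` leaves its standard deviation at `sigma`
#' while boosting the peak response to a matching transient.
#'
#' @param decayS decay time constant in seconds (> 0).
#' @param riseS rise time constant in seconds (>= 0; 0 = instant rise).
#' @param frameRate sampling rate in frames per second.
#' @return An object of class `"FilterKernel"` with elements `taps`
#'   (unit-L2-norm, non-negative, time-reversed template) and `frameRate`.
#' @export
buildMatchedKernel <- function(decayS, riseS = 0, frameRate = 30) {
    if (decayS <= 0) stop("decayS must be positive")
    if (riseS < 0) stop("riseS must be non-negative")
    tMax <- 10 * decayS + 10 * riseS
    t <- seq(0, tMax, by = 1 / frameRate)
    h <- exp(-t / decayS)
    if (riseS > 0) h <- h - exp(-t / riseS)
    pk <- max(h)
    last <- max(which(h >= 0.01 * pk))
    h <- h[seq_len(last)]
    taps <- rev(h) / sqrt(sum(h^2))
    structure(list(taps = taps, frameRate = frameRate),
              class = "FilterKernel")
}

#' Apply a matched temporal filter to a trace or trace matrix
#'
#' Computes the correlation of the signal with the forward template
#' (equivalently, convolution with the stored time-reversed taps), aligned
#' so that the response to a transient peaks at the transient onset — event
#' timing does not shift. Output has the same length as the input; the
#' trailing frames, where the kernel window runs past the end of the
#' trace, see the last sample replicated, so a constant baseline passes
#' through the filter as a constant (the final kernel-length frames are
#' still edge-affected for fluctuating signals).
#'
#' @param x numeric vector, or a matrix filtered along rows.
#' @param kernel a `"FilterKernel"` from [buildMatchedKernel()].
#' @return Filtered signal with the dimensions of `x`.
#' @export
applyMatchedFilter <- function(x, kernel) {
    stopifnot(inherits(kernel, "FilterKernel"))
    tpl <- rev(kernel$taps)            # forward template, unit norm
    if (is.matrix(x)) {
        return(t(apply(x, 1L, applyMatchedFilter, kernel = kernel)))
    }
    n <- length(x)
    k <- length(tpl)
    xx <- c(x, rep(x[n], k - 1L))      # replicate-pad the trailing edge
    y <- numeric(n)
    for (j in seq_len(k)) {
        y <- y + tpl[j] * xx[j:(j + n - 1L)]
    }
    y
}

#' Whiten a video pixel-by-pixel into SNR units
#'
#' Each pixel's time series is centered by its temporal median and divided
#' by its quantile-based standard deviation (floored at `eps` to protect
#' dead pixels), so that quiescent fluctuations have unit scale and
#' transients read directly in noise units.
#'
#' @param video a [VideoStack-class] with at least 2 frames.
#' @param eps noise floor for the per-pixel scale (default 1e-9).
#' @return An snr-kind [VideoStack-class].
#' @export
whitenPixels <- function(video, eps = 1e-9) {
    stopifnot(is(video, "VideoStack"))
    d <- videoData(video)
    nt <- dim(d)[1L]
    if (nt < 2L) stop("whitenPixels needs at least 2 frames")
    hw <- dim(d)[2:3]
    dim(d) <- c(nt, prod(hw))
    med <- apply(d, 2L, median)
    sc <- pmax(apply(d, 2L, quantileStd), eps)
    d <- sweep(sweep(d, 2L, med, "-"), 2L, sc, "/")
    dim(d) <- c(nt, hw)
    VideoStack(d, frameRate = frameRate(video), kind = "snr")
}

#' Convert a raw video into a signal-to-noise-ratio video
#'
#' Runs the three-stage SNR conversion: spatial homomorphic filtering to
#' remove broad background, temporal matched filtering to enhance
#' stereotyped calcium transients, and per-pixel whitening. In the output,
#' pixel values are in noise units: quiescent pixels fluctuate around 0
#' with unit robust scale, and transients stand out as large positive
#' excursions.
#'
#' @param video a raw-kind [VideoStack-class].
#' @param spatialFwhmUm homomorphic low-pass FWHM in micrometers.
#' @param pixelSizeUm pixel pitch in micrometers per pixel.
#' @param decayS,riseS matched-filter template time constants in seconds.
#' @param logOffset offset added before the log (see
#'   [homomorphicFilter()]).
#' @return An snr-kind [VideoStack-class].
#' @export
generateSnrVideo <- function(video, spatialFwhmUm = 30, pixelSizeUm = 1,
                             decayS = 0.2, riseS = 0, logOffset = 1) {
    stopifnot(is(video, "VideoStack"))
    if (videoKind(video) != "raw")
        stop("generateSnrVideo expects a raw-kind video")
    hf <- homomorphicFilter(video, spatialFwhmUm, pixelSizeUm, logOffset)
    kern <- buildMatchedKernel(decayS, riseS, frameRate(video))
    d <- videoData(hf)
    nt <- dim(d)[1L]; hw <- dim(d)[2:3]
    dim(d) <- c(nt, prod(hw))
    for (p in seq_len(ncol(d))) d[, p] <- applyMatchedFilter(d[, p], kern)
    dim(d) <- c(nt, hw)
    filtered <- VideoStack(d, frameRate = frameRate(video), kind = "snr")
    whitenPixels(filtered)
}
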