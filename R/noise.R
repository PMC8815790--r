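#' Quantile-based standard deviation
#'
#' Robust spread estimate from the gap between the median and the 25th
#' percentile, `(Q50 - Q25) / 0.6745`. The divisor is the 0.75 quantile of
#' the standard normal, so for Gaussian data the estimate converges to the
#' true standard deviation; sparse positive transients inflate it far less
#' than they inflate [stats::sd()]. Quantiles use linear interpolation
#' (type 7).
#'
#' @param x numeric vector, length >= 2, finite.
#' @return Non-negative scalar; 0 for a constant series.
#' @examples
#' quantileStd(rnorm(1000))  # close to 1
#' quantileStd(rep(5, 10))   # exactly 0
#' @export
quantileStd <- function(x) {
    if (length(x) < 2L)
        stop("quantileStd needs at least 2 samples")
    q <- quantile(x, c(0.25, 0.5), names = FALSE, type = 7)
    (q[2L] - q[1L]) / 0.6745
}

#' Baseline from the peak of a kernel density estimate
#'
#' Estimates a trace's resting level as the mode of a Gaussian kernel
#' density estimate of its values: transients are sparse, so the density
#' peaks at the baseline. Bandwidth is Silverman's rule-of-thumb; the argmax
#' is taken over a 256-point grid spanning the sample range.
#'
#' @param x numeric vector, length >= 2, finite.
#' @return Scalar baseline estimate.
#' @export
kdeBaseline <- function(x) {
    if (length(x) < 2L)
        stop("kdeBaseline needs at least 2 samples")
    if (max(x) == min(x))
        return(x[1L])
    d <- density(x, bw = "nrd0", n = 256L, from = min(x), to = max(x))
    d$x[which.max(d$y)]
}

#' Noise level from the high-frequency power spectral density
#'
#' Estimates the white-noise standard deviation of a trace from the mean of
#' its one-sided Welch power spectral density over the upper half of the
#' Nyquist range, where calcium-transient energy is negligible. Scaled so
#' that white noise of standard deviation `sigma` returns approximately
#' `sigma`.
#'
#' @param x numeric vector, length >= 16.
#' @param bandFraction lower edge of the noise band as a fraction of the
#'   Nyquist frequency (default 0.5: the top half).
#' @return Non-negative scalar; 0 for a constant series.
#' @export
psdNoise <- function(x, bandFraction = 0.5) {
    n <- length(x)
    if (n < 16L)
        stop("psdNoise needs at least 16 samples")
    if (max(x) == min(x))
        return(0)
    w <- welchPsd(x)
    band <- w$freq >= bandFraction * 0.5 & w$freq < 0.5
    sqrt(mean(w$psd[band]) * 0.5)
}

# Welch PSD with Hann windows and 50% overlap, normalized as a one-sided
# density on normalized frequency [0, 0.5]: sum(psd) * df ~= var(x) for
# white noise. Segment length: power of two near length(x)/8, clamped to
# [16, 256].
welchPsd <- function(x) {
    n <- length(x)
    nseg <- 2^floor(log2(max(min(n / 8, 256), 16)))
    nseg <- min(nseg, n)
    step <- max(1L, nseg %/% 2L)
    starts <- seq(1L, n - nseg + 1L, by = step)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
    u <- sum(win^2)
    nf <- nseg %/% 2L
    acc <- numeric(nf + 1L)
    for (s in starts) {
        seg <- x[s:(s + nseg - 1L)]
        seg <- (seg - mean(seg)) * win
        p <- Mod(fft(seg))^2 / u
        acc <- acc + p[seq_len(nf + 1L)]
    }
    p <- acc / length(starts)
    # one-sided density on normalized frequency: double interior bins so
    # that sum(psd) / nseg ~= var(x) for white noise
    if (nf >= 2L) p[2:nf] <- 2 * p[2:nf]
    freq <- (0:nf) / nseg
    list(freq = freq, psd = p)
}
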