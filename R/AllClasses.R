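#' @import methods
#' @importFrom stats median quantile sd density fft rnorm runif rpois convolve
#' @importFrom utils write.csv read.csv head tail
NULL

#' VideoStack: a fluorescence video with frame-rate metadata
#'
#' Holds a `T x H x W` array of intensities (frame index first), the
#' acquisition frame rate, and a kind flag distinguishing raw intensity
#' videos (non-negative) from signal-to-noise-ratio videos (real-valued,
#' obtained by [generateSnrVideo()]).
#'
#' @slot data numeric array, dimension `c(T, H, W)`.
#' @slot frameRate frames per second.
#' @slot kind `"raw"` or `"snr"`.
#' @export
setClass("VideoStack",
    representation(data = "array", frameRate = "numeric", kind = "character"),
    prototype(frameRate = 30, kind = "raw"))

setValidity("VideoStack", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
        return("data must be a 3-D array (frame, row, column)")
    if (any(dim(d) < 1L))
        return("all of T, H, W must be >= 1")
    if (!all(is.finite(d)))
        return("video values must be finite")
    if (!object@kind %in% c("raw", "snr"))
        return("kind must be 'raw' or 'snr'")
    if (object@kind == "raw" && any(d < 0))
        return("raw-kind video contains negative values")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
        return("frameRate must be a single positive number")
    TRUE
})

#' Construct a VideoStack
#'
#' @param data 3-D numeric array `(T, H, W)`; widened to double.
#' @param frameRate frames per second.
#' @param kind `"raw"` (non-negative intensities) or `"snr"`.
#' @return A [VideoStack-class] object.
#' @examples
#' v <- VideoStack(array(1, c(3, 4, 4)), frameRate = 30)
#' nFrames(v)
#' @export
VideoStack <- function(data, frameRate = 30, kind = c("raw", "snr")) {
    kind <- match.arg(kind)
    storage.mode(data) <- "double"
    new("VideoStack", data = data, frameRate = frameRate, kind = kind)
}

#' NeuronMasks: binary neuron footprints on a shared grid
#'
#' @slot masks logical array, dimension `c(N, H, W)`; every slice must have
#'   at least one TRUE pixel.
#' @slot ids stable integer labels, one per mask.
#' @export
setClass("NeuronMasks",
    representation(masks = "array", ids = "integer"))

setValidity("NeuronMasks", function(object) {
    m <- object@masks
    if (length(dim(m)) != 3L)
        return("masks must be a 3-D logical array (neuron, row, column)")
    if (!is.logical(m))
        return("masks must be logical")
    if (dim(m)[1L] != length(object@ids))
        return("one id per mask required")
    if (anyDuplicated(object@ids))
        return("mask ids must be unique")
    areas <- apply(m, 1L, sum)
    if (any(areas < 1L))
        return(sprintf("empty mask (id %s)", object@ids[which(areas < 1L)[1L]]))
    TRUE
})

#' Construct a NeuronMasks object
#'
#' @param masks logical array `(N, H, W)`, or a list of `H x W` logical
#'   matrices.
#' @param ids integer labels; defaults to `0:(N-1)` in storage order.
#' @return A [NeuronMasks-class] object.
#' @export
NeuronMasks <- function(masks, ids = NULL) {
    if (is.list(masks)) {
        d <- dim(masks[[1L]])
        arr <- array(FALSE, c(length(masks), d[1L], d[2L]))
        for (i in seq_along(masks)) arr[i, , ] <- masks[[i]]
        masks <- arr
    }
    if (!is.logical(masks)) {
        mode(masks) <- "logical"
    }
    if (is.null(ids)) ids <- seq_len(dim(masks)[1L]) - 1L
    new("NeuronMasks", masks = masks, ids = as.integer(ids))
}

#' NeuronRegions: auxiliary regions for one neuron
#'
#' The background mask is a disk centered at the neuron centroid with radius
#' 2.5 times the radius of a circle whose area equals the average neuron
#' area. Neighbors are the other neurons whose centroids fall inside that
#' disk. The outside mask is the (possibly radius-grown) disk minus the union
#' of all neuron masks.
#'
#' @slot neuronId integer id of the neuron.
#' @slot backgroundMask logical `H x W` disk.
#' @slot outsideMask logical `H x W` neuron-free region.
#' @slot neighborIds integer ids of neighboring neurons, ascending.
#' @slot bgRadiusPx background-disk radius in pixels.
#' @slot outsideRadiusPx final radius of the outside-region disk (grown in
#'   1-px steps when the region is too small).
#' @export
setClass("NeuronRegions",
    representation(neuronId = "integer", backgroundMask = "matrix",
        outsideMask = "matrix", neighborIds = "integer",
        bgRadiusPx = "numeric", outsideRadiusPx = "numeric"))

setValidity("NeuronRegions", function(object) {
    if (!all(object@backgroundMask[object@outsideMask] |
             object@outsideRadiusPx > object@bgRadiusPx))
        return("outside mask must lie within the background disk unless grown")
    if (sum(object@outsideMask) < 1L)
        return("outside mask is empty")
    TRUE
})

#' TraceMatrix: the measured trace set fed to the unmixer
#'
#' Rows are background-subtracted traces ordered target neuron first, then
#' neighbors in ascending id order, then the outside region last.
#'
#' @slot values numeric `(k+2) x T` matrix.
#' @slot rowLabels character labels (`"neuron"`, `"neighbor_<id>"`,
#'   `"outside"`).
#' @slot neuronId id of the target neuron.
#' @slot neighborIds ids of the neighbor rows, ascending.
#' @export
setClass("TraceMatrix",
    representation(values = "matrix", rowLabels = "character",
        neuronId = "integer", neighborIds = "integer"))

setValidity("TraceMatrix", function(object) {
    v <- object@values
    if (nrow(v) != length(object@rowLabels))
        return("one label per row required")
    if (nrow(v) != length(object@neighborIds) + 2L)
        return("row count must be number of neighbors + 2")
    if (object@rowLabels[1L] != "neuron" ||
        object@rowLabels[nrow(v)] != "outside")
        return("first row must be the target neuron, last row the outside region")
    if (!all(is.finite(v)))
        return("trace values must be finite")
    TRUE
})

#' UnmixResult: output of the targeted NMF unmixing of one neuron
#'
#' @slot Fsep numeric `(k+2) x T` matrix of separated traces, matched to the
#'   input row order (component i explains measured row i).
#' @slot M non-negative `(k+2) x (k+2)` mixing matrix with unit diagonal;
#'   `M[i, j]` is the contribution of component j to measured trace i.
#' @slot finalTraces separated traces rescaled to the input amplitude with
#'   medians aligned to the input rows; row 1 is the decontaminated trace of
#'   the target neuron.
#' @slot alphaInitial,alphaFinal regularization weight before/after the
#'   floating-alpha recursion.
#' @slot nIterations solver iterations of the accepted run.
#' @slot converged TRUE if the solver met its tolerance before the
#'   iteration cap.
#' @slot rowLabels row labels copied from the input [TraceMatrix-class].
#' @export
setClass("UnmixResult",
    representation(Fsep = "matrix", M = "matrix", finalTraces = "matrix",
        alphaInitial = "numeric", alphaFinal = "numeric",
        nIterations = "integer", converged = "logical",
        rowLabels = "character"))

setValidity("UnmixResult", function(object) {
    if (any(object@M < 0))
        return("mixing matrix must be non-negative")
    if (nrow(object@Fsep) != nrow(object@M))
        return("Fsep and M disagree on component count")
    if (max(abs(diag(object@M) - 1)) > 1e-8)
        return("mixing-matrix diagonal must be 1 after matching")
    TRUE
})

#' Run configuration for the unmixing pipeline
#'
#' Defaults reproduce the reference settings: `l1 = 0.5`, at most 20000
#' solver iterations, tolerance `1e-4`, initial regularization weight 1.
#'
#' @param alphaInitial initial regularization weight, >= 0.
#' @param l1Ratio balance between L1 and L2 penalties in `[0, 1]`.
#' @param thSnr transient-detection threshold on the SNR trace.
#' @param downsampleRatio positive integer temporal decimation factor for
#'   the mixing-matrix estimate (1 = no downsampling).
#' @param useSnrVideo convert the raw video to an SNR video before trace
#'   extraction.
#' @param workers number of worker processes for per-neuron stages.
#' @param seed integer seed for the solver's random initialization fill-in.
#' @param maxIter solver iteration cap.
#' @param tol solver relative tolerance.
#' @param alphaFloor below this the floating-alpha recursion falls back to a
#'   single unregularized pass.
#' @return A named list of class `"RunConfig"`.
#' @export
runConfig <- function(alphaInitial = 1, l1Ratio = 0.5, thSnr = 5,
                      downsampleRatio = 1L, useSnrVideo = FALSE,
                      workers = 1L, seed = 1L,
                      maxIter = 20000L, tol = 1e-4, alphaFloor = 1e-4) {
    stopifnot(alphaInitial >= 0, l1Ratio >= 0, l1Ratio <= 1, thSnr > 0,
              downsampleRatio >= 1, workers >= 1)
    structure(list(alphaInitial = alphaInitial, l1Ratio = l1Ratio,
                   thSnr = thSnr, downsampleRatio = as.integer(downsampleRatio),
                   useSnrVideo = useSnrVideo, workers = as.integer(workers),
                   seed = as.integer(seed), maxIter = as.integer(maxIter),
                   tol = tol, alphaFloor = alphaFloor),
              class = "RunConfig")
}
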