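#' Mean trace over a binary mask
#'
#' Per-frame arithmetic mean of the video intensities over the mask pixels.
#' Overlapping neuron masks both keep their shared pixels: no exclusive
#' assignment is made at this stage; unmixing resolves the shared signal.
#'
#' @param video a [VideoStack-class].
#' @param mask logical `H x W` matrix with at least one TRUE pixel.
#' @return Numeric vector of length `T`.
#' @export
extractMeanTrace <- function(video, mask) {
    stopifnot(is(video, "VideoStack"))
    d <- videoData(video)
    if (!identical(dim(d)[2:3], dim(mask)))
        stop("mask grid does not match the video")
    if (!any(mask)) stop("empty mask")
    nt <- dim(d)[1L]
    dim(d) <- c(nt, prod(dim(mask)))
    rowMeans(d[, as.vector(mask), drop = FALSE])
}

#' Median background trace over a background disk
#'
#' Per-frame median of the video intensities over the disk pixels. With an
#' even pixel count the mean of the two middle values is used. The median
#' tracks the broad background level while ignoring the sparse bright
#' pixels of neurons inside the disk.
#'
#' @param video a [VideoStack-class].
#' @param backgroundMask logical `H x W` matrix with at least one TRUE
#'   pixel.
#' @return Numeric vector of length `T`.
#' @export
extractBackgroundTrace <- function(video, backgroundMask) {
    stopifnot(is(video, "VideoStack"))
    d <- videoData(video)
    if (!identical(dim(d)[2:3], dim(backgroundMask)))
        stop("mask grid does not match the video")
    if (!any(backgroundMask)) stop("empty mask")
    nt <- dim(d)[1L]
    dim(d) <- c(nt, prod(dim(backgroundMask)))
    sub <- d[, as.vector(backgroundMask), drop = FALSE]
    apply(sub, 1L, median)
}

# Per-neuron trace bundle: raw neuron / raw outside / background traces and
# their background-subtracted versions. Background subtraction may leave
# negative values; non-negativity is restored by the global-minimum shift
# inside the unmixer.
traceBundle <- function(video, masks, regions, i) {
    mask <- getMask(masks, i)
    reg <- regions[[i]]
    rawNeuron <- extractMeanTrace(video, mask)
    rawOutside <- extractMeanTrace(video, reg@outsideMask)
    background <- extractBackgroundTrace(video, reg@backgroundMask)
    list(neuronId = maskIds(masks)[i],
         rawNeuron = rawNeuron, rawOutside = rawOutside,
         background = background,
         bgSubNeuron = rawNeuron - background,
         bgSubOutside = rawOutside - background)
}

#' Assemble the measured trace matrix for one neuron
#'
#' Builds the `(k+2) x T` input to the unmixer: row 1 is the target
#' neuron's background-subtracted trace (its own background disk), the
#' middle rows are each neighbor's neuron trace minus that neighbor's own
#' background, and the last row is the target's outside-region trace minus
#' the target's background.
#'
#' @param video a [VideoStack-class].
#' @param masks a [NeuronMasks-class].
#' @param regions region list from [buildRegions()].
#' @param i 1-based index of the target neuron.
#' @param bundles optional precomputed list of trace bundles (one per
#'   neuron, in mask order) to avoid re-extraction.
#' @return A [TraceMatrix-class].
#' @export
assembleFmeas <- function(video, masks, regions, i, bundles = NULL) {
    stopifnot(length(regions) == nMasks(masks))
    if (is.null(bundles)) {
        need <- c(i, match(regions[[i]]@neighborIds, maskIds(masks)))
        bundles <- vector("list", nMasks(masks))
        for (j in need) bundles[[j]] <- traceBundle(video, masks, regions, j)
    }
    own <- bundles[[i]]
    nb <- regions[[i]]@neighborIds
    nbIdx <- match(nb, maskIds(masks))
    rows <- rbind(own$bgSubNeuron,
                  if (length(nbIdx))
                      do.call(rbind, lapply(nbIdx, function(j)
                          bundles[[j]]$bgSubNeuron)),
                  own$bgSubOutside)
    labels <- c("neuron",
                if (length(nb)) paste0("neighbor_", nb),
                "outside")
    dimnames(rows) <- NULL
    new("TraceMatrix", values = rows, rowLabels = labels,
        neuronId = own$neuronId, neighborIds = as.integer(nb))
}
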