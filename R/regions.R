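#' Average equivalent neuron radius
#'
#' Radius of a circle whose area equals the average area of all neuron
#' masks, `sqrt(mean_area / pi)`.
#'
#' @param masks a [NeuronMasks-class] object.
#' @return Radius in pixels.
#' @export
averageNeuronRadius <- function(masks) {
    stopifnot(is(masks, "NeuronMasks"))
    sqrt(mean(apply(maskArray(masks), 1L, sum)) / pi)
}

# Unweighted centroid of the TRUE pixels of a binary matrix, as (row, col)
# in 0-based pixel-center coordinates.
maskCentroid <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    colMeans(idx) - 1
}

# Disk of pixel centers within `radius` of `center` (0-based row/col),
# clipped to the H x W frame.
diskMask <- function(center, radius, h, w) {
    rows <- matrix(0:(h - 1L), h, w)
    cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
    (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
}

#' Background disk of one neuron
#'
#' A disk centered at the neuron's centroid with radius 2.5 times the
#' average equivalent neuron radius, clipped to the frame. Pixel membership
#' is decided at pixel centers (distance <= radius).
#'
#' @param masks a [NeuronMasks-class] object.
#' @param i 1-based neuron index.
#' @return List with `mask` (logical `H x W`), `radius` (pixels) and
#'   `centroid` (0-based row/col).
#' @export
backgroundMask <- function(masks, i) {
    stopifnot(is(masks, "NeuronMasks"), i >= 1, i <= nMasks(masks))
    r <- 2.5 * averageNeuronRadius(masks)
    ctr <- maskCentroid(getMask(masks, i))
    hw <- dim(maskArray(masks))[2:3]
    list(mask = diskMask(ctr, r, hw[1L], hw[2L]), radius = r, centroid = ctr)
}

#' Neighboring neurons of one neuron
#'
#' Neurons whose centroids fall inside the neuron's background disk
#' (centroid-to-centroid distance <= disk radius), in ascending id order.
#'
#' @param masks a [NeuronMasks-class] object.
#' @param i 1-based neuron index.
#' @param bg background-disk description from [backgroundMask()]
#'   (recomputed if omitted).
#' @return Integer vector of neighbor ids (possibly empty).
#' @export
neighborIds <- function(masks, i, bg = backgroundMask(masks, i)) {
    ids <- maskIds(masks)
    ctr <- bg$centroid
    keep <- vapply(seq_len(nMasks(masks)), function(j) {
        if (j == i) return(FALSE)
        cj <- maskCentroid(getMask(masks, j))
        sqrt(sum((cj - ctr)^2)) <= bg$radius
    }, logical(1L))
    sort(ids[keep])
}

#' Outside region of one neuron
#'
#' The background disk minus the union of all neuron masks. If the
#' remaining area is smaller than half the average neuron area, the disk
#' radius used for the outside region is grown by one pixel (re-clipping,
#' re-subtracting) until the area reaches that threshold; the background
#' disk itself is never grown.
#'
#' @param masks a [NeuronMasks-class] object.
#' @param i 1-based neuron index.
#' @param bg background-disk description from [backgroundMask()].
#' @return List with `mask` (logical `H x W`) and `radius` (final radius of
#'   the disk the outside region was cut from).
#' @export
outsideMask <- function(masks, i, bg = backgroundMask(masks, i)) {
    arr <- maskArray(masks)
    hw <- dim(arr)[2:3]
    anyNeuron <- apply(arr, c(2L, 3L), any)
    thr <- mean(apply(arr, 1L, sum)) / 2
    r <- bg$radius
    out <- bg$mask & !anyNeuron
    maxR <- sqrt(sum(hw^2))
    while (sum(out) < thr) {
        r <- r + 1
        if (r > maxR)
            stop("field too crowded: outside region cannot reach the minimum area")
        out <- diskMask(bg$centroid, r, hw[1L], hw[2L]) & !anyNeuron
    }
    list(mask = out, radius = r)
}

#' Build auxiliary regions for every neuron
#'
#' Constructs, for each neuron, its background disk, outside region and
#' neighbor list (the inputs to trace extraction and unmixing). The result
#' is deterministic: it depends only on the masks.
#'
#' @param masks a [NeuronMasks-class] object.
#' @return A list of [NeuronRegions-class], one per neuron, in mask order.
#' @export
buildRegions <- function(masks) {
    stopifnot(is(masks, "NeuronMasks"), nMasks(masks) >= 1L)
    lapply(seq_len(nMasks(masks)), function(i) {
        bg <- backgroundMask(masks, i)
        os <- outsideMask(masks, i, bg)
        new("NeuronRegions",
            neuronId = maskIds(masks)[i],
            backgroundMask = bg$mask,
            outsideMask = os$mask,
            neighborIds = neighborIds(masks, i, bg),
            bgRadiusPx = bg$radius,
            outsideRadiusPx = os$radius)
    })
}
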