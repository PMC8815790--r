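#' @rdname VideoStack-class
#' @param object,x a `VideoStack` or `NeuronMasks` object
#' @export
setGeneric("videoData", function(object) standardGeneric("videoData"))

#' @rdname VideoStack-class
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname VideoStack-class
#' @export
setGeneric("videoKind", function(object) standardGeneric("videoKind"))

#' @rdname VideoStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname NeuronMasks-class
#' @param object a `NeuronMasks` object
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname NeuronMasks-class
#' @export
setGeneric("maskIds", function(object) standardGeneric("maskIds"))

#' @rdname NeuronMasks-class
#' @export
setGeneric("nMasks", function(object) standardGeneric("nMasks"))

#' @rdname NeuronMasks-class
#' @param i mask index (1-based position, not id)
#' @export
setGeneric("getMask", function(object, i) standardGeneric("getMask"))

#' @rdname UnmixResult-class
#' @param object an `UnmixResult`
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))

#' @rdname UnmixResult-class
#' @export
setGeneric("separatedTraces", function(object) standardGeneric("separatedTraces"))

#' @rdname UnmixResult-class
#' @export
setGeneric("finalTraces", function(object) standardGeneric("finalTraces"))

#' @rdname UnmixResult-class
#' @export
setGeneric("alphaFinal", function(object) standardGeneric("alphaFinal"))

setMethod("videoData", "VideoStack", function(object) object@data)
setMethod("frameRate", "VideoStack", function(object) object@frameRate)
setMethod("videoKind", "VideoStack", function(object) object@kind)
setMethod("nFrames", "VideoStack", function(object) dim(object@data)[1L])

#' @rdname VideoStack-class
#' @export
setMethod("dim", "VideoStack", function(x) dim(x@data))

setMethod("maskArray", "NeuronMasks", function(object) object@masks)
setMethod("maskIds", "NeuronMasks", function(object) object@ids)
setMethod("nMasks", "NeuronMasks", function(object) dim(object@masks)[1L])
setMethod("getMask", "NeuronMasks", function(object, i) {
    m <- object@masks[i, , , drop = TRUE]
    dim(m) <- dim(object@masks)[2:3]
    m
})

setMethod("mixingMatrix", "UnmixResult", function(object) object@M)
setMethod("separatedTraces", "UnmixResult", function(object) object@Fsep)
setMethod("finalTraces", "UnmixResult", function(object) object@finalTraces)
setMethod("alphaFinal", "UnmixResult", function(object) object@alphaFinal)

setMethod("show", "VideoStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("VideoStack: %d frames of %d x %d (%s kind, %.4g fps)\n",
                d[1L], d[2L], d[3L], object@kind, object@frameRate))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@data), max(object@data)))
})

setMethod("show", "NeuronMasks", function(object) {
    d <- dim(object@masks)
    cat(sprintf("NeuronMasks: %d masks on a %d x %d grid\n", d[1L], d[2L], d[3L]))
    areas <- apply(object@masks, 1L, sum)
    cat(sprintf("  areas %d-%d px (mean %.1f)\n",
                min(areas), max(areas), mean(areas)))
})

setMethod("show", "NeuronRegions", function(object) {
    cat(sprintf(
        "NeuronRegions for neuron %d: bg disk r=%.2f px (%d px), outside %d px (r=%.2f), %d neighbor(s)\n",
        object@neuronId, object@bgRadiusPx, sum(object@backgroundMask),
        sum(object@outsideMask), object@outsideRadiusPx,
        length(object@neighborIds)))
})

setMethod("show", "TraceMatrix", function(object) {
    cat(sprintf("TraceMatrix for neuron %d: %d x %d (%s)\n",
                object@neuronId, nrow(object@values), ncol(object@values),
                paste(object@rowLabels, collapse = ", ")))
})

setMethod("show", "UnmixResult", function(object) {
    cat(sprintf(
        "UnmixResult: %d components x %d frames; alpha %.4g -> %.4g; %d iterations (%s)\n",
        nrow(object@Fsep), ncol(object@Fsep), object@alphaInitial,
        object@alphaFinal, object@nIterations,
        if (object@converged) "converged" else "iteration cap"))
})

#' @rdname TraceMatrix-class
#' @param object a `TraceMatrix`
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
setMethod("traceValues", "TraceMatrix", function(object) object@values)

#' @rdname TraceMatrix-class
#' @export
setGeneric("rowLabels", function(object) standardGeneric("rowLabels"))
setMethod("rowLabels", "TraceMatrix", function(object) object@rowLabels)
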