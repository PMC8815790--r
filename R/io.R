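#' Read a fluorescence video from TIFF or HDF5
#'
#' Multipage TIFF files are stacked in page order; HDF5 files must
#' contain a 3-D dataset (named via `dataset`, otherwise the single 3-D
#' dataset in the file) stored with the frame axis first. Values are
#' widened to double.
#'
#' @param path path to a `.tif`/`.tiff` or `.h5`/`.hdf5` file.
#' @param frameRate frames per second to attach (metadata).
#' @param kind `"raw"` or `"snr"`; raw videos must be non-negative.
#' @param dataset HDF5 dataset name; if `NULL`, the single 3-D dataset
#'   is used (with a warning if it is not named "video").
#' @return A [VideoStack-class].
#' @export
readVideo <- function(path, frameRate = 30, kind = c("raw", "snr"),
                      dataset = NULL) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("missing file: ", path)
    if (isTiff(path)) {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        arr <- stackPages(pages)
    } else {
        arr <- readH5Array(path, dataset, expectDims = 3L,
                           preferred = "video")
    }
    VideoStack(arr, frameRate = frameRate, kind = kind)
}

isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

stackPages <- function(pages) {
    if (length(pages) == 1L && length(dim(pages[[1L]])) == 3L)
        return(pages[[1L]] * 1)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L))))
        stop("only grayscale pages are supported")
    h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
    arr <- array(0, c(length(pages), h, w))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
}

readH5Array <- function(path, dataset, expectDims, preferred) {
    ls <- rhdf5::h5ls(path)
    ds <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
    if (!is.null(dataset)) {
        if (!dataset %in% ds$name)
            stop("dataset '", dataset, "' not found in ", path)
        pick <- dataset
        pickPath <- file.path(ds$group[match(dataset, ds$name)], dataset)
    } else {
        ndims <- vapply(strsplit(ds$dim, " x "), length, integer(1L))
        cand <- which(ndims == expectDims)
        if (length(cand) == 0L) {
            if (nrow(ds) > 0L)
                stop("dataset not ", expectDims, "-D in ", path)
            stop("no dataset found in ", path)
        }
        if (length(cand) > 1L) {
            hit <- cand[ds$name[cand] == preferred]
            if (length(hit) == 1L) cand <- hit
            else {
                cand <- cand[1L]
                warning("multiple ", expectDims, "-D datasets; using '",
                        ds$name[cand], "'")
            }
        }
        pick <- ds$name[cand]
        pickPath <- file.path(ds$group[cand], pick)
        if (!pick %in% preferred)
            warning("using dataset '", pick, "'")
    }
    arr <- rhdf5::h5read(path, pickPath)
    if (length(dim(arr)) != expectDims)
        stop("dataset not ", expectDims, "-D in ", path)
    storage.mode(arr) <- "double"
    arr
}

#' Write a video to TIFF or HDF5
#'
#' HDF5 output (`.h5`/`.hdf5`) stores the `(T, H, W)` array as dataset
#' "video" in double precision (lossless round trip). TIFF output writes
#' 16-bit grayscale pages and therefore requires integer values in
#' `[0, 65535]`.
#'
#' @param video a [VideoStack-class].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writeVideo <- function(video, path) {
    stopifnot(is(video, "VideoStack"))
    d <- videoData(video)
    if (isTiff(path)) {
        if (any(d != round(d)) || min(d) < 0 || max(d) > 65535)
            stop("TIFF output needs integer values in [0, 65535]; ",
                 "use an .h5 path for float videos")
        pages <- lapply(seq_len(dim(d)[1L]), function(t)
            matrix(d[t, , ], dim(d)[2L], dim(d)[3L]) / 65535)
        tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    } else {
        if (file.exists(path)) file.remove(path)
        rhdf5::h5createFile(path)
        rhdf5::h5write(d, path, "video")
        rhdf5::h5write(frameRate(video), path, "frame_rate")
        rhdf5::h5write(videoKind(video), path, "kind")
        rhdf5::h5closeAll()
    }
    invisible(path)
}

#' Read neuron masks from HDF5 or TIFF
#'
#' Accepts either a 3-D boolean/0-1 array `(N, H, W)` (HDF5 dataset
#' "FinalMasks" by default; any single 3-D dataset is accepted with a
#' warning) or a 2-D integer label image (0 = background), as a 2-D HDF5
#' dataset or a single-page TIFF. Mask ids are `0..N-1` in storage order
#' for stacks and the label values for label images. Empty masks are
#' rejected.
#'
#' @param path path to the mask file.
#' @param dataset HDF5 dataset name (default tries "FinalMasks").
#' @return A [NeuronMasks-class].
#' @export
readMasks <- function(path, dataset = NULL) {
    if (!file.exists(path)) stop("missing file: ", path)
    if (isTiff(path)) {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (length(pages) == 1L && length(dim(pages[[1L]])) == 2L)
            return(masksFromLabels(pages[[1L]]))
        arr <- stackPages(pages)
        return(masksFromStack(arr))
    }
    ls <- rhdf5::h5ls(path)
    ds <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
    name <- dataset
    if (is.null(name) && "FinalMasks" %in% ds$name) name <- "FinalMasks"
    if (!is.null(name)) {
        arr <- rhdf5::h5read(path, file.path(
            ds$group[match(name, ds$name)], name))
    } else {
        ndims <- vapply(strsplit(ds$dim, " x "), length, integer(1L))
        cand <- which(ndims %in% c(2L, 3L))
        if (length(cand) == 0L) stop("no 2-D or 3-D mask dataset in ", path)
        if (length(cand) > 1L) cand <- cand[1L]
        warning("mask dataset 'FinalMasks' not found; using '",
                ds$name[cand], "'")
        arr <- rhdf5::h5read(path, file.path(ds$group[cand], ds$name[cand]))
    }
    if (length(dim(arr)) == 2L) {
        storage.mode(arr) <- "integer"
        masksFromLabels(arr)
    } else if (length(dim(arr)) == 3L) {
        masksFromStack(arr)
    } else {
        stop("mask dataset must be 2-D (labels) or 3-D (stack)")
    }
}

masksFromLabels <- function(lab) {
    labels <- sort(setdiff(unique(as.vector(lab)), 0))
    if (length(labels) == 0L) stop("label image contains no masks")
    arr <- array(FALSE, c(length(labels), nrow(lab), ncol(lab)))
    for (i in seq_along(labels)) arr[i, , ] <- lab == labels[i]
    NeuronMasks(arr, ids = as.integer(labels))
}

masksFromStack <- function(arr) {
    mode(arr) <- "logical"
    NeuronMasks(arr)
}

#' Write neuron masks to HDF5
#'
#' Stores the `(N, H, W)` binary stack as 8-bit integers under
#' "FinalMasks" together with the ids.
#'
#' @param masks a [NeuronMasks-class].
#' @param path output `.h5` path.
#' @return `path`, invisibly.
#' @export
writeMasks <- function(masks, path) {
    stopifnot(is(masks, "NeuronMasks"))
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    arr <- maskArray(masks)
    mode(arr) <- "integer"
    rhdf5::h5write(arr, path, "FinalMasks")
    rhdf5::h5write(maskIds(masks), path, "ids")
    rhdf5::h5closeAll()
    invisible(path)
}

#' Write unmixing results to HDF5 (and optionally CSV)
#'
#' One HDF5 group per neuron holding the raw, background-subtracted and
#' unmixed traces, the matched mixing matrix, the initial and final
#' regularization weights and the row labels; double-precision storage
#' makes [readTraces()] an exact inverse. The optional CSV export is a
#' long table with one row per (neuron, trace kind, frame).
#'
#' @param run an `"UnmixRun"` from [unmixVideo()].
#' @param path output `.h5` path.
#' @param csv optional path for a CSV export of the traces.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(run, path, csv = NULL) {
    stopifnot(inherits(run, "UnmixRun"))
    if (file.exists(path)) file.remove(path)
    ok <- rhdf5::h5createFile(path)
    if (!isTRUE(ok)) stop("cannot write to ", path)
    rhdf5::h5write(run$neuronIds, path, "neuron_ids")
    for (i in seq_along(run$neuronIds)) {
        g <- sprintf("/neuron_%d", run$neuronIds[i])
        rhdf5::h5createGroup(path, g)
        b <- run$bundles[[i]]
        rhdf5::h5write(b$rawNeuron, path, file.path(g, "raw"))
        rhdf5::h5write(b$bgSubNeuron, path, file.path(g, "bg_sub"))
        res <- run$results[[i]]
        if (!is.null(res)) {
            rhdf5::h5write(finalTraces(res)[1L, ], path,
                           file.path(g, "unmixed"))
            rhdf5::h5write(mixingMatrix(res), path, file.path(g, "M"))
            rhdf5::h5write(alphaFinal(res), path,
                           file.path(g, "alpha_final"))
            rhdf5::h5write(res@alphaInitial, path,
                           file.path(g, "alpha_initial"))
            rhdf5::h5write(res@rowLabels, path,
                           file.path(g, "row_labels"))
        } else {
            rhdf5::h5write(run$errors[i], path, file.path(g, "error"))
        }
    }
    rhdf5::h5closeAll()
    if (!is.null(csv)) {
        long <- do.call(rbind, lapply(seq_along(run$neuronIds), function(i) {
            b <- run$bundles[[i]]
            res <- run$results[[i]]
            kinds <- list(raw = b$rawNeuron, bg_sub = b$bgSubNeuron)
            if (!is.null(res)) kinds$unmixed <- finalTraces(res)[1L, ]
            do.call(rbind, lapply(names(kinds), function(k)
                data.frame(neuron = run$neuronIds[i], kind = k,
                           frame = seq_along(kinds[[k]]) - 1L,
                           value = kinds[[k]])))
        }))
        write.csv(long, csv, row.names = FALSE)
    }
    invisible(path)
}

#' Read unmixing results written by [writeTraces()]
#'
#' @param path an `.h5` file produced by [writeTraces()].
#' @return List with `neuronIds` and per-neuron lists of `raw`,
#'   `bgSub`, `unmixed`, `M`, `alphaFinal`, `alphaInitial`, `rowLabels`
#'   (or `error`).
#' @export
readTraces <- function(path) {
    if (!file.exists(path)) stop("missing file: ", path)
    ids <- as.integer(rhdf5::h5read(path, "neuron_ids"))
    per <- lapply(ids, function(id) {
        g <- sprintf("/neuron_%d", id)
        obj <- rhdf5::h5read(path, g)
        out <- list(raw = as.numeric(obj$raw),
                    bgSub = as.numeric(obj$bg_sub))
        if (!is.null(obj$unmixed)) {
            out$unmixed <- as.numeric(obj$unmixed)
            out$M <- obj$M
            out$alphaFinal <- as.numeric(obj$alpha_final)
            out$alphaInitial <- as.numeric(obj$alpha_initial)
            out$rowLabels <- as.character(obj$row_labels)
        } else {
            out$error <- as.character(obj$error)
        }
        out
    })
    names(per) <- sprintf("neuron_%d", ids)
    rhdf5::h5closeAll()
    list(neuronIds = ids, neurons = per)
}

#' Write a transient table to CSV
#'
#' @param transients data.frame with `start`, `end`, `peak` (0-based), or
#'   a list of such data.frames (one per neuron; a `neuron` column is
#'   added).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTransients <- function(transients, path) {
    if (is.data.frame(transients)) {
        write.csv(transients, path, row.names = FALSE)
    } else {
        long <- do.call(rbind, lapply(seq_along(transients), function(i)
            if (nrow(transients[[i]]))
                cbind(neuron = i - 1L, transients[[i]])
            else NULL))
        if (is.null(long))
            long <- data.frame(neuron = integer(0L), start = integer(0L),
                               end = integer(0L), peak = integer(0L))
        write.csv(long, path, row.names = FALSE)
    }
    invisible(path)
}

#' Read a transient table written by [writeTransients()]
#'
#' @param path CSV path.
#' @return A data.frame; when a `neuron` column is present, a list of
#'   per-neuron data.frames keyed by the 0-based neuron index.
#' @export
readTransients <- function(path) {
    df <- read.csv(path)
    if (!"neuron" %in% names(df)) return(df)
    ids <- sort(unique(df$neuron))
    out <- lapply(ids, function(i)
        df[df$neuron == i, c("start", "end", "peak"), drop = FALSE])
    names(out) <- ids
    out
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [runConfig()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @return A `"RunConfig"` list.
#' @export
readRunConfig <- function(path) {
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    known <- names(formals(runConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(runConfig, vals)
}
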