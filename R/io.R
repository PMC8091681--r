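# File I/O: CSV/TSV and Matrix Market readers/writers for count matrices,
# embedding and label files, and the run manifest that makes a run
# reproducible bit for bit.

# Format-level reader shared by readModality (counts) and embedFiles
# (counts or already-processed views); no type enforcement here.
#' @importFrom data.table fread
#' @importFrom Matrix readMM
#' @noRd
.readMatrixFile <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format %in% c("csv", "tsv")) {
    dt <- data.table::fread(path, sep = if (format == "csv") "," else "\t",
                            header = TRUE, data.table = FALSE)
    cells <- as.character(dt[[1]])
    if (anyDuplicated(cells))
      stop("duplicate cell ids in ", path, ": ",
           paste(utils::head(unique(cells[duplicated(cells)]), 3),
                 collapse = ", "))
    m <- as.matrix(dt[, -1, drop = FALSE])
    list(values = m, cellIds = cells, featureIds = colnames(m))
  } else if (format == "mtx") {
    dir <- dirname(path)
    m <- as.matrix(Matrix::readMM(path))
    bcPath <- file.path(dir, "barcodes.tsv")
    ftPath <- file.path(dir, "features.tsv")
    if (!file.exists(bcPath) || !file.exists(ftPath))
      stop("MTX sidecars barcodes.tsv / features.tsv not found next to ",
           path)
    barcodes <- readLines(bcPath)
    features <- readLines(ftPath)
    if (length(barcodes) != ncol(m))
      stop(sprintf("barcode count (%d) does not match MTX columns (%d)",
                   length(barcodes), ncol(m)))
    if (length(features) != nrow(m))
      stop(sprintf("feature count (%d) does not match MTX rows (%d)",
                   length(features), nrow(m)))
    list(values = t(m), cellIds = barcodes, featureIds = features)
  } else {
    stop("unsupported format: ", format)
  }
}

#' Read a count matrix from CSV/TSV or Matrix Market
#'
#' CSV/TSV: cells as rows, header row of feature ids, first column cell
#' ids. MTX: 10x convention — features as rows, cells as columns
#' (transposed on load) with `barcodes.tsv` and `features.tsv` sidecars in
#' the same directory.
#'
#' @param path file path; `.mtx`, `.csv` or `.tsv`.
#' @param format override the extension-based format guess
#'   (`"csv"`, `"tsv"`, `"mtx"`).
#' @param modalityName label; defaults to the file name stem.
#' @return A [CountMatrix-class].
#' @export
readModality <- function(path, format = NULL, modalityName = NULL) {
  if (is.null(modalityName))
    modalityName <- tools::file_path_sans_ext(basename(path))
  raw <- .readMatrixFile(path, format)
  if (any(raw$values < 0)) {
    idx <- which(raw$values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row %d (cell %s), column %d (%s) of %s",
                 idx[1], raw$cellIds[idx[1]], idx[2],
                 raw$featureIds[idx[2]], path))
  }
  countMatrix(raw$values, cellIds = raw$cellIds,
              featureIds = raw$featureIds, modalityName = modalityName)
}

#' Write a count matrix to CSV/TSV or Matrix Market
#'
#' Inverse of [readModality()]; the CSV/TSV layout is cells x features with
#' a `cell_id` first column, the MTX layout is features x cells with
#' sidecar files.
#'
#' @param x a [CountMatrix-class].
#' @param path output path (`.csv`, `.tsv` or `.mtx`).
#' @param format override the extension-based guess.
#' @return `path`, invisibly.
#' @importFrom data.table fwrite
#' @importFrom Matrix writeMM Matrix
#' @export
writeModality <- function(x, path, format = NULL) {
  stopifnot(is(x, "CountMatrix"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format %in% c("csv", "tsv")) {
    df <- data.frame(cell_id = x@cellIds, x@values, check.names = FALSE)
    colnames(df) <- c("cell_id", x@featureIds)
    data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  } else if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(x@values), sparse = TRUE), path)
    writeLines(x@cellIds, file.path(dirname(path), "barcodes.tsv"))
    writeLines(x@featureIds, file.path(dirname(path), "features.tsv"))
  } else {
    stop("unsupported format: ", format)
  }
  invisible(path)
}

#' Read a label vector
#'
#' One- or two-column CSV; with two columns the first is the cell id, the
#' second the label.
#'
#' @param path CSV path.
#' @return Character label vector (named by cell id when present).
#' @export
readLabels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) >= 2L) stats::setNames(as.character(dt[[2]]),
                                      as.character(dt[[1]]))
  else as.character(dt[[1]])
}

#' Write a label vector
#' @param labels character vector (names used as cell ids when present).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  ids <- if (is.null(names(labels))) paste0("cell", seq_along(labels))
         else names(labels)
  data.table::fwrite(data.frame(cell_id = ids, label = as.character(labels)),
                     path)
  invisible(path)
}

#' Write an embedding as CSV (cell_id, dim1, dim2, ...)
#' @param x a [JointResult-class] or coordinate matrix with rownames.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(x, path) {
  Y <- if (is(x, "JointResult")) embedding(x) else as.matrix(x)
  ids <- if (!is.null(rownames(Y))) rownames(Y) else
    paste0("cell", seq_len(nrow(Y)))
  df <- data.frame(cell_id = ids, Y)
  colnames(df) <- c("cell_id", paste0("dim", seq_len(ncol(Y))))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an embedding CSV written by [writeEmbedding()]
#' @param path CSV path.
#' @return Coordinate matrix with cell ids as rownames.
#' @export
readEmbedding <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

# Align raw modality records to the cell order of the first one: reorder
# by id when the id sets coincide, error otherwise.
.alignModalities <- function(mods, names) {
  ref <- mods[[1]]$cellIds
  Map(function(m, nm) {
    if (identical(m$cellIds, ref)) return(m)
    if (!setequal(m$cellIds, ref) || length(m$cellIds) != length(ref))
      stop(sprintf("modality '%s' cells do not match the first modality", nm))
    idx <- match(ref, m$cellIds)
    m$values <- m$values[idx, , drop = FALSE]
    m$cellIds <- ref
    m
  }, mods, names)
}

#' Run a joint embedding from modality files and write all outputs
#'
#' Reads the modalities (cells aligned to the first file's order). Files
#' holding nonnegative integer counts get the standard preprocessing
#' (library-size scaling, log1p, PCA); real-valued files are used directly
#' as views. Runs [runJSNE()] or [runJUMAP()] and writes `embedding.csv`,
#' `weights.json`, `history.csv` and `manifest.json` into `outDir`. The manifest records config, input
#' checksums and the optimization trace, and suffices to reproduce the run
#' bit-identically via [rerunFromManifest()].
#'
#' @param modalityPaths character vector of input files.
#' @param method `"jsne"` or `"jumap"`.
#' @param config a [JointConfig-class].
#' @param kernel an [UmapKernelParams-class] (UMAP branch only).
#' @param nComponents PCs per modality in preprocessing.
#' @param outDir output directory (created if missing).
#' @return The [JointResult-class], invisibly.
#' @importFrom jsonlite write_json
#' @importFrom utils packageVersion
#' @export
embedFiles <- function(modalityPaths, method = c("jsne", "jumap"),
                       config = jointConfig(), kernel = umapKernelParams(),
                       nComponents = 20L, outDir) {
  method <- match.arg(method)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nms <- make.unique(tools::file_path_sans_ext(basename(modalityPaths)))
  mods <- .alignModalities(lapply(modalityPaths, .readMatrixFile), nms)
  # nonnegative integer matrices are counts and get the standard
  # normalization; real-valued inputs are taken as already-processed views
  views <- Map(function(m, nm) {
    isCounts <- all(m$values >= 0) && all(m$values == round(m$values))
    if (isCounts) {
      cm <- countMatrix(m$values, cellIds = m$cellIds,
                        featureIds = m$featureIds, modalityName = nm)
      v <- logNormalize(cm)
      if (ncol(v@values) >= nComponents) pcaProject(v, nComponents) else v
    } else {
      modalityView(m$values, modalityName = nm, cellIds = m$cellIds,
                   transformLog = "loaded-as-view")
    }
  }, mods, nms)
  names(views) <- nms
  res <- if (method == "jsne") runJSNE(views, config)
         else runJUMAP(views, config, kernel)
  writeEmbedding(res, file.path(outDir, "embedding.csv"))
  jsonlite::write_json(as.list(modalityWeightsOf(res)),
                       file.path(outDir, "weights.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(lossHistory(res), file.path(outDir, "history.csv"))
  manifest <- list(
    package = "jembed",
    version = as.character(utils::packageVersion("jembed")),
    method = method,
    lambdaReg = res@lambdaReg,
    nComponents = as.integer(nComponents),
    config = .configAsList(config),
    kernel = .kernelAsList(kernel),
    inputs = data.frame(path = modalityPaths,
                        md5 = unname(tools::md5sum(modalityPaths)),
                        stringsAsFactors = FALSE),
    seed = config@seed,
    trace = lossHistory(res))
  # digits = I(17): doubles (e.g. the fitted kernel shape) must survive
  # the JSON round trip bit-exactly for reruns to be byte-identical
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       na = "null")
  invisible(res)
}

.configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

.kernelAsList <- .configAsList

.configFromList <- function(lst) {
  # jsonlite serializes NA as null, which reads back as NULL
  if (is.null(lst$lambdaReg)) lst$lambdaReg <- NA_real_
  jointConfig(lambdaReg = lst$lambdaReg, maxOuterIter = lst$maxOuterIter,
              perplexity = lst$perplexity, nNeighbors = lst$nNeighbors,
              nComponentsEmbed = lst$nComponentsEmbed,
              innerItersFirst = lst$innerItersFirst,
              innerItersLater = lst$innerItersLater,
              earlyExaggeration = lst$earlyExaggeration,
              learningRate = lst$learningRate, seed = lst$seed,
              alphaTol = lst$alphaTol, fixedWeights = lst$fixedWeights,
              init = lst$init)
}

.kernelFromList <- function(lst) {
  umapKernelParams(minDist = lst$minDist, spread = lst$spread, a = lst$a,
                   b = lst$b, nEpochs = lst$nEpochs,
                   nEpochsLater = lst$nEpochsLater,
                   negSampleRate = lst$negSampleRate,
                   ceNegSampleRate = lst$ceNegSampleRate)
}

#' Reproduce a run from its manifest
#'
#' Reads `manifest.json`, verifies input checksums, and reruns the embedding
#' with the recorded configuration; outputs are byte-identical to the
#' original run.
#'
#' @param manifestPath path to a `manifest.json` written by [embedFiles()].
#' @param outDir output directory for the reproduced run.
#' @return The [JointResult-class], invisibly.
#' @importFrom jsonlite read_json
#' @export
rerunFromManifest <- function(manifestPath, outDir) {
  mf <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  paths <- mf$inputs$path
  md5 <- unname(tools::md5sum(paths))
  if (!identical(md5, mf$inputs$md5))
    stop("input files changed since the manifest was written")
  embedFiles(paths, method = mf$method,
             config = .configFromList(mf$config),
             kernel = .kernelFromList(mf$kernel),
             nComponents = mf$nComponents, outDir = outDir)
}
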