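#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix dgCMatrix
#' @useDynLib jembed, .registration = TRUE
NULL

#' CountMatrix: raw counts for one modality
#'
#' Cells are rows, features are columns. All modalities of one dataset must
#' share an identical ordered set of cell identifiers.
#'
#' @slot values cells x features matrix of nonnegative integer counts.
#' @slot cellIds character vector of unique cell identifiers (row order).
#' @slot featureIds character vector of feature identifiers (column order).
#' @slot modalityName single label, e.g. "rna" or "adt".
#' @exportClass CountMatrix
setClass("CountMatrix",
  representation(values = "matrix", cellIds = "character",
                 featureIds = "character", modalityName = "character"))

setValidity("CountMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@modalityName) != 1L)
    msg <- c(msg, "modalityName must be a single string")
  if (nrow(v) != length(object@cellIds))
    msg <- c(msg, "cellIds length must equal number of rows")
  if (ncol(v) != length(object@featureIds))
    msg <- c(msg, "featureIds length must equal number of columns")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "cellIds must be unique")
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    msg <- c(msg, "counts must be finite and nonnegative")
  if (length(v) && any(v != round(v)))
    msg <- c(msg, "counts must be integers")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param values cells x features nonnegative integer matrix.
#' @param cellIds,featureIds identifiers; taken from dimnames when `NULL`.
#' @param modalityName modality label.
#' @return A [CountMatrix-class] object.
#' @export
countMatrix <- function(values, cellIds = NULL, featureIds = NULL,
                        modalityName = "modality") {
  values <- as.matrix(values)
  if (is.null(cellIds)) {
    cellIds <- if (!is.null(rownames(values))) rownames(values) else
      paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(featureIds)) {
    featureIds <- if (!is.null(colnames(values))) colnames(values) else
      paste0("feat", seq_len(ncol(values)))
  }
  dimnames(values) <- NULL
  storage.mode(values) <- "double"
  new("CountMatrix", values = values, cellIds = as.character(cellIds),
      featureIds = as.character(featureIds),
      modalityName = as.character(modalityName))
}

#' ModalityView: one modality's processed real-valued matrix
#'
#' The per-modality space (after e.g. library-size scaling, log1p, PCA) on
#' which high-dimensional similarities are computed.
#'
#' @slot values cells x components real matrix with finite entries.
#' @slot modalityName modality label.
#' @slot cellIds ordered cell identifiers.
#' @slot transformLog character vector recording the processing steps applied.
#' @exportClass ModalityView
setClass("ModalityView",
  representation(values = "matrix", modalityName = "character",
                 cellIds = "character", transformLog = "character"))

setValidity("ModalityView", function(object) {
  msg <- character()
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@cellIds) &&
      nrow(object@values) != length(object@cellIds))
    msg <- c(msg, "cellIds length must equal number of rows")
  if (length(msg)) msg else TRUE
})

#' Construct a ModalityView
#'
#' @param values cells x components real matrix.
#' @param modalityName modality label.
#' @param cellIds cell identifiers (rownames used when `NULL`).
#' @param transformLog provenance notes, one entry per processing step.
#' @return A [ModalityView-class] object.
#' @export
modalityView <- function(values, modalityName = "modality", cellIds = NULL,
                         transformLog = character()) {
  values <- as.matrix(values)
  if (is.null(cellIds)) {
    cellIds <- if (!is.null(rownames(values))) rownames(values) else
      paste0("cell", seq_len(nrow(values)))
  }
  dimnames(values) <- NULL
  storage.mode(values) <- "double"
  new("ModalityView", values = values, modalityName = as.character(modalityName),
      cellIds = as.character(cellIds), transformLog = as.character(transformLog))
}

#' AffinityMatrix: symmetric pairwise probability matrix
#'
#' Either a high-dimensional joint distribution P (perplexity-calibrated,
#' symmetrized Gaussian conditionals) or the low-dimensional Student-t
#' distribution Q. Off-diagonal entries sum to one.
#'
#' @slot values n x n symmetric nonnegative matrix with zero diagonal.
#' @slot role one of `"high_dim_P"`, `"low_dim_Q"`.
#' @exportClass AffinityMatrix
setClass("AffinityMatrix",
  representation(values = "matrix", role = "character"))

setValidity("AffinityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "must be square")
  if (!(object@role %in% c("high_dim_P", "low_dim_Q")))
    msg <- c(msg, "role must be high_dim_P or low_dim_Q")
  if (any(v < 0)) msg <- c(msg, "entries must be nonnegative")
  if (any(abs(diag(v)) > 0)) msg <- c(msg, "diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "must be symmetric")
  if (abs(sum(v) - 1) > 1e-8)
    msg <- c(msg, "off-diagonal entries must sum to 1")
  if (length(msg)) msg else TRUE
})

affinityMatrix <- function(values, role) {
  dimnames(values) <- NULL
  new("AffinityMatrix", values = values, role = role)
}

#' FuzzyGraph: sparse symmetric fuzzy k-NN membership graph
#'
#' UMAP-style fuzzy simplicial set over cells: membership strengths in (0, 1],
#' symmetrized with the probabilistic t-conorm a + b - ab.
#'
#' @slot edges sparse symmetric `dgCMatrix` of membership strengths.
#' @slot nNeighbors integer, the k used to build the graph.
#' @exportClass FuzzyGraph
setClass("FuzzyGraph",
  representation(edges = "dgCMatrix", nNeighbors = "integer"))

setValidity("FuzzyGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (nrow(e) != ncol(e)) msg <- c(msg, "edges must be square")
  x <- e@x
  if (length(x) && (any(x <= 0) || any(x > 1 + 1e-12)))
    msg <- c(msg, "membership strengths must lie in (0,1]")
  if (any(Matrix::diag(e) != 0)) msg <- c(msg, "diagonal must be empty")
  if (max(abs(e - Matrix::t(e))) > 1e-12) msg <- c(msg, "must be symmetric")
  if (length(msg)) msg else TRUE
})

#' ModalityWeights: a point on the K-simplex
#'
#' Importance coefficients alpha of the convex combination of per-modality
#' divergences; nonnegative, summing to one.
#'
#' @slot alpha named numeric vector on the simplex.
#' @exportClass ModalityWeights
setClass("ModalityWeights", representation(alpha = "numeric"))

setValidity("ModalityWeights", function(object) {
  a <- object@alpha
  msg <- character()
  if (!length(a)) msg <- c(msg, "alpha must be non-empty")
  if (any(a < 0)) msg <- c(msg, "alpha entries must be nonnegative")
  if (abs(sum(a) - 1) > 1e-10) msg <- c(msg, "alpha must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct ModalityWeights
#' @param alpha nonnegative numeric vector summing to one.
#' @return A [ModalityWeights-class] object.
#' @export
modalityWeights <- function(alpha) new("ModalityWeights", alpha = alpha)

#' JointConfig: settings of the alternating joint-embedding scheme
#'
#' @slot lambdaReg entropy-regularization strength lambda (>= 0). `NA` means
#'   use the method default: 3 for j-SNE, 1 for j-UMAP.
#' @slot maxOuterIter maximum alternating (outer) iterations, default 10.
#' @slot perplexity t-SNE branch perplexity, default 30.
#' @slot nNeighbors UMAP branch neighborhood size, default 15.
#' @slot nComponentsEmbed embedding dimension, default 2.
#' @slot innerItersFirst gradient-descent iterations in the first outer
#'   iteration (t-SNE branch), default 500.
#' @slot innerItersLater continuation iterations per later outer iteration,
#'   default 100.
#' @slot earlyExaggeration multiplier on P during the early phase, default 12.
#' @slot learningRate t-SNE learning rate, default 200.
#' @slot seed integer seed controlling every source of randomness.
#' @slot alphaTol stop when max |delta alpha| falls below this, default 1e-3.
#' @slot fixedWeights freeze alpha at uniform 1/K (the fixed-uniform baseline).
#' @slot init embedding initialization: "gaussian" (sigma = 1e-4) or "pca".
#' @exportClass JointConfig
setClass("JointConfig",
  representation(lambdaReg = "numeric", maxOuterIter = "integer",
                 perplexity = "numeric", nNeighbors = "integer",
                 nComponentsEmbed = "integer", innerItersFirst = "integer",
                 innerItersLater = "integer", earlyExaggeration = "numeric",
                 learningRate = "numeric", seed = "integer",
                 alphaTol = "numeric", fixedWeights = "logical",
                 init = "character"))

setValidity("JointConfig", function(object) {
  msg <- character()
  if (!is.na(object@lambdaReg) && object@lambdaReg < 0)
    msg <- c(msg, "lambdaReg must be >= 0")
  if (object@maxOuterIter < 1L) msg <- c(msg, "maxOuterIter must be >= 1")
  if (!(object@init %in% c("gaussian", "pca")))
    msg <- c(msg, "init must be 'gaussian' or 'pca'")
  if (length(msg)) msg else TRUE
})

#' Construct a JointConfig
#'
#' @param lambdaReg regularization lambda; `NA` picks the method default
#'   (3 for j-SNE, 1 for j-UMAP).
#' @param maxOuterIter,perplexity,nNeighbors,nComponentsEmbed,innerItersFirst,innerItersLater,earlyExaggeration,learningRate,seed,alphaTol,fixedWeights,init
#'   see slot documentation in [JointConfig-class].
#' @return A [JointConfig-class] object.
#' @export
jointConfig <- function(lambdaReg = NA_real_, maxOuterIter = 10L,
                        perplexity = 30, nNeighbors = 15L,
                        nComponentsEmbed = 2L, innerItersFirst = 500L,
                        innerItersLater = 100L, earlyExaggeration = 12,
                        learningRate = 200, seed = 42L, alphaTol = 1e-3,
                        fixedWeights = FALSE, init = "gaussian") {
  new("JointConfig", lambdaReg = as.numeric(lambdaReg),
      maxOuterIter = as.integer(maxOuterIter),
      perplexity = as.numeric(perplexity),
      nNeighbors = as.integer(nNeighbors),
      nComponentsEmbed = as.integer(nComponentsEmbed),
      innerItersFirst = as.integer(innerItersFirst),
      innerItersLater = as.integer(innerItersLater),
      earlyExaggeration = as.numeric(earlyExaggeration),
      learningRate = as.numeric(learningRate), seed = as.integer(seed),
      alphaTol = as.numeric(alphaTol), fixedWeights = as.logical(fixedWeights),
      init = as.character(init))
}

#' UmapKernelParams: low-dimensional kernel and SGD settings (UMAP branch)
#'
#' The low-dimensional membership kernel is w(d) = (1 + a d^(2b))^-1 with
#' (a, b) fitted from `minDist` and `spread`.
#'
#' @slot a,b positive kernel shape parameters.
#' @slot minDist,spread layout parameters the kernel is fitted to.
#' @slot nEpochs SGD epochs in the first outer iteration.
#' @slot nEpochsLater SGD epochs per later outer iteration.
#' @slot negSampleRate negative samples per positive edge update in SGD.
#' @slot ceNegSampleRate negative samples per edge for the cross-entropy
#'   estimate driving the weight update.
#' @exportClass UmapKernelParams
setClass("UmapKernelParams",
  representation(a = "numeric", b = "numeric", minDist = "numeric",
                 spread = "numeric", nEpochs = "integer",
                 nEpochsLater = "integer", negSampleRate = "integer",
                 ceNegSampleRate = "integer"))

setValidity("UmapKernelParams", function(object) {
  if (object@a <= 0 || object@b <= 0) "a and b must be positive" else TRUE
})

#' Construct UmapKernelParams
#'
#' @param minDist,spread target layout curve parameters (defaults 0.1, 1.0).
#' @param a,b kernel shape; fitted from `minDist`/`spread` when `NULL`.
#' @param nEpochs,nEpochsLater,negSampleRate,ceNegSampleRate see
#'   [UmapKernelParams-class].
#' @return An [UmapKernelParams-class] object.
#' @export
umapKernelParams <- function(minDist = 0.1, spread = 1.0, a = NULL, b = NULL,
                             nEpochs = 500L, nEpochsLater = 100L,
                             negSampleRate = 5L, ceNegSampleRate = 50L) {
  if (is.null(a) || is.null(b)) {
    ab <- fitAB(minDist, spread)
    a <- ab[["a"]]
    b <- ab[["b"]]
  }
  new("UmapKernelParams", a = as.numeric(a), b = as.numeric(b),
      minDist = as.numeric(minDist), spread = as.numeric(spread),
      nEpochs = as.integer(nEpochs), nEpochsLater = as.integer(nEpochsLater),
      negSampleRate = as.integer(negSampleRate),
      ceNegSampleRate = as.integer(ceNegSampleRate))
}

#' JointResult: output of a joint embedding run
#'
#' @slot embedding n x d matrix of cell coordinates (rownames = cell ids).
#' @slot weights final [ModalityWeights-class].
#' @slot history data.frame with one row per outer iteration: per-modality
#'   losses, alpha, the total objective before and after the alpha update,
#'   and the maximal alpha change.
#' @slot method `"jsne"` or `"jumap"`.
#' @slot lambdaReg the lambda actually used.
#' @exportClass JointResult
setClass("JointResult",
  representation(embedding = "matrix", weights = "ModalityWeights",
                 history = "data.frame", method = "character",
                 lambdaReg = "numeric"))

setValidity("JointResult", function(object) {
  msg <- character()
  if (!(object@method %in% c("jsne", "jumap")))
    msg <- c(msg, "method must be jsne or jumap")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the multimodal count simulator
#'
#' Hierarchical gamma-Poisson (negative binomial) model in the style of
#' Splatter: feature means ~ Gamma, expression outliers, per-group
#' multiplicative differential-expression factors ~ log-normal, log-normal
#' cell library sizes, gamma-Poisson counts, and logistic dropout on the
#' log mean. RNA- and ADT-specific values are named entries (rna, adt) of
#' the two-element slots.
#'
#' @slot nCells,nGenes,nAdt,nGroups integers.
#' @slot groupProbs simplex vector of group probabilities.
#' @slot deProb probability a feature is differentially expressed per group
#'   (named rna/adt; antibody panels are curated marker panels, so the ADT
#'   default is much higher).
#' @slot deLogfcScale sd of the log-normal DE factor.
#' @slot meanShape,meanRate gamma hyperparameters of baseline feature means.
#' @slot libsizeMu,libsizeSigma log-normal library size (named rna/adt).
#' @slot dispersion NB dispersion (named rna/adt).
#' @slot dropoutMid,dropoutShape logistic dropout parameters (named rna/adt).
#' @slot outlierProb,outlierScale expression-outlier parameters.
#' @slot seed integer seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nCells = "integer", nGenes = "integer", nAdt = "integer",
                 nGroups = "integer", groupProbs = "numeric",
                 deProb = "numeric", deLogfcScale = "numeric",
                 meanShape = "numeric", meanRate = "numeric",
                 libsizeMu = "numeric", libsizeSigma = "numeric",
                 dispersion = "numeric", dropoutMid = "numeric",
                 dropoutShape = "numeric", outlierProb = "numeric",
                 outlierScale = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (abs(sum(object@groupProbs) - 1) > 1e-8)
    msg <- c(msg, "groupProbs must sum to 1")
  if (any(object@groupProbs < 0)) msg <- c(msg, "groupProbs must be >= 0")
  if (length(object@groupProbs) != object@nGroups)
    msg <- c(msg, "groupProbs length must equal nGroups")
  if (any(object@deProb < 0) || any(object@deProb > 1))
    msg <- c(msg, "deProb must be in [0,1]")
  for (s in c("deLogfcScale", "meanShape", "meanRate", "dispersion"))
    if (any(slot(object, s) <= 0)) msg <- c(msg, paste(s, "must be positive"))
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults emulate sparse, overdispersed CITE-seq-like counts: a deep RNA
#' modality with strong dropout and a small ADT panel with large library
#' sizes and weak dropout. These are documented stand-ins, not estimates
#' from real data.
#'
#' @param nCells,nGenes,nAdt,nGroups,groupProbs,deProb,deLogfcScale,meanShape,meanRate,libsizeMu,libsizeSigma,dispersion,dropoutMid,dropoutShape,outlierProb,outlierScale,seed
#'   see [SimConfig-class].
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nCells = 1000L, nGenes = 1000L, nAdt = 50L,
                      nGroups = 5L, groupProbs = rep(1 / nGroups, nGroups),
                      deProb = c(rna = 0.1, adt = 0.5), deLogfcScale = 1.0,
                      meanShape = 0.6, meanRate = 0.3,
                      libsizeMu = c(rna = 9.5, adt = 7.0),
                      libsizeSigma = c(rna = 0.35, adt = 0.35),
                      dispersion = c(rna = 0.2, adt = 0.4),
                      dropoutMid = c(rna = 2.0, adt = -2.0),
                      dropoutShape = c(rna = -1.0, adt = -1.0),
                      outlierProb = 0.05, outlierScale = 4.0, seed = 1L) {
  new("SimConfig", nCells = as.integer(nCells), nGenes = as.integer(nGenes),
      nAdt = as.integer(nAdt), nGroups = as.integer(nGroups),
      groupProbs = as.numeric(groupProbs), deProb = deProb,
      deLogfcScale = as.numeric(deLogfcScale),
      meanShape = as.numeric(meanShape), meanRate = as.numeric(meanRate),
      libsizeMu = libsizeMu, libsizeSigma = libsizeSigma,
      dispersion = dispersion, dropoutMid = dropoutMid,
      dropoutShape = dropoutShape, outlierProb = as.numeric(outlierProb),
      outlierScale = as.numeric(outlierScale), seed = as.integer(seed))
}

#' SimResult: a simulated multimodal dataset
#'
#' @slot modalities named list of [CountMatrix-class] (or, for the toy
#'   scenario, [ModalityView-class]) objects sharing cell order.
#' @slot labels character vector of true group labels.
#' @slot paramsUsed echo of the generating configuration (list).
#' @exportClass SimResult
setClass("SimResult",
  representation(modalities = "list", labels = "character",
                 paramsUsed = "list"))

setValidity("SimResult", function(object) {
  msg <- character()
  ns <- vapply(object@modalities, function(m) nrow(m@values), integer(1))
  if (length(unique(ns)) > 1)
    msg <- c(msg, "all modalities must share the cell count")
  if (length(ns) && ns[1] != length(object@labels))
    msg <- c(msg, "labels length must equal cell count")
  if (length(msg)) msg else TRUE
})
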