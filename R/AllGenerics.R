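#' Extract the numeric matrix held by a container
#' @param x a CountMatrix, ModalityView or AffinityMatrix.
#' @return The underlying numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @describeIn values counts of a CountMatrix.
#' @export
setMethod("values", "CountMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@cellIds, x@featureIds)
  v
})

#' @describeIn values processed matrix of a ModalityView.
#' @export
setMethod("values", "ModalityView", function(x) {
  v <- x@values
  rownames(v) <- x@cellIds
  v
})

#' @describeIn values probability matrix of an AffinityMatrix.
#' @export
setMethod("values", "AffinityMatrix", function(x) x@values)

#' Cell identifiers
#' @param x a CountMatrix, ModalityView or SimResult.
#' @return Character vector of cell ids in order.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @describeIn cellIds cell ids of a CountMatrix.
#' @export
setMethod("cellIds", "CountMatrix", function(x) x@cellIds)

#' @describeIn cellIds cell ids of a ModalityView.
#' @export
setMethod("cellIds", "ModalityView", function(x) x@cellIds)

#' Feature identifiers
#' @param x a CountMatrix.
#' @return Character vector of feature ids.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @describeIn featureIds feature ids of a CountMatrix.
#' @export
setMethod("featureIds", "CountMatrix", function(x) x@featureIds)

#' Modality label
#' @param x a CountMatrix or ModalityView.
#' @return Single character label.
#' @export
setGeneric("modalityName", function(x) standardGeneric("modalityName"))

#' @describeIn modalityName label of a CountMatrix.
#' @export
setMethod("modalityName", "CountMatrix", function(x) x@modalityName)

#' @describeIn modalityName label of a ModalityView.
#' @export
setMethod("modalityName", "ModalityView", function(x) x@modalityName)

#' Embedding coordinates of a joint result
#' @param x a JointResult.
#' @return n x d numeric matrix, rownames are cell ids.
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' @describeIn embedding coordinates of a JointResult.
#' @export
setMethod("embedding", "JointResult", function(x) x@embedding)

#' Learned modality weights
#' @param x a JointResult or ModalityWeights.
#' @return Named numeric vector on the simplex.
#' @export
setGeneric("modalityWeightsOf", function(x) standardGeneric("modalityWeightsOf"))

#' @describeIn modalityWeightsOf final alpha of a JointResult.
#' @export
setMethod("modalityWeightsOf", "JointResult", function(x) x@weights@alpha)

#' @describeIn modalityWeightsOf alpha vector of a ModalityWeights.
#' @export
setMethod("modalityWeightsOf", "ModalityWeights", function(x) x@alpha)

#' Per-outer-iteration optimization trace
#' @param x a JointResult.
#' @return data.frame with losses, alpha, objectives and alpha change per
#'   outer iteration.
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @describeIn lossHistory trace of a JointResult.
#' @export
setMethod("lossHistory", "JointResult", function(x) x@history)

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix '%s': %d cells x %d features, %.1f%% zeros\n",
              object@modalityName, nrow(object@values), ncol(object@values),
              100 * mean(object@values == 0)))
})

setMethod("show", "ModalityView", function(object) {
  cat(sprintf("ModalityView '%s': %d cells x %d components\n",
              object@modalityName, nrow(object@values), ncol(object@values)))
  if (length(object@transformLog))
    cat("  transforms:", paste(object@transformLog, collapse = " -> "), "\n")
})

setMethod("show", "AffinityMatrix", function(object) {
  cat(sprintf("AffinityMatrix (%s): %d x %d\n", object@role,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "FuzzyGraph", function(object) {
  cat(sprintf("FuzzyGraph: %d cells, %d undirected edges (k = %d)\n",
              nrow(object@edges), length(object@edges@x) / 2L,
              object@nNeighbors))
})

setMethod("show", "ModalityWeights", function(object) {
  cat("ModalityWeights:", paste(sprintf("%s=%.4f",
      if (is.null(names(object@alpha))) seq_along(object@alpha)
      else names(object@alpha), object@alpha), collapse = " "), "\n")
})

setMethod("show", "JointResult", function(object) {
  cat(sprintf("JointResult (%s, lambda = %g): %d cells in %d-D, %d outer iterations\n",
              object@method, object@lambdaReg, nrow(object@embedding),
              ncol(object@embedding), nrow(object@history)))
  show(object@weights)
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d cells, %d groups, modalities: %s\n",
              length(object@labels), length(unique(object@labels)),
              paste(names(object@modalities), collapse = ", ")))
})
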