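# Preprocessing: raw counts -> real-valued per-modality views, plus the
# concatenation baselines.

.asCountValues <- function(x) {
  if (is(x, "CountMatrix")) x@values else as.matrix(x)
}

#' Library-size scaling and log transform
#'
#' Scales each cell's counts to the median total count across cells and
#' applies log(1 + x) elementwise — the standard single-cell normalization
#' preceding PCA.
#'
#' @param x a [CountMatrix-class] or nonnegative matrix (cells x features).
#' @return A [ModalityView-class]; the steps applied are recorded in its
#'   `transformLog`.
#' @export
logNormalize <- function(x) {
  cm <- if (is(x, "CountMatrix")) x else countMatrix(x)
  v <- cm@values
  if (nrow(v) < 2L) stop("need at least 2 cells")
  totals <- rowSums(v)
  if (any(totals == 0)) {
    bad <- cm@cellIds[totals == 0]
    stop("cells with all-zero counts (library-size scaling undefined): ",
         paste(bad, collapse = ", "))
  }
  med <- stats::median(totals)
  out <- log1p(v / totals * med)
  modalityView(out, modalityName = cm@modalityName, cellIds = cm@cellIds,
               transformLog = c(sprintf("scale-to-median-total(%g)", med),
                                "log1p"))
}

#' Project a view onto its leading principal components
#'
#' Columns of the result are PC scores of the centered input, ordered by
#' decreasing explained variance. The defaults used throughout are 20 or 50
#' components.
#'
#' @param v a [ModalityView-class] or numeric matrix.
#' @param nComponents number of components; must not exceed
#'   `min(cells - 1, features)`.
#' @return A [ModalityView-class] of PC scores.
#' @importFrom stats prcomp
#' @export
pcaProject <- function(v, nComponents = 20L) {
  mv <- if (is(v, "ModalityView")) v else modalityView(v)
  n <- nrow(mv@values)
  p <- ncol(mv@values)
  bound <- min(n - 1L, p)
  if (nComponents > bound)
    stop(sprintf("nComponents = %d exceeds min(cells - 1, features) = %d",
                 nComponents, bound))
  pc <- stats::prcomp(mv@values, center = TRUE, scale. = FALSE,
                      rank. = as.integer(nComponents))
  modalityView(pc$x[, seq_len(nComponents), drop = FALSE],
               modalityName = mv@modalityName, cellIds = mv@cellIds,
               transformLog = c(mv@transformLog,
                                sprintf("pca(%d)", nComponents)))
}

#' Feature-wise concatenation of modalities (baseline)
#'
#' The concatenation baseline: optionally divides each count matrix by its
#' own Frobenius norm, then stacks the (scaled) columns of all modalities
#' into one wide matrix to be embedded by conventional t-SNE/UMAP.
#'
#' @param xList list of [CountMatrix-class] or matrices over the same cells.
#' @param normalize divide each block by its Frobenius norm (default TRUE);
#'   `FALSE` gives the unnormalized variant.
#' @return A [ModalityView-class] with the concatenated columns.
#' @export
frobeniusConcat <- function(xList, normalize = TRUE) {
  if (!length(xList)) stop("xList must be non-empty")
  mats <- lapply(xList, .asCountValues)
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) > 1)
    stop("modalities disagree in cell count: ", paste(ns, collapse = ", "))
  if (normalize) {
    mats <- lapply(mats, function(m) {
      fn <- sqrt(sum(m^2))
      if (fn == 0) stop("cannot Frobenius-normalize an all-zero matrix")
      m / fn
    })
  }
  ids <- if (is(xList[[1]], "CountMatrix")) xList[[1]]@cellIds else
    paste0("cell", seq_len(ns[1]))
  modalityView(do.call(cbind, mats), modalityName = "concat", cellIds = ids,
               transformLog = if (normalize) "frobenius-normalized-concat"
                              else "raw-concat")
}

#' Standard preprocessing of a multimodal dataset
#'
#' Applies [logNormalize()] then [pcaProject()] to each modality. PCA is
#' skipped for modalities with fewer features than `nComponents` (small
#' antibody panels), where the reduction would be ill-posed.
#'
#' @param modalities named list of [CountMatrix-class] or count matrices.
#' @param nComponents PCs per modality (default 20).
#' @return Named list of [ModalityView-class] objects.
#' @export
prepareViews <- function(modalities, nComponents = 20L) {
  lapply(modalities, function(m) {
    v <- logNormalize(m)
    if (ncol(v@values) >= nComponents) pcaProject(v, nComponents) else v
  })
}
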