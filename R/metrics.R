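# Embedding evaluation: the k-nearest-neighbor index (KNI), mean silhouette
# width and the adjusted Rand index.

.checkLabels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n)
    stop(sprintf("labels length (%d) does not match embedding rows (%d)",
                 length(labels), n))
  labels
}

#' k-nearest-neighbor index (KNI)
#'
#' For each cell, the fraction of its k Euclidean nearest neighbors in the
#' embedding (self excluded) that share its label, averaged across all
#' cells. Distance ties are broken toward the lower cell index. 1 means
#' perfectly homogeneous neighborhoods; random mixing gives the chance
#' level sum_c m_c (m_c - 1) / (n (n - 1)).
#'
#' @param Y n x d embedding matrix.
#' @param labels length-n label vector.
#' @param k neighborhood size, 1 <= k < n (default 10).
#' @return Scalar in \[0, 1\].
#' @export
kni <- function(Y, labels, k = 10L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  labels <- .checkLabels(labels, n)
  if (k >= n) stop(sprintf("k (%d) must be smaller than n (%d)", k, n))
  if (k < 1L) stop("k must be >= 1")
  D <- pairwise_sq_dists_cpp(Y)
  diag(D) <- Inf
  acc <- 0
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[seq_len(k)]  # stable: ties resolve to lower index
    acc <- acc + mean(labels[nn] == labels[i])
  }
  acc / n
}

#' Mean silhouette width of an embedding
#'
#' Per-cell (b - a) / max(a, b) with a the mean intra-cluster distance and
#' b the smallest mean distance to another cluster (Euclidean, in the
#' embedding); singleton clusters score 0. Averaged over cells; range
#' \[-1, 1\].
#'
#' @param Y n x d embedding matrix.
#' @param labels length-n label vector with >= 2 distinct values.
#' @return Scalar mean silhouette width.
#' @importFrom cluster silhouette
#' @importFrom stats dist
#' @export
silhouetteMean <- function(Y, labels) {
  Y <- as.matrix(Y)
  labels <- .checkLabels(labels, nrow(Y))
  if (length(unique(labels)) < 2L)
    stop("silhouette undefined for a single label")
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(Y))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between two labelings
#'
#' Chance-adjusted agreement computed from the contingency table; 1 for
#' identical partitions (up to renaming), ~0 for independent ones.
#'
#' @param labels1,labels2 equal-length label vectors.
#' @return Scalar ARI.
#' @export
ari <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(labels1), length(labels2)))
  mclust::adjustedRandIndex(as.character(labels1), as.character(labels2))
}

#' Per-class silhouette breakdown
#'
#' Mean silhouette width within each class, alongside the overall mean.
#'
#' @param Y n x d embedding matrix.
#' @param labels length-n label vector.
#' @return Named list: `mean` and per-class means.
#' @export
silhouettePerClass <- function(Y, labels) {
  Y <- as.matrix(Y)
  labels <- .checkLabels(labels, nrow(Y))
  f <- factor(labels)
  sil <- cluster::silhouette(as.integer(f), stats::dist(Y))
  widths <- sil[, "sil_width"]
  perClass <- tapply(widths, f, mean)
  list(mean = mean(widths), perClass = as.list(perClass))
}
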