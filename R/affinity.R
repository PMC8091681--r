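# Per-modality high-dimensional similarity structures: perplexity-calibrated
# symmetric probabilities P (t-SNE branch) and fuzzy k-NN membership graphs V
# (UMAP branch).

.viewValues <- function(v) {
  if (is(v, "ModalityView")) v@values else as.matrix(v)
}

#' Pairwise squared Euclidean distances
#'
#' @param v a [ModalityView-class] or numeric matrix (>= 2 rows).
#' @return n x n symmetric matrix of squared distances, zero diagonal.
#' @export
pairwiseSqDists <- function(v) {
  x <- .viewValues(v)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (any(!is.finite(x))) stop("input contains non-finite values")
  pairwise_sq_dists_cpp(x)
}

#' Perplexity-calibrated Gaussian conditionals
#'
#' For each point i finds the Gaussian bandwidth sigma_i by bisection such
#' that the conditional distribution p_{j|i} over its neighbors has the
#' requested perplexity 2^H, and returns the row-stochastic matrix of
#' conditionals (p_{i|i} = 0).
#'
#' @param D squared-distance matrix (as from [pairwiseSqDists()]).
#' @param perplexity target perplexity; must satisfy `perplexity <= n - 1`.
#' @param tol tolerance on the row entropy (nats), default 1e-7.
#' @param maxIter maximal bisection steps per row, default 200.
#' @return Row-stochastic n x n matrix of conditional probabilities, with
#'   the per-row precisions `beta` (= 1 / (2 sigma^2)) as attribute.
#' @export
calibrateConditionals <- function(D, perplexity, tol = 1e-7, maxIter = 200L) {
  n <- nrow(D)
  if (perplexity <= 0) stop("perplexity must be positive")
  if (perplexity > n - 1)
    stop(sprintf("perplexity (%g) must not exceed n - 1 = %d", perplexity,
                 n - 1L))
  res <- perplexity_search_cpp(D, perplexity, tol, as.integer(maxIter))
  if (!all(res$converged)) {
    bad <- which(!res$converged)
    stop("perplexity calibration did not converge for rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  P <- res$P
  attr(P, "beta") <- res$beta
  P
}

#' Symmetrize conditional probabilities into a joint distribution
#'
#' The t-SNE convention p_ij = (p_{j|i} + p_{i|j}) / (2n), making the
#' off-diagonal entries sum to one.
#'
#' @param Pcond row-stochastic matrix of conditionals.
#' @return An [AffinityMatrix-class] with role `"high_dim_P"`.
#' @export
symmetrizeP <- function(Pcond) {
  rs <- rowSums(Pcond)
  if (max(abs(rs - 1)) > 1e-6)
    stop("rows of the conditional matrix must sum to 1")
  n <- nrow(Pcond)
  P <- (Pcond + t(Pcond)) / (2 * n)
  diag(P) <- 0
  affinityMatrix(P, role = "high_dim_P")
}

#' High-dimensional affinity matrix of one modality
#'
#' Convenience wrapper: squared distances, perplexity calibration,
#' symmetrization.
#'
#' @param v a [ModalityView-class] or matrix.
#' @param perplexity target perplexity (default 30).
#' @return An [AffinityMatrix-class] P for this modality.
#' @export
modalityAffinity <- function(v, perplexity = 30) {
  symmetrizeP(calibrateConditionals(pairwiseSqDists(v), perplexity))
}

# Solve per-point smooth-kNN bandwidths: rho_i = distance to nearest
# neighbor, sigma_i such that sum_j exp(-max(0, d_ij - rho_i) / sigma_i)
# equals log2(k). Returns list(rho, sigma).
.smoothKnnDist <- function(knnDist, nIter = 64L, tol = 1e-5) {
  k <- ncol(knnDist)
  target <- log2(k)
  n <- nrow(knnDist)
  rho <- knnDist[, 1]
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    d <- pmax(0, knnDist[i, ] - rho[i])
    lo <- 0
    hi <- Inf
    mid <- 1
    for (it in seq_len(nIter)) {
      val <- sum(exp(-d / mid))
      if (abs(val - target) < tol) break
      if (val > target) {
        hi <- mid
        mid <- (lo + mid) / 2
      } else {
        lo <- mid
        mid <- if (is.infinite(hi)) mid * 2 else (lo + hi) / 2
      }
    }
    sigma[i] <- mid
  }
  list(rho = rho, sigma = sigma)
}

#' Fuzzy k-NN membership graph of one modality
#'
#' Standard UMAP construction: exact k nearest neighbors (Euclidean), local
#' connectivity offset rho_i (distance to the nearest neighbor, whose edge
#' therefore has directed strength exp(0) = 1), smooth bandwidth sigma_i
#' solved by bisection so the total membership equals log2(k), and
#' symmetrization by the probabilistic t-conorm a + b - ab.
#'
#' @param v a [ModalityView-class] or matrix.
#' @param nNeighbors neighborhood size k (2 <= k < n), default 15.
#' @return A [FuzzyGraph-class].
#' @importFrom Matrix sparseMatrix t diag drop0
#' @export
fuzzyGraph <- function(v, nNeighbors = 15L) {
  x <- .viewValues(v)
  n <- nrow(x)
  if (nNeighbors >= n)
    stop(sprintf("nNeighbors (%d) must be smaller than the number of cells (%d)",
                 nNeighbors, n))
  if (nNeighbors < 2L) stop("nNeighbors must be >= 2")
  if (any(!is.finite(x))) stop("input contains non-finite values")
  nn <- knn_exact_cpp(x, as.integer(nNeighbors))
  sk <- .smoothKnnDist(nn$dist)
  w <- exp(-pmax(0, nn$dist - sk$rho) / sk$sigma)
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), times = nNeighbors),
                            j = as.vector(nn$idx), x = as.vector(w),
                            dims = c(n, n))
  V <- W + Matrix::t(W) - W * Matrix::t(W)
  V <- Matrix::drop0(V)
  V <- as(as(V, "generalMatrix"), "CsparseMatrix")
  new("FuzzyGraph", edges = V, nNeighbors = as.integer(nNeighbors))
}
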