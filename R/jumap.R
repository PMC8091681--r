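# j-UMAP: convex combination of per-modality fuzzy cross entropies. The
# attractive force on an edge is proportional to the combined membership
# sum_k alpha_k v_ij^(k), so the layout subproblem runs stochastic gradient
# descent on the combined graph Vbar; the weight step shares updateWeights()
# with the j-SNE branch, driven by an explicit per-modality cross-entropy
# estimate.

#' Fit the low-dimensional kernel shape (a, b)
#'
#' Least-squares fit of w(d) = (1 + a d^(2b))^-1 to the target layout curve
#' (1 for d < minDist, exp(-(d - minDist)/spread) beyond), over a 300-point
#' grid on (0, 3 spread).
#'
#' @param minDist,spread target curve parameters, 0 <= minDist < spread.
#' @return Named vector c(a, b).
#' @importFrom minpack.lm nlsLM
#' @export
fitAB <- function(minDist = 0.1, spread = 1.0) {
  if (minDist < 0 || minDist >= spread)
    stop("need 0 <= minDist < spread")
  d <- seq(0, 3 * spread, length.out = 301L)[-1]
  y <- ifelse(d < minDist, 1, exp(-(d - minDist) / spread))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + a * d^(2 * b)),
                      start = list(a = 1, b = 1),
                      data = data.frame(d = d, y = y),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("kernel fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  c(a = unname(cf["a"]), b = unname(cf["b"]))
}

#' Combine per-modality fuzzy graphs with convex weights
#'
#' Sparse union of the edge sets with weighted-sum strengths
#' sum_k alpha_k v_ij^(k); strengths stay in (0, 1] because each v <= 1 and
#' alpha is convex.
#'
#' @param vList list of [FuzzyGraph-class] objects over the same cells.
#' @param alpha [ModalityWeights-class] or simplex vector.
#' @return A [FuzzyGraph-class].
#' @export
combineGraphs <- function(vList, alpha) {
  a <- .alphaVec(alpha)
  if (length(vList) != length(a))
    stop("alpha length must equal the number of graphs")
  ns <- vapply(vList, function(v) nrow(v@edges), integer(1))
  if (length(unique(ns)) > 1) stop("graphs disagree in size")
  V <- Reduce(`+`, Map(function(v, w) w * v@edges, vList, a))
  V <- Matrix::drop0(V)
  V <- as(as(V, "generalMatrix"), "CsparseMatrix")
  new("FuzzyGraph", edges = V, nNeighbors = vList[[1]]@nNeighbors)
}

# Undirected edge list (i < j) of a FuzzyGraph as a data.frame(i, j, w).
.edgeTriplets <- function(V) {
  s <- Matrix::summary(V)
  s <- s[s$i < s$j, , drop = FALSE]
  data.frame(i = s$i, j = s$j, w = s$x)
}

# Expected number of SGD updates per edge over n_epochs: proportional to
# edge strength (strongest edge updated every epoch).
.epochsPerSample <- function(w, nEpochs) {
  ns <- nEpochs * w / max(w)
  ifelse(ns > 0, nEpochs / ns, Inf)
}

.kernelW <- function(Y, i, j, a, b) {
  d2 <- rowSums((Y[i, , drop = FALSE] - Y[j, , drop = FALSE])^2)
  w <- 1 / (1 + a * d2^b)
  pmin(pmax(w, 1e-12), 1 - 1e-12)
}

#' Fuzzy cross entropy of a graph given an embedding
#'
#' CE = sum over unordered pairs of v log(v/w) + (1-v) log((1-v)/(1-w)),
#' with w the low-dimensional kernel. The contribution of the stored edges
#' is summed exactly; the non-edge part (v = 0, contribution -log(1 - w))
#' is estimated from `negSampleRate` seeded uniform non-edge samples per
#' edge, rescaled to the number of non-edge pairs. Deterministic given
#' `negSeed`. Kernel values are clipped to [1e-12, 1 - 1e-12].
#'
#' @param V a [FuzzyGraph-class].
#' @param Y n x d embedding.
#' @param params an [UmapKernelParams-class] (kernel shape a, b).
#' @param negSeed integer seed of the non-edge sampler.
#' @param negSampleRate non-edge samples per stored edge; 0 evaluates the
#'   stored edges only.
#' @param exact evaluate the full O(n^2) sum instead of sampling.
#' @param negPairs optional m x 2 matrix of precomputed non-edge pairs to
#'   reuse across modalities (overrides sampling).
#' @return Scalar total cross entropy (nats).
#' @export
crossEntropyTerm <- function(V, Y, params = umapKernelParams(),
                             negSeed = 1L, negSampleRate = NULL,
                             exact = FALSE, negPairs = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(V@edges) != n) stop("graph and embedding sizes do not match")
  if (is.null(negSampleRate)) negSampleRate <- params@ceNegSampleRate
  a <- params@a
  b <- params@b
  ed <- .edgeTriplets(V@edges)
  w <- .kernelW(Y, ed$i, ed$j, a, b)
  v <- pmin(ed$w, 1)
  edgeTerm <- sum(v * (log(v) - log(w))) +
    sum(ifelse(v < 1, (1 - v) * (log1p(-v) - log1p(-w)), 0))
  nPairs <- n * (n - 1) / 2
  nEdges <- nrow(ed)

  if (exact) {
    D2 <- pairwise_sq_dists_cpp(Y)
    Wall <- 1 / (1 + a * D2^b)
    Wall <- pmin(pmax(Wall, 1e-12), 1 - 1e-12)
    allRep <- sum(-log1p(-Wall[upper.tri(Wall)]))
    edgeRep <- sum(-log1p(-w))
    return(edgeTerm + (allRep - edgeRep))
  }
  if (is.null(negPairs)) {
    m <- as.integer(negSampleRate) * nEdges
    if (m == 0L) return(edgeTerm)
    keys <- sort((ed$i - 1) * n + (ed$j - 1))
    negPairs <- sample_nonedge_pairs_cpp(n, m, as.numeric(keys),
                                         as.integer(negSeed))
  }
  wNeg <- .kernelW(Y, negPairs[, 1], negPairs[, 2], a, b)
  edgeTerm + (nPairs - nEdges) * mean(-log1p(-wNeg))
}

# Spectral initialization on the combined graph: leading non-trivial
# eigenvectors of the normalized adjacency, scaled to max-abs 10. Returns
# NULL when the graph is disconnected or too large for a dense solve.
.spectralInit <- function(V, d) {
  n <- nrow(V)
  if (n > 2048L) return(NULL)
  # connectivity check by sparse BFS
  reached <- logical(n)
  frontier <- 1L
  reached[1L] <- TRUE
  A <- V != 0
  while (length(frontier)) {
    nxt <- unique(Matrix::summary(A[frontier, , drop = FALSE])$j)
    frontier <- nxt[!reached[nxt]]
    reached[frontier] <- TRUE
  }
  if (!all(reached)) return(NULL)
  deg <- Matrix::rowSums(V)
  Dm <- 1 / sqrt(deg)
  An <- as.matrix(V) * outer(Dm, Dm)
  es <- eigen(An, symmetric = TRUE)
  coords <- es$vectors[, 2:(d + 1), drop = FALSE]
  coords / max(abs(coords)) * 10
}

#' Run the joint j-UMAP embedding
#'
#' Structure mirrors [runJSNE()]: per-modality fuzzy graphs are built once;
#' each outer iteration combines them with the current weights, advances the
#' layout by edge-sampling stochastic gradient descent (epochs per edge
#' proportional to combined strength; warm-started after the first outer
#' iteration), evaluates per-modality cross entropies on one shared seeded
#' negative sample, and updates alpha with the same closed form as j-SNE.
#' Cross entropies are normalized by n * nNeighbors before the weight
#' update so their scale matches the lambda = 1 default.
#'
#' @param views list of [ModalityView-class] objects (or matrices), or a
#'   [SimResult-class].
#' @param config a [JointConfig-class]; `lambdaReg = NA` defaults to 1.
#' @param kernel an [UmapKernelParams-class].
#' @return A [JointResult-class].
#' @export
runJUMAP <- function(views, config = jointConfig(),
                     kernel = umapKernelParams()) {
  views <- .normalizeViews(views)
  K <- length(views)
  lambda <- if (is.na(config@lambdaReg)) 1 else config@lambdaReg
  graphs <- lapply(views, fuzzyGraph, nNeighbors = config@nNeighbors)
  n <- nrow(views[[1]]@values)
  d <- config@nComponentsEmbed
  alpha <- stats::setNames(rep(1 / K, K), names(views))

  vBar0 <- combineGraphs(graphs, alpha)
  Y <- .spectralInit(vBar0@edges, d)
  set.seed(config@seed)
  if (is.null(Y)) Y <- matrix(stats::rnorm(n * d, sd = 10), n, d)

  # union edge list across modalities: the complement of the union is a
  # non-edge for every modality, so one shared negative sample serves all
  # K cross-entropy estimates; union pairs that are not edges of modality k
  # are handled exactly below so no modality's repulsive part is biased.
  edK <- lapply(graphs, function(g) {
    ed <- .edgeTriplets(g@edges)
    ed$key <- (ed$i - 1) * n + (ed$j - 1)
    ed
  })
  unionKeys <- sort(unique(unlist(lapply(edK, `[[`, "key"))))
  unionI <- unionKeys %/% n + 1
  unionJ <- unionKeys %% n + 1
  nUnion <- length(unionKeys)
  posK <- lapply(edK, function(ed) match(ed$key, unionKeys))
  nPairs <- n * (n - 1) / 2
  nNeg <- min(as.integer(kernel@ceNegSampleRate) * nUnion, 2000000L)
  # one shared seeded non-edge sample, reused across modalities and outer
  # iterations, so differences in the estimated losses reflect the graphs
  # and the layout, never sampling noise
  negSeed <- as.integer((abs(config@seed) + 69069) %% 2147483647)
  negPairs <- sample_nonedge_pairs_cpp(n, nNeg, as.numeric(unionKeys),
                                       negSeed)

  history <- NULL
  for (t in seq_len(config@maxOuterIter)) {
    vBar <- combineGraphs(graphs, alpha)
    ed <- .edgeTriplets(vBar@edges)
    nEpochs <- if (t == 1L) kernel@nEpochs else kernel@nEpochsLater
    # directed enumeration (both orientations), as in reference UMAP SGD:
    # attraction moves both endpoints, negatives repel the head only
    eps <- .epochsPerSample(ed$w, nEpochs)
    sgdSeed <- as.integer((abs(config@seed) + t * 1013904.0) %% 2147483647)
    # later outer iterations are continuations with an annealed initial
    # learning rate: the warm-started layout adapts to the new weights
    # without being shaken apart, and settles so the weights can converge
    Y <- umap_sgd_cpp(Y, c(ed$i, ed$j), c(ed$j, ed$i), c(eps, eps),
                      kernel@a, kernel@b, gamma = 1,
                      initial_alpha = if (t == 1L) 1 else 0.5 / (t - 1)^2,
                      n_epochs = as.integer(nEpochs),
                      negative_sample_rate = kernel@negSampleRate,
                      seed = sgdSeed)
    # per-pair repulsive terms -log(1 - w): exactly on every union pair,
    # sampled (shared across modalities) beyond the union
    wUnion <- .kernelW(Y, unionI, unionJ, kernel@a, kernel@b)
    repUnion <- -log1p(-wUnion)
    wNeg <- .kernelW(Y, negPairs[, 1], negPairs[, 2], kernel@a, kernel@b)
    repOutside <- (nPairs - nUnion) * mean(-log1p(-wNeg))
    L <- vapply(seq_len(K), function(k) {
      edk <- edK[[k]]
      w <- wUnion[posK[[k]]]
      v <- pmin(edk$w, 1)
      edgeTerm <- sum(v * (log(v) - log(w))) +
        sum(ifelse(v < 1, (1 - v) * (log1p(-v) - log1p(-w)), 0))
      repExact <- sum(repUnion) - sum(repUnion[posK[[k]]])
      (edgeTerm + repExact + repOutside) / (n * config@nNeighbors)
    }, numeric(1))
    names(L) <- names(views)
    objBefore <- sum(alpha * L) + lambda * .plogp(alpha)
    alphaNew <- if (config@fixedWeights) alpha
                else modalityWeightsOf(updateWeights(L, lambda))
    objAfter <- sum(alphaNew * L) + lambda * .plogp(alphaNew)
    maxDelta <- max(abs(alphaNew - alpha))
    history <- rbind(history,
                     .historyRow(t, L, alphaNew, objBefore, objAfter, maxDelta))
    alpha <- alphaNew
    if (maxDelta < config@alphaTol) break
  }
  rownames(Y) <- views[[1]]@cellIds
  new("JointResult", embedding = Y, weights = modalityWeights(alpha),
      history = history, method = "jumap", lambdaReg = lambda)
}

#' Conventional (unimodal) UMAP of one view
#'
#' Equivalent to [runJUMAP()] with a single modality.
#'
#' @param view a [ModalityView-class] or matrix.
#' @param config a [JointConfig-class].
#' @param kernel an [UmapKernelParams-class].
#' @return A [JointResult-class].
#' @export
runUMAP <- function(view, config = jointConfig(),
                    kernel = umapKernelParams()) {
  runJUMAP(list(view), config, kernel)
}
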