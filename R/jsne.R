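# j-SNE: entropy-regularized convex combination of per-modality KL
# divergences, minimized by alternating between t-SNE-style gradient descent
# on the embedding and a closed-form weight update on the simplex.
#
# Because all KL terms share one low-dimensional Q, the embedding subproblem
# for fixed alpha is exactly t-SNE on the aggregated affinity
# Pbar = sum_k alpha_k P^(k):
#   sum_k alpha_k KL(P^(k) || Q) = -sum_{ij} Pbar_ij log q_ij + const(alpha, P).

.affValues <- function(p) if (is(p, "AffinityMatrix")) p@values else as.matrix(p)

.alphaVec <- function(alpha) {
  a <- if (is(alpha, "ModalityWeights")) alpha@alpha else as.numeric(alpha)
  if (any(a < -1e-12) || abs(sum(a) - 1) > 1e-8)
    stop("alpha must lie on the probability simplex")
  pmax(a, 0)
}

.plogp <- function(a) sum(ifelse(a > 0, a * log(a), 0))

#' Aggregate per-modality affinities with convex weights
#'
#' Pbar = sum_k alpha_k P^(k); the embedding subproblem for fixed weights is
#' plain t-SNE on Pbar.
#'
#' @param pList list of [AffinityMatrix-class] objects over the same cells.
#' @param alpha [ModalityWeights-class] or simplex vector, length = K.
#' @return An [AffinityMatrix-class].
#' @export
aggregateP <- function(pList, alpha) {
  a <- .alphaVec(alpha)
  if (length(pList) != length(a))
    stop("alpha length must equal the number of modalities")
  ns <- vapply(pList, function(p) nrow(.affValues(p)), integer(1))
  if (length(unique(ns)) > 1) stop("affinity matrices disagree in size")
  P <- Reduce(`+`, Map(function(p, w) w * .affValues(p), pList, a))
  affinityMatrix(P, role = "high_dim_P")
}

#' Low-dimensional Student-t distribution Q
#'
#' q_ij proportional to (1 + |y_i - y_j|^2)^-1, normalized over all
#' off-diagonal pairs.
#'
#' @param Y n x d embedding matrix (n >= 2).
#' @return An [AffinityMatrix-class] with role `"low_dim_Q"`.
#' @export
lowDimQ <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 points")
  W <- 1 / (1 + pairwise_sq_dists_cpp(Y))
  diag(W) <- 0
  affinityMatrix(W / sum(W), role = "low_dim_Q")
}

#' Kullback-Leibler divergence between affinity matrices
#'
#' sum over off-diagonal pairs of p log(p/q), with the convention
#' 0 log 0 = 0 and q floored at 1e-12 inside the log.
#'
#' @param P,Q [AffinityMatrix-class] objects (or matrices) of equal size.
#' @return Nonnegative scalar (nats).
#' @export
klTerm <- function(P, Q) {
  p <- .affValues(P)
  q <- .affValues(Q)
  if (!identical(dim(p), dim(q))) stop("P and Q must have matching shapes")
  m <- p > 0
  if (any(q[m] == 0))
    stop("Q is zero at pairs where P is positive; KL undefined")
  sum(p[m] * (log(p[m]) - log(pmax(q[m], 1e-12))))
}

#' Gradient of the j-SNE objective with respect to the embedding
#'
#' The t-SNE gradient on the aggregated affinity Pbar:
#' dC/dy_i = 4 sum_j (pbar_ij - q_ij)(y_i - y_j)(1 + |y_i - y_j|^2)^-1.
#'
#' @param pBar [AffinityMatrix-class] (or matrix), the weighted combination.
#' @param Y n x d embedding.
#' @return n x d gradient matrix.
#' @export
jsneGradient <- function(pBar, Y) {
  p <- .affValues(pBar)
  Y <- as.matrix(Y)
  if (nrow(p) != nrow(Y)) stop("shapes of pBar and Y do not match")
  tsne_grad_cpp(p, Y)
}

#' Optimal modality weights for fixed point locations
#'
#' Minimizes sum_k alpha_k L_k + lambda sum_k alpha_k log alpha_k over the
#' simplex; the solution is the Gibbs distribution alpha_k proportional to
#' exp(-L_k / lambda). At lambda = 0 the analytic limit is the vertex
#' selecting the smallest loss (first index on ties) — the single most
#' informative modality.
#'
#' @param losses finite numeric vector of per-modality divergences.
#' @param lambdaReg regularization lambda >= 0.
#' @return A [ModalityWeights-class] (names carried over from `losses`).
#' @export
updateWeights <- function(losses, lambdaReg) {
  if (!length(losses)) stop("losses must be non-empty")
  if (any(!is.finite(losses))) stop("losses must be finite")
  if (lambdaReg < 0) stop("lambdaReg must be >= 0")
  if (lambdaReg == 0) {
    a <- numeric(length(losses))
    a[which.min(losses)] <- 1
  } else {
    z <- exp(-(losses - min(losses)) / lambdaReg)
    a <- z / sum(z)
  }
  names(a) <- names(losses)
  modalityWeights(a)
}

# --- shared run-loop plumbing -------------------------------------------

.normalizeViews <- function(views) {
  if (is(views, "ModalityView") || (is.matrix(views))) views <- list(views)
  if (is(views, "SimResult")) views <- views@modalities
  if (!length(views)) stop("need at least one modality")
  views <- lapply(views, function(v) {
    if (is(v, "ModalityView")) v else modalityView(as.matrix(v))
  })
  nm <- names(views)
  auto <- vapply(views, modalityName, character(1))
  if (is.null(nm)) nm <- auto
  nm[nm == ""] <- auto[nm == ""]
  nm[nm == "modality"] <- paste0("modality", seq_along(views))[nm == "modality"]
  names(views) <- make.unique(nm)
  ns <- vapply(views, function(v) nrow(v@values), integer(1))
  if (length(unique(ns)) > 1)
    stop("modalities disagree in cell count: ", paste(ns, collapse = ", "))
  if (ns[1] < 4L) stop("need at least 4 cells")
  views
}

.initEmbedding <- function(views, config) {
  n <- nrow(views[[1]]@values)
  d <- config@nComponentsEmbed
  if (config@init == "pca") {
    X <- do.call(cbind, lapply(views, function(v) v@values))
    pc <- stats::prcomp(X, center = TRUE, rank. = d)$x[, seq_len(d),
                                                       drop = FALSE]
    pc / stats::sd(pc[, 1]) * 1e-4
  } else {
    matrix(stats::rnorm(n * d, sd = 1e-4), n, d)
  }
}

.historyRow <- function(outer, L, alphaNew, objBefore, objAfter, maxDelta) {
  row <- data.frame(outer = outer, objectiveBefore = objBefore,
                    objective = objAfter, maxDeltaAlpha = maxDelta)
  for (k in seq_along(L)) row[[paste0("loss.", names(L)[k])]] <- L[k]
  for (k in seq_along(alphaNew))
    row[[paste0("alpha.", names(alphaNew)[k])]] <- alphaNew[k]
  row
}

#' Run the joint j-SNE embedding
#'
#' Alternating optimization: with weights alpha fixed (initialized uniform),
#' the embedding is advanced by t-SNE gradient descent on the aggregated
#' affinity Pbar (full schedule with early exaggeration in the first outer
#' iteration, warm-started continuation afterwards); with the embedding
#' fixed, per-modality divergences L_k = KL(P^(k) || Q) are evaluated and
#' alpha is set to its closed-form optimum. Stops when the largest alpha
#' change falls below `alphaTol` or after `maxOuterIter` outer iterations.
#' Identical config and seed give bit-identical results.
#'
#' @param views list of [ModalityView-class] objects (or matrices) over the
#'   same ordered cells; a [SimResult-class] is also accepted.
#' @param config a [JointConfig-class]; `lambdaReg = NA` defaults to 3.
#' @return A [JointResult-class].
#' @export
runJSNE <- function(views, config = jointConfig()) {
  views <- .normalizeViews(views)
  K <- length(views)
  lambda <- if (is.na(config@lambdaReg)) 3 else config@lambdaReg
  pList <- lapply(views, modalityAffinity, perplexity = config@perplexity)
  set.seed(config@seed)
  Y <- .initEmbedding(views, config)
  alpha <- stats::setNames(rep(1 / K, K), names(views))
  history <- NULL
  exIters <- min(250L, config@innerItersFirst %/% 2L)
  for (t in seq_len(config@maxOuterIter)) {
    pBar <- aggregateP(pList, alpha)
    first <- t == 1L
    Y <- tsne_inner_cpp(pBar@values, Y,
                        iters = if (first) config@innerItersFirst
                                else config@innerItersLater,
                        eta = config@learningRate,
                        mom_start = 0.5, mom_final = 0.8,
                        mom_switch = if (first) min(250L, exIters) else 0L,
                        exaggeration = if (first) config@earlyExaggeration
                                       else 1,
                        exagger_iters = if (first) exIters else 0L)
    Q <- lowDimQ(Y)
    L <- vapply(pList, klTerm, numeric(1), Q = Q)
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
      history = history, method = "jsne", lambdaReg = lambda)
}

#' Plain t-SNE on a precomputed affinity matrix
#'
#' The single-modality reference path: seeded initialization followed by one
#' full gradient-descent schedule (early exaggeration, momentum switch) on
#' the given P. `runJSNE` with one modality reduces exactly to this.
#'
#' @param P an [AffinityMatrix-class] (role `"high_dim_P"`).
#' @param config a [JointConfig-class] (seed, learning rate, schedule).
#' @param iters iteration count; defaults to `config@innerItersFirst`.
#' @return n x d embedding matrix.
#' @export
tsneOnAffinity <- function(P, config = jointConfig(), iters = NULL) {
  p <- .affValues(P)
  if (is.null(iters)) iters <- config@innerItersFirst
  n <- nrow(p)
  set.seed(config@seed)
  Y <- if (config@init == "gaussian")
    matrix(stats::rnorm(n * config@nComponentsEmbed, sd = 1e-4), n,
           config@nComponentsEmbed)
  else stop("tsneOnAffinity supports gaussian initialization only")
  exIters <- min(250L, as.integer(iters) %/% 2L)
  tsne_inner_cpp(p, Y, iters = as.integer(iters), eta = config@learningRate,
                 mom_start = 0.5, mom_final = 0.8, mom_switch = exIters,
                 exaggeration = config@earlyExaggeration,
                 exagger_iters = exIters)
}

#' Conventional (unimodal) t-SNE of one view
#'
#' Equivalent to [runJSNE()] with a single modality.
#'
#' @param view a [ModalityView-class] or matrix.
#' @param config a [JointConfig-class].
#' @return A [JointResult-class].
#' @export
runTSNE <- function(view, config = jointConfig()) {
  runJSNE(list(view), config)
}
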