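# The j-UMAP branch: kernel fit, graph combination, cross-entropy
# estimator and the alternating loop.

test_that("fitAB reproduces the standard kernel shape", {
  ab <- fitAB(0.1, 1.0)
  expect_equal(unname(ab["a"]), 1.58, tolerance = 0.05)
  expect_equal(unname(ab["b"]), 0.90, tolerance = 0.03)
  d <- seq(0.01, 3, length.out = 100)
  k <- 1 / (1 + ab["a"] * d^(2 * ab["b"]))
  expect_true(all(diff(k) < 0))
  ab0 <- fitAB(1e-8, 1.0)
  expect_equal(1 / (1 + ab0["a"] * 1e-12^ab0["b"]), c(a = 1),
               tolerance = 1e-3)
  expect_error(fitAB(1.2, 1.0), "minDist < spread")
})

test_that("combineGraphs takes weighted sums over the edge union", {
  x <- twoBlobs(8, 3, gap = 30, seed = 2)
  g1 <- fuzzyGraph(x, 4L)
  g2 <- fuzzyGraph(x + rnorm(length(x), sd = 0.05), 4L)
  expect_equal(combineGraphs(list(g1), 1)@edges, g1@edges)
  comb <- combineGraphs(list(g1, g2), c(0.5, 0.5))
  expect_equal(comb@edges, Matrix::drop0((g1@edges + g2@edges) / 2),
               tolerance = 1e-12)
  expect_lte(max(comb@edges@x), 1)
  # an edge present in one modality only is scaled by that alpha
  only1 <- which(as.matrix(g1@edges != 0 & g2@edges == 0), arr.ind = TRUE)
  if (nrow(only1)) {
    i <- only1[1, 1]; j <- only1[1, 2]
    expect_equal(comb@edges[i, j], 0.5 * g1@edges[i, j])
  }
  expect_error(combineGraphs(list(g1, fuzzyGraph(x[1:10, ], 4L)),
                             c(0.5, 0.5)), "size")
})

test_that("an edge with matching kernel value contributes zero CE", {
  k <- umapKernelParams()
  v <- 0.6
  # place two points so the low-dimensional kernel equals v exactly
  d2 <- ((1 / v - 1) / k@a)^(1 / k@b)
  Y <- matrix(c(0, sqrt(d2), 0, 0), 2, 2)
  V <- new("FuzzyGraph",
           edges = methods::as(Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1),
                                                    x = v, dims = c(2, 2)),
                               "CsparseMatrix"),
           nNeighbors = 2L)
  expect_equal(crossEntropyTerm(V, Y, k, negSampleRate = 0), 0,
               tolerance = 1e-10)
  # and v = w minimizes the contribution over nearby w
  ce <- vapply(c(0.8, 1.0, 1.25) * sqrt(d2), function(s) {
    crossEntropyTerm(V, matrix(c(0, s, 0, 0), 2, 2), k, negSampleRate = 0)
  }, numeric(1))
  expect_equal(which.min(ce), 2L)
})

test_that("a fully-on edge rendered at w ~ 1 costs ~ nothing", {
  k <- umapKernelParams()
  V <- new("FuzzyGraph",
           edges = methods::as(Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1),
                                                    x = 1, dims = c(2, 2)),
                               "CsparseMatrix"),
           nNeighbors = 2L)
  Y <- matrix(c(0, 1e-9, 0, 0), 2, 2)
  expect_lt(abs(crossEntropyTerm(V, Y, k, negSampleRate = 0)), 1e-6)
})

test_that("cross-entropy estimator agrees with the exact evaluation", {
  k <- umapKernelParams()
  set.seed(13)
  x <- matrix(rnorm(5 * 3), 5, 3)
  g <- fuzzyGraph(x, 2L)
  Y <- matrix(rnorm(10), 5, 2)
  # with no negative samples only the stored edges are evaluated; this
  # must equal the exact total minus the brute-force non-edge part
  ed <- getFromNamespace(".edgeTriplets", "jembed")(g@edges)
  keys <- (ed$i - 1) * 5 + (ed$j - 1)
  nonEdge <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    if (((i - 1) * 5 + (j - 1)) %in% keys) next
    w <- 1 / (1 + k@a * sum((Y[i, ] - Y[j, ])^2)^k@b)
    nonEdge <- nonEdge - log1p(-min(max(w, 1e-12), 1 - 1e-12))
  }
  expect_equal(crossEntropyTerm(g, Y, k, negSampleRate = 0),
               crossEntropyTerm(g, Y, k, exact = TRUE) - nonEdge,
               tolerance = 1e-10)
})

test_that("sampled cross entropy is close to exact and seed-stable", {
  k <- umapKernelParams()
  for (s in 1:3) {
    set.seed(s)
    x <- rbind(matrix(rnorm(50 * 4), 50, 4),
               matrix(rnorm(50 * 4, mean = 4), 50, 4))
    g <- fuzzyGraph(x, 10L)
    Y <- x[, 1:2] + rnorm(200, sd = 0.3)
    exact <- crossEntropyTerm(g, Y, k, exact = TRUE)
    est <- crossEntropyTerm(g, Y, k, negSeed = s, negSampleRate = 50)
    expect_lt(abs(est - exact) / exact, 0.05)
    expect_identical(est, crossEntropyTerm(g, Y, k, negSeed = s,
                                           negSampleRate = 50))
  }
})

test_that("stronger edges receive more SGD update epochs", {
  eps <- getFromNamespace(".epochsPerSample", "jembed")
  w <- c(0.05, 0.2, 0.5, 1.0)
  schedule <- eps(w, 100)
  counts <- 100 / schedule  # expected updates over the run
  expect_true(all(diff(counts) > 0))
  expect_equal(counts[4], 100)
})

test_that("runJUMAP with one modality keeps alpha at one", {
  v <- randomView(60, 5, seed = 12)
  cfg <- jointConfig(seed = 3, nNeighbors = 8L)
  kern <- umapKernelParams(nEpochs = 100L, nEpochsLater = 30L)
  res <- runJUMAP(list(v), cfg, kern)
  expect_equal(unname(modalityWeightsOf(res)), 1)
  expect_equal(res@lambdaReg, 1)  # j-UMAP default
  expect_equal(nrow(lossHistory(res)), 1L)
})

test_that("runJUMAP is deterministic and shares the alpha update rule", {
  d <- list(a = randomView(70, 4, seed = 5), b = randomView(70, 4, seed = 6))
  cfg <- jointConfig(seed = 21, nNeighbors = 8L, maxOuterIter = 4L)
  kern <- umapKernelParams(nEpochs = 120L, nEpochsLater = 40L)
  r1 <- runJUMAP(d, cfg, kern)
  r2 <- runJUMAP(d, cfg, kern)
  expect_identical(embedding(r1), embedding(r2))
  expect_identical(lossHistory(r1), lossHistory(r2))
  h <- lossHistory(r1)
  # each recorded alpha is the closed-form optimum of the recorded losses
  for (r in seq_len(nrow(h))) {
    L <- unlist(h[r, c("loss.a", "loss.b")])
    expect_equal(unname(unlist(h[r, c("alpha.a", "alpha.b")])),
                 unname(modalityWeightsOf(updateWeights(L, 1))),
                 tolerance = 1e-12)
  }
  expect_true(all(h$objective <= h$objectiveBefore + 1e-12))
})

test_that("spectral initialization is deterministic and used when connected", {
  set.seed(7)
  x <- matrix(rnorm(40 * 3), 40, 3)
  g <- fuzzyGraph(x, 6L)
  init <- getFromNamespace(".spectralInit", "jembed")
  y1 <- init(g@edges, 2L)
  y2 <- init(g@edges, 2L)
  expect_identical(y1, y2)
  expect_equal(max(abs(y1)), 10)
  # disconnected graph falls back
  far <- fuzzyGraph(twoBlobs(10, 3, gap = 1000, seed = 8), 3L)
  expect_null(init(far@edges, 2L))
})
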