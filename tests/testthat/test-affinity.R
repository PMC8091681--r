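test_that("pairwiseSqDists matches a brute-force double loop", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  D <- pairwiseSqDists(x)
  ref <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) ref[i, j] <- sum((x[i, ] - x[j, ])^2)
  expect_equal(D, ref, tolerance = 1e-10)
  expect_equal(pairwiseSqDists(rbind(c(0, 0), c(3, 4)))[1, 2], 25)
  expect_equal(pairwiseSqDists(matrix(1, 4, 3)), matrix(0, 4, 4))
  expect_error(pairwiseSqDists(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("calibrateConditionals hits maximal-entropy cases exactly", {
  # equilateral triangle: two equidistant neighbors, perplexity 2
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  P <- calibrateConditionals(pairwiseSqDists(tri), 2)
  expect_equal(P[1, 2:3], c(0.5, 0.5), tolerance = 1e-6)
  # regular simplex: n - 1 equidistant neighbors at perplexity n - 1
  simplex <- diag(4)
  P4 <- calibrateConditionals(pairwiseSqDists(simplex), 3)
  expect_equal(unname(P4[1, 2:4]), rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("calibrateConditionals matches a dense sigma grid search", {
  x <- matrix(c(0, 1, 2, 4), 4, 1)
  D <- pairwiseSqDists(x)
  P <- calibrateConditionals(D, 2)
  sigmas <- exp(seq(log(1e-3), log(100), length.out = 40000))
  for (i in 1:4) {
    d <- D[i, -i]
    best <- NULL
    bestErr <- Inf
    for (s in sigmas) {
      pr <- exp(-d / (2 * s^2))
      if (sum(pr) == 0) next
      pr <- pr / sum(pr)
      H <- -sum(ifelse(pr > 0, pr * log2(pr), 0))
      err <- abs(2^H - 2)
      if (err < bestErr) {
        bestErr <- err
        best <- pr
      }
    }
    expect_lt(max(abs(P[i, -i] - best)), 1e-4)
  }
})

test_that("calibrated rows realize the target perplexity", {
  set.seed(7)
  x <- matrix(rnorm(200), 40, 5)
  P <- calibrateConditionals(pairwiseSqDists(x), 10)
  for (i in 1:40) {
    p <- P[i, -i]
    H <- -sum(ifelse(p > 0, p * log2(p), 0))
    expect_equal(2^H, 10, tolerance = 1e-3)
  }
})

test_that("calibrateConditionals rejects out-of-range perplexity", {
  D <- pairwiseSqDists(matrix(rnorm(10), 5, 2))
  expect_error(calibrateConditionals(D, 4.5), "n - 1")
  expect_error(calibrateConditionals(D, 0), "positive")
})

test_that("symmetrizeP applies the (p + p') / 2n convention", {
  pc <- rbind(c(0, 0.7, 0.3), c(0.4, 0, 0.6), c(0.5, 0.5, 0))
  P <- symmetrizeP(pc)
  expect_equal(values(P)[1, 2], (0.7 + 0.4) / 6)
  # symmetric (uniform) input reduces to division by n
  pc2 <- matrix(1 / 5, 6, 6)
  diag(pc2) <- 0
  expect_equal(values(symmetrizeP(pc2)), pc2 / 6)
})

test_that("symmetrizeP output satisfies the affinity invariants", {
  for (s in 1:5) {
    P <- symmetrizeP(randomConditionals(9, seed = s))
    v <- values(P)
    expect_equal(sum(v), 1, tolerance = 1e-8)
    expect_equal(max(abs(v - t(v))), 0, tolerance = 1e-12)
    expect_true(all(diag(v) == 0))
    expect_true(all(v >= 0))
  }
  expect_error(symmetrizeP(matrix(0.3, 4, 4)), "sum to 1")
})

test_that("fuzzyGraph gives every cell a full-strength nearest edge", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  g <- fuzzyGraph(x, 5L)
  e <- g@edges
  # t-conorm a + b - ab with a = 1 keeps the nearest edge at 1
  rowMax <- vapply(seq_len(20), function(i) max(e[i, ]), numeric(1))
  expect_equal(rowMax, rep(1, 20), tolerance = 1e-12)
  expect_true(all(e@x > 0 & e@x <= 1 + 1e-12))
  expect_equal(max(abs(e - Matrix::t(e))), 0, tolerance = 1e-12)
})

test_that("the probabilistic t-conorm absorbs one-sided strengths", {
  # directed strengths a = 1, b = 0 must symmetrize to 1: the nearest
  # neighbor edge survives even if unreciprocated. Construct a geometry
  # where cell 1's nearest neighbor 2 has a different neighborhood.
  x <- matrix(c(0, 1.0, 1.9, 2.7, 40, 41, 42, 43), ncol = 1)
  g <- fuzzyGraph(x, 2L)
  expect_equal(g@edges[1, 2], 1)
})

test_that("fuzzyGraph keeps distant blobs disconnected and solves sigma", {
  x <- twoBlobs(10, 3, gap = 50, seed = 4)
  g <- fuzzyGraph(x, 5L)
  expect_equal(sum(g@edges[1:10, 11:20]), 0)
  # bisection oracle: the smooth-kNN normalization must hold per point
  nn <- getFromNamespace("knn_exact_cpp", "jembed")(x, 5L)
  sk <- getFromNamespace(".smoothKnnDist", "jembed")(nn$dist)
  for (i in seq_len(20)) {
    total <- sum(exp(-pmax(0, nn$dist[i, ] - sk$rho[i]) / sk$sigma[i]))
    expect_equal(total, log2(5), tolerance = 1e-3)
  }
  # directed strengths decrease with distance within a source row
  w <- exp(-matrix(pmax(0, nn$dist - sk$rho), 20) / sk$sigma)
  expect_true(all(apply(w, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("fuzzyGraph rejects invalid neighborhood sizes", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fuzzyGraph(x, 10L), "smaller")
  expect_error(fuzzyGraph(x, 1L), ">= 2")
})

test_that("fuzzy graph strengths agree with an independent implementation", {
  skip_if_not_installed("uwot")
  set.seed(9)
  x <- matrix(rnorm(200 * 5), 200, 5)
  g <- fuzzyGraph(x, 15L)
  ref <- uwot::similarity_graph(x, n_neighbors = 15, nn_method = "fnn")
  # conventions differ slightly (self-inclusion in the neighbor count,
  # bandwidth floors), so demand structural agreement, not identity
  dif <- abs(g@edges - methods::as(ref, "CsparseMatrix"))
  expect_lt(mean(dif@x), 3e-2)
  common <- which(as.matrix(g@edges != 0 & ref != 0), arr.ind = TRUE)
  expect_gt(stats::cor(g@edges[common], ref[common]), 0.95)
})
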