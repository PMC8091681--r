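# The j-SNE objective, its gradient, the closed-form weight update and the
# alternating loop.

test_that("aggregateP forms the convex combination of affinities", {
  p1 <- randomAffinity(8, seed = 1)
  p2 <- randomAffinity(8, seed = 2)
  expect_equal(values(aggregateP(list(p1), 1)), values(p1))
  mid <- aggregateP(list(p1, p2), c(0.5, 0.5))
  expect_equal(values(mid), (values(p1) + values(p2)) / 2)
  for (s in 1:3) {
    set.seed(s)
    a <- runif(2)
    a <- a / sum(a)
    expect_equal(sum(values(aggregateP(list(p1, p2), a))), 1,
                 tolerance = 1e-10)
  }
  expect_error(aggregateP(list(p1, randomAffinity(5)), c(0.5, 0.5)),
               "size")
  expect_error(aggregateP(list(p1, p2), c(0.9, 0.3)), "simplex")
})

test_that("lowDimQ normalizes the Student-t kernel over pairs", {
  expect_equal(values(lowDimQ(matrix(c(0, 17), 2, 1)))[1, 2], 0.5)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(unique(round(values(lowDimQ(tri))[upper.tri(diag(3))], 12)),
               1 / 6)
  # collinear points 0, 1, 3: kernels 1/2, 1/10, 1/5
  Y <- matrix(c(0, 1, 3), 3, 1)
  q <- values(lowDimQ(Y))
  tot <- 2 * (1 / 2 + 1 / 10 + 1 / 5)
  expect_equal(q[1, 2], (1 / 2) / tot)
  expect_equal(q[1, 3], (1 / 10) / tot)
  expect_equal(q[2, 3], (1 / 5) / tot)
})

test_that("klTerm computes sum p log(p/q) with its conventions", {
  P <- randomAffinity(7, seed = 3)
  expect_equal(klTerm(P, P), 0)
  expect_gte(klTerm(P, randomAffinity(7, seed = 4)), -1e-12)
  # two-mass worked case: 0.5 log(0.5/0.9) + 0.5 log(0.5/0.1)
  p <- matrix(0, 2, 2); p[1, 2] <- 0.5; p[2, 1] <- 0.5
  q <- matrix(0, 2, 2); q[1, 2] <- 0.9; q[2, 1] <- 0.1
  expect_equal(klTerm(p, q), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1))
  qz <- q; qz[2, 1] <- 0
  expect_error(klTerm(p, qz), "zero")
  expect_error(klTerm(p, matrix(0.1, 3, 3)), "shapes")
})

test_that("jsneGradient matches central finite differences", {
  objective <- function(P, Y) klTerm(P, values(lowDimQ(Y)))
  set.seed(11)
  for (rep in 1:3) {
    P <- values(randomAffinity(15, seed = rep + 20))
    Y <- matrix(rnorm(30), 15, 2)
    G <- jsneGradient(P, Y)
    h <- 1e-5
    Gnum <- matrix(0, 15, 2)
    for (i in 1:15) for (m in 1:2) {
      Yp <- Y; Yp[i, m] <- Y[i, m] + h
      Ym <- Y; Ym[i, m] <- Y[i, m] - h
      Gnum[i, m] <- (objective(P, Yp) - objective(P, Ym)) / (2 * h)
    }
    expect_lt(norm(G - Gnum, "F") / norm(Gnum, "F"), 1e-4)
  }
})

test_that("jsneGradient is zero for two points and translation invariant", {
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.5
  expect_equal(jsneGradient(P, matrix(c(0, 3, 1, -2), 2, 2)),
               matrix(0, 2, 2))
  Pb <- values(randomAffinity(9, seed = 5))
  set.seed(6)
  Y <- matrix(rnorm(18), 9, 2)
  shift <- sweep(Y, 2, c(13.7, -2.1), `+`)
  expect_equal(jsneGradient(Pb, Y), jsneGradient(Pb, shift),
               tolerance = 1e-10)
})

test_that("updateWeights solves the entropy-regularized simplex problem", {
  # closed form alpha_k ~ exp(-L_k / lambda)
  a <- modalityWeightsOf(updateWeights(c(1, 2), 1))
  expect_equal(unname(a), c(exp(-1), exp(-2)) / (exp(-1) + exp(-2)),
               tolerance = 1e-12)
  expect_equal(unname(a), c(0.7311, 0.2689), tolerance = 1e-4)
  # large lambda: regularizer dominates, weights near uniform
  big <- modalityWeightsOf(updateWeights(c(5, 1, 3), 1e6))
  expect_equal(unname(big), rep(1 / 3, 3), tolerance = 1e-4)
  # lambda = 0: vertex on the smallest loss, first index on ties
  expect_equal(unname(modalityWeightsOf(updateWeights(c(0.4, 0.2, 0.9), 0))),
               c(0, 1, 0))
  expect_equal(unname(modalityWeightsOf(updateWeights(c(0.3, 0.3), 0))),
               c(1, 0))
  expect_error(updateWeights(numeric(0), 1), "non-empty")
  expect_error(updateWeights(c(1, NaN), 1), "finite")
})

test_that("updateWeights is monotone and agrees with a simplex grid", {
  for (s in 1:5) {
    set.seed(s)
    L <- runif(3, 0, 3)
    lam <- runif(1, 0.2, 4)
    a <- modalityWeightsOf(updateWeights(L, lam))
    expect_equal(order(L), order(-a))
    # coarse 2-simplex grid oracle
    grid <- seq(0, 1, by = 1e-3)
    gi <- expand.grid(a1 = grid, a2 = grid)
    gi <- gi[gi$a1 + gi$a2 <= 1, ]
    gi$a3 <- 1 - gi$a1 - gi$a2
    plogp <- function(x) ifelse(x > 0, x * log(pmax(x, 1e-300)), 0)
    obj <- gi$a1 * L[1] + gi$a2 * L[2] + gi$a3 * L[3] +
      lam * (plogp(gi$a1) + plogp(gi$a2) + plogp(gi$a3))
    best <- gi[which.min(obj), ]
    expect_equal(unname(a), c(best$a1, best$a2, best$a3), tolerance = 2e-3)
  }
})

test_that("runJSNE with one modality reduces to plain t-SNE", {
  v <- randomView(60, 5, seed = 8)
  cfg <- jointConfig(seed = 4, perplexity = 12, innerItersFirst = 150L)
  res <- runJSNE(list(v), cfg)
  expect_equal(unname(modalityWeightsOf(res)), 1)
  expect_true(all(lossHistory(res)[, grep("^alpha", names(lossHistory(res)))]
                  == 1))
  ref <- tsneOnAffinity(modalityAffinity(v, 12), cfg, iters = 150L)
  expect_equal(unname(embedding(res)), ref)
})

test_that("runJSNE is deterministic and keeps alpha on the simplex", {
  d <- list(a = randomView(50, 4, seed = 1), b = randomView(50, 4, seed = 2))
  cfg <- jointConfig(seed = 9, perplexity = 10, innerItersFirst = 120L,
                     innerItersLater = 40L, maxOuterIter = 4L)
  r1 <- runJSNE(d, cfg)
  r2 <- runJSNE(d, cfg)
  expect_identical(embedding(r1), embedding(r2))
  expect_identical(lossHistory(r1), lossHistory(r2))
  h <- lossHistory(r1)
  A <- as.matrix(h[, grep("^alpha", names(h))])
  expect_true(all(A >= 0))
  expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-10)
  expect_lte(nrow(h), 4L)
  # the exact alpha step never increases the total objective
  expect_true(all(h$objective <= h$objectiveBefore + 1e-12))
})

test_that("runJSNE honours fixed uniform weights and rejects bad input", {
  d <- list(a = randomView(40, 3, seed = 3), b = randomView(40, 3, seed = 4))
  cfg <- jointConfig(seed = 2, perplexity = 8, innerItersFirst = 80L,
                     fixedWeights = TRUE, maxOuterIter = 3L)
  res <- runJSNE(d, cfg)
  h <- lossHistory(res)
  expect_true(all(h[, grep("^alpha", names(h))] == 0.5))
  expect_error(runJSNE(list(randomView(10, 3), randomView(12, 3))),
               "cell count")
  expect_error(runJSNE(list(modalityView(matrix(1, 1, 3)))), "cells")
})
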