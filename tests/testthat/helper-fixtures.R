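# Small fixture builders shared across test files.

randomCounts <- function(n = 12, p = 8, seed = 1, lambda = 5) {
  set.seed(seed)
  matrix(rpois(n * p, lambda), n, p)
}

randomView <- function(n = 20, p = 4, seed = 1) {
  set.seed(seed)
  modalityView(matrix(rnorm(n * p), n, p))
}

# A valid symmetric affinity matrix (zero diagonal, off-diagonal sum 1).
randomAffinity <- function(n = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- m + t(m)
  diag(m) <- 0
  affinityMatrix <- getFromNamespace("affinityMatrix", "jembed")
  affinityMatrix(m / sum(m), role = "high_dim_P")
}

# Random row-stochastic matrix with zero diagonal.
randomConditionals <- function(n = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  diag(m) <- 0
  m / rowSums(m)
}

# Two well-separated Gaussian blobs.
twoBlobs <- function(nPer = 10, d = 3, gap = 50, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(nPer * d), nPer, d),
        matrix(rnorm(nPer * d, mean = gap), nPer, d))
}

# Small three-modality dataset (rna, adt, shuffled rna) for joint runs.
smallNoiseDataset <- function(n = 200, fraction = 0.8, seed = 1) {
  sim <- simulateMultimodal(simConfig(nCells = as.integer(n), nGenes = 300L,
                                      nAdt = 30L, seed = as.integer(seed)))
  sh <- makeShuffledModality(sim@modalities$rna, fraction,
                             seed = as.integer(seed) + 500L)
  list(views = prepareViews(list(rna = sim@modalities$rna,
                                 adt = sim@modalities$adt, noise = sh)),
       labels = sim@labels)
}
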