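# Synthetic multimodal data: a Splatter-style hierarchical gamma-Poisson
# count model for RNA and ADT with shared group labels, a shuffled-noise
# modality, a two-modality toy scenario with complementary confounding, and
# the runtime-scaling suite.

.pick <- function(x, modality) {
  if (length(x) == 1L) unname(x) else unname(x[[modality]])
}

# One modality's counts given group labels. Hierarchy: feature base means
# ~ Gamma(meanShape, meanRate); expression outliers replace the mean by a
# log-normal multiple of the median; per-group DE multiplies a deProb
# fraction of features by log-normal factors (inverted with prob 1/2);
# cell library sizes ~ log-normal; counts ~ gamma-Poisson (NB) with the
# given dispersion; zero inflation by logistic dropout on the log mean.
.simulateCounts <- function(cfg, modality, nFeatures, groups) {
  nCells <- length(groups)
  nGroups <- cfg@nGroups
  baseMean <- stats::rgamma(nFeatures, shape = cfg@meanShape,
                            rate = cfg@meanRate)
  isOut <- stats::runif(nFeatures) < cfg@outlierProb
  if (any(isOut))
    baseMean[isOut] <- stats::median(baseMean) *
      stats::rlnorm(sum(isOut), log(cfg@outlierScale), 0.5)

  deProb <- .pick(cfg@deProb, modality)
  facs <- matrix(1, nGroups, nFeatures)
  for (g in seq_len(nGroups)) {
    sel <- stats::runif(nFeatures) < deProb
    if (any(sel)) {
      f <- stats::rlnorm(sum(sel), 0, cfg@deLogfcScale)
      inv <- stats::runif(sum(sel)) < 0.5
      f[inv] <- 1 / f[inv]
      facs[g, sel] <- f
    }
  }
  groupMeans <- sweep(facs, 2, baseMean, `*`)
  groupProb <- groupMeans / rowSums(groupMeans)  # per-group feature profile

  lib <- stats::rlnorm(nCells, .pick(cfg@libsizeMu, modality),
                       .pick(cfg@libsizeSigma, modality))
  mu <- groupProb[groups, , drop = FALSE] * lib
  disp <- .pick(cfg@dispersion, modality)
  lambda <- matrix(stats::rgamma(nCells * nFeatures, shape = 1 / disp,
                                 scale = as.vector(mu) * disp),
                   nCells, nFeatures)
  counts <- matrix(stats::rpois(nCells * nFeatures, as.vector(lambda)),
                   nCells, nFeatures)
  dMid <- .pick(cfg@dropoutMid, modality)
  dShape <- .pick(cfg@dropoutShape, modality)
  pKeep <- 1 - 1 / (1 + exp(-dShape * (log(mu) - dMid)))
  keep <- matrix(stats::rbinom(nCells * nFeatures, 1L, as.vector(pKeep)),
                 nCells, nFeatures)
  counts * keep
}

#' Simulate a grouped multimodal (RNA + ADT) count dataset
#'
#' Draws shared group labels from `groupProbs`, then RNA and ADT counts from
#' the hierarchical gamma-Poisson model of [SimConfig-class]. Identical
#' seeds give identical output.
#'
#' @param config a [SimConfig-class].
#' @return A [SimResult-class] with modalities `rna` and `adt`.
#' @export
simulateMultimodal <- function(config = simConfig()) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nCells
  groups <- sample.int(config@nGroups, n, replace = TRUE,
                       prob = config@groupProbs)
  labels <- paste0("group", groups)
  cells <- sprintf("cell%04d", seq_len(n))
  rna <- .simulateCounts(config, "rna", config@nGenes, groups)
  adt <- .simulateCounts(config, "adt", config@nAdt, groups)
  mods <- list(
    rna = countMatrix(rna, cellIds = cells,
                      featureIds = sprintf("gene%04d", seq_len(config@nGenes)),
                      modalityName = "rna"),
    adt = countMatrix(adt, cellIds = cells,
                      featureIds = sprintf("adt%03d", seq_len(config@nAdt)),
                      modalityName = "adt"))
  new("SimResult", modalities = mods, labels = labels,
      paramsUsed = .simConfigAsList(config))
}

.simConfigAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

#' Shuffled-noise copy of a modality
#'
#' Duplicates a count matrix and randomly permutes the expression vectors
#' (rows) of a uniformly chosen subset of `floor(fraction * n)` cells among
#' themselves; remaining rows are untouched, so the multiset of rows is
#' preserved. `fraction = 1` destroys all label signal.
#'
#' @param x a [CountMatrix-class] (or matrix).
#' @param fraction fraction of cells whose measurements are shuffled,
#'   in \[0, 1\].
#' @param seed integer seed.
#' @return A [CountMatrix-class] named `<modality>_shuffled`.
#' @export
makeShuffledModality <- function(x, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  cm <- if (is(x, "CountMatrix")) x else countMatrix(x)
  v <- cm@values
  n <- nrow(v)
  m <- floor(fraction * n)
  set.seed(seed)
  if (m >= 2) {
    subset <- sample.int(n, m)
    v[subset, ] <- v[sample(subset), , drop = FALSE]
  }
  countMatrix(v, cellIds = cm@cellIds, featureIds = cm@featureIds,
              modalityName = paste0(cm@modalityName, "_shuffled"))
}

#' Toy two-modality scenario with complementary confounding
#'
#' Four equal true groups of Gaussian blobs in two 10-dimensional
#' modalities: in modality A, groups 1 and 2 share a center (separation 0)
#' while 3 and 4 are well separated; in modality B the roles are swapped.
#' Neither modality alone can resolve all four groups, but jointly they can
#' — the canonical motivation for a joint embedding.
#'
#' @param nCells total cells, >= 40 and divisible by 4.
#' @param seed integer seed.
#' @param separation distance between distinguishable centers (default 6;
#'   within-blob noise is standard normal).
#' @return A [SimResult-class] whose modalities are [ModalityView-class]
#'   objects `modA`, `modB` (already real-valued; no preprocessing needed).
#' @export
toyConfoundedScenario <- function(nCells = 200L, seed = 1L, separation = 6) {
  if (nCells < 40L) stop("nCells must be >= 40")
  if (nCells %% 4L != 0L) stop("nCells must be divisible by 4")
  set.seed(seed)
  per <- nCells %/% 4L
  groups <- rep(1:4, each = per)
  dims <- 10L
  centers <- function(confounded) {
    # confounded pair shares the origin; the other two sit far apart
    ctr <- matrix(0, 4, dims)
    if (identical(confounded, c(1L, 2L))) {
      ctr[3, 1] <- separation
      ctr[4, 2] <- separation
    } else {
      ctr[1, 1] <- separation
      ctr[2, 2] <- separation
    }
    ctr
  }
  blob <- function(ctr) {
    ctr[groups, , drop = FALSE] + matrix(stats::rnorm(nCells * dims),
                                         nCells, dims)
  }
  cells <- sprintf("cell%04d", seq_len(nCells))
  modA <- modalityView(blob(centers(c(1L, 2L))), modalityName = "modA",
                       cellIds = cells, transformLog = "toy-gaussian-blobs")
  modB <- modalityView(blob(centers(c(3L, 4L))), modalityName = "modB",
                       cellIds = cells, transformLog = "toy-gaussian-blobs")
  new("SimResult", modalities = list(modA = modA, modB = modB),
      labels = paste0("group", groups),
      paramsUsed = list(nCells = nCells, seed = seed,
                        separation = separation, dims = dims,
                        confoundedA = c(1L, 2L), confoundedB = c(3L, 4L)))
}

#' Scaling suite: datasets of increasing size with 2 or 4 modalities
#'
#' For each requested cell count, simulates RNA + ADT (2 modalities) or
#' additionally their shuffled copies at fraction 0.4 (4 modalities).
#'
#' @param nCellsList integer vector of dataset sizes.
#' @param nModalities 2 or 4.
#' @param seed integer seed.
#' @param config template [SimConfig-class]; `nCells`/`seed` are overridden
#'   per dataset.
#' @return List of [SimResult-class] objects.
#' @export
scalingSuite <- function(nCellsList, nModalities = 2L, seed = 1L,
                         config = simConfig()) {
  if (!nModalities %in% c(2L, 4L)) stop("nModalities must be 2 or 4")
  lapply(seq_along(nCellsList), function(i) {
    cfg <- config
    cfg@nCells <- as.integer(nCellsList[i])
    cfg@seed <- as.integer(seed + i - 1L)
    sim <- simulateMultimodal(cfg)
    if (nModalities == 4L) {
      sim@modalities$rna_shuffled <-
        makeShuffledModality(sim@modalities$rna, 0.4, seed = cfg@seed + 1000L)
      sim@modalities$adt_shuffled <-
        makeShuffledModality(sim@modalities$adt, 0.4, seed = cfg@seed + 2000L)
    }
    sim
  })
}

#' Named simulation presets
#'
#' Convenience configurations patterned on a 1k/5k-cell design with an
#' optional reduced gene count; the concrete sizes are this package's own
#' reconstructions.
#'
#' @param name one of `"N1k"` (1000 cells, 2000 genes), `"N5k"` (5000
#'   cells, 2000 genes), `"N5kD1k"` (5000 cells, 1000 genes).
#' @param seed integer seed.
#' @return A [SimConfig-class].
#' @export
simPreset <- function(name = c("N1k", "N5k", "N5kD1k"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    N1k = simConfig(nCells = 1000L, nGenes = 2000L, seed = seed),
    N5k = simConfig(nCells = 5000L, nGenes = 2000L, seed = seed),
    N5kD1k = simConfig(nCells = 5000L, nGenes = 1000L, seed = seed))
}
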