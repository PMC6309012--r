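#' Simulate structured-coalescent genealogies
#'
#' Runs the backward-in-time three-deme coalescent under one of the six
#' demographic models and returns per-branch records (subtended sample
#' counts per deme and branch length in generations) together with each
#' replicate's TMRCA.
#'
#' @param model a `ModelSpec` from [modelCatalog()].
#' @param params a `ParameterVector` for that model.
#' @param config haploid sample sizes from [sampleConfig()].
#' @param seed integer seed; replicate r uses a seed derived from
#'   (seed, r), so results are independent of batching.
#' @param nReps number of independent genealogies.
#' @return List with `branches` (data.frame: rep, nS, nC, nO, length) and
#'   `tmrca` (numeric vector of length `nReps`).
#' @export
simulateGenealogy <- function(model, params, config = sampleConfig(),
                              seed, nReps = 1L) {
  validateParams(model, params)
  a <- engineArgs(model, params)
  .coalBranchTable(as.integer(config), a$sizes, a$TD, a$TA, a$TSC,
                   a$mS, a$mC, a$migWindow, as.integer(nReps),
                   as.double(seed))
}

#' Expected joint SFS by branch-length accumulation
#'
#' Monte-Carlo expectation of the unfolded joint SFS: entry (i, j, k) is
#' the mutation rate per generation times the mean total branch length
#' subtending exactly (i, j, k) sampled chromosomes, averaged over
#' `nReps` genealogies (Rao-Blackwellized over the Poisson mutation
#' process, so no SNPs are sampled). Linear in `mu`; the monomorphic
#' corners are masked. Per-entry Monte-Carlo standard errors are stored
#' in `metadata$se`.
#'
#' @inheritParams simulateGenealogy
#' @param nReps number of genealogies to average.
#' @param mu mutation rate per site per generation; defaults to the fixed
#'   calibration (2.21e-9 with a 1-year generation).
#' @param antithetic pair replicates on mirrored uniform streams
#'   (u, 1-u); waiting times anticorrelate within a pair, reducing the
#'   Monte-Carlo variance of the mean at no extra cost. Standard errors
#'   are computed over independent pairs.
#' @return A [JointSFS-class] of expected counts per site of sequence.
#' @export
expectedSFS <- function(model, params, config = sampleConfig(), nReps,
                        seed, mu = NULL, antithetic = FALSE) {
  validateParams(model, params)
  if (is.null(mu)) mu <- model$fixed$mu * model$fixed$generationTime
  a <- engineArgs(model, params)
  raw <- .coalExpectedSfs(as.integer(config), a$sizes, a$TD, a$TA, a$TSC,
                          a$mS, a$mC, a$migWindow, as.integer(nReps),
                          as.double(seed), antithetic)
  dims <- as.integer(config) + 1L
  meanBranch <- array(raw$sum / raw$nReps, dim = dims)
  varUnits <- array(pmax(0, raw$sumsq / raw$nEff -
                           (raw$sum / raw$nReps)^2), dim = dims)
  se <- mu * sqrt(varUnits / raw$nEff)
  JointSFS(mu * meanBranch, sampleSizes = as.integer(config),
           metadata = list(se = se, nReps = raw$nReps, mu = mu, seed = seed,
                           modelId = model$modelId))
}

#' Draw an observed joint SFS of segregating sites under a model
#'
#' Computes the expected spectrum at `nReps` genealogies, normalizes it
#' over the unmasked cells, and draws `nSnps` sites multinomially: the
#' parametric simulation used for refit harnesses and bootstrap
#' replicates.
#'
#' @inheritParams expectedSFS
#' @param nSnps number of segregating sites to draw.
#' @param nReps genealogies behind the expected spectrum (default 3000).
#' @return A [JointSFS-class] of integer site counts.
#' @export
simulateSFS <- function(model, params, config = sampleConfig(), nSnps,
                        seed, nReps = 3000L) {
  exp0 <- expectedSFS(model, params, config, nReps = nReps, seed = seed)
  p <- sfsCounts(exp0)
  msk <- sfsMask(exp0)
  p[msk] <- 0
  tot <- sum(p)
  if (tot <= 0) stop("expected spectrum has no unmasked mass")
  withr::local_seed(seed %% .Machine$integer.max)
  draw <- stats::rmultinom(1, size = nSnps, prob = as.vector(p / tot))
  JointSFS(array(as.numeric(draw), dim = dim(p)),
           sampleSizes = sampleSizes(exp0),
           metadata = list(nSnps = nSnps, seed = seed,
                           modelId = model$modelId))
}

#' Simulate a diploid SNP genotype matrix under a demographic model
#'
#' Draws `nSnps` biallelic segregating sites, one per genealogy, with the
#' mutated branch chosen proportional to its length. Diploids are formed
#' by pairing consecutive haploid lineages within each deme. Missing
#' calls are i.i.d. at `missingRate`; each SNP sits on its own locus.
#' The REF allele is always the ancestral state.
#'
#' @inheritParams simulateGenealogy
#' @param nInd diploid individuals per population, length 3 (SON, CHI,
#'   CAR).
#' @param nSnps number of SNPs.
#' @param missingRate probability a genotype call is missing.
#' @return A [GenotypeMatrix-class].
#' @export
sampleSNPMatrix <- function(model, params, nInd = c(5L, 5L, 1L), nSnps,
                            missingRate = 0, seed) {
  validateParams(model, params)
  stopifnot(nSnps >= 1, missingRate >= 0, missingRate < 1)
  nInd <- as.integer(nInd)
  ns <- 2L * nInd
  a <- engineArgs(model, params)
  hap <- .coalSampleSnps(ns, a$sizes, a$TD, a$TA, a$TSC, a$mS, a$mC,
                         a$migWindow, as.integer(nSnps), as.double(seed))
  # consecutive haploids pair into diploids
  odd <- seq(1, ncol(hap), by = 2)
  calls <- hap[, odd, drop = FALSE] + hap[, odd + 1L, drop = FALSE]
  popLabels <- rep(c("SON", "CHI", "CAR"), times = nInd)
  ids <- paste0(popLabels, "_",
                unlist(lapply(nInd, seq_len), use.names = FALSE))
  if (missingRate > 0) {
    withr::local_seed(seed %% .Machine$integer.max)
    miss <- matrix(stats::runif(length(calls)) < missingRate,
                   nrow = nrow(calls))
    calls[miss] <- NA_integer_
  }
  sites <- data.frame(
    chrom = sprintf("locus%06d", seq_len(nSnps)),
    pos = 1L,
    locus_id = sprintf("L%06d", seq_len(nSnps)),
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
  GenotypeMatrix(calls, sites, ids,
                 stats::setNames(popLabels, ids),
                 metadata = list(seed = seed, modelId = model$modelId,
                                 missingRate = missingRate))
}
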