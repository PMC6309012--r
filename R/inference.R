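#' Composite log-likelihood of an observed SFS
#'
#' Multinomial composite likelihood over the unmasked cells: the expected
#' spectrum is normalized to cell probabilities, floored at `pMin` (so a
#' cell with zero Monte-Carlo mass but observed sites stays finite) and
#' renormalized; sites are treated as independent. Invariant to rescaling
#' of the expected spectrum.
#'
#' @param obs observed [JointSFS-class] (site counts).
#' @param expected expected [JointSFS-class] (any positive scale).
#' @param pMin probability floor; defaults to 1 / (10 x total accumulated
#'   branch mass) when the expected spectrum carries its Monte-Carlo
#'   provenance, else 1 / (10 x observed total).
#' @return Natural-log composite likelihood.
#' @export
compositeLogLik <- function(obs, expected, pMin = NULL) {
  if (!identical(dim(sfsCounts(obs)), dim(sfsCounts(expected))))
    stop("observed and expected spectra differ in shape")
  if (!identical(sfsMask(obs), sfsMask(expected)))
    stop("observed and expected spectra differ in mask")
  keep <- !sfsMask(obs)
  o <- sfsCounts(obs)[keep]
  e <- sfsCounts(expected)[keep]
  tot <- sum(e)
  if (tot <= 0) stop("expected spectrum has no unmasked mass")
  if (is.null(pMin)) {
    md <- expected@metadata
    branchMass <- if (!is.null(md$mu) && !is.null(md$nReps))
      tot / md$mu * md$nReps else 10 * max(1, sum(o))
    pMin <- 1 / (10 * branchMass)
  }
  p <- pmax(e / tot, pMin)
  p <- p / sum(p)
  sum(o * log(p))
}

#' Search settings for [fitModel()]
#'
#' @param nPriorDraws prior draws scored in the global phase.
#' @param nRefine coordinate hill-climbing sweeps in the local phase.
#' @param repsPerEval genealogies per likelihood evaluation.
#' @param nStarts number of top prior draws used as independent
#'   hill-climbing starts (the composite surface is multimodal along a
#'   small-size/high-migration ridge).
#' @param nChains number of independent search chains (each with its own
#'   common-random-number surfaces); the chain whose endpoint scores best
#'   on one shared high-precision evaluation is returned — the scaled-
#'   down analog of running many search iterations and keeping the one
#'   with the highest likelihood.
#' @param nmEvals,nmFactor,nmRestarts budget per run, reps multiplier and
#'   maximum restarts of the Nelder-Mead simplex stage run from the best
#'   climbed point. The simplex moves along the correlated size/time
#'   ridge that axis-aligned steps cross slowly, but it also contracts
#'   onto Monte-Carlo wiggles; restarting it with a fresh simplex at its
#'   own endpoint escapes those, and the loop stops as soon as a restart
#'   gains less than two log-likelihood units. Set `nmEvals = 0` to
#'   disable.
#' @param finalNmEvals budget of one last simplex run at
#'   `finalFactor x repsPerEval` genealogies, pinning the optimum down at
#'   low Monte-Carlo noise. Set to 0 to disable.
#' @param finalFactor multiplier on `repsPerEval` for the final simplex
#'   and the final re-evaluation of the best point.
#' @param pMin probability floor passed to [compositeLogLik()]; `NULL`
#'   floors at one tenth of a single observed site, the resolution of
#'   the data.
#' @return A list of settings.
#' @export
fitSettings <- function(nPriorDraws = 100L, nRefine = 3L,
                        repsPerEval = 2000L, nStarts = 2L, nChains = 2L,
                        nmEvals = 100L, nmFactor = 8L, nmRestarts = 2L,
                        finalNmEvals = 100L,
                        finalFactor = 25L, pMin = NULL) {
  stopifnot(nPriorDraws >= 1, nRefine >= 0, repsPerEval >= 1, nStarts >= 1,
            nChains >= 1, nmEvals >= 0, nmRestarts >= 1, finalNmEvals >= 0)
  list(nPriorDraws = as.integer(nPriorDraws), nRefine = as.integer(nRefine),
       repsPerEval = as.integer(repsPerEval), nStarts = as.integer(nStarts),
       nChains = as.integer(nChains),
       nmEvals = as.integer(nmEvals), nmFactor = as.integer(nmFactor),
       nmRestarts = as.integer(nmRestarts),
       finalNmEvals = as.integer(finalNmEvals),
       finalFactor = as.integer(finalFactor), pMin = pMin)
}

deriveSeed <- function(seed, i) {
  (as.double(seed) * 1000003 + i) %% 2147483629
}

# search-scale <-> natural-scale transforms over the model's paramTable
toSearch <- function(pt, nat) {
  x <- nat
  x[pt$scale == "log"] <- log(nat[pt$scale == "log"])
  x
}
fromSearch <- function(pt, x) {
  nat <- x
  nat[pt$scale == "log"] <- exp(x[pt$scale == "log"])
  nat
}
natToParams <- function(model, pt, nat) {
  vals <- as.list(nat)
  names(vals) <- pt$name
  if (!is.null(vals$TSC)) vals$TSC <- min(vals$TSC, vals$TD)
  do.call(parameterVector, c(list(model), vals))
}
drawToNat <- function(pt, params) {
  nat <- stats::setNames(numeric(nrow(pt)), pt$name)
  for (nm in pt$name) {
    nat[nm] <- switch(nm,
      M = params$mS * params$NeC,      # back-convert to migrants/generation
      MS = params$mS * params$NeC,
      MC = params$mC * params$NeS,
      params[[nm]])
  }
  nat
}

#' Fit a demographic model to an observed joint SFS
#'
#' Layered maximum composite-likelihood search, all stages using common
#' random numbers (every evaluation in a stage reuses the same genealogy
#' seeds, so its Monte-Carlo surface is a fixed deterministic function):
#' (1) score `nPriorDraws` prior draws; (2) coordinate-wise hill climbing
#' from the best `nStarts` draws, on the log scale for sizes and
#' migration and the natural scale for times, halving all steps after a
#' sweep with no improvement; (3) a restarted Nelder-Mead simplex at
#' `nmFactor x repsPerEval` genealogies, which crosses the correlated
#' size/time ridge that axis-aligned steps cannot; (4) one final simplex
#' at `finalFactor x repsPerEval` genealogies. Hard lower bounds are
#' enforced; upper bounds are soft and may be exceeded (capped far above
#' the prior). The returned log-likelihood is re-evaluated at
#' `finalFactor x repsPerEval` genealogies with fresh seeds.
#'
#' @param obs observed [JointSFS-class].
#' @param model a `ModelSpec`.
#' @param prior prior data.frame, see [defaultPriors()].
#' @param settings see [fitSettings()].
#' @param seed integer seed.
#' @return A `FitResult` list: `modelId`, `mle` (ParameterVector),
#'   `loglik`, `aic = 2k - 2 loglik`, `k`, `nEvaluations`, `seed`.
#' @export
fitModel <- function(obs, model, prior = defaultPriors(model),
                     settings = fitSettings(), seed) {
  pt <- paramTable(model$modelId)
  config <- sampleSizes(obs)
  crnSeed <- deriveSeed(seed, 777001)
  nEval <- 0L
  pMin <- if (is.null(settings$pMin))
    1 / (10 * sum(sfsCounts(obs)[!sfsMask(obs)])) else settings$pMin

  score <- function(x, reps = settings$repsPerEval, evalSeed = crnSeed) {
    nat <- fromSearch(pt, x)
    params <- natToParams(model, pt, nat)
    e <- expectedSFS(model, params, config, nReps = reps, seed = evalSeed)
    nEval <<- nEval + 1L
    compositeLogLik(obs, e, pMin = pMin)
  }

  # phase 1: prior sampling
  draws <- matrix(NA_real_, settings$nPriorDraws, nrow(pt))
  drawLL <- numeric(settings$nPriorDraws)
  for (d in seq_len(settings$nPriorDraws)) {
    params <- drawParameters(model, prior, seed = deriveSeed(seed, d))
    draws[d, ] <- toSearch(pt, drawToNat(pt, params))
    drawLL[d] <- score(draws[d, ])
  }

  # phase 2: coordinate hill climbing with step halving, from the top
  # nStarts prior draws
  lowerS <- toSearch(pt, stats::setNames(pt$lower, pt$name))
  lowerS[pt$name == "TSC"] <- 0
  # soft upper bounds may be exceeded, but cap the search far above them
  # so proposals stay inside the model's admissible region
  upperS <- toSearch(pt, stats::setNames(pt$upper, pt$name)) +
    ifelse(pt$scale == "log", log(30), 0.9 * (pt$upper - pt$lower))
  upperS[pt$name == "TD"] <- min(upperS[pt$name == "TD"],
                                 model$fixed$TA * 0.999)
  climb <- function(x0, ll0, nSweeps, reps, evalSeed, step0) {
    bx <- x0; bll <- ll0
    step <- step0
    for (sweep in seq_len(nSweeps)) {
      improved <- FALSE
      for (i in seq_len(nrow(pt))) {
        for (dir in c(1, -1)) {
          cand <- bx
          cand[i] <- min(max(cand[i] + dir * step[i], lowerS[i]), upperS[i])
          if (cand[i] == bx[i]) next
          ll <- score(cand, reps = reps, evalSeed = evalSeed)
          if (ll > bll) { bll <- ll; bx <- cand; improved <- TRUE }
        }
      }
      if (!improved) step <- step / 2
    }
    list(x = bx, ll = bll)
  }
  stepWide <- ifelse(pt$scale == "log", 0.6, 0.15 * (pt$upper - pt$lower))
  starts <- order(drawLL, decreasing = TRUE)[seq_len(
    min(settings$nStarts, settings$nPriorDraws))]

  # simplex runner: parscale sizes the initial simplex — without it the
  # default 10% steps are enormous on the log scale and the simplex
  # never contracts onto the ridge.  The simplex also likes to collapse
  # onto Monte-Carlo wiggles, so callers restart it at its own endpoint
  # until a restart gains < 2 log-likelihood units.
  pscale <- ifelse(pt$scale == "log", 0.4, 0.08 * (pt$upper - pt$lower))
  runNm <- function(x0, reps, evalSeed, maxit) {
    obj <- function(x) {
      viol <- pmax(lowerS - x, 0) + pmax(x - upperS, 0)
      xc <- pmin(pmax(x, lowerS), upperS)
      -score(xc, reps = reps, evalSeed = evalSeed) + 1e4 * sum(viol^2)
    }
    nm <- stats::optim(x0, obj, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10,
                                      parscale = pscale))
    list(x = pmin(pmax(nm$par, lowerS), upperS), ll = -nm$value)
  }
  restartedNm <- function(x0, reps, evalSeed, maxit, maxRestarts) {
    cur <- list(x = x0, ll = score(x0, reps = reps, evalSeed = evalSeed))
    for (r in seq_len(maxRestarts)) {
      res <- runNm(cur$x, reps, evalSeed, maxit)
      gain <- res$ll - cur$ll
      if (res$ll > cur$ll) cur <- res
      if (gain < 2) break
    }
    cur$x
  }

  # chains: independent climb + simplex trajectories on their own CRN
  # surfaces; the endpoint that wins one shared high-precision
  # evaluation is kept (run many searches, keep the best likelihood)
  repsHi <- settings$repsPerEval * settings$finalFactor
  selSeed <- deriveSeed(seed, 888001)
  bestX <- NULL
  bestSel <- -Inf
  for (chain in seq_len(settings$nChains)) {
    crnChain <- deriveSeed(seed, 555000 + 101 * chain)
    cx <- draws[starts[1], ]
    cll <- -Inf
    for (s in starts) {
      res <- climb(draws[s, ], drawLL[s], settings$nRefine,
                   settings$repsPerEval, crnChain, stepWide)
      if (res$ll > cll) { cll <- res$ll; cx <- res$x }
    }
    if (settings$nmEvals > 0)
      cx <- restartedNm(cx, settings$repsPerEval * settings$nmFactor,
                        deriveSeed(seed, 556000 + 101 * chain),
                        settings$nmEvals, settings$nmRestarts)
    if (settings$finalNmEvals > 0)
      cx <- restartedNm(cx, repsHi,
                        deriveSeed(seed, 557000 + 101 * chain),
                        settings$finalNmEvals, 2L)
    sel <- score(cx, reps = repsHi, evalSeed = selSeed)
    if (sel > bestSel) { bestSel <- sel; bestX <- cx }
  }

  mleNat <- fromSearch(pt, bestX)
  names(mleNat) <- pt$name
  mle <- natToParams(model, pt, mleNat)
  onLower <- pt$name[abs(bestX - lowerS) < 1e-12 & pt$lower > 0]
  if (length(onLower))
    warning(sprintf("MLE for %s sits on a hard lower bound (model %s)",
                    paste(onLower, collapse = ", "), model$modelId))
  llFinal <- bestSel
  structure(list(
    modelId = model$modelId,
    mle = mle,
    mleNatural = mleNat,
    loglik = llFinal,
    k = model$k,
    aic = 2 * model$k - 2 * llFinal,
    nEvaluations = nEval,
    seed = seed,
    settings = settings
  ), class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult[%s]: loglik %.3f, AIC %.3f (k = %d, %d evaluations)\n",
              x$modelId, x$loglik, x$aic, x$k, x$nEvaluations))
  print(round(unlist(x$mleNatural), 6))
  invisible(x)
}

# translate a fitted model's natural-scale parameters into another
# model's parameter space: missing migration rates enter at the prior
# floor (effectively zero flow), missing contact times at zero
translateNat <- function(natFrom, ptTo) {
  out <- stats::setNames(numeric(nrow(ptTo)), ptTo$name)
  for (nm in ptTo$name) {
    out[nm] <- if (nm %in% names(natFrom)) natFrom[[nm]]
    else if (nm == "TSC") 0
    else if (nm == "M") {
      ms <- c(natFrom["MS"], natFrom["MC"])
      ms <- ms[!is.na(ms)]
      if (length(ms)) mean(ms) else ptTo$lower[ptTo$name == nm]
    }
    else ptTo$lower[ptTo$name == nm]   # MS / MC at the prior floor
  }
  out
}

#' Fit the whole model catalog to one spectrum, with cross-seeding
#'
#' Fits every requested model with [fitModel()] under a shared seed, then
#' runs a cross-seeding pass: each model's candidate set is its own
#' optimum plus every other model's optimum translated into its parameter
#' space (absent migration rates enter at the prior floor, absent contact
#' times at zero). Candidates are compared on one shared high-precision
#' evaluation per model, and a short simplex polishes a foreign candidate
#' that wins. Because the six models nest, this keeps their maximized
#' likelihoods consistent: a nested model can never appear to fit much
#' worse than a richer one merely because its own search stopped short —
#' the property delta-AIC comparisons rely on.
#'
#' @param obs observed [JointSFS-class].
#' @param settings see [fitSettings()].
#' @param seed integer seed shared by all model fits (this also makes the
#'   final evaluations common-random-number comparable across models).
#' @param modelIds models to fit (default: all six).
#' @return Named list of `FitResult`s.
#' @export
fitAllModels <- function(obs, settings = fitSettings(), seed,
                         modelIds = names(modelCatalog())) {
  fits <- lapply(modelIds, function(id)
    fitModel(obs, getModel(id), settings = settings, seed = seed))
  names(fits) <- modelIds
  pMin <- if (is.null(settings$pMin))
    1 / (10 * sum(sfsCounts(obs)[!sfsMask(obs)])) else settings$pMin
  config <- sampleSizes(obs)
  repsHi <- settings$repsPerEval * settings$finalFactor
  selSeed <- deriveSeed(seed, 888001)

  for (id in modelIds) {
    model <- getModel(id)
    pt <- paramTable(id)
    evalNat <- function(nat) {
      params <- natToParams(model, pt, nat)
      compositeLogLik(obs, expectedSFS(model, params, config,
                                       nReps = repsHi, seed = selSeed),
                      pMin = pMin)
    }
    bestNat <- fits[[id]]$mleNatural
    bestLL <- fits[[id]]$loglik
    foreign <- FALSE
    for (other in setdiff(modelIds, id)) {
      cand <- translateNat(fits[[other]]$mleNatural, pt)
      ll <- tryCatch(evalNat(cand), error = function(e) -Inf)
      if (ll > bestLL) { bestLL <- ll; bestNat <- cand; foreign <- TRUE }
    }
    if (foreign && settings$finalNmEvals > 0) {
      # short polish from the adopted foreign candidate
      sub <- settings
      sub$nPriorDraws <- 1L
      sub$nRefine <- 0L
      sub$nStarts <- 1L
      sub$nChains <- 1L
      sub$nmEvals <- 0L
      refit <- fitModelFrom(obs, model, bestNat, sub, seed)
      if (refit$loglik > bestLL) {
        bestLL <- refit$loglik
        bestNat <- refit$mleNatural
      }
    }
    if (bestLL > fits[[id]]$loglik) {
      fits[[id]]$mleNatural <- bestNat
      fits[[id]]$mle <- natToParams(model, pt, bestNat)
      fits[[id]]$loglik <- bestLL
      fits[[id]]$aic <- 2 * model$k - 2 * bestLL
    }
  }
  fits
}

# internal: run only the final simplex + shared evaluation from a given
# natural-scale starting point
fitModelFrom <- function(obs, model, natStart, settings, seed) {
  pt <- paramTable(model$modelId)
  pMin <- if (is.null(settings$pMin))
    1 / (10 * sum(sfsCounts(obs)[!sfsMask(obs)])) else settings$pMin
  config <- sampleSizes(obs)
  lowerS <- toSearch(pt, stats::setNames(pt$lower, pt$name))
  lowerS[pt$name == "TSC"] <- 0
  upperS <- toSearch(pt, stats::setNames(pt$upper, pt$name)) +
    ifelse(pt$scale == "log", log(30), 0.9 * (pt$upper - pt$lower))
  upperS[pt$name == "TD"] <- min(upperS[pt$name == "TD"],
                                 model$fixed$TA * 0.999)
  repsHi <- settings$repsPerEval * settings$finalFactor
  crn <- deriveSeed(seed, 559001)
  selSeed <- deriveSeed(seed, 888001)
  scoreX <- function(x, evalSeed) {
    nat <- fromSearch(pt, x)
    names(nat) <- pt$name
    compositeLogLik(obs, expectedSFS(model, natToParams(model, pt, nat),
                                     config, nReps = repsHi,
                                     seed = evalSeed), pMin = pMin)
  }
  pscale <- ifelse(pt$scale == "log", 0.4, 0.08 * (pt$upper - pt$lower))
  x0 <- pmin(pmax(toSearch(pt, natStart[pt$name]), lowerS), upperS)
  obj <- function(x) {
    viol <- pmax(lowerS - x, 0) + pmax(x - upperS, 0)
    xc <- pmin(pmax(x, lowerS), upperS)
    -scoreX(xc, crn) + 1e4 * sum(viol^2)
  }
  nm <- stats::optim(x0, obj, method = "Nelder-Mead",
                     control = list(maxit = settings$finalNmEvals,
                                    reltol = 1e-10, parscale = pscale))
  xBest <- pmin(pmax(nm$par, lowerS), upperS)
  if (scoreX(xBest, crn) < scoreX(x0, crn)) xBest <- x0
  nat <- fromSearch(pt, xBest)
  names(nat) <- pt$name
  ll <- scoreX(xBest, selSeed)
  list(mleNatural = nat, loglik = ll)
}

#' AIC model comparison with the 2.0 / 10.0 support thresholds
#'
#' Computes delta-AIC against the best model and labels each fit: the best
#' model; `not_significant` when the gap is below 2; `significant` at 2 or
#' more; `highly_significant` at 10 or more.
#'
#' @param fits list of `FitResult`s on the same observed spectrum.
#' @return data.frame (model_id, k, loglik, aic, delta_aic, label), sorted
#'   by AIC.
#' @export
selectModel <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  ids <- vapply(fits, function(f) f$modelId, character(1))
  if (anyDuplicated(ids)) stop("duplicate model_id in fits")
  tab <- data.frame(
    model_id = ids,
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$label <- ifelse(tab$delta_aic == 0, "best",
               ifelse(tab$delta_aic < 2, "not_significant",
               ifelse(tab$delta_aic < 10, "significant",
                      "highly_significant")))
  tab[order(tab$aic), ]
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `B` observed spectra of `nSnps` segregating sites under the
#' fitted parameters, refits the same model to each, and reports the
#' bootstrap mean and 2.5/97.5 percentile interval per parameter (sizes
#' and times on the natural scale; migration as backward per-lineage
#' probabilities). Replicates whose fit fails are recorded and excluded;
#' more than 20% failures is an error.
#'
#' @param model a `ModelSpec`.
#' @param mle fitted `ParameterVector` (the generating truth).
#' @param config haploid [sampleConfig()].
#' @param B number of bootstrap replicates (>= 2).
#' @param nSnps segregating sites per replicate.
#' @param seed integer seed.
#' @param settings refit settings, see [fitSettings()].
#' @param prior prior for the refits.
#' @return A `BootstrapSummary` list: `table` (parameter, mean, ci_low,
#'   ci_high), `B`, `nFailed`, `replicates` (matrix of estimates).
#' @export
parametricBootstrap <- function(model, mle, config = sampleConfig(), B,
                                nSnps, seed, settings = fitSettings(),
                                prior = defaultPriors(model)) {
  if (B < 2) stop("B must be >= 2")
  pt <- paramTable(model$modelId)
  reportName <- function(nm) switch(nm, M = "m", MS = "mS", MC = "mC", nm)
  est <- matrix(NA_real_, nrow = B, ncol = nrow(pt),
                dimnames = list(NULL, vapply(pt$name, reportName,
                                             character(1))))
  nFailed <- 0L
  for (b in seq_len(B)) {
    obs <- simulateSFS(model, mle, config, nSnps,
                       seed = deriveSeed(seed, 5000 + b))
    fit <- tryCatch(
      fitModel(obs, model, prior, settings,
               seed = deriveSeed(seed, 9000 + b)),
      error = function(e) NULL)
    if (is.null(fit)) { nFailed <- nFailed + 1L; next }
    p <- fit$mle
    for (j in seq_len(nrow(pt))) {
      nm <- pt$name[j]
      est[b, j] <- switch(nm, M = p$mS, MS = p$mS, MC = p$mC, p[[nm]])
    }
  }
  if (nFailed > 0.2 * B)
    stop(sprintf("%d of %d bootstrap fits failed", nFailed, B))
  ok <- stats::complete.cases(est)
  tab <- data.frame(
    parameter = colnames(est),
    mean = colMeans(est[ok, , drop = FALSE]),
    ci_low = apply(est[ok, , drop = FALSE], 2, stats::quantile,
                   probs = 0.025, type = 1),
    ci_high = apply(est[ok, , drop = FALSE], 2, stats::quantile,
                    probs = 0.975, type = 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, B = B, nFailed = nFailed, replicates = est),
            class = "BootstrapSummary")
}

#' @export
print.BootstrapSummary <- function(x, ...) {
  cat(sprintf("BootstrapSummary: %d replicates (%d failed)\n",
              x$B, x$nFailed))
  print(x$table, digits = 6)
  invisible(x)
}
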