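#' Fixed calibration constants for the demographic model family
#'
#' The outgroup split is fixed at 2,000,000 years to calibrate all other
#' parameters into absolute units; generation time is 1 year; the mutation
#' rate is 2.21e-9 per site per year.
#' @return Named list with `TA`, `generationTime`, `mu`.
#' @export
fixedConstants <- function() {
  list(TA = 2e6, generationTime = 1, mu = 2.21e-9)
}

MODEL_IDS <- c("ISO", "SYM", "ASYM", "SON2CHI", "CHI2SON", "SECCONTACT")

# search-scale parameter table for one model: name, scale, prior bounds
paramTable <- function(modelId) {
  ne <- function(nm) data.frame(name = nm, scale = "log", dist = "log-uniform",
                                lower = 5e4, upper = 1e6, soft = TRUE,
                                stringsAsFactors = FALSE)
  td <- data.frame(name = "TD", scale = "lin", dist = "uniform",
                   lower = 5e5, upper = 1e6, soft = TRUE,
                   stringsAsFactors = FALSE)
  tsc <- data.frame(name = "TSC", scale = "lin", dist = "uniform",
                    lower = 0, upper = 21000, soft = TRUE,
                    stringsAsFactors = FALSE)
  mig <- function(nm) data.frame(name = nm, scale = "log", dist = "log-uniform",
                                 lower = 1e-3, upper = 20, soft = TRUE,
                                 stringsAsFactors = FALSE)
  base <- do.call(rbind, c(lapply(c("NeS", "NeC", "NeO", "NeD", "NeA"), ne),
                           list(td)))
  extra <- switch(modelId,
    ISO = NULL,
    SYM = mig("M"),
    ASYM = rbind(mig("MS"), mig("MC")),
    SON2CHI = mig("MS"),
    CHI2SON = mig("MC"),
    SECCONTACT = rbind(tsc, mig("MS"), mig("MC")),
    stop("unknown model id: ", modelId))
  rbind(base, extra)
}

#' The six demographic models
#'
#' Returns the catalog of three-population isolation / isolation-with-
#' migration models: pure isolation (`ISO`), isolation with symmetric
#' (`SYM`), asymmetric (`ASYM`), Sonoran-to-Chihuahuan-only (`SON2CHI`) or
#' Chihuahuan-to-Sonoran-only (`CHI2SON`) migration, and isolation with
#' secondary contact since the last glacial maximum (`SECCONTACT`).
#' Migration parameters are priors on the migrants-per-generation scale
#' (converted internally to backward per-lineage probabilities); `ISO` is
#' nested in every other model (migration -> 0, or contact time -> 0).
#'
#' @return Named list of `ModelSpec` lists with elements `modelId`,
#'   `freeParameters`, `k` (free-parameter count), `migWindow`, `fixed`.
#' @export
modelCatalog <- function() {
  specs <- lapply(MODEL_IDS, function(id) {
    pt <- paramTable(id)
    structure(list(
      modelId = id,
      freeParameters = pt$name,
      k = nrow(pt),
      migWindow = switch(id, ISO = 0L, SECCONTACT = 2L, 1L),
      # secondary contact allows bidirectional-asymmetric flow in [0, TSC]
      fixed = fixedConstants()
    ), class = "ModelSpec")
  })
  stats::setNames(specs, MODEL_IDS)
}

#' Retrieve one model specification
#' @param modelId one of `ISO`, `SYM`, `ASYM`, `SON2CHI`, `CHI2SON`,
#'   `SECCONTACT`.
#' @return A `ModelSpec` list.
#' @export
getModel <- function(modelId) {
  modelId <- match.arg(modelId, MODEL_IDS)
  modelCatalog()[[modelId]]
}

#' Default prior specification for a model
#'
#' Effective sizes: log-uniform on 50,000-1,000,000 haploid individuals;
#' migration: log-uniform on 0.001-20 migrants per generation (converted to
#' per-lineage probabilities with the recipient deme's size); divergence
#' time: uniform on 500,000-1,000,000 years; secondary-contact time:
#' uniform on 0-21,000 years. Upper bounds are soft (optimization may
#' exceed them); lower bounds are hard.
#'
#' @param model a `ModelSpec` from [modelCatalog()].
#' @return data.frame with one row per free parameter (name, dist, lower,
#'   upper, soft).
#' @export
defaultPriors <- function(model) {
  pt <- paramTable(model$modelId)
  pt[, c("name", "dist", "lower", "upper", "soft")]
}

#' Build a concrete parameter vector for a model
#'
#' `...` supplies values for the model's free parameters (by name, on the
#' natural scale; migration as `M`, `MS`, `MC` in migrants per generation
#' or as `mS`, `mC` per-lineage probabilities). Parameters that are not in
#' the model raise an error.
#'
#' @param model a `ModelSpec`.
#' @param ... named parameter values.
#' @return A `ParameterVector` list with effective sizes, times, and
#'   backward per-lineage migration probabilities `mS`, `mC`.
#' @export
parameterVector <- function(model, ...) {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1]]) && is.null(names(vals)[1]))
    vals <- vals[[1]]
  pt <- paramTable(model$modelId)
  allowedDirect <- c(pt$name,
                     if ("M" %in% pt$name) "m",
                     if ("MS" %in% pt$name) "mS",
                     if ("MC" %in% pt$name) "mC")
  bad <- setdiff(names(vals), allowedDirect)
  if (length(bad))
    stop(sprintf("parameter(s) not in model %s: %s", model$modelId,
                 paste(bad, collapse = ", ")))
  need <- setdiff(pt$name, c("M", "MS", "MC"))
  missingPar <- setdiff(need, names(vals))
  if (length(missingPar))
    stop("missing parameter(s): ", paste(missingPar, collapse = ", "))

  p <- list(NeS = vals$NeS, NeC = vals$NeC, NeO = vals$NeO,
            NeD = vals$NeD, NeA = vals$NeA, TD = vals$TD)
  p$TSC <- if ("TSC" %in% pt$name) vals$TSC else 0
  # migration: per-lineage if given directly, else converted from migrants
  mS <- mC <- 0
  if ("M" %in% pt$name) {
    # symmetric migrant count M in both directions; each direction converts
    # with its recipient deme (backward C->S mirrors forward S->C into C)
    if (!is.null(vals$m)) mS <- mC <- vals$m
    else if (!is.null(vals$M)) { mS <- vals$M / p$NeC; mC <- vals$M / p$NeS }
    else stop("missing parameter(s): M")
  }
  if ("MS" %in% pt$name) {
    if (!is.null(vals$mS)) mS <- vals$mS
    else if (!is.null(vals$MS)) mS <- vals$MS / p$NeC
    else stop("missing parameter(s): MS")
  }
  if ("MC" %in% pt$name) {
    if (!is.null(vals$mC)) mC <- vals$mC
    else if (!is.null(vals$MC)) mC <- vals$MC / p$NeS
    else stop("missing parameter(s): MC")
  }
  p$mS <- mS
  p$mC <- mC
  validateParams(model, p)
  structure(p, class = "ParameterVector", modelId = model$modelId)
}

validateParams <- function(model, p) {
  TA <- model$fixed$TA
  sizes <- unlist(p[c("NeS", "NeC", "NeO", "NeD", "NeA")])
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("effective sizes must be positive")
  if (!(p$TD > 0 && p$TD < TA))
    stop("TD must lie in (0, TA)")
  if (p$TSC < 0 || p$TSC > p$TD)
    stop("TSC must lie in [0, TD]")
  if (p$mS < 0 || p$mS >= 1 || p$mC < 0 || p$mC >= 1)
    stop("per-lineage migration probabilities must lie in [0, 1)")
  invisible(TRUE)
}

#' Access one parameter of a ParameterVector
#'
#' Errors when the parameter is not part of the vector's model (e.g. any
#' migration rate under pure isolation).
#'
#' @param params a `ParameterVector`.
#' @param name parameter name.
#' @return The parameter value.
#' @export
getParam <- function(params, name) {
  modelId <- attr(params, "modelId")
  pt <- paramTable(modelId)
  allowed <- c(setdiff(pt$name, c("M", "MS", "MC")),
               if ("M" %in% pt$name) c("m", "mS", "mC"),
               if ("MS" %in% pt$name) "mS",
               if ("MC" %in% pt$name) "mC")
  if (!name %in% allowed)
    stop(sprintf("parameter '%s' is not in model %s", name, modelId))
  if (name == "m") return(params$mS)
  params[[name]]
}

#' Draw a parameter vector from the priors
#'
#' Log-uniform parameters satisfy `log(x) ~ Uniform(log lower, log upper)`;
#' uniform parameters are drawn on the natural scale. Reproducible under
#' the seed.
#'
#' @param model a `ModelSpec`.
#' @param prior data.frame as returned by [defaultPriors()].
#' @param seed integer seed.
#' @return A `ParameterVector`.
#' @export
drawParameters <- function(model, prior = defaultPriors(model), seed) {
  pt <- paramTable(model$modelId)
  missingPrior <- setdiff(pt$name, prior$name)
  if (length(missingPrior))
    stop("prior missing for free parameter(s): ",
         paste(missingPrior, collapse = ", "))
  withr::local_seed(seed)
  draws <- stats::setNames(numeric(nrow(pt)), pt$name)
  for (i in seq_len(nrow(pt))) {
    pr <- prior[prior$name == pt$name[i], ][1, ]
    draws[i] <- if (pr$dist == "log-uniform")
      exp(stats::runif(1, log(pr$lower), log(pr$upper)))
    else stats::runif(1, pr$lower, pr$upper)
  }
  if ("TSC" %in% names(draws)) draws["TSC"] <- min(draws["TSC"], draws["TD"])
  do.call(parameterVector, c(list(model), as.list(draws)))
}

# engine-facing parameterization
engineArgs <- function(model, params) {
  list(sizes = c(params$NeS, params$NeC, params$NeO, params$NeD, params$NeA),
       TD = params$TD, TA = model$fixed$TA,
       TSC = if (model$migWindow == 2L) params$TSC else 0,
       mS = params$mS, mC = params$mC,
       migWindow = model$migWindow)
}

#' Haploid sample configuration for the three demes
#'
#' @param nS,nC,nO haploid chromosomes sampled from the Sonoran,
#'   Chihuahuan and outgroup demes.
#' @return Integer vector of length 3.
#' @export
sampleConfig <- function(nS = 10L, nC = 10L, nO = 2L) {
  ns <- as.integer(c(nS, nC, nO))
  if (any(ns < 0L) || sum(ns) < 2L)
    stop("need at least two sampled chromosomes in total")
  ns
}
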