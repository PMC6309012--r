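#' Reported best-fit demographic parameters (bootstrap means)
#'
#' The asymmetric-migration parameter set used as the generating truth of
#' the synthetic genetic scenarios: haploid effective sizes
#' N_eS = 153,451, N_eC = 706,389, N_eO = 212,169, N_eD = 776,869,
#' N_eA = 181,138; divergence time T_D = 991,414 years; backward
#' per-lineage migration probabilities m_S = 1.18e-5 (Sonoran-to-
#' Chihuahuan forward) and m_C = 1.02e-5.
#'
#' @return A `ParameterVector` for the `ASYM` model.
#' @export
bestFitParameters <- function() {
  parameterVector(getModel("ASYM"),
                  NeS = 153451, NeC = 706389, NeO = 212169,
                  NeD = 776869, NeA = 181138,
                  TD = 991414, mS = 1.18e-5, mC = 1.02e-5)
}

#' Synthetic genotype scenario
#'
#' Defaults mirror the study conditions: the best-fit asymmetric-migration
#' parameters as truth, 54 Sonoran + 31 Chihuahuan + 3 outgroup-subspecies
#' diploids, 28,798 unlinked SNPs, and a 30% missing-call rate typical of
#' reduced-representation SNP matrices.
#'
#' @param modelId demographic model id.
#' @param params generating `ParameterVector` (default
#'   [bestFitParameters()] when the model is `ASYM`).
#' @param nIndividuals diploid individuals per population (SON, CHI, CAR).
#' @param nSnps number of unlinked SNPs.
#' @param missingRate i.i.d. missing-call probability.
#' @return A `GenotypeScenario` list.
#' @export
genotypeScenario <- function(modelId = "ASYM", params = NULL,
                             nIndividuals = c(SON = 54L, CHI = 31L, CAR = 3L),
                             nSnps = 28798L, missingRate = 0.3) {
  model <- getModel(modelId)
  if (is.null(params)) {
    if (modelId != "ASYM")
      stop("params must be supplied for models other than ASYM")
    params <- bestFitParameters()
  }
  stopifnot(nSnps >= 1, missingRate >= 0, missingRate < 1)
  structure(list(model = model, params = params,
                 nIndividuals = as.integer(nIndividuals),
                 nSnps = as.integer(nSnps), missingRate = missingRate),
            class = "GenotypeScenario")
}

#' Generate a synthetic genotype dataset (VCF + population map)
#'
#' Simulates the SNP matrix under the scenario's demographic model, adds a
#' synthetic outgroup individual fixed homozygous for the ancestral allele
#' (so polarization by outgroup consensus recovers the known derived
#' states), and writes a VCF, a two-column population map, and a metadata
#' file recording all generator parameters.
#'
#' @param scenario a [genotypeScenario()].
#' @param dir output directory (created if needed).
#' @param seed integer seed; identical seeds give byte-identical files.
#' @return List with the [GenotypeMatrix-class] (`gm`) and the `vcf`,
#'   `popmap` and `metadata` file paths.
#' @export
makeGenotypeDataset <- function(scenario, dir = tempfile("geno"), seed) {
  stopifnot(inherits(scenario, "GenotypeScenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm0 <- sampleSNPMatrix(scenario$model, scenario$params,
                         nInd = scenario$nIndividuals,
                         nSnps = scenario$nSnps,
                         missingRate = scenario$missingRate, seed = seed)
  # synthetic ancestral carrier: REF is the ancestral allele throughout
  calls <- cbind(gm0@calls, ANC_1 = 0L)
  ids <- c(gm0@individuals, "ANC_1")
  popOf <- c(gm0@popOf, ANC_1 = "OUTGROUP")
  gm <- GenotypeMatrix(calls, gm0@sites, ids, popOf,
                       metadata = c(gm0@metadata,
                                    list(syntheticOutgroup = "ANC_1")))
  vcfPath <- file.path(dir, "genotypes.vcf")
  popmapPath <- file.path(dir, "popmap.tsv")
  metaPath <- file.path(dir, "metadata.tsv")
  writeGenotypesVCF(gm, vcfPath)
  writeLines(paste(ids, popOf[ids], sep = "\t"), popmapPath)
  meta <- c(modelId = scenario$model$modelId,
            unlist(scenario$params),
            nSnps = scenario$nSnps,
            missingRate = scenario$missingRate, seed = seed)
  writeLines(paste(names(meta), meta, sep = "\t"), metaPath)
  list(gm = gm, vcf = vcfPath, popmap = popmapPath, metadata = metaPath)
}

#' Write a GenotypeMatrix as a minimal VCFv4.2 file
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(gm, path) {
  gtStr <- c("0/0", "0/1", "1/1")
  gtOf <- function(v) ifelse(is.na(v), "./.", gtStr[v + 1L])
  body <- apply(gm@calls, 1, gtOf)
  body <- if (is.matrix(body)) t(body) else matrix(body, ncol = 1)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=desertSong",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm@individuals), collapse = "\t"),
    paste(gm@sites$chrom, gm@sites$pos, gm@sites$locus_id,
          gm@sites$ref, gm@sites$alt, ".", "PASS", ".", "GT",
          apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic playback scenario
#'
#' Defaults mirror the field design: 67 Sonoran and 61 Chihuahuan sites
#' with four playbacks each (one per treatment), 6 stimulus sets per song
#' treatment and a single control recording, and 16 Sonoran / 25
#' Chihuahuan sites without a detected male. Treatment effects default to
#' a strong local-song response with near-zero responses to distant,
#' across-barrier and control stimuli; random-effect and residual scales
#' sit near the magnitudes of the field mixed-model fits.
#'
#' @param nSites named sites per desert.
#' @param treatmentEffects latent aggression shift per treatment.
#' @param preEffect slope of the response latent on the pre-trial latent.
#' @param siteSd,stimulusSd,residualSd random-effect and residual SDs of
#'   the latent aggression.
#' @param nStimulusSets stimulus sets per treatment.
#' @param nUndetected exact undetected site counts per desert (used when
#'   `detectionRate` is NULL).
#' @param detectionRate alternative i.i.d. per-site detection probability.
#' @param measureLoadings slopes of the five measures on the latent.
#' @param measureBase baseline of each measure at latent 0.
#' @param measureNoise measure-level noise SDs.
#' @param nSeries distance-series samples per 3-minute period (10-s
#'   sampling).
#' @return A `PlaybackScenario` list.
#' @export
playbackScenario <- function(
    nSites = c(SON = 67L, CHI = 61L),
    treatmentEffects = c(CONTROL = 0, ACROSS = 0.1, DISTANT = 0.25,
                         LOCAL = 2.0),
    preEffect = 0.4,
    siteSd = 0.2, stimulusSd = 0.3, residualSd = 0.6,
    nStimulusSets = c(CONTROL = 1L, ACROSS = 6L, DISTANT = 6L, LOCAL = 6L),
    nUndetected = c(SON = 16L, CHI = 25L),
    detectionRate = NULL,
    measureLoadings = c(flybys = 1.2, calls_present = 1.1,
                        close_songs = 1.8, far_songs = -0.7,
                        mean_distance = -5),
    measureBase = c(flybys = 1.5, calls_present = 0.2, close_songs = 2.5,
                    far_songs = 2, mean_distance = 13),
    measureNoise = c(flybys = 2, calls_present = 1.4, close_songs = 2.6,
                     far_songs = 1.8, mean_distance = 9),
    nSeries = 18L) {
  stopifnot(all(nSites >= 1), all(c(siteSd, stimulusSd, residualSd) >= 0))
  if (!is.null(detectionRate))
    stopifnot(detectionRate > 0, detectionRate <= 1)
  structure(list(nSites = nSites, treatmentEffects = treatmentEffects,
                 preEffect = preEffect, siteSd = siteSd,
                 stimulusSd = stimulusSd, residualSd = residualSd,
                 nStimulusSets = nStimulusSets, nUndetected = nUndetected,
                 detectionRate = detectionRate,
                 measureLoadings = measureLoadings,
                 measureBase = measureBase, measureNoise = measureNoise,
                 nSeries = as.integer(nSeries)),
            class = "PlaybackScenario")
}

# latent aggression -> one period's raw measures
latentToMeasures <- function(a, sc) {
  L <- sc$measureLoadings
  B <- sc$measureBase
  S <- sc$measureNoise
  n <- length(a)
  flybys <- pmax(0, round(B["flybys"] + L["flybys"] * a +
                            stats::rnorm(n, 0, S["flybys"])))
  # probit-style threshold: deterministic when the call noise is zero
  calls <- as.integer(B["calls_present"] + L["calls_present"] * a +
                        stats::rnorm(n, 0, S["calls_present"]) > 0.5)
  close <- pmax(0, round(B["close_songs"] + L["close_songs"] * a +
                           stats::rnorm(n, 0, S["close_songs"])))
  far <- pmax(0, round(B["far_songs"] + L["far_songs"] * a +
                         stats::rnorm(n, 0, S["far_songs"])))
  # distance every 10 s: monotone map of the latent with Gaussian jitter,
  # clamped to the field distance bins
  thresholds <- c(1, 2, 4, 8, 16, 24)
  series <- vapply(seq_len(n), function(i) {
    d <- B["mean_distance"] + L["mean_distance"] * a[i] +
      stats::rnorm(sc$nSeries, 0, S["mean_distance"])
    bins <- DISTANCE_BINS[findInterval(pmax(d, 0), thresholds) + 1L]
    paste(bins, collapse = ";")
  }, character(1))
  closest <- vapply(strsplit(series, ";", fixed = TRUE), function(b)
    b[which.min(binMidpoint(b))], character(1))
  data.frame(flybys = as.numeric(flybys), calls_present = calls,
             close_songs = as.numeric(close), far_songs = as.numeric(far),
             distance_series = series, closest_distance = closest,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic playback trial table
#'
#' One trial per site x treatment, each with Pre-Playback, Playback and
#' Post-Playback period rows. The latent response aggression is
#' `treatment effect + preEffect x pre-trial latent + site effect +
#' stimulus-set effect + residual`; the five raw measures are monotone
#' noisy maps of the latent (counts floored at zero, the distance series
#' binned into the field distance bins). Sites without a detected male
#' keep their rows with missing measures.
#'
#' @param scenario a [playbackScenario()].
#' @param seed integer seed.
#' @return Trial table data.frame (one row per site x treatment x
#'   period) with attributes `nTrials` (all trials) and
#'   `nDetectedTrials`.
#' @export
makePlaybackDataset <- function(scenario, seed) {
  stopifnot(inherits(scenario, "PlaybackScenario"))
  sc <- scenario
  withr::local_seed(seed)
  rows <- list()
  for (desert in names(sc$nSites)) {
    n <- sc$nSites[[desert]]
    siteIds <- sprintf("%s_S%03d", desert, seq_len(n))
    siteEff <- stats::rnorm(n, 0, sc$siteSd)
    undet <- if (!is.null(sc$detectionRate))
      siteIds[stats::runif(n) > sc$detectionRate]
    else siteIds[sample.int(n, min(sc$nUndetected[[desert]], n))]
    stimEff <- list()
    for (tr in TREATMENTS) {
      k <- sc$nStimulusSets[[tr]]
      stimEff[[tr]] <- stats::setNames(stats::rnorm(k, 0, sc$stimulusSd),
                                       sprintf("%s_%s_%d", desert, tr,
                                               seq_len(k)))
    }
    for (i in seq_len(n)) {
      for (tr in TREATMENTS) {
        stimId <- sample(names(stimEff[[tr]]), 1)
        preLatent <- stats::rnorm(1)
        a <- sc$treatmentEffects[[tr]] + sc$preEffect * preLatent +
          siteEff[i] + stimEff[[tr]][[stimId]] +
          stats::rnorm(1, 0, sc$residualSd)
        detected <- !(siteIds[i] %in% undet)
        for (period in PERIODS) {
          lat <- if (period == "PRE") preLatent else a
          meas <- if (detected) latentToMeasures(lat, sc) else
            data.frame(flybys = NA_real_, calls_present = NA_integer_,
                       close_songs = NA_real_, far_songs = NA_real_,
                       distance_series = NA_character_,
                       closest_distance = NA_character_,
                       stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(site_id = siteIds[i], desert = desert,
                       treatment = tr, stimulus_set_id = stimId,
                       period = period, stringsAsFactors = FALSE),
            meas)
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  trials <- unique(out[, c("site_id", "treatment")])
  detectedTrials <- unique(out[!is.na(out$flybys),
                               c("site_id", "treatment")])
  attr(out, "nTrials") <- nrow(trials)
  attr(out, "nDetectedTrials") <- nrow(detectedTrials)
  attr(out, "seed") <- seed
  out
}

#' Refit harness at the reported best-fit operating point
#'
#' For each of `nSeeds` replicates: simulate an observed unfolded joint
#' SFS of `nSnps` segregating sites under the asymmetric-migration model
#' at the best-fit parameters (haploid samples 10 x 10 x 2 by default),
#' refit the same model with the default priors, and collect the
#' estimates. The divergence-time and Chihuahuan-size columns are the
#' recovery targets.
#'
#' @param nSeeds number of independent simulate-and-refit replicates.
#' @param seed base integer seed.
#' @param nSnps segregating sites per simulated spectrum.
#' @param config haploid [sampleConfig()].
#' @param settings refit [fitSettings()].
#' @param truth generating `ParameterVector` (default
#'   [bestFitParameters()]).
#' @param simReps genealogies behind each simulated spectrum.
#' @return data.frame with one row per seed: estimates of all model
#'   parameters plus `loglik`.
#' @export
refitHarness <- function(nSeeds = 10L, seed, nSnps = 20000L,
                         config = sampleConfig(), settings = fitSettings(),
                         truth = bestFitParameters(), simReps = 30000L) {
  model <- getModel(attr(truth, "modelId"))
  rows <- lapply(seq_len(nSeeds), function(i) {
    obs <- simulateSFS(model, truth, config, nSnps,
                       seed = deriveSeed(seed, 31 * i), nReps = simReps)
    fit <- fitModel(obs, model, settings = settings,
                    seed = deriveSeed(seed, 77 * i))
    data.frame(seedIndex = i, NeS = fit$mle$NeS, NeC = fit$mle$NeC,
               NeO = fit$mle$NeO, NeD = fit$mle$NeD, NeA = fit$mle$NeA,
               TD = fit$mle$TD, mS = fit$mle$mS, mC = fit$mle$mC,
               loglik = fit$loglik)
  })
  do.call(rbind, rows)
}
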