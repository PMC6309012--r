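TREATMENTS <- c("CONTROL", "ACROSS", "DISTANT", "LOCAL")
PERIODS <- c("PRE", "PLAYBACK", "POST")
DISTANCE_BINS <- c("0-1", "1-2", "2-4", "4-8", "8-16", "16-24", ">24")
BIN_MIDPOINTS <- c("0-1" = 0.5, "1-2" = 1.5, "2-4" = 3, "4-8" = 6,
                   "8-16" = 12, "16-24" = 20, ">24" = 28)

normalizeBins <- function(x) gsub("–", "-", x)

binMidpoint <- function(labels, over24 = 28) {
  labels <- normalizeBins(labels)
  mids <- BIN_MIDPOINTS
  mids[">24"] <- over24
  bad <- setdiff(unique(labels), names(mids))
  if (length(bad))
    stop("unknown distance bin label(s): ", paste(bad, collapse = ", "))
  unname(mids[labels])
}

#' Reduce raw playback measures to the five-measure aggression vector
#'
#' Pools the Playback and Post-Playback periods into a single Response
#' period per site x treatment (counts summed, alarm calls OR-ed, distance
#' series concatenated) and reduces each period to the vector
#' (flybys, calls_present, close_songs, far_songs, mean_distance), where
#' the distance series maps to bin midpoints (0.5, 1.5, 3, 6, 12, 20 m;
#' the open `>24` bin is coded `over24`, default 28 m). The closest
#' distance bin is retained for reporting. Rows for undetected sites
#' (missing measures) are dropped and counted.
#'
#' @param trials trial table: one row per site x treatment x period with
#'   columns `site_id`, `desert`, `treatment`, `stimulus_set_id`,
#'   `period`, `flybys`, `calls_present`, `close_songs`, `far_songs`,
#'   `distance_series` (semicolon-joined bin labels), `closest_distance`.
#' @param over24 numeric midpoint code for the open `>24` m bin.
#' @return data.frame with one row per site x treatment x period
#'   (`PRE`, `RESPONSE`) carrying the five measures; attribute
#'   `nUndetectedTrials` counts dropped trials.
#' @export
reduceMeasures <- function(trials, over24 = 28) {
  trials$period <- toupper(trials$period)
  detected <- !is.na(trials$flybys)
  undetectedTrials <- unique(trials[!detected, c("site_id", "treatment")])
  trials <- trials[detected, , drop = FALSE]
  if (!nrow(trials)) stop("no detected trials")
  trials$respPeriod <- ifelse(trials$period == "PRE", "PRE", "RESPONSE")
  key <- interaction(trials$site_id, trials$treatment, trials$respPeriod,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(i) {
    tr <- trials[i, , drop = FALSE]
    series <- unlist(strsplit(paste(tr$distance_series, collapse = ";"),
                              ";", fixed = TRUE))
    series <- series[nzchar(series)]
    if (!length(series)) stop("empty distance series for an observed male")
    mids <- binMidpoint(series, over24)
    closest <- c(as.character(tr$closest_distance), series)
    closest <- normalizeBins(closest[!is.na(closest)])
    closest <- closest[which.min(binMidpoint(closest, over24))]
    data.frame(
      site_id = tr$site_id[1], desert = tr$desert[1],
      treatment = tr$treatment[1],
      stimulus_set_id = tr$stimulus_set_id[1],
      period = tr$respPeriod[1],
      flybys = sum(tr$flybys),
      calls_present = as.integer(any(tr$calls_present > 0)),
      close_songs = sum(tr$close_songs),
      far_songs = sum(tr$far_songs),
      mean_distance = mean(mids),
      closest_distance = closest,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "nUndetectedTrials") <- nrow(undetectedTrials)
  out
}

MEASURES <- c("flybys", "calls_present", "close_songs", "far_songs",
              "mean_distance")

#' Composite aggression score via PCA on the Response period
#'
#' Principal components are computed on the correlation matrix of the
#' Response-period five-measure vectors (measures mix counts, a flag and
#' meters, so each is standardized). PC1 scores the per-trial composite;
#' the Pre-Playback vectors are standardized with the Response means and
#' scales and projected onto the same loadings ("pre-treatment
#' aggression"). The raw PC1 orientation is preserved;
#' `orientationSign` is the sign of the correlation between PC1 and
#' negated mean distance (+1 means larger PC1 = more aggressive).
#' Zero-variance measures are dropped with a warning and their loadings
#' padded with 0.
#'
#' @param responseVectors matrix/data.frame of Response-period measures
#'   (>= 6 rows, columns in the order flybys, calls_present, close_songs,
#'   far_songs, mean_distance).
#' @param preVectors matching Pre-Playback measures (same columns).
#' @return An `AggressionScore` list: `loadings` (unit 5-vector), `pc1`,
#'   `preScore`, `varExplained`, `orientationSign`, `center`, `scale`.
#' @export
aggressionPCA <- function(responseVectors, preVectors) {
  resp <- as.matrix(responseVectors[, MEASURES, drop = FALSE])
  pre <- as.matrix(preVectors[, MEASURES, drop = FALSE])
  if (nrow(resp) < 6) stop("need at least six response vectors")
  ctr <- colMeans(resp)
  scl <- apply(resp, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("zero-variance measure(s) dropped: ",
            paste(MEASURES[!keep], collapse = ", "))
  }
  z <- scale(resp[, keep, drop = FALSE], center = ctr[keep],
             scale = scl[keep])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1]
  loadings <- stats::setNames(numeric(length(MEASURES)), MEASURES)
  loadings[keep] <- rot
  pc1 <- as.vector(z %*% rot)
  zPre <- scale(pre[, keep, drop = FALSE], center = ctr[keep],
                scale = scl[keep])
  preScore <- as.vector(zPre %*% rot)
  structure(list(
    loadings = loadings,
    pc1 = pc1,
    preScore = preScore,
    varExplained = pc$sdev[1]^2 / length(MEASURES),
    orientationSign = sign(stats::cor(pc1, -resp[, "mean_distance"])),
    center = ctr, scale = scl
  ), class = "AggressionScore")
}

#' Score a reduced trial table
#'
#' Convenience wrapper pairing the Response and Pre rows of
#' [reduceMeasures()] output and running [aggressionPCA()].
#'
#' @param reduced output of [reduceMeasures()].
#' @return data.frame of per-trial scores (site_id, desert, treatment,
#'   stimulus_set_id, pc1, pre_score) with the `AggressionScore` in
#'   attribute `score`.
#' @export
scoreAggression <- function(reduced) {
  respRows <- reduced[reduced$period == "RESPONSE", , drop = FALSE]
  preRows <- reduced[reduced$period == "PRE", , drop = FALSE]
  key <- function(d) paste(d$site_id, d$treatment, sep = "\r")
  m <- match(key(respRows), key(preRows))
  if (anyNA(m)) stop("response trial without a matching pre-playback row")
  preRows <- preRows[m, , drop = FALSE]
  sc <- aggressionPCA(respRows[, MEASURES], preRows[, MEASURES])
  out <- data.frame(
    site_id = respRows$site_id, desert = respRows$desert,
    treatment = respRows$treatment,
    stimulus_set_id = respRows$stimulus_set_id,
    pc1 = sc$pc1, pre_score = sc$preScore,
    stringsAsFactors = FALSE
  )
  attr(out, "score") <- sc
  out
}

aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) stop("too few trials for the AICc correction")
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Treatment-effect comparison with linear mixed models under AICc
#'
#' Fits, by full maximum likelihood, the null model
#' `pc1 ~ pre_score + (1|stimulus_set) + (1|site)` and the full model
#' adding `treatment`, compares them by AICc
#' (`AIC + 2k(k+1)/(n-k-1)`, k counting fixed effects, variance
#' components and the residual), and reports Wald chi-square tests for
#' the treatment factor (3 df) and the pre-treatment slope (1 df) plus
#' all six pairwise treatment contrasts (Wald z, no multiplicity
#' correction).
#'
#' @param scores data.frame with columns `pc1`, `pre_score`,
#'   `treatment`, `site_id`, `stimulus_set_id` (all four treatments, >= 2
#'   sites and >= 2 stimulus sets).
#' @return A `BehaviorComparison` list: `aiccNull`, `aiccFull`,
#'   `deltaAicc` (= null - full, positive favors the full model), `wald`
#'   data.frame, `contrasts` data.frame, `varcomp` (site, stimulus set,
#'   residual variances of the full model), and the fitted models.
#' @export
compareModels <- function(scores) {
  need <- c("pc1", "pre_score", "treatment", "site_id", "stimulus_set_id")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("scores lacks column(s): ",
                         paste(miss, collapse = ", "))
  scores$treatment <- factor(scores$treatment, levels = TREATMENTS)
  if (anyNA(scores$treatment) || nlevels(droplevels(scores$treatment)) < 4)
    stop("all four treatments must be present")
  if (length(unique(scores$site_id)) < 2) stop("need >= 2 sites")
  if (length(unique(scores$stimulus_set_id)) < 2)
    stop("need >= 2 stimulus sets")

  fitOne <- function(formula, label) {
    tryCatch(
      lme4::lmer(formula, data = scores, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) stop(sprintf("%s model failed to converge: %s",
                                       label, conditionMessage(e)),
                               call. = FALSE))
  }
  null <- fitOne(pc1 ~ pre_score + (1 | stimulus_set_id) + (1 | site_id),
                 "null")
  full <- fitOne(pc1 ~ treatment + pre_score +
                   (1 | stimulus_set_id) + (1 | site_id), "full")

  aiccNull <- aicc(null)
  aiccFull <- aicc(full)

  beta <- lme4::fixef(full)
  V <- as.matrix(stats::vcov(full))
  treatCoefs <- grep("^treatment", names(beta))
  bT <- beta[treatCoefs]
  xT <- as.numeric(t(bT) %*% solve(V[treatCoefs, treatCoefs]) %*% bT)
  zPre <- beta[["pre_score"]] / sqrt(V["pre_score", "pre_score"])
  wald <- data.frame(
    effect = c("treatment", "pre_score"),
    statistic = c(xT, zPre^2),
    df = c(length(treatCoefs), 1),
    p = c(stats::pchisq(xT, length(treatCoefs), lower.tail = FALSE),
          stats::pchisq(zPre^2, 1, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )

  # all pairwise treatment contrasts; CONTROL is the reference level
  lev <- TREATMENTS
  coefOf <- function(l) if (l == lev[1]) 0 else beta[[paste0("treatment", l)]]
  rowOf <- function(l) {
    v <- numeric(length(beta))
    names(v) <- names(beta)
    if (l != lev[1]) v[paste0("treatment", l)] <- 1
    v
  }
  pairs <- utils::combn(lev, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    L <- rowOf(b) - rowOf(a)
    est <- coefOf(b) - coefOf(a)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    z <- est / se
    data.frame(pair = paste(b, "vs", a), estimate = est, se = se,
               z = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))

  vc <- as.data.frame(lme4::VarCorr(full))
  getvc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else NA_real_
  }
  structure(list(
    aiccNull = aiccNull, aiccFull = aiccFull,
    deltaAicc = aiccNull - aiccFull,
    wald = wald, contrasts = contrasts,
    varcomp = c(site = getvc("site_id"),
                stimulus_set = getvc("stimulus_set_id"),
                residual = getvc("Residual")),
    nullModel = null, fullModel = full
  ), class = "BehaviorComparison")
}

#' @export
print.BehaviorComparison <- function(x, ...) {
  cat(sprintf("BehaviorComparison: AICc null %.2f, full %.2f (delta %.2f)\n",
              x$aiccNull, x$aiccFull, x$deltaAicc))
  print(x$wald, digits = 4)
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Territory radius from a circular territory area
#'
#' `r = sqrt(area x 10000 / pi)`, reported to 0.1 m.
#'
#' @param areaHectares territory area in hectares (> 0).
#' @return Radius in meters, rounded to 0.1 m.
#' @export
territoryRadius <- function(areaHectares) {
  if (any(areaHectares <= 0)) stop("territory area must be positive")
  round(sqrt(areaHectares * 1e4 / pi), 1)
}
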