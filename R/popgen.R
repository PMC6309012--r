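#' Nei's G_ST and Hedrick's G'_ST from SNP genotypes
#'
#' Per biallelic locus: allele frequencies are computed per population from
#' the called genotypes; `H_S` is the unweighted mean across populations of
#' the expected heterozygosity `2p(1-p)`; `H_T` is `2p(1-p)` at the
#' unweighted mean frequency; `G_ST = (H_T - H_S)/H_T` (0 when `H_T = 0`)
#' and `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))` standardizes by
#' the maximum attainable given within-population diversity. Multilocus
#' values use the means of `H_T` and `H_S` over retained loci. Loci with a
#' population entirely missing are skipped and counted.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param pops population labels to compare (default: the non-outgroup
#'   labels present).
#' @param weighted if TRUE, population frequencies are averaged weighted
#'   by called chromosomes instead of unweighted.
#' @return A `DifferentiationResult` list: `perLocus` data.frame
#'   (locus_id, H_S, H_T, G_ST, Gp_ST), `multilocus` (H_S, H_T, G_ST,
#'   Gp_ST), `k`, `nSkipped`.
#' @export
differentiation <- function(gm, pops = NULL, weighted = FALSE) {
  labels <- gm@popOf[gm@individuals]
  if (is.null(pops))
    pops <- intersect(c("SON", "CHI", "CAR"), unique(labels))
  if (length(pops) < 2) stop("need at least two populations")
  k <- length(pops)
  idx <- lapply(pops, function(p) which(labels == p))

  nLoci <- nrow(gm@calls)
  freq <- nchrom <- matrix(NA_real_, nLoci, k)
  for (j in seq_len(k)) {
    sub <- gm@calls[, idx[[j]], drop = FALSE]
    called <- rowSums(!is.na(sub))
    nchrom[, j] <- 2 * called
    freq[, j] <- ifelse(called > 0, rowSums(sub, na.rm = TRUE) / (2 * called),
                        NA_real_)
  }
  ok <- rowSums(nchrom > 0) == k
  nSkipped <- sum(!ok)
  if (!any(ok)) stop("no locus has calls in every population")
  f <- freq[ok, , drop = FALSE]
  w <- nchrom[ok, , drop = FALSE]

  HS <- rowMeans(2 * f * (1 - f))
  pbar <- if (weighted) rowSums(f * w) / rowSums(w) else rowMeans(f)
  HT <- 2 * pbar * (1 - pbar)
  GST <- ifelse(HT > 0, (HT - HS) / HT, 0)
  GpST <- ifelse(HS < 1,
                 GST * (k - 1 + HS) / ((k - 1) * (1 - HS)),
                 GST)
  mHS <- mean(HS)
  mHT <- mean(HT)
  mG <- if (mHT > 0) (mHT - mHS) / mHT else 0
  mGp <- if (mHS < 1) mG * (k - 1 + mHS) / ((k - 1) * (1 - mHS)) else mG
  structure(list(
    perLocus = data.frame(locus_id = gm@sites$locus_id[ok],
                          H_S = HS, H_T = HT, G_ST = GST, Gp_ST = GpST,
                          stringsAsFactors = FALSE),
    multilocus = list(H_S = mHS, H_T = mHT, G_ST = mG, Gp_ST = mGp),
    k = k, nSkipped = nSkipped
  ), class = "DifferentiationResult")
}

#' @export
print.DifferentiationResult <- function(x, ...) {
  cat(sprintf("DifferentiationResult over %d loci (%d skipped), k = %d\n",
              nrow(x$perLocus), x$nSkipped, x$k))
  cat(sprintf("  multilocus G_ST = %.4f, G'_ST = %.4f\n",
              x$multilocus$G_ST, x$multilocus$Gp_ST))
  invisible(x)
}

#' Evanno delta-K from a table of clustering log-likelihoods
#'
#' For each interior K of a consecutive span,
#' `deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd L(K)` where
#' the standard deviation is across replicate runs at K. Endpoint K values
#' have no second difference and are absent from the output.
#'
#' @param table data.frame with columns `K`, `replicate`, `loglik`
#'   (at least two replicates per K).
#' @return data.frame (K, deltaK), possibly empty when no interior K
#'   exists.
#' @export
evannoDeltaK <- function(table) {
  need <- c("K", "loglik")
  if (!all(need %in% names(table)))
    stop("table needs columns K, replicate, loglik")
  ks <- sort(unique(table$K))
  mu <- vapply(ks, function(k) mean(table$loglik[table$K == k]), numeric(1))
  sdv <- vapply(ks, function(k) stats::sd(table$loglik[table$K == k]),
                numeric(1))
  nrep <- vapply(ks, function(k) sum(table$K == k), numeric(1))
  interior <- which(ks %in% intersect(ks - 1, ks + 1) &
                    (ks - 1) %in% ks & (ks + 1) %in% ks)
  if (!length(interior))
    return(data.frame(K = integer(0), deltaK = numeric(0)))
  if (any(nrep[interior] < 2))
    stop("need at least two replicates per interior K")
  out <- data.frame(K = ks[interior], deltaK = NA_real_)
  for (r in seq_along(interior)) {
    i <- interior[r]
    if (is.na(sdv[i]) || sdv[i] == 0)
      stop(sprintf("zero replicate standard deviation at K = %d", ks[i]))
    out$deltaK[r] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
  }
  out
}
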