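# Small in-code fixtures shared across tests.

# write a minimal VCF with the given GT body (list of rows)
writeTestVCF <- function(path, fix, gtRows, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_along(gtRows), function(i)
      paste(c(fix[[i]], "GT", gtRows[[i]]), collapse = "\t"), character(1))
  )
  writeLines(lines, path)
  path
}

# three-sample, one-outgroup GenotypeMatrix built directly
smallGenotypeMatrix <- function(calls, ref = "A", alt = "G") {
  n <- nrow(calls)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n),
                      locus_id = sprintf("L%03d", seq_len(n)),
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  ids <- colnames(calls)
  pops <- attr(calls, "pops")
  GenotypeMatrix(calls, sites, ids, stats::setNames(pops, ids))
}

# genotype calls with population attribution for differentiation tests:
# `freqs` is a loci x pops matrix of allele frequencies; each population
# gets `nDip` diploids with deterministic genotype counts approximating
# the frequency exactly (2*nDip*freq must be integral).
callsFromFreqs <- function(freqs, nDip, popLabels = c("SON", "CHI")) {
  k <- ncol(freqs)
  calls <- NULL
  for (j in seq_len(k)) {
    cnt <- round(2 * nDip * freqs[, j])
    block <- t(vapply(cnt, function(cc) {
      g <- integer(nDip)
      full <- cc %/% 2
      if (full > 0) g[seq_len(full)] <- 2L
      if (cc %% 2 == 1) g[full + 1] <- 1L
      g
    }, integer(nDip)))
    calls <- cbind(calls, block)
  }
  ids <- paste0(rep(popLabels, each = nDip), "_", rep(seq_len(nDip), k))
  colnames(calls) <- ids
  attr(calls, "pops") <- rep(popLabels, each = nDip)
  calls
}

# small ISO parameter set that coalesces quickly (for engine tests)
quickIsoParams <- function(NeS = 60000, NeC = 60000, NeO = 60000) {
  parameterVector(getModel("ISO"), NeS = NeS, NeC = NeC, NeO = NeO,
                  NeD = 60000, NeA = 60000, TD = 6e5)
}
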