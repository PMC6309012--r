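#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (v4.x) with vcfR, keeps biallelic SNP records, and encodes
#' diploid GT fields as alternate-allele counts. Multi-allelic records are
#' skipped and counted in the result's metadata (`nMultiallelicSkipped`).
#'
#' @param vcfPath path to an uncompressed or gzipped VCF with GT fields.
#' @param popmap sample-to-population map: a named character vector, a
#'   two-column data.frame (sample_id, population), or the path of a
#'   two-column delimited text file.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(vcfPath, popmap) {
  popOf <- resolvePopmap(popmap)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- vcf@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF records lack a GT field")
  samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(samples, names(popOf))
  if (length(unknown))
    stop("sample(s) absent from population map: ",
         paste(unknown, collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, samples))

  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- nchar(ref) == 1L & nchar(gsub(",.*", "", alt)) == 1L
  keep <- !multi & snp
  nSkipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in ", vcfPath)

  calls <- encodeGT(gt[keep, , drop = FALSE])
  sites <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    locus_id = if ("ID" %in% colnames(fix) && !all(is.na(fix[keep, "ID"])))
      fix[keep, "ID"] else paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    stringsAsFactors = FALSE
  )
  GenotypeMatrix(calls, sites, samples, popOf,
                 metadata = list(nMultiallelicSkipped = nSkipped))
}

# GT strings ("0/1", "1|1", "./.", ...) -> integer alt-allele counts
encodeGT <- function(gt) {
  al1 <- substr(gt, 1, 1)
  al2 <- substr(gt, 3, 3)
  hap <- nchar(gt) == 1L & !is.na(gt)   # haploid calls tolerated, counted once
  al2[hap] <- al1[hap]
  miss <- is.na(gt) | al1 == "." | al2 == "."
  out <- suppressWarnings(as.integer(al1) + as.integer(al2))
  out[miss] <- NA_integer_
  matrix(out, nrow = nrow(gt), dimnames = NULL)
}

resolvePopmap <- function(popmap) {
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap)) {
    tab <- utils::read.table(popmap, header = FALSE, stringsAsFactors = FALSE)
    popmap <- stats::setNames(tab[[2]], tab[[1]])
  } else if (is.data.frame(popmap)) {
    popmap <- stats::setNames(as.character(popmap[[2]]),
                              as.character(popmap[[1]]))
  }
  if (is.null(names(popmap)))
    stop("popmap must map sample IDs to population labels")
  popmap
}

#' Thin to one SNP per locus
#'
#' Retains exactly one site per `locus_id`, chosen uniformly at random under
#' the given seed, so linked SNPs from the same assembled locus do not enter
#' the SFS twice. Deterministic given the seed; the seed is recorded in the
#' result metadata.
#'
#' @param gm A [GenotypeMatrix-class] with `locus_id` populated.
#' @param seed integer seed.
#' @return A thinned [GenotypeMatrix-class].
#' @export
thinToUnlinked <- function(gm, seed) {
  withr::local_seed(seed)
  loci <- gm@sites$locus_id
  idx <- unlist(lapply(split(seq_along(loci), loci), function(i) {
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
  }), use.names = FALSE)
  idx <- sort(idx)
  md <- gm@metadata
  md$thinSeed <- seed
  GenotypeMatrix(gm@calls[idx, , drop = FALSE],
                 gm@sites[idx, , drop = FALSE],
                 gm@individuals, gm@popOf, md)
}

#' Polarize sites to derived-allele counts using an outgroup consensus
#'
#' The ancestral allele at each site is the allele carried homozygously by
#' the outgroup consensus. Sites whose outgroup calls are heterozygous,
#' polymorphic across outgroup individuals, or entirely missing are dropped
#' (counted in `nDropped`).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param outgroupIds individual IDs to use as outgroup; defaults to all
#'   individuals labelled `OUTGROUP`.
#' @param pops ingroup population labels, in SFS axis order.
#' @return A list with matrices `derived` and `observed` (sites x
#'   populations, observed in chromosomes), `pops`, the retained `sites`
#'   data.frame, and `nDropped`.
#' @export
polarizeSites <- function(gm, outgroupIds = NULL,
                          pops = c("SON", "CHI", "CAR")) {
  if (is.null(outgroupIds))
    outgroupIds <- gm@individuals[gm@popOf[gm@individuals] == "OUTGROUP"]
  if (!length(outgroupIds)) stop("at least one outgroup individual required")
  ogIdx <- match(outgroupIds, gm@individuals)
  if (anyNA(ogIdx)) stop("unknown outgroup individual")
  og <- gm@calls[, ogIdx, drop = FALSE]

  # consensus: all called outgroup genotypes homozygous for the same allele
  anc <- apply(og, 1, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_integer_)
    if (all(g == 0L)) return(0L)
    if (all(g == 2L)) return(2L)
    NA_integer_
  })
  keep <- !is.na(anc)
  nDropped <- sum(!keep)
  if (!any(keep)) stop("no polarizable sites")

  popIdxs <- lapply(pops, function(p)
    which(gm@popOf[gm@individuals] == p))
  calls <- gm@calls[keep, , drop = FALSE]
  ancK <- anc[keep]
  derived <- observed <- matrix(0L, nrow = sum(keep), ncol = length(pops),
                                dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    sub <- calls[, popIdxs[[j]], drop = FALSE]
    nCalled <- rowSums(!is.na(sub))
    altCount <- rowSums(sub, na.rm = TRUE)
    observed[, j] <- 2L * nCalled
    # ancestral = ref (anc 0): derived = alt count; ancestral = alt: flipped
    derived[, j] <- ifelse(ancK == 0L, altCount, 2L * nCalled - altCount)
  }
  list(derived = derived, observed = observed, pops = pops,
       sites = gm@sites[keep, , drop = FALSE], nDropped = nDropped)
}

#' Hypergeometric projection of one site to a smaller sample
#'
#' Averages over all ways of drawing `m` chromosomes without replacement
#' from the `n` observed, of which `d` carry the derived allele. Entry
#' `j + 1` of the result is the probability that the subsample contains `j`
#' derived copies. When fewer chromosomes were observed than the target
#' (`n < m`) the site contributes nothing and a zero vector is returned.
#'
#' @param d derived-allele count at the site (0 <= d <= n).
#' @param n observed chromosomes at the site.
#' @param m target (projected) chromosome count, >= 1.
#' @return Numeric vector of length `m + 1` summing to 1 (or all zero when
#'   `n < m`).
#' @export
projectSite <- function(d, n, m) {
  if (d > n) stop("derived count d exceeds observed chromosomes n")
  if (m < 1) stop("target size m must be >= 1")
  if (n < m) return(numeric(m + 1))
  stats::dhyper(0:m, d, n - d, m)
}

#' Projection specification
#'
#' @param targetSizes integer haploid target sizes (m1, m2, m3).
#' @param diploidUnits if TRUE, `targetSizes` are diploid individuals and
#'   are doubled to chromosome counts (the spectrum then has shape
#'   `2*targetSizes + 1`).
#' @return A list with class `ProjectionSpec`.
#' @export
projectionSpec <- function(targetSizes = c(10L, 10L, 2L),
                           diploidUnits = FALSE) {
  targetSizes <- as.integer(targetSizes)
  if (any(targetSizes < 1L)) stop("target sizes must be positive")
  if (diploidUnits) targetSizes <- 2L * targetSizes
  structure(list(targetSizes = targetSizes, dropRule = "drop"),
            class = "ProjectionSpec")
}

#' Build the unfolded joint SFS by projection
#'
#' Each polarized site contributes the outer product of its three per-
#' population hypergeometric projection vectors; sites observed at fewer
#' chromosomes than the target in any population are dropped (the
#' "projecting down" rule). The two monomorphic corners are masked.
#'
#' @param polarized result of [polarizeSites()].
#' @param proj a [projectionSpec()].
#' @return A [JointSFS-class]; metadata records `nProjectionDropped`.
#' @export
buildJointSFS <- function(polarized, proj = projectionSpec()) {
  m <- proj$targetSizes
  der <- polarized$derived
  obs <- polarized$observed
  ok <- obs[, 1] >= m[1] & obs[, 2] >= m[2] & obs[, 3] >= m[3]
  if (!any(ok))
    stop("projection target exceeds the observed chromosomes at every site")
  counts <- array(0, dim = m + 1L)
  for (s in which(ok)) {
    v1 <- stats::dhyper(0:m[1], der[s, 1], obs[s, 1] - der[s, 1], m[1])
    v2 <- stats::dhyper(0:m[2], der[s, 2], obs[s, 2] - der[s, 2], m[2])
    v3 <- stats::dhyper(0:m[3], der[s, 3], obs[s, 3] - der[s, 3], m[3])
    counts <- counts + outer(outer(v1, v2), v3)
  }
  JointSFS(counts, sampleSizes = m,
           metadata = list(nProjectionDropped = sum(!ok),
                           nPolarizationDropped = polarized$nDropped,
                           nSitesProjected = sum(ok)))
}

#' Write a joint SFS in the plain-text SFS dialect
#'
#' Three lines: a header `d1 d2 d3 unfolded` giving the array shape, the
#' flattened counts (last axis fastest), and a 0/1 mask line in the same
#' order (1 = masked).
#'
#' @param sfs A [JointSFS-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSFS <- function(sfs, path) {
  d <- dim(sfs@counts)
  flat <- function(a) as.vector(aperm(a, c(3, 2, 1)))
  lines <- c(
    paste(c(d, if (sfs@polarized) "unfolded" else "folded"), collapse = " "),
    paste(sprintf("%.12g", flat(sfs@counts)), collapse = " "),
    paste(as.integer(flat(sfs@mask)), collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a joint SFS from the plain-text SFS dialect
#'
#' @param path file written by [writeSFS()] (mask line optional; when
#'   absent only the monomorphic corners are masked).
#' @return A [JointSFS-class].
#' @export
readSFS <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  dims <- suppressWarnings(as.integer(hdr[1:3]))
  if (anyNA(dims) || length(hdr) < 3L)
    stop("malformed SFS header: ", lines[1])
  polarized <- !("folded" %in% hdr)
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(vals) != prod(dims))
    stop(sprintf("SFS dimension mismatch: header implies %d entries, found %d",
                 prod(dims), length(vals)))
  unflat <- function(v) aperm(array(v, dim = rev(dims)), c(3, 2, 1))
  counts <- unflat(vals)
  mask <- NULL
  if (length(lines) >= 3L) {
    mv <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
    if (length(mv) != prod(dims)) stop("SFS mask length mismatch")
    mask <- unflat(mv) > 0
  }
  JointSFS(counts, sampleSizes = dims - 1L, mask = mask, polarized = polarized)
}
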