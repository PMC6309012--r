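#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib desertSong, .registration = TRUE
NULL

#' Code for a missing diploid genotype call
#'
#' Genotype calls are stored as integer counts of the alternate allele
#' (0, 1, 2); cells with no call carry `NA_integer_`.
#' @export
MISSING_CALL <- NA_integer_

POPULATION_LABELS <- c("SON", "CHI", "CAR", "OUTGROUP")

#' Diploid SNP genotype matrix with population labels
#'
#' Container for biallelic SNP calls across individuals. `calls` holds the
#' alternate-allele count per site x individual (0, 1, 2 or `NA` for a
#' missing call); `sites` is a data.frame with one row per site
#' (`chrom`, `pos`, `locus_id`, `ref`, `alt`); `popOf` assigns every
#' individual to one of `SON`, `CHI`, `CAR`, `OUTGROUP`.
#'
#' @slot calls integer matrix, sites x individuals, values in 0:2 or NA.
#' @slot sites data.frame of site records.
#' @slot individuals character vector of individual IDs (column order).
#' @slot popOf named character vector, individual -> population label.
#' @slot metadata list of provenance (seeds, drop/skip counters).
#' @export
setClass("GenotypeMatrix",
  representation(
    calls = "matrix",
    sites = "data.frame",
    individuals = "character",
    popOf = "character",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  if (nrow(object@calls) != nrow(object@sites))
    msgs <- c(msgs, "nrow(calls) must equal nrow(sites)")
  if (ncol(object@calls) != length(object@individuals))
    msgs <- c(msgs, "ncol(calls) must equal length(individuals)")
  if (!all(object@individuals %in% names(object@popOf)))
    msgs <- c(msgs, "every individual needs a population label in popOf")
  if (!all(object@popOf %in% POPULATION_LABELS))
    msgs <- c(msgs, sprintf("population labels must be in {%s}",
                            paste(POPULATION_LABELS, collapse = ", ")))
  vals <- object@calls[!is.na(object@calls)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L)))
    msgs <- c(msgs, "calls must be 0, 1, 2 or NA")
  need <- c("chrom", "pos", "locus_id", "ref", "alt")
  if (!all(need %in% names(object@sites)))
    msgs <- c(msgs, sprintf("sites must have columns %s",
                            paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of alt-allele counts (sites x individuals).
#' @param sites data.frame with columns chrom, pos, locus_id, ref, alt.
#' @param individuals character IDs matching the columns of `calls`.
#' @param popOf named character vector mapping individual to population.
#' @param metadata optional list of provenance.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, sites, individuals, popOf, metadata = list()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls, sites = sites,
      individuals = as.character(individuals), popOf = popOf,
      metadata = metadata)
}

#' Unfolded joint site-frequency spectrum over three populations
#'
#' `counts` is an array of shape (n1+1, n2+1, n3+1) indexed by derived-allele
#' count in each population (index 1 corresponds to zero copies). `mask` is a
#' logical array of the same shape; masked entries (at minimum the two
#' monomorphic corners) are excluded from all likelihood sums.
#'
#' @slot counts numeric array of non-negative expected or observed counts.
#' @slot sampleSizes integer vector (n1, n2, n3) of haploid chromosomes.
#' @slot mask logical array, TRUE where the entry is masked.
#' @slot polarized logical flag; TRUE for an unfolded spectrum.
#' @slot metadata list of provenance.
#' @export
setClass("JointSFS",
  representation(
    counts = "array",
    sampleSizes = "integer",
    mask = "array",
    polarized = "logical",
    metadata = "list"
  ),
  prototype(polarized = TRUE, metadata = list())
)

setValidity("JointSFS", function(object) {
  msgs <- character()
  ss <- object@sampleSizes
  if (length(ss) != 3L || any(ss < 0L) || sum(ss) < 2L)
    msgs <- c(msgs, "sampleSizes must be three haploid counts summing to >= 2")
  if (!identical(dim(object@counts), ss + 1L))
    msgs <- c(msgs, "counts must have shape sampleSizes + 1")
  if (!identical(dim(object@mask), dim(object@counts)))
    msgs <- c(msgs, "mask must match counts in shape")
  if (any(object@counts < 0, na.rm = TRUE))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a JointSFS
#'
#' @param counts numeric array of shape (n1+1, n2+1, n3+1).
#' @param sampleSizes integer haploid sample sizes (n1, n2, n3); defaults to
#'   `dim(counts) - 1`.
#' @param mask logical array; defaults to masking only the two monomorphic
#'   corners.
#' @param polarized logical, TRUE for an unfolded spectrum.
#' @param metadata optional provenance list.
#' @return A [JointSFS-class] object.
#' @export
JointSFS <- function(counts, sampleSizes = dim(counts) - 1L, mask = NULL,
                     polarized = TRUE, metadata = list()) {
  sampleSizes <- as.integer(sampleSizes)
  counts <- array(as.numeric(counts), dim = sampleSizes + 1L)
  if (is.null(mask)) mask <- cornerMask(sampleSizes)
  new("JointSFS", counts = counts, sampleSizes = sampleSizes, mask = mask,
      polarized = polarized, metadata = metadata)
}

#' Mask covering only the monomorphic corners
#'
#' @param sampleSizes integer haploid sample sizes (n1, n2, n3).
#' @return Logical array of shape `sampleSizes + 1` that is TRUE at the
#'   all-ancestral and all-derived corners.
#' @export
cornerMask <- function(sampleSizes) {
  d <- as.integer(sampleSizes) + 1L
  m <- array(FALSE, dim = d)
  m[1, 1, 1] <- TRUE
  m[d[1], d[2], d[3]] <- TRUE
  m
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sites x %d individuals\n",
              nrow(object@calls), ncol(object@calls)))
  tab <- table(factor(object@popOf[object@individuals],
                      levels = POPULATION_LABELS))
  cat("  populations:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  pm <- mean(is.na(object@calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * pm))
  invisible(object)
})

setMethod("show", "JointSFS", function(object) {
  cat(sprintf("JointSFS (%s): shape %s, haploid samples (%s)\n",
              if (object@polarized) "unfolded" else "folded",
              paste(dim(object@counts), collapse = " x "),
              paste(object@sampleSizes, collapse = ", ")))
  cat(sprintf("  unmasked mass %.4g over %d cells (%d masked)\n",
              sum(object@counts[!object@mask]), sum(!object@mask),
              sum(object@mask)))
  invisible(object)
})

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))
#' @rdname accessors
#' @export
setGeneric("sfsMask", function(x) standardGeneric("sfsMask"))
#' @rdname accessors
#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))

#' Accessors for GenotypeMatrix and JointSFS
#'
#' `genotypeCalls` returns the sites x individuals call matrix; `siteInfo`
#' the per-site data.frame; `populations` the named individual -> population
#' vector; `sfsCounts`/`sfsMask` the SFS array and its mask; `sampleSizes`
#' the haploid sample sizes.
#'
#' @param x A [GenotypeMatrix-class] or [JointSFS-class] object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("siteInfo", "GenotypeMatrix", function(x) x@sites)
#' @rdname accessors
setMethod("populations", "GenotypeMatrix", function(x) x@popOf)
#' @rdname accessors
setMethod("sfsCounts", "JointSFS", function(x) x@counts)
#' @rdname accessors
setMethod("sfsMask", "JointSFS", function(x) x@mask)
#' @rdname accessors
setMethod("sampleSizes", "JointSFS", function(x) x@sampleSizes)
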