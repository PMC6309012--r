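test_that("VCF genotypes are read, encoded and filtered correctly", {
  vcf <- writeTestVCF(
    tempfile(fileext = ".vcf"),
    fix = list(c("chr1", 100, "L1", "A", "G", ".", "PASS", "."),
               c("chr1", 200, "L2", "C", "T", ".", "PASS", "."),
               c("chr1", 300, "L3", "G", "A,T", ".", "PASS", ".")),
    gtRows = list(c("0/0", "0/1", "1/1"),
                  c("./.", "0/0", "0/1"),
                  c("0/0", "0/1", "2/2")),
    samples = c("s1", "s2", "s3"))
  popmap <- c(s1 = "SON", s2 = "CHI", s3 = "OUTGROUP")
  gm <- readGenotypes(vcf, popmap)

  expect_equal(nrow(genotypeCalls(gm)), 2L)          # tri-allelic skipped
  expect_equal(gm@metadata$nMultiallelicSkipped, 1L)
  expect_equal(unname(genotypeCalls(gm)[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(genotypeCalls(gm)[2, 1]))        # ./. -> MISSING
  expect_equal(unname(genotypeCalls(gm)[2, 2:3]), c(0L, 1L))

  expect_error(readGenotypes(vcf, c(s1 = "SON", s2 = "CHI")), "s3")
})

test_that("thinning keeps one random SNP per locus, deterministically", {
  nLoci <- 1000L
  calls <- matrix(0L, nrow = 3 * nLoci, ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  attr(calls, "pops") <- c("SON", "CHI")
  gm <- smallGenotypeMatrix(calls)
  gm@sites$locus_id <- rep(sprintf("L%04d", seq_len(nLoci)), each = 3)

  thin1 <- thinToUnlinked(gm, seed = 11)
  thin2 <- thinToUnlinked(gm, seed = 11)
  expect_equal(nrow(genotypeCalls(thin1)), nLoci)
  expect_equal(anyDuplicated(siteInfo(thin1)$locus_id), 0L)
  expect_identical(siteInfo(thin1)$pos, siteInfo(thin2)$pos)

  # mixed locus sizes: 3 SNPs on one locus + 1 on another -> 2 sites
  calls4 <- calls[1:4, , drop = FALSE]
  attr(calls4, "pops") <- attr(calls, "pops")
  gm2 <- smallGenotypeMatrix(calls4)
  gm2@sites$locus_id <- c("LA", "LA", "LA", "LB")
  expect_equal(nrow(genotypeCalls(thinToUnlinked(gm2, 5))), 2L)
})

test_that("outgroup consensus polarization flips and drops correctly", {
  # columns: 2 SON, 2 CHI, 1 CAR, 1 OUTGROUP
  calls <- rbind(
    c(1L, 2L, 0L, 1L, 0L, 0L),  # outgroup hom ref: derived = alt counts
    c(1L, 2L, 0L, 1L, 0L, 2L),  # outgroup hom alt: derived flipped
    c(1L, 1L, 1L, 1L, 1L, 1L),  # outgroup het: dropped
    c(0L, 1L, 2L, 0L, 1L, NA)   # outgroup missing: dropped
  )
  colnames(calls) <- c("son1", "son2", "chi1", "chi2", "car1", "out1")
  attr(calls, "pops") <- c("SON", "SON", "CHI", "CHI", "CAR", "OUTGROUP")
  gm <- smallGenotypeMatrix(calls)
  pol <- polarizeSites(gm)

  expect_equal(pol$nDropped, 2L)
  expect_equal(unname(pol$derived[1, ]), c(3L, 1L, 0L))
  # flipped site: ref is derived; counts = 2*called - alt
  expect_equal(unname(pol$derived[2, ]), c(4 - 3, 4 - 1, 2 - 0))
  expect_equal(unname(pol$observed[1, ]), c(4L, 4L, 2L))

  allHet <- gm
  allHet@calls[, 6] <- 1L
  expect_error(polarizeSites(allHet), "no polarizable sites")
})

test_that("projection matches exhaustive subsample enumeration (n <= 8)", {
  bruteProject <- function(d, n, m) {
    alleles <- c(rep(1, d), rep(0, n - d))
    subs <- utils::combn(n, m)
    tab <- tabulate(colSums(matrix(alleles[subs], nrow = m)) + 1L, m + 1L)
    tab / ncol(subs)
  }
  for (n in 1:8) for (m in 1:n) for (d in 0:n) {
    expect_equal(projectSite(d, n, m), bruteProject(d, n, m),
                 tolerance = 1e-12,
                 label = sprintf("d=%d n=%d m=%d", d, n, m))
  }
  expect_equal(projectSite(2, 4, 2), c(1, 4, 1) / 6)
  expect_equal(projectSite(0, 6, 3), c(1, 0, 0, 0))       # point mass at 0
  expect_equal(projectSite(3, 5, 5), c(0, 0, 0, 1, 0, 0)) # identity
  expect_error(projectSite(5, 4, 2), "exceeds")
  expect_equal(projectSite(2, 3, 4), rep(0, 5))           # n < m drops
})

test_that("joint SFS projection conserves mass and places fixed sites", {
  # one site fixed derived in SON only, complete data
  calls <- rbind(c(2L, 2L, 0L, 0L, 0L, 0L))
  colnames(calls) <- c("son1", "son2", "chi1", "chi2", "car1", "out1")
  attr(calls, "pops") <- c("SON", "SON", "CHI", "CHI", "CAR", "OUTGROUP")
  gm <- smallGenotypeMatrix(calls)
  sfs <- buildJointSFS(polarizeSites(gm),
                       projectionSpec(targetSizes = c(2, 2, 2)))
  expect_equal(dim(sfsCounts(sfs)), c(3L, 3L, 3L))
  expect_equal(sfsCounts(sfs)[3, 1, 1], 1)
  expect_equal(sum(sfsCounts(sfs)), 1)

  # conservation: complete data, projection to own size keeps every site
  set.seed(42)
  nSites <- 100L
  big <- matrix(sample(0:2, nSites * 6, replace = TRUE), ncol = 6)
  big[, 6] <- 0L  # clean outgroup
  colnames(big) <- colnames(calls)
  attr(big, "pops") <- attr(calls, "pops")
  gmB <- smallGenotypeMatrix(big)
  sfsB <- buildJointSFS(polarizeSites(gmB),
                        projectionSpec(targetSizes = c(4, 4, 2)))
  expect_equal(sum(sfsCounts(sfsB)), nSites, tolerance = 1e-9)

  # study-sized target interpreted as haploid counts -> shape 11 x 11 x 3
  expect_equal(projectionSpec(c(10, 10, 2))$targetSizes, c(10L, 10L, 2L))
  expect_equal(projectionSpec(c(10, 10, 2), diploidUnits = TRUE)$targetSizes,
               c(20L, 20L, 4L))
})

test_that("polarization flip symmetry mirrors the SFS", {
  set.seed(7)
  calls <- matrix(sample(0:2, 50 * 6, replace = TRUE), ncol = 6)
  calls[, 6] <- 0L
  colnames(calls) <- c("son1", "son2", "chi1", "chi2", "car1", "out1")
  attr(calls, "pops") <- c("SON", "SON", "CHI", "CHI", "CAR", "OUTGROUP")
  gm <- smallGenotypeMatrix(calls)
  sfs <- buildJointSFS(polarizeSites(gm), projectionSpec(c(4, 4, 2)))

  # flipping the ancestral designation (outgroup carries the other
  # allele) mirrors every derived count
  flipped <- calls
  flipped[, 6] <- 2L
  attr(flipped, "pops") <- attr(calls, "pops")
  gmF <- smallGenotypeMatrix(flipped)
  sfsF <- buildJointSFS(polarizeSites(gmF), projectionSpec(c(4, 4, 2)))

  rev3 <- function(a) a[rev(seq_len(dim(a)[1])), rev(seq_len(dim(a)[2])),
                        rev(seq_len(dim(a)[3]))]
  expect_equal(sfsCounts(sfsF), rev3(sfsCounts(sfs)), tolerance = 1e-12)
})

test_that("SFS text round-trips and honors its mask line", {
  set.seed(3)
  sfs <- JointSFS(array(runif(27), dim = c(3, 3, 3)))
  path <- tempfile(fileext = ".sfs")
  writeSFS(sfs, path)
  back <- readSFS(path)
  expect_equal(sfsCounts(back), sfsCounts(sfs), tolerance = 1e-12)
  expect_true(sfsMask(back)[1, 1, 1] && sfsMask(back)[3, 3, 3])
  expect_equal(sum(sfsMask(back)), 2L)

  # hand-written 2x2x2 file: flattening is last-axis-fastest
  hand <- tempfile(fileext = ".sfs")
  writeLines(c("2 2 2 unfolded",
               "0 1 2 3 4 5 6 7",
               "1 0 0 0 0 0 0 1"), hand)
  got <- readSFS(hand)
  expect_equal(got@counts[1, 1, 2], 1)   # second value: k advances first
  expect_equal(got@counts[1, 2, 1], 2)
  expect_equal(got@counts[2, 1, 1], 4)
  expect_equal(got@counts[2, 2, 2], 7)

  bad <- tempfile(fileext = ".sfs")
  writeLines(c("3 3 3 unfolded", "0 1 2"), bad)
  expect_error(readSFS(bad), "mismatch")
})
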