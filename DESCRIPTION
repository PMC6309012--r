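Package: desertSong
Title: Demographic Inference and Song-Playback Analysis Across a Desert Filter Barrier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing how a biogeographic filter barrier structures a
    songbird population genetically and behaviorally. Builds unfolded joint
    site-frequency spectra (SFS) from SNP genotypes with hypergeometric
    projection over missing data, simulates three-deme structured-coalescent
    genealogies under six isolation/isolation-with-migration models, fits
    observed spectra by maximum composite likelihood with AIC model selection
    and parametric-bootstrap confidence intervals, computes Nei's G_ST and
    Hedrick's G'_ST plus the Evanno delta-K statistic, and scores
    playback-experiment aggression via a PCA composite compared across song
    treatments with linear mixed models under AICc. A synthetic-data module
    generates genotype and playback datasets with the statistical structure
    the analyses assume, so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    lme4,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
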