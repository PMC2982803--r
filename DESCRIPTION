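Package: phylosym
Title: Community Phylogenetics of Host-Associated Microbiota from 16S Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for asking whether gut microbial community
    composition recapitulates host phylogeny (phylosymbiosis). Simulates 16S
    amplicon ("pyrotag") datasets with species-structured community divergence
    along a known host tree; performs quality trimming, exact barcode/primer
    demultiplexing, naive-Bayes taxonomic classification with bootstrap
    confidence, and length/position/chloroplast filtering; clusters reads into
    99.5 percent-identity OTUs with Markov clustering (MCL, inflation 1.5);
    codes normalized OTU frequencies as six ordered log-unit states; infers
    host-sample trees by ordered-character (Wagner) maximum parsimony with
    Sankoff dynamic programming, heuristic search and bootstrap; and provides
    congruence analytics (Robinson-Foulds distance, constrained unrooted
    topology counting, branch-length apportionment, internal-branch
    correlation, technical-replicate overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
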