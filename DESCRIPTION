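Package: coalABC
Title: Coalescent Simulation and Approximate Bayesian Computation for
    RAD-Seq Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic inference for reduced-representation (RAD-seq) SNP
    data in the DIYABC style. Simulates unlinked biallelic SNPs and short
    sequence loci under piecewise-constant coalescent models (constant size,
    glacial-onset expansion, interglacial expansion), performs approximate
    Bayesian computation for model choice (rejection and weighted multinomial
    logistic regression) and parameter estimation (Beaumont local-linear
    adjustment on logit-transformed parameters), and validates inferences via
    posterior-predictive checks, pseudo-observed-data error rates, bias and
    precision, and a power analysis over SNP counts. Also provides the
    supporting population-genomic summary statistics (observed
    heterozygosity, effective number of alleles, polymorphic information
    content, nucleotide diversity, Tajima's D, Weir-Cockerham F_ST with
    permutation tests, Dxy, Nei's distance, net p-distance) and
    population-structure diagnostics (PCoA, individual-based Mantel test,
    Evanno delta-K, mutual k-nearest-neighbour graphs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    igraph,
    nnet,
    geosphere,
    vcfR,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
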