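# Coalescent simulation under piecewise-constant Ne. The compiled kernels in
# src/coalsim.cpp draw from R's RNG stream, so set.seed() gives bit-identical
# output across runs.

.kindCode <- function(scenario) {
  if (scenario@kind == "constant") 0L else 1L
}

.scenArgs <- function(scenario) {
  validObject(scenario)
  list(kind = .kindCode(scenario),
       Nc = ifelse(is.na(scenario@Nc), 0, scenario@Nc),
       Nanc = ifelse(is.na(scenario@Nanc), 0, scenario@Nanc),
       Npost = ifelse(is.na(scenario@Npost), 0, scenario@Npost),
       Texp = ifelse(is.na(scenario@Texp), Inf, scenario@Texp))
}

#' Simulate a coalescent genealogy
#'
#' Standard n-coalescent with piecewise-constant diploid effective size:
#' while `j` lineages remain the waiting time to the next coalescence has
#' hazard `choose(j,2) / (2 Ne(t))` (backwards time), with `Ne(t) = Npost`
#' for `t < Texp` and `Nanc` beyond under the expansion scenarios, and `Nc`
#' throughout under the constant scenario. Event times are obtained by
#' piecewise rescaling of unit exponentials, never by rejection.
#'
#' @param nHaploid number of haploid lineages (tips), >= 2.
#' @param scenario a [DemographicScenario-class].
#' @param seed optional integer; calls `set.seed()` first.
#' @return An [ape::ape-package] `"phylo"` tree with branch lengths in
#'   generations, plus attributes `node.time` (coalescence times) and
#'   `total.length` (sum of branch lengths).
#' @examples
#' tr <- simulateTree(6, demographicScenario("constant", Nc = 1000), seed = 1)
#' attr(tr, "total.length")
#' @export
simulateTree <- function(nHaploid, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nHaploid <- as.integer(nHaploid)
  if (nHaploid < 2L) stop("nHaploid must be >= 2")
  a <- .scenArgs(scenario)
  res <- cpp_sim_tree(nHaploid, a$kind, a$Nc, a$Nanc, a$Npost, a$Texp)
  phy <- structure(list(edge = res$edge,
                        edge.length = as.numeric(res$edge.length),
                        tip.label = paste0("h", seq_len(nHaploid)),
                        Nnode = nHaploid - 1L),
                   class = "phylo", order = "postorder")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "node.time") <- res$node.time
  attr(phy, "total.length") <- sum(phy$edge.length)
  phy
}

# tip indices (1..n) below each edge's child node
.tipsBelow <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Drop a single SNP mutation onto a genealogy
#'
#' Places exactly one mutation on a branch chosen with probability
#' proportional to branch length (the DIYABC-style SNP model: loci are
#' retained conditional on being variable, so every simulated locus carries
#' one mutation and is polymorphic in-sample by construction).
#'
#' @param tree a `"phylo"` genealogy from [simulateTree()].
#' @return Integer vector of derived-allele indicators (0/1), one per tip,
#'   in tip order; derived count is always in `[1, n - 1]`.
#' @export
simulateSnpLocus <- function(tree) {
  len <- tree$edge.length
  if (!sum(len) > 0) stop("degenerate tree: zero total branch length")
  e <- sample.int(length(len), 1L, prob = len)
  carriers <- .tipsBelow(tree, tree$edge[e, 2])
  out <- integer(length(tree$tip.label))
  out[carriers] <- 1L
  out
}

#' Simulate a sequence locus under the infinite-sites model
#'
#' Mutation count is Poisson with mean `muPerSite * length * total branch
#' length`; each mutation falls on a branch chosen proportionally to its
#' length and occupies a fresh site. If more mutations are requested than
#' sites exist the locus saturates with a warning.
#'
#' @param tree a `"phylo"` genealogy from [simulateTree()].
#' @param muPerSite mutation rate per site per generation.
#' @param length locus length in bp.
#' @return A [Biostrings::DNAStringSet] of haplotypes (one per tip).
#' @export
simulateSequenceLocus <- function(tree, muPerSite, length) {
  n <- base::length(tree$tip.label)
  L <- as.integer(length)
  total <- sum(tree$edge.length)
  lambda <- muPerSite * L * total
  if (!is.finite(lambda)) stop("non-finite expected mutation count")
  nmut <- stats::rpois(1L, lambda)
  if (nmut > L) {
    warning("requested mutations exceed locus length; saturating at ", L)
    nmut <- L
  }
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  haps <- matrix(rep(anc, each = n), nrow = n)
  if (nmut > 0) {
    sites <- sample.int(L, nmut)
    edges <- sample.int(base::length(tree$edge.length), nmut,
                        replace = TRUE, prob = tree$edge.length)
    for (k in seq_len(nmut)) {
      carriers <- .tipsBelow(tree, tree$edge[edges[k], 2])
      derived <- sample(setdiff(c("A", "C", "G", "T"), anc[sites[k]]), 1L)
      haps[carriers, sites[k]] <- derived
    }
  }
  seqs <- apply(haps, 1, paste0, collapse = "")
  Biostrings::DNAStringSet(stats::setNames(seqs, tree$tip.label))
}

#' Simulate per-locus derived-allele counts for unlinked SNPs
#'
#' Fast sampling path used for reference tables and simulated datasets:
#' for each locus the inter-coalescent interval times are simulated under
#' the scenario, the mutation's level `j` is drawn with probability
#' proportional to `j * T_j`, and the subtended tip count comes from the
#' exchangeable-topology distribution
#' `P(i | j) = C(n-i-1, j-2) / C(n-1, j-1)` (Fu 1995). This is
#' distributionally identical to dropping one mutation on an explicitly
#' simulated genealogy ([simulateTree()] + [simulateSnpLocus()]) but avoids
#' building topologies for the millions of loci an ABC run consumes.
#'
#' @param nHaploid haploid sample size.
#' @param scenario a [DemographicScenario-class].
#' @param nLoci number of unlinked loci.
#' @param seed optional integer seed.
#' @return Integer vector of derived-allele counts in `[1, nHaploid - 1]`.
#' @export
simulateSnpCounts <- function(nHaploid, scenario, nLoci, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- .scenArgs(scenario)
  cpp_snp_counts(as.integer(nHaploid), as.integer(nLoci),
                 a$kind, a$Nc, a$Nanc, a$Npost, a$Texp)
}

#' Simulate times to most recent common ancestor
#'
#' @inheritParams simulateSnpCounts
#' @param reps number of independent genealogies.
#' @return Numeric vector of TMRCAs in generations.
#' @export
simulateTmrca <- function(nHaploid, scenario, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- .scenArgs(scenario)
  cpp_tmrca(as.integer(nHaploid), as.integer(reps),
            a$kind, a$Nc, a$Nanc, a$Npost, a$Texp)
}

#' Simulate a complete RAD-style dataset
#'
#' Generates unlinked biallelic SNP genotypes (and optionally short sequence
#' loci) for `spec@nDiploid` individuals under a demographic scenario.
#' Haploid lineages `2k-1, 2k` are paired into diploid genotypes coded by
#' derived-allele count; by tip exchangeability the carriers of each
#' mutation are a uniform random subset of lineages given the derived
#' count. Per-genotype missingness is injected uniformly at random at
#' `spec@missingRate`.
#'
#' @param scenario a [DemographicScenario-class]; recorded as the truth.
#' @param spec a [SampleSpec-class].
#' @param muPerSite per-site per-generation mutation rate for sequence loci
#'   (default `1e-8`).
#' @param seed optional integer seed.
#' @return A list with elements `genotypes` ([GenotypeMatrix-class]),
#'   `alignments` ([LocusAlignmentSet-class] or `NULL` when
#'   `spec@nSeqLoci == 0`) and `truth` (the scenario).
#' @examples
#' sc <- demographicScenario("lgm", Nanc = 1e4, Npost = 1e5, Texp = 28000)
#' d <- simulateDataset(sc, sampleSpec(nDiploid = 10, nSnpLoci = 100), seed = 1)
#' d$genotypes
#' @export
simulateDataset <- function(scenario, spec, muPerSite = 1e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validObject(spec)
  nHap <- 2L * spec@nDiploid
  counts <- simulateSnpCounts(nHap, scenario, spec@nSnpLoci)
  g <- matrix(0L, nrow = spec@nDiploid, ncol = spec@nSnpLoci)
  for (l in seq_len(spec@nSnpLoci)) {
    carriers <- sample.int(nHap, counts[l])
    ind <- (carriers + 1L) %/% 2L
    tab <- tabulate(ind, nbins = spec@nDiploid)
    g[, l] <- tab
  }
  if (spec@missingRate > 0) {
    miss <- stats::runif(base::length(g)) < spec@missingRate
    g[miss] <- NA_integer_
  }
  rownames(g) <- paste0("ind_", seq_len(spec@nDiploid))
  colnames(g) <- paste0("locus_", seq_len(spec@nSnpLoci))
  sex <- rep_len(c("m", "f"), spec@nDiploid)  # provenance only; autosomal loci
  gm <- genotypeMatrix(g,
    sampleData = data.frame(id = rownames(g), sex = sex),
    locusData = data.frame(locus = colnames(g), radLocus = colnames(g)))
  aln <- NULL
  if (spec@nSeqLoci > 0) {
    alns <- vector("list", spec@nSeqLoci)
    for (l in seq_len(spec@nSeqLoci)) {
      tr <- simulateTree(nHap, scenario)
      alns[[l]] <- simulateSequenceLocus(tr, muPerSite, spec@seqLocusLength)
      names(alns[[l]]) <- paste0("ind_", (seq_len(nHap) + 1L) %/% 2L,
                                 rep_len(c("_a", "_b"), nHap))
    }
    names(alns) <- paste0("seqlocus_", seq_len(spec@nSeqLoci))
    aln <- locusAlignmentSet(alns)
  }
  list(genotypes = gm, alignments = aln, truth = scenario)
}
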