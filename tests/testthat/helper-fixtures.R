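# Small fixture builders used across test files.

# genotype matrix from a plain integer matrix (rows = individuals)
gm_fix <- function(m, radLocus = NULL) {
  m <- as.matrix(m)
  if (nrow(m)) rownames(m) <- paste0("ind_", seq_len(nrow(m)))
  if (ncol(m)) colnames(m) <- paste0("locus_", seq_len(ncol(m)))
  ld <- data.frame(locus = colnames(m))
  if (!is.null(radLocus)) ld$radLocus <- radLocus
  genotypeMatrix(m, locusData = ld)
}

# one-locus alignment set from character sequences named by haplotype
aln_fix <- function(seqs, ids = NULL) {
  if (is.null(ids))
    ids <- paste0("ind_", (seq_along(seqs) + 1) %/% 2,
                  rep_len(c("_a", "_b"), length(seqs)))
  locusAlignmentSet(list(locus_1 =
    Biostrings::DNAStringSet(stats::setNames(seqs, ids))))
}

# genotype columns realising an exact alternate-allele frequency among
# nInd diploids: count = round(2 * nInd * p) copies of the alt allele
gm_freq <- function(p, nInd = 10, nLoci = 1) {
  col <- function(pp) {
    cnt <- round(2 * nInd * pp)
    g <- integer(nInd)
    g[seq_len(cnt %/% 2)] <- 2L
    if (cnt %% 2 == 1) g[cnt %/% 2 + 1] <- 1L
    g
  }
  gm_fix(vapply(rep(p, length.out = nLoci), col, integer(nInd)))
}

# hand-built toy reference table
ref_fix <- function(modelId, params, stats, priors,
                    spec = sampleSpec(nDiploid = 10, nSnpLoci = 10)) {
  if (is.null(colnames(stats)))
    colnames(stats) <- paste0("s", seq_len(ncol(stats)))
  full <- matrix(NA_real_, nrow(params), 4,
                 dimnames = list(NULL, c("Nc", "Nanc", "Npost", "Texp")))
  full[, colnames(params)] <- params
  new("ReferenceTable", modelId = modelId, params = full, stats = stats,
      statSd = apply(stats, 2, stats::sd), priors = priors, spec = spec)
}
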