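# SNP-matrix summary statistics (Tables of descriptive diversity and the
# four-statistic ABC summary vector). All statistics use complete-case
# allele frequencies per locus and are invariant to allele-label swap.

# per-locus alt-allele frequency and allele sample size (2 x non-missing)
.alleleFreq <- function(g) {
  gm <- genotypes(g)
  nonmiss <- colSums(!is.na(gm))
  p <- colSums(gm, na.rm = TRUE) / (2 * nonmiss)
  list(p = p, nAlleles = 2L * nonmiss)
}

.dropAllMissing <- function(g) {
  gm <- genotypes(g)
  bad <- colSums(!is.na(gm)) == 0
  if (any(bad)) {
    warning(sum(bad), " all-missing loci excluded")
    gm <- gm[, !bad, drop = FALSE]
    g <- genotypeMatrix(gm, sampleData = sampleData(g),
                        locusData = locusData(g)[!bad, , drop = FALSE])
  }
  g
}

#' Observed heterozygosity
#'
#' Per-locus fraction of heterozygous genotypes among non-missing calls,
#' and its mean across loci.
#'
#' @param g a [GenotypeMatrix-class].
#' @return List with `perLocus` (named numeric) and `mean`.
#' @examples
#' observedHeterozygosity(genotypeMatrix(matrix(c(0L, 1L, 2L), 3)))$mean
#' @export
observedHeterozygosity <- function(g) {
  g <- .dropAllMissing(g)
  gm <- genotypes(g)
  ho <- colMeans(gm == 1L, na.rm = TRUE)
  list(perLocus = ho, mean = mean(ho))
}

#' Effective number of alleles
#'
#' `Ae = 1 / sum(p_i^2)` from complete-case allele frequencies; 1 for a
#' monomorphic locus, at most 2 for a biallelic one.
#'
#' @inheritParams observedHeterozygosity
#' @return List with `perLocus` and `mean`.
#' @export
effectiveNumAlleles <- function(g) {
  g <- .dropAllMissing(g)
  p <- .alleleFreq(g)$p
  ae <- 1 / (p^2 + (1 - p)^2)
  list(perLocus = ae, mean = mean(ae))
}

#' Polymorphic information content
#'
#' Botstein et al. PIC for a biallelic locus:
#' `1 - p^2 - q^2 - 2 p^2 q^2`; 0 when monomorphic, maximal (0.375) at
#' p = 0.5.
#'
#' @inheritParams observedHeterozygosity
#' @return List with `perLocus` and `mean`.
#' @export
pic <- function(g) {
  g <- .dropAllMissing(g)
  p <- .alleleFreq(g)$p
  q <- 1 - p
  v <- 1 - p^2 - q^2 - 2 * p^2 * q^2
  list(perLocus = v, mean = mean(v))
}

#' SNP summary table
#'
#' Convenience wrapper mirroring the descriptive SNP diversity table:
#' number of loci, mean effective number of alleles, mean observed
#' heterozygosity and mean PIC.
#'
#' @inheritParams observedHeterozygosity
#' @return A one-row data.frame.
#' @export
snpSummary <- function(g) {
  data.frame(nSnps = nLoci(g),
             effectiveNumAlleles = effectiveNumAlleles(g)$mean,
             observedHeterozygosity = observedHeterozygosity(g)$mean,
             pic = pic(g)$mean)
}

#' ABC summary-statistic vector
#'
#' The four single-population SNP statistics used for DIYABC-style model
#' choice and parameter estimation, in fixed order:
#' \enumerate{
#'   \item `propMono` — proportion of loci monomorphic among non-missing
#'     calls (after any projection/missingness);
#'   \item `meanH` — mean per-locus unbiased gene diversity
#'     `2n/(2n-1) * (1 - p^2 - q^2)` with `2n` the locus allele sample size;
#'   \item `varH` — sample variance of per-locus gene diversity;
#'   \item `meanMAF` — mean minor-allele frequency.
#' }
#' The identical routine is applied to observed and simulated data.
#'
#' @inheritParams observedHeterozygosity
#' @return Named numeric vector of length 4.
#' @export
abcStats <- function(g) {
  if (nLoci(g) == 0) stop("genotype matrix has zero loci")
  af <- .alleleFreq(g)
  p <- af$p
  n <- af$nAlleles
  if (any(n == 0)) stop("all-missing locus; filter before computing stats")
  H <- ifelse(n > 1, n / (n - 1) * (1 - p^2 - (1 - p)^2), 0)
  mono <- p == 0 | p == 1
  c(propMono = mean(mono),
    meanH = mean(H),
    varH = if (length(H) > 1) stats::var(H) else 0,
    meanMAF = mean(pmin(p, 1 - p)))
}

# abcStats computed directly from haploid derived-allele counts with full
# sample size (simulation fast path); must agree with abcStats() on the
# equivalent GenotypeMatrix -- enforced by tests.
.abcStatsFromCounts <- function(counts, nHaploid) {
  p <- counts / nHaploid
  H <- nHaploid / (nHaploid - 1) * (1 - p^2 - (1 - p)^2)
  c(propMono = mean(p == 0 | p == 1),
    meanH = mean(H),
    varH = if (length(H) > 1) stats::var(H) else 0,
    meanMAF = mean(pmin(p, 1 - p)))
}
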