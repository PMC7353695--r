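#' @useDynLib coalABC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Demographic scenario with piecewise-constant effective size
#'
#' One of the three single-population demographic models compared by the
#' pipeline: constant diploid effective size (`"constant"`), a step expansion
#' at the onset of the last glaciation (`"lgm"`), or a step expansion during
#' the last interglacial (`"interglacial"`). The two expansion kinds share
#' the same mathematical form — backwards in time the population has size
#' `Npost` until `Texp` generations before present and size `Nanc` earlier —
#' and differ only in the prior window placed on `Texp`.
#'
#' @slot kind character; `"constant"`, `"lgm"` or `"interglacial"`.
#' @slot Nc diploid effective size of the constant model (unused otherwise).
#' @slot Nanc ancestral (pre-expansion) diploid effective size.
#' @slot Npost post-expansion (current) diploid effective size.
#' @slot Texp expansion time in generations before present.
#' @slot generationTime years per generation (1 for small passerines).
#'
#' @seealso [demographicScenario()], [simulateTree()], [simulateDataset()]
#' @export
setClass("DemographicScenario",
  representation(kind = "character", Nc = "numeric", Nanc = "numeric",
                 Npost = "numeric", Texp = "numeric",
                 generationTime = "numeric"),
  prototype(kind = "constant", Nc = 1e4, Nanc = NA_real_, Npost = NA_real_,
            Texp = NA_real_, generationTime = 1))

setValidity("DemographicScenario", function(object) {
  msg <- character()
  if (!object@kind %in% c("constant", "lgm", "interglacial"))
    msg <- c(msg, "kind must be 'constant', 'lgm' or 'interglacial'")
  sizes <- if (object@kind == "constant") object@Nc else
    c(object@Nanc, object@Npost)
  if (any(!is.finite(sizes)) || any(sizes < 2))
    msg <- c(msg, "population sizes must be finite and >= 2")
  if (object@kind != "constant" &&
      (!is.finite(object@Texp) || object@Texp <= 0))
    msg <- c(msg, "Texp must be finite and > 0 for expansion scenarios")
  if (!is.finite(object@generationTime) || object@generationTime <= 0)
    msg <- c(msg, "generationTime must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a demographic scenario
#'
#' @param kind `"constant"`, `"lgm"` or `"interglacial"`.
#' @param Nc constant-model diploid effective size.
#' @param Nanc ancestral diploid effective size (expansion kinds).
#' @param Npost post-expansion diploid effective size (expansion kinds).
#' @param Texp expansion time, generations before present (expansion kinds).
#' @param generationTime years per generation (default 1).
#' @return A [DemographicScenario-class] object.
#' @examples
#' demographicScenario("lgm", Nanc = 1e4, Npost = 1e5, Texp = 28000)
#' @export
demographicScenario <- function(kind = c("constant", "lgm", "interglacial"),
                                Nc = NA_real_, Nanc = NA_real_,
                                Npost = NA_real_, Texp = NA_real_,
                                generationTime = 1) {
  kind <- match.arg(kind)
  new("DemographicScenario", kind = kind, Nc = as.numeric(Nc),
      Nanc = as.numeric(Nanc), Npost = as.numeric(Npost),
      Texp = as.numeric(Texp), generationTime = as.numeric(generationTime))
}

#' Sampling design for a simulated dataset
#'
#' @slot nDiploid number of diploid individuals sampled.
#' @slot nSnpLoci number of unlinked biallelic SNP loci.
#' @slot nSeqLoci number of short sequence (RAD-locus) alignments.
#' @slot seqLocusLength locus length in bp (RAD reads trimmed to 140 bp).
#' @slot missingRate per-genotype missingness probability in `[0, 1)`.
#' @seealso [sampleSpec()]
#' @export
setClass("SampleSpec",
  representation(nDiploid = "integer", nSnpLoci = "integer",
                 nSeqLoci = "integer", seqLocusLength = "integer",
                 missingRate = "numeric"),
  prototype(nDiploid = 20L, nSnpLoci = 2000L, nSeqLoci = 0L,
            seqLocusLength = 140L, missingRate = 0))

setValidity("SampleSpec", function(object) {
  msg <- character()
  if (object@nDiploid < 2L) msg <- c(msg, "nDiploid must be >= 2")
  if (object@nSnpLoci < 0L || object@nSeqLoci < 0L)
    msg <- c(msg, "locus counts must be non-negative")
  if (object@seqLocusLength < 1L) msg <- c(msg, "seqLocusLength must be >= 1")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a sampling design
#'
#' @param nDiploid diploid individuals (default 20, ten males + ten females
#'   in the motivating power analysis; loci are autosomal so sex is
#'   provenance only).
#' @param nSnpLoci unlinked biallelic SNP loci (default 2000).
#' @param nSeqLoci sequence loci (default 0).
#' @param seqLocusLength bp per sequence locus (default 140).
#' @param missingRate per-genotype missing probability (default 0).
#' @return A [SampleSpec-class] object.
#' @export
sampleSpec <- function(nDiploid = 20, nSnpLoci = 2000, nSeqLoci = 0,
                       seqLocusLength = 140, missingRate = 0) {
  new("SampleSpec", nDiploid = as.integer(nDiploid),
      nSnpLoci = as.integer(nSnpLoci), nSeqLoci = as.integer(nSeqLoci),
      seqLocusLength = as.integer(seqLocusLength),
      missingRate = as.numeric(missingRate))
}

#' Diploid SNP genotype matrix
#'
#' Individuals x loci matrix of alternate/derived-allele counts
#' (0, 1, 2 or `NA` for missing), with per-individual metadata (group or
#' elevational band, coordinates, species) and per-locus metadata (the
#' RAD-locus group each SNP came from, used by the one-SNP-per-locus filter).
#'
#' @slot genotypes integer matrix, rows = individuals, cols = loci.
#' @slot sampleData data.frame keyed by individual id (`id`, optionally
#'   `group`, `lat`, `lon`, `species`).
#' @slot locusData data.frame keyed by locus id (`locus`, optionally
#'   `radLocus`).
#' @seealso [genotypeMatrix()], [readGenotypes()], [filterLoci()]
#' @export
setClass("GenotypeMatrix",
  representation(genotypes = "matrix", sampleData = "data.frame",
                 locusData = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  msg <- character()
  ok <- is.na(g) | g %in% 0:2
  if (!all(ok)) msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (nrow(g) && (is.null(rownames(g)) || anyDuplicated(rownames(g))))
    msg <- c(msg, "rownames (individual ids) must be present and unique")
  if (ncol(g) && (is.null(colnames(g)) || anyDuplicated(colnames(g))))
    msg <- c(msg, "colnames (locus ids) must be present and unique")
  if (nrow(object@sampleData) != nrow(g))
    msg <- c(msg, "sampleData must have one row per individual")
  if (nrow(object@locusData) != ncol(g))
    msg <- c(msg, "locusData must have one row per locus")
  if (length(msg)) msg else TRUE
})

#' Construct a genotype matrix
#'
#' @param genotypes numeric/integer matrix of 0/1/2/`NA`; row and column
#'   names are taken as individual and locus ids (defaults supplied if
#'   absent).
#' @param sampleData optional data.frame of per-individual metadata.
#' @param locusData optional data.frame of per-locus metadata.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- genotypeMatrix(matrix(c(0, 1, 2, 0, NA, 2), nrow = 3))
#' observedHeterozygosity(g)
#' @export
genotypeMatrix <- function(genotypes, sampleData = NULL, locusData = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) && nrow(genotypes) > 0)
    rownames(genotypes) <- paste0("ind_", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)) && ncol(genotypes) > 0)
    colnames(genotypes) <- paste0("locus_", seq_len(ncol(genotypes)))
  if (is.null(sampleData))
    sampleData <- data.frame(id = rownames(genotypes))
  if (is.null(locusData))
    locusData <- data.frame(locus = colnames(genotypes))
  new("GenotypeMatrix", genotypes = genotypes,
      sampleData = as.data.frame(sampleData),
      locusData = as.data.frame(locusData))
}

#' Set of per-locus haplotype alignments
#'
#' Each element is a [Biostrings::DNAStringSet] of equal-length haplotypes
#' for one RAD locus; haplotype names carry the individual of origin
#' (`<id>_a` / `<id>_b`).
#'
#' @slot alignments named list of `DNAStringSet`, one per locus.
#' @seealso [locusAlignmentSet()], [nucleotideDiversity()], [tajimasD()]
#' @export
setClass("LocusAlignmentSet", representation(alignments = "list"))

setValidity("LocusAlignmentSet", function(object) {
  msg <- character()
  for (a in object@alignments) {
    if (!methods::is(a, "DNAStringSet")) {
      msg <- c(msg, "all elements must be DNAStringSet"); break
    }
    if (length(unique(Biostrings::width(a))) > 1) {
      msg <- c(msg, "haplotypes within a locus must have equal length"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a locus alignment set
#' @param alignments list of `DNAStringSet` (one per locus).
#' @return A [LocusAlignmentSet-class] object.
#' @export
locusAlignmentSet <- function(alignments) {
  if (length(alignments) && is.null(names(alignments)))
    names(alignments) <- paste0("locus_", seq_along(alignments))
  new("LocusAlignmentSet", alignments = alignments)
}

#' ABC reference table
#'
#' Rows of (model id, parameter vector, summary-statistic vector) simulated
#' from the priors, together with the statistic normalisation constants used
#' for rejection distances.
#'
#' @slot modelId character vector, one entry per simulated row.
#' @slot params numeric matrix; union of model parameters (`Nc`, `Nanc`,
#'   `Npost`, `Texp`) with `NA` where a parameter does not apply.
#' @slot stats numeric matrix of summary statistics.
#' @slot statSd per-statistic standard deviation over the full table.
#' @slot priors named list of `c(lower, upper)` prior bounds per parameter
#'   per model.
#' @slot spec the [SampleSpec-class] the rows were simulated under.
#' @seealso [buildReferenceTable()], [abcReject()]
#' @export
setClass("ReferenceTable",
  representation(modelId = "character", params = "matrix", stats = "matrix",
                 statSd = "numeric", priors = "list", spec = "SampleSpec"))

setValidity("ReferenceTable", function(object) {
  msg <- character()
  n <- length(object@modelId)
  if (nrow(object@params) != n || nrow(object@stats) != n)
    msg <- c(msg, "modelId, params and stats must have matching rows")
  if (length(object@statSd) != ncol(object@stats))
    msg <- c(msg, "statSd must have one entry per statistic")
  if (length(msg)) msg else TRUE
})

#' Model-choice result
#'
#' Posterior model probabilities under the rejection estimator (model
#' frequency among accepted simulations) and the weighted multinomial
#' logistic regression estimator, evaluated at the observed statistics.
#'
#' @slot rejection named probabilities (sum 1).
#' @slot logistic named probabilities (sum 1).
#' @slot nAccepted accepted rows per model.
#' @slot fallback TRUE if the logistic fit fell back to rejection.
#' @seealso [modelChoice()]
#' @export
setClass("ModelChoiceResult",
  representation(rejection = "numeric", logistic = "numeric",
                 nAccepted = "integer", fallback = "logical"))

setValidity("ModelChoiceResult", function(object) {
  msg <- character()
  for (p in list(object@rejection, object@logistic)) {
    if (any(p < -1e-9 | p > 1 + 1e-9) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "probabilities must lie in [0,1] and sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' ABC posterior for one demographic model
#'
#' Accepted parameter draws, their Beaumont local-linear regression
#' adjustment (on the logit scale defined by the prior bounds, so adjusted
#' draws respect the prior support), Epanechnikov weights, and weighted
#' 5/50/95 percent quantiles.
#'
#' @slot model model id the posterior refers to.
#' @slot accepted raw accepted parameter draws (rows).
#' @slot adjusted regression-adjusted draws, same shape.
#' @slot weights Epanechnikov weights on acceptance distance.
#' @slot distances acceptance distances (normalised Euclidean).
#' @slot threshold the largest accepted distance.
#' @slot quantiles parameters x c(q5, median, q95).
#' @slot priors prior bounds used for the logit transform.
#' @slot flags character; e.g. `"regression_fallback"` when the local-linear
#'   fit was singular and raw draws were kept.
#' @seealso [estimateParams()]
#' @export
setClass("ABCPosterior",
  representation(model = "character", accepted = "matrix",
                 adjusted = "matrix", weights = "numeric",
                 distances = "numeric", threshold = "numeric",
                 quantiles = "matrix", priors = "list", flags = "character"))

setValidity("ABCPosterior", function(object) {
  msg <- character()
  if (!all(dim(object@accepted) == dim(object@adjusted)))
    msg <- c(msg, "accepted and adjusted must have the same shape")
  if (length(object@weights) != nrow(object@accepted))
    msg <- c(msg, "one weight per accepted draw required")
  qs <- object@quantiles
  if (ncol(qs) == 3 && nrow(qs) &&
      any(qs[, 1] > qs[, 2] + 1e-9 | qs[, 2] > qs[, 3] + 1e-9))
    msg <- c(msg, "quantiles must be ordered q5 <= median <= q95")
  if (length(msg)) msg else TRUE
})
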