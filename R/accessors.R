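#' @rdname GenotypeMatrix-class
#' @param object,x a `GenotypeMatrix`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleData", "GenotypeMatrix", function(x) x@sampleData)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("locusData", function(x) standardGeneric("locusData"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("locusData", "GenotypeMatrix", function(x) x@locusData)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@genotypes))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nLoci", "GenotypeMatrix", function(x) ncol(x@genotypes))

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@genotypes
  cat("GenotypeMatrix:", nrow(g), "individuals x", ncol(g), "loci\n")
  cat("  missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(g))), "\n")
  extra <- setdiff(colnames(object@sampleData), "id")
  if (length(extra)) cat("  sample metadata:", paste(extra, collapse = ", "), "\n")
})

#' @rdname LocusAlignmentSet-class
#' @param x a `LocusAlignmentSet`.
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname LocusAlignmentSet-class
#' @export
setMethod("alignments", "LocusAlignmentSet", function(x) x@alignments)

#' @rdname LocusAlignmentSet-class
#' @export
setMethod("length", "LocusAlignmentSet", function(x) length(x@alignments))

setMethod("show", "LocusAlignmentSet", function(object) {
  a <- object@alignments
  w <- if (length(a)) range(vapply(a, function(s) Biostrings::width(s)[1],
                                   numeric(1))) else c(NA, NA)
  cat("LocusAlignmentSet:", length(a), "loci, widths",
      paste(unique(w), collapse = "-"), "bp\n")
})

setMethod("show", "DemographicScenario", function(object) {
  if (object@kind == "constant") {
    cat("DemographicScenario: constant, Nc =", object@Nc, "\n")
  } else {
    cat(sprintf("DemographicScenario: %s expansion, Nanc = %g -> Npost = %g at Texp = %g generations BP\n",
                object@kind, object@Nanc, object@Npost, object@Texp))
  }
})

setMethod("show", "SampleSpec", function(object) {
  cat(sprintf("SampleSpec: %d diploids, %d SNP loci, %d sequence loci (%d bp), missing rate %.2f\n",
              object@nDiploid, object@nSnpLoci, object@nSeqLoci,
              object@seqLocusLength, object@missingRate))
})

#' @rdname ReferenceTable-class
#' @param x,object a `ReferenceTable`.
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname ReferenceTable-class
#' @export
setMethod("modelId", "ReferenceTable", function(x) x@modelId)

#' @rdname ReferenceTable-class
#' @export
setGeneric("refParams", function(x) standardGeneric("refParams"))

#' @rdname ReferenceTable-class
#' @export
setMethod("refParams", "ReferenceTable", function(x) x@params)

#' @rdname ReferenceTable-class
#' @export
setGeneric("refStats", function(x) standardGeneric("refStats"))

#' @rdname ReferenceTable-class
#' @export
setMethod("refStats", "ReferenceTable", function(x) x@stats)

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", length(object@modelId), "rows,",
      ncol(object@stats), "summary statistics\n")
  print(table(object@modelId))
})

setMethod("show", "ModelChoiceResult", function(object) {
  cat("ModelChoiceResult (posterior model probabilities)\n")
  out <- rbind(rejection = object@rejection, logistic = object@logistic)
  print(round(out, 4))
  if (object@fallback)
    cat("  note: logistic fit fell back to rejection probabilities\n")
})

#' @rdname ABCPosterior-class
#' @param x,object an `ABCPosterior`.
#' @export
setGeneric("posteriorQuantiles", function(x) standardGeneric("posteriorQuantiles"))

#' @rdname ABCPosterior-class
#' @export
setMethod("posteriorQuantiles", "ABCPosterior", function(x) x@quantiles)

#' @rdname ABCPosterior-class
#' @export
setGeneric("adjustedDraws", function(x) standardGeneric("adjustedDraws"))

#' @rdname ABCPosterior-class
#' @export
setMethod("adjustedDraws", "ABCPosterior", function(x) x@adjusted)

#' @rdname ABCPosterior-class
#' @export
setGeneric("posteriorWeights", function(x) standardGeneric("posteriorWeights"))

#' @rdname ABCPosterior-class
#' @export
setMethod("posteriorWeights", "ABCPosterior", function(x) x@weights)

setMethod("show", "ABCPosterior", function(object) {
  cat("ABCPosterior for model '", object@model, "' (",
      nrow(object@accepted), " accepted draws)\n", sep = "")
  print(signif(object@quantiles, 4))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
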