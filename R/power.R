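# Power analysis: accuracy of ABC model choice and parameter estimation as
# a function of the number of SNPs genotyped.

#' Design of a power analysis over SNP counts
#'
#' Defaults follow the motivating simulation study: an expansion from
#' 10,000 to 100,000 diploids at 28,000 generations BP, 20 sampled
#' individuals, SNP counts 500/1000/2000/3000 with five replicate observed
#' datasets per count. `nSimsPerModel` defaults to a desk-scale 10,000
#' (scaled down from the study's one million).
#'
#' @param snpCounts strictly increasing SNP counts.
#' @param replicates replicate observed datasets per count (>= 2 for SDs).
#' @param truth a [DemographicScenario-class] used to generate observed
#'   data.
#' @param nDiploid diploid individuals sampled.
#' @param nSimsPerModel reference-table simulations per model.
#' @param nAccept rejection acceptance count.
#' @param models models entered in the reference table.
#' @param priors prior bounds ([defaultPriors()]).
#' @return A named list of class `"powerDesign"`.
#' @export
powerDesign <- function(snpCounts = c(500, 1000, 2000, 3000),
                        replicates = 5,
                        truth = demographicScenario("lgm", Nanc = 1e4,
                                                    Npost = 1e5,
                                                    Texp = 28000),
                        nDiploid = 20, nSimsPerModel = 10000, nAccept = 500,
                        models = c("constant", "lgm", "interglacial"),
                        priors = defaultPriors()) {
  if (any(diff(snpCounts) <= 0)) stop("snpCounts must be strictly increasing")
  if (replicates < 2) stop("need >= 2 replicates per SNP count")
  structure(list(snpCounts = snpCounts, replicates = replicates,
                 truth = truth, nDiploid = nDiploid,
                 nSimsPerModel = nSimsPerModel, nAccept = nAccept,
                 models = models, priors = priors),
            class = "powerDesign")
}

#' Run the power analysis
#'
#' For each SNP count, builds one reference table and, for each replicate,
#' simulates an observed dataset from the truth scenario, performs model
#' choice and estimates the expansion parameters. Posterior medians are
#' always taken under the truth-kind expansion model so that replicates are
#' aggregable; model misidentifications are counted separately. A failed
#' replicate is recorded (`NA` row), not fatal.
#'
#' @param design a [powerDesign()].
#' @param seed optional integer seed.
#' @return List of class `"powerReport"` with `medians` (one row per
#'   replicate: snpCount, replicate, bestModel, posterior medians),
#'   `summary` (per snpCount x parameter: mean and SD of medians) and
#'   `misidentified` (per snpCount).
#' @export
runPower <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(design, "powerDesign"))
  truthModel <- design$truth@kind
  pnames <- .modelParamNames[[truthModel]]
  rows <- list()
  misid <- stats::setNames(integer(length(design$snpCounts)),
                           design$snpCounts)
  for (sc in design$snpCounts) {
    spec <- sampleSpec(nDiploid = design$nDiploid, nSnpLoci = sc)
    tab <- buildReferenceTable(design$models, spec,
                               design$nSimsPerModel, design$priors)
    for (r in seq_len(design$replicates)) {
      row <- tryCatch({
        obs <- simulateDataset(design$truth, spec)
        sObs <- abcStats(obs$genotypes)
        mc <- modelChoice(tab, sObs, design$nAccept)
        best <- names(which.max(mc@rejection))
        if (best != truthModel)
          misid[as.character(sc)] <- misid[as.character(sc)] + 1L
        post <- estimateParams(tab, sObs, truthModel, design$nAccept)
        med <- posteriorQuantiles(post)[, "median"]
        c(list(snpCount = sc, replicate = r, bestModel = best),
          as.list(med))
      }, error = function(e) {
        warning("replicate failed (snpCount=", sc, ", rep=", r, "): ",
                conditionMessage(e))
        c(list(snpCount = sc, replicate = r, bestModel = NA_character_),
          stats::setNames(as.list(rep(NA_real_, length(pnames))), pnames))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  medians <- do.call(rbind, lapply(rows, as.data.frame))
  agg <- do.call(rbind, lapply(split(medians, medians$snpCount), function(df) {
    do.call(rbind, lapply(pnames, function(p) {
      data.frame(snpCount = df$snpCount[1], parameter = p,
                 mean = mean(df[[p]], na.rm = TRUE),
                 sd = stats::sd(df[[p]], na.rm = TRUE))
    }))
  }))
  rownames(agg) <- NULL
  structure(list(medians = medians, summary = agg, misidentified = misid,
                 truth = design$truth),
            class = "powerReport")
}

#' Monotonicity of estimation spread with SNP count
#'
#' Spearman rank correlation of the across-replicate SD of posterior
#' medians against SNP count, per parameter; the verdict is `"decreasing"`
#' when rho < 0.
#'
#' @param report a `"powerReport"` from [runPower()].
#' @return data.frame with `parameter`, `rho`, `decreasing`.
#' @export
summarizeSdTrend <- function(report) {
  stopifnot(inherits(report, "powerReport"))
  s <- report$summary
  if (length(unique(s$snpCount)) < 3)
    stop("need >= 3 SNP counts for a trend")
  out <- do.call(rbind, lapply(split(s, s$parameter), function(df) {
    df <- df[is.finite(df$sd), ]
    rho <- suppressWarnings(
      stats::cor(df$snpCount, df$sd, method = "spearman"))
    data.frame(parameter = df$parameter[1], rho = rho,
               decreasing = is.finite(rho) && rho < 0)
  }))
  rownames(out) <- NULL
  out
}
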