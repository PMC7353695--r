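# DIYABC-style approximate Bayesian computation: reference tables,
# rejection, model choice (rejection frequency + weighted multinomial
# logistic regression), Beaumont local-linear parameter adjustment on the
# logit scale, and the validation machinery (posterior-predictive check,
# pseudo-observed error rate, bias/precision).

.modelParamNames <- list(constant = "Nc",
                         lgm = c("Nanc", "Npost", "Texp"),
                         interglacial = c("Nanc", "Npost", "Texp"))
.allParamNames <- c("Nc", "Nanc", "Npost", "Texp")

#' Default uniform priors for the three demographic models
#'
#' Bounds in natural units (diploid effective sizes; generations). The
#' expansion-time windows follow the glaciological framing of the models:
#' the glacial-onset expansion is constrained to the last glaciation
#' (10,000-40,000 generations BP) and the interglacial expansion to the
#' last interglacial (110,000-130,000 generations BP).
#'
#' @return Named list (per model) of named lists of `c(lower, upper)`.
#' @export
defaultPriors <- function() {
  list(constant = list(Nc = c(100, 200000)),
       lgm = list(Nanc = c(100, 30000), Npost = c(10000, 200000),
                  Texp = c(10000, 40000)),
       interglacial = list(Nanc = c(100, 30000), Npost = c(10000, 200000),
                           Texp = c(110000, 130000)))
}

.checkPriors <- function(priors) {
  for (m in names(priors)) for (p in names(priors[[m]])) {
    b <- priors[[m]][[p]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("degenerate prior for ", m, "$", p,
           ": need 0 < lower < upper")
  }
  invisible(priors)
}

# draw nSims parameter vectors for one model; columns = union parameters
.drawParams <- function(model, priors, nSims) {
  out <- matrix(NA_real_, nSims, length(.allParamNames),
                dimnames = list(NULL, .allParamNames))
  for (p in .modelParamNames[[model]]) {
    b <- priors[[model]][[p]]
    out[, p] <- stats::runif(nSims, b[1], b[2])
  }
  out
}

.scenarioFor <- function(model, params) {
  if (model == "constant") {
    demographicScenario("constant", Nc = params[["Nc"]])
  } else {
    demographicScenario(model, Nanc = params[["Nanc"]],
                        Npost = params[["Npost"]], Texp = params[["Texp"]])
  }
}

# batch summary-statistic simulation for one model (compiled kernel)
.simStats <- function(model, params, spec) {
  n <- nrow(params)
  kind <- rep(if (model == "constant") 0L else 1L, n)
  z <- function(x) ifelse(is.na(x), 0, x)
  s <- cpp_ref_stats(2L * spec@nDiploid, spec@nSnpLoci, kind,
                     z(params[, "Nc"]), z(params[, "Nanc"]),
                     z(params[, "Npost"]),
                     ifelse(is.na(params[, "Texp"]), Inf, params[, "Texp"]))
  colnames(s) <- c("propMono", "meanH", "varH", "meanMAF")
  s
}

#' Build an ABC reference table
#'
#' Draws parameters from the uniform priors, simulates a SNP dataset per
#' draw under the corresponding demographic scenario, and records the
#' four-statistic summary vector ([abcStats()] definition, computed by the
#' same kernel used for observed data).
#'
#' @param models character vector of model ids among `"constant"`, `"lgm"`,
#'   `"interglacial"`.
#' @param spec a [SampleSpec-class] matching the observed data (individuals
#'   and SNP count).
#' @param nSimsPerModel simulations per model (>= 1000 for inference use).
#' @param priors prior bounds, see [defaultPriors()].
#' @param seed optional integer seed.
#' @return A [ReferenceTable-class].
#' @examples
#' tab <- buildReferenceTable("constant", sampleSpec(10, 50),
#'                            nSimsPerModel = 100, seed = 1)
#' tab
#' @export
buildReferenceTable <- function(models = c("constant", "lgm", "interglacial"),
                                spec = sampleSpec(),
                                nSimsPerModel = 10000,
                                priors = defaultPriors(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  models <- match.arg(models, c("constant", "lgm", "interglacial"),
                      several.ok = TRUE)
  .checkPriors(priors[models])
  params <- NULL; stats <- NULL; ids <- character(0)
  for (m in models) {
    pm <- .drawParams(m, priors, nSimsPerModel)
    sm <- .simStats(m, pm, spec)
    params <- rbind(params, pm)
    stats <- rbind(stats, sm)
    ids <- c(ids, rep(m, nSimsPerModel))
  }
  sds <- apply(stats, 2, stats::sd)
  if (any(sds <= 1e-12))
    message("zero-variance statistics excluded from distances: ",
            paste(colnames(stats)[sds <= 1e-12], collapse = ", "))
  new("ReferenceTable", modelId = ids, params = params, stats = stats,
      statSd = sds, priors = priors[models], spec = spec)
}

# standardized coordinates for distance computation; drops zero-sd stats
.standardize <- function(table, sObs) {
  keep <- which(table@statSd > 1e-12 & is.finite(table@statSd))
  sObs <- sObs[colnames(table@stats)]
  list(Z = sweep(table@stats[, keep, drop = FALSE], 2, table@statSd[keep],
                 "/"),
       zObs = sObs[keep] / table@statSd[keep], keep = keep)
}

#' Rejection step: closest simulations to the observed statistics
#'
#' Euclidean distance on statistics standardised by the reference-table
#' standard deviations (zero-variance statistics dropped); returns the
#' `nAccept` closest rows, ties broken by row index.
#'
#' @param table a [ReferenceTable-class].
#' @param sObs observed summary-statistic vector ([abcStats()]).
#' @param nAccept number of rows to accept (default 500).
#' @return List with `indices`, `distances` (sorted), `model` (per accepted
#'   row), `params`, `threshold` (largest accepted distance).
#' @export
abcReject <- function(table, sObs, nAccept = 500) {
  n <- length(table@modelId)
  if (nAccept > n) stop("nAccept exceeds reference-table size")
  st <- .standardize(table, sObs)
  d <- sqrt(rowSums(sweep(st$Z, 2, st$zObs, "-")^2))
  idx <- order(d)[seq_len(nAccept)]
  list(indices = idx, distances = d[idx], model = table@modelId[idx],
       params = table@params[idx, , drop = FALSE], threshold = max(d[idx]))
}

.epanechnikov <- function(d) {
  dmax <- max(d) * (1 + 1e-8)
  if (dmax == 0) return(rep(1, length(d)))
  1 - (d / dmax)^2
}

#' Posterior model probabilities
#'
#' Rejection estimate: each model's frequency among the accepted
#' simulations. Logistic estimate: weighted multinomial logistic regression
#' (Epanechnikov weights in acceptance distance) of the model indicator on
#' the standardised statistic deviations, evaluated at the observed point.
#' If any model present in the accepted set has fewer than 2 rows, or the
#' fit fails, the logistic estimate falls back to the rejection estimate
#' (flagged).
#'
#' @inheritParams abcReject
#' @return A [ModelChoiceResult-class].
#' @export
modelChoice <- function(table, sObs, nAccept = 500) {
  acc <- abcReject(table, sObs, nAccept)
  models <- unique(table@modelId)
  cnt <- vapply(models, function(m) sum(acc$model == m), numeric(1))
  rejection <- cnt / sum(cnt)
  st <- .standardize(table, sObs)
  X <- sweep(st$Z[acc$indices, , drop = FALSE], 2, st$zObs, "-")
  w <- .epanechnikov(acc$distances)
  present <- models[cnt > 0]
  fallback <- FALSE
  if (length(present) == 1) {
    logistic <- rejection
  } else if (any(cnt[cnt > 0] < 2)) {
    logistic <- rejection; fallback <- TRUE
  } else {
    df <- data.frame(mod = factor(acc$model, levels = present), X)
    fit <- tryCatch(
      nnet::multinom(mod ~ ., data = df, weights = w, trace = FALSE,
                     maxit = 500),
      error = function(e) NULL)
    if (is.null(fit)) {
      logistic <- rejection; fallback <- TRUE
    } else {
      nd <- as.data.frame(matrix(0, 1, ncol(X)))
      colnames(nd) <- colnames(df)[-1]
      pr <- predict(fit, newdata = nd, type = "probs")
      logistic <- stats::setNames(rep(0, length(models)), models)
      if (length(present) == 2) {
        logistic[present] <- c(1 - pr, pr)
      } else {
        logistic[colnames(t(pr))] <- as.numeric(pr)
      }
      logistic <- logistic / sum(logistic)
    }
  }
  new("ModelChoiceResult", rejection = rejection,
      logistic = stats::setNames(as.numeric(logistic), models),
      nAccepted = stats::setNames(as.integer(cnt), models),
      fallback = fallback)
}

.logitTransform <- function(theta, lo, hi) {
  u <- (theta - lo) / (hi - lo)
  u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
  stats::qlogis(u)
}

.logitBack <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Weighted quantiles
#' @param x numeric values.
#' @param w non-negative weights.
#' @param probs quantile levels.
#' @return Numeric vector of quantiles.
#' @export
weightedQuantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(q) x[which(cw >= q)[1]], numeric(1))
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Accepts the `nAccept` simulations of one model closest to the observed
#' statistics, maps each parameter to the logit scale defined by its prior
#' bounds, fits an Epanechnikov-weighted linear regression of the
#' transformed parameters on the standardised statistic deviations, and
#' adjusts each draw to the observed point
#' (`theta* = theta - beta' (s - s_obs)`), back-transforming afterwards so
#' adjusted draws always respect the prior support. Reports weighted 5/50/95
#' percent quantiles of the adjusted draws. A singular design falls back to
#' the unadjusted rejection posterior (flagged).
#'
#' @inheritParams abcReject
#' @param model model id whose parameters are estimated; the rejection step
#'   is restricted to that model's rows.
#' @return An [ABCPosterior-class].
#' @export
estimateParams <- function(table, sObs, model, nAccept = 500) {
  rows <- which(table@modelId == model)
  if (!length(rows)) stop("model not present in reference table")
  sub <- new("ReferenceTable", modelId = table@modelId[rows],
             params = table@params[rows, , drop = FALSE],
             stats = table@stats[rows, , drop = FALSE],
             statSd = table@statSd, priors = table@priors,
             spec = table@spec)
  nAccept <- min(nAccept, length(rows))
  acc <- abcReject(sub, sObs, nAccept)
  pnames <- .modelParamNames[[model]]
  theta <- acc$params[, pnames, drop = FALSE]
  pri <- table@priors[[model]]
  lo <- vapply(pnames, function(p) pri[[p]][1], numeric(1))
  hi <- vapply(pnames, function(p) pri[[p]][2], numeric(1))
  Y <- vapply(seq_along(pnames),
              function(k) .logitTransform(theta[, k], lo[k], hi[k]),
              numeric(nrow(theta)))
  Y <- matrix(Y, nrow = nrow(theta),
              dimnames = list(NULL, pnames))
  st <- .standardize(sub, sObs)
  X <- sweep(st$Z[acc$indices, , drop = FALSE], 2, st$zObs, "-")
  w <- .epanechnikov(acc$distances)
  flags <- character(0)
  design <- cbind(Intercept = 1, X)
  fit <- stats::lm.wfit(design, Y, w)
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))
    coefs <- matrix(coefs, ncol = ncol(Y),
                    dimnames = list(colnames(design), colnames(Y)))
  if (fit$rank < ncol(design) || anyNA(coefs)) {
    adjT <- Y
    flags <- "regression_fallback"
  } else {
    adjT <- Y - X %*% coefs[-1, , drop = FALSE]
  }
  adjusted <- vapply(seq_along(pnames),
                     function(k) .logitBack(adjT[, k], lo[k], hi[k]),
                     numeric(nrow(adjT)))
  adjusted <- matrix(adjusted, nrow = nrow(adjT),
                     dimnames = list(NULL, pnames))
  qs <- t(vapply(pnames, function(p)
    weightedQuantile(adjusted[, p], w, c(0.05, 0.5, 0.95)), numeric(3)))
  colnames(qs) <- c("q5", "median", "q95")
  new("ABCPosterior", model = model, accepted = theta, adjusted = adjusted,
      weights = w, distances = acc$distances, threshold = acc$threshold,
      quantiles = qs, priors = pri, flags = flags)
}

#' Posterior-predictive check
#'
#' Simulates datasets from parameters sampled (with posterior weights) from
#' the adjusted posterior and reports the percentile rank of each observed
#' statistic in the posterior-predictive cloud. The observed data are
#' declared "within the posterior space" when every percentile lies in
#' (0.5, 99.5).
#'
#' @param posterior an [ABCPosterior-class].
#' @param spec the [SampleSpec-class] of the observed data.
#' @param sObs observed summary statistics.
#' @param nDraws posterior-predictive simulations (default 500).
#' @param seed optional integer seed.
#' @return List with `percentiles` (per statistic), `within` (logical) and
#'   `stats` (the simulated cloud).
#' @export
ppcCheck <- function(posterior, spec, sObs, nDraws = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- sample.int(nrow(posterior@adjusted), nDraws, replace = TRUE,
                     prob = posterior@weights)
  pm <- matrix(NA_real_, nDraws, length(.allParamNames),
               dimnames = list(NULL, .allParamNames))
  pm[, colnames(posterior@adjusted)] <- posterior@adjusted[draw, , drop = FALSE]
  sims <- .simStats(posterior@model, pm, spec)
  sObs <- sObs[colnames(sims)]
  # mid-percentile: ties (e.g. a statistic degenerate in both cloud and
  # observation) contribute half, placing an exact match at 50
  pct <- vapply(seq_along(sObs),
                function(k) 100 * (mean(sims[, k] < sObs[k]) +
                                   0.5 * mean(sims[, k] == sObs[k])),
                numeric(1))
  names(pct) <- colnames(sims)
  list(percentiles = pct, within = all(pct > 0.5 & pct < 99.5),
       stats = sims)
}

#' Posterior error rate from pseudo-observed data
#'
#' Samples (with replacement) models and parameter values from the
#' `nAccept` simulations closest to the observed data, generates a fresh
#' pseudo-observed dataset from each, reruns rejection model choice against
#' the reference table (the source row excluded), and reports the fraction
#' of pseudo-observed datasets whose true model is not the top model.
#'
#' @inheritParams abcReject
#' @param nPseudo number of pseudo-observed datasets (default 500).
#' @param resimulate if `FALSE`, the sampled row's own statistics are used
#'   as the pseudo-observation instead of simulating a fresh dataset.
#' @param seed optional integer seed.
#' @return List with `errorRate`, `nPseudo` and `topModel` (per pseudo
#'   dataset).
#' @export
posteriorErrorRate <- function(table, sObs, nPseudo = 500, nAccept = 500,
                               resimulate = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nPseudo < 1) stop("nPseudo must be >= 1")
  acc <- abcReject(table, sObs, nAccept)
  pick <- sample(acc$indices, nPseudo, replace = TRUE)
  models <- unique(table@modelId)
  if (resimulate) {
    pstats <- matrix(NA_real_, nPseudo, ncol(table@stats),
                     dimnames = list(NULL, colnames(table@stats)))
    for (m in models) {
      sel <- which(table@modelId[pick] == m)
      if (!length(sel)) next
      pstats[sel, ] <- .simStats(m, table@params[pick[sel], , drop = FALSE],
                                 table@spec)
    }
  } else {
    pstats <- table@stats[pick, , drop = FALSE]
  }
  keep <- which(table@statSd > 1e-12 & is.finite(table@statSd))
  Z <- sweep(table@stats[, keep, drop = FALSE], 2, table@statSd[keep], "/")
  top <- character(nPseudo)
  for (i in seq_len(nPseudo)) {
    z <- pstats[i, keep] / table@statSd[keep]
    d <- sqrt(rowSums(sweep(Z, 2, z, "-")^2))
    d[pick[i]] <- Inf  # exclude the source row when scoring
    sel <- order(d)[seq_len(nAccept)]
    cnt <- vapply(models, function(m) sum(table@modelId[sel] == m),
                  numeric(1))
    top[i] <- models[which.max(cnt)]  # ties broken by model order
  }
  truth <- table@modelId[pick]
  list(errorRate = mean(top != truth), nPseudo = nPseudo, topModel = top,
       trueModel = truth)
}

#' Bias and precision of parameter estimation
#'
#' Draws true parameter values from the fitted posterior, simulates a
#' dataset from each, re-estimates the parameters against the same
#' reference table, and reports per-parameter mean relative bias
#' `mean((median_hat - truth) / truth)` and relative RMSE.
#'
#' @param posterior an [ABCPosterior-class] for the chosen model.
#' @param table the [ReferenceTable-class] used for re-estimation.
#' @param nDatasets simulated validation datasets (default 500).
#' @param nAccept acceptance count for re-estimation.
#' @param estimator optional override: `function(sObs)` returning a named
#'   vector of parameter medians (used to stub the estimator in tests).
#' @param seed optional integer seed.
#' @return List with `relativeBias`, `relativeRmse` (named per parameter)
#'   and `nDatasets`.
#' @export
biasPrecision <- function(posterior, table, nDatasets = 500, nAccept = 500,
                          estimator = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- posterior@model
  pnames <- colnames(posterior@adjusted)
  draw <- sample.int(nrow(posterior@adjusted), nDatasets, replace = TRUE,
                     prob = posterior@weights)
  truths <- posterior@adjusted[draw, , drop = FALSE]
  pm <- matrix(NA_real_, nDatasets, length(.allParamNames),
               dimnames = list(NULL, .allParamNames))
  pm[, pnames] <- truths
  sims <- .simStats(model, pm, table@spec)
  rel <- matrix(NA_real_, nDatasets, length(pnames),
                dimnames = list(NULL, pnames))
  for (i in seq_len(nDatasets)) {
    est <- if (is.null(estimator)) {
      posteriorQuantiles(estimateParams(table, sims[i, ], model,
                                        nAccept))[, "median"]
    } else {
      estimator(sims[i, ])
    }
    rel[i, ] <- (est[pnames] - truths[i, ]) / truths[i, ]
  }
  list(relativeBias = colMeans(rel),
       relativeRmse = sqrt(colMeans(rel^2)),
       nDatasets = nDatasets)
}

#' One-call ABC fit
#'
#' Convenience wrapper: model choice over the reference table, then
#' parameter estimation for the model with the highest rejection posterior
#' probability.
#'
#' @inheritParams abcReject
#' @param g optional [GenotypeMatrix-class]; when supplied, `sObs` is
#'   computed as `abcStats(g)`.
#' @return List with `modelChoice` ([ModelChoiceResult-class]), `bestModel`
#'   and `posterior` ([ABCPosterior-class]).
#' @export
abcFit <- function(table, sObs = NULL, g = NULL, nAccept = 500) {
  if (is.null(sObs)) {
    if (is.null(g)) stop("supply sObs or g")
    sObs <- abcStats(g)
  }
  mc <- modelChoice(table, sObs, nAccept)
  best <- names(which.max(mc@rejection))
  list(modelChoice = mc, bestModel = best,
       posterior = estimateParams(table, sObs, best, nAccept))
}
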