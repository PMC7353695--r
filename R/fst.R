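# Weir & Cockerham (1984) theta with a permutation test for differentiation.

# Variance components for two samples of diploid genotype columns.
# Returns multi-locus ratio-of-sums theta. Loci with fewer than two
# non-missing genotypes in either group are dropped pairwise.
.wcTheta <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  keep <- n1 >= 2 & n2 >= 2
  if (!any(keep)) return(NA_real_)
  g1 <- g1[, keep, drop = FALSE]; g2 <- g2[, keep, drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- sum(a + b + cc)
  if (denom == 0) return(NA_real_)
  sum(a) / denom
}

#' Pairwise F_ST with permutation tests
#'
#' Weir & Cockerham (1984) multi-locus theta (ratio of sums of the a, b, c
#' variance components across loci) for every pair of groups, with a
#' permutation test: individuals of the two groups are relabelled at random
#' and `p = (# permuted theta >= observed + 1) / (nPerm + 1)`.
#'
#' @param g a [GenotypeMatrix-class].
#' @param groups group label per individual: either the name of a
#'   `sampleData` column or a vector of length `nIndividuals(g)`.
#' @param nPerm permutations per pair (default 10000).
#' @param seed optional integer seed.
#' @return List with symmetric matrices `theta` and `p` (p has `NA` on the
#'   diagonal).
#' @export
pairwiseFst <- function(g, groups, nPerm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- genotypes(g)
  if (is.character(groups) && length(groups) == 1)
    groups <- sampleData(g)[[groups]]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(gm))
  levs <- unique(groups)
  if (length(levs) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 individuals")
  theta <- matrix(0, length(levs), length(levs),
                  dimnames = list(levs, levs))
  pval <- matrix(NA_real_, length(levs), length(levs),
                 dimnames = list(levs, levs))
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    idx1 <- which(groups == levs[i]); idx2 <- which(groups == levs[j])
    obs <- .wcTheta(gm[idx1, , drop = FALSE], gm[idx2, , drop = FALSE])
    cnt <- 0L
    pool <- c(idx1, idx2)
    for (b in seq_len(nPerm)) {
      perm <- sample(pool)
      t1 <- perm[seq_along(idx1)]
      t2 <- perm[-seq_along(idx1)]
      tb <- .wcTheta(gm[t1, , drop = FALSE], gm[t2, , drop = FALSE])
      if (!is.na(tb) && tb >= obs) cnt <- cnt + 1L
    }
    theta[i, j] <- theta[j, i] <- obs
    pval[i, j] <- pval[j, i] <- (cnt + 1) / (nPerm + 1)
  }
  list(theta = theta, p = pval)
}

#' Pairwise differentiation table
#'
#' Combined table in the supplementary-table layout: Weir-Cockerham F_ST
#' (with permutation p-values) in the lower triangle, Dxy in the upper
#' triangle.
#'
#' @inheritParams pairwiseFst
#' @param x optional [LocusAlignmentSet-class] for sequence-based Dxy; when
#'   `NULL`, Dxy is computed per SNP from the genotype matrix.
#' @return List with `combined` (matrix: F_ST below, Dxy above), `p`
#'   (F_ST permutation p-values).
#' @export
pairwiseDiffMatrix <- function(g, groups, x = NULL, nPerm = 10000,
                               seed = NULL) {
  fst <- pairwiseFst(g, groups, nPerm = nPerm, seed = seed)
  if (is.character(groups) && length(groups) == 1)
    groups <- sampleData(g)[[groups]]
  grp <- stats::setNames(as.character(groups), rownames(genotypes(g)))
  dx <- if (is.null(x)) dxy(g, grp) else dxy(x, grp)
  comb <- fst$theta
  comb[upper.tri(comb)] <- dx[upper.tri(dx)]
  list(combined = comb, p = fst$p)
}

#' Nei's (1972) standard genetic distance
#'
#' `D = -ln I` with `I = sum_l J12 / sqrt(sum_l J11 * sum_l J22)` where
#' `J` are the locus-wise sums of allele-frequency products. In
#' `units = "individuals"` mode each individual's allele frequencies are
#' 0, 0.5 or 1 and loci missing in either member of a pair are dropped for
#' that pair.
#'
#' @param g a [GenotypeMatrix-class].
#' @param units `"individuals"` (distance between all individual pairs,
#'   the PCoA/Mantel input) or `"groups"`.
#' @param groups required for `units = "groups"`; see [pairwiseFst()].
#' @param cap finite distance reported when `I = 0` (no shared alleles);
#'   default 50, with a warning.
#' @return Symmetric distance matrix.
#' @export
neisDistance <- function(g, units = c("individuals", "groups"),
                         groups = NULL, cap = 50) {
  units <- match.arg(units)
  gm <- genotypes(g)
  if (units == "individuals") {
    P <- gm / 2
    n <- nrow(P)
    out <- matrix(0, n, n, dimnames = list(rownames(gm), rownames(gm)))
  } else {
    if (is.character(groups) && length(groups) == 1)
      groups <- sampleData(g)[[groups]]
    groups <- as.character(groups)
    levs <- unique(groups)
    P <- t(vapply(levs, function(lv) {
      sub <- gm[groups == lv, , drop = FALSE]
      colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
    }, numeric(ncol(gm))))
    rownames(P) <- levs
    n <- nrow(P)
    out <- matrix(0, n, n, dimnames = list(levs, levs))
  }
  capped <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(P[i, ]) & !is.na(P[j, ])
    p1 <- P[i, ok]; p2 <- P[j, ok]
    j12 <- sum(p1 * p2 + (1 - p1) * (1 - p2))
    j11 <- sum(p1^2 + (1 - p1)^2)
    j22 <- sum(p2^2 + (1 - p2)^2)
    I <- j12 / sqrt(j11 * j22)
    d <- if (I <= 0) { capped <- TRUE; cap } else min(-log(I), cap)
    out[i, j] <- out[j, i] <- d
  }
  if (capped) warning("pairs with no shared alleles capped at D = ", cap)
  out
}
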