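# Sequence-based statistics (nucleotide diversity, Tajima's D, Dxy, net
# p-distance) on per-locus haplotype alignments. Sites that are not A/C/G/T
# in either member of a pair are excluded from that pair (pairwise deletion).

.alnMatrix <- function(a) {
  m <- as.matrix(a)
  mode(m) <- "character"
  m
}

# total and mean pairwise differences within one alignment
.pairwiseDiffs <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("alignment needs >= 2 haplotypes")
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  tot <- 0
  npairs <- n * (n - 1) / 2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      tot <- tot + sum(m[i, ok] != m[j, ok])
    }
  }
  list(total = tot, mean = tot / npairs, nPairs = npairs)
}

# mean pairwise differences between rows of m1 and rows of m2
.betweenDiffs <- function(m1, m2) {
  stopifnot(ncol(m1) == ncol(m2))
  v1 <- m1 %in% c("A", "C", "G", "T"); dim(v1) <- dim(m1)
  v2 <- m2 %in% c("A", "C", "G", "T"); dim(v2) <- dim(m2)
  tot <- 0
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(nrow(m2))) {
      ok <- v1[i, ] & v2[j, ]
      tot <- tot + sum(m1[i, ok] != m2[j, ok])
    }
  }
  tot / (nrow(m1) * nrow(m2))
}

.asAlignmentList <- function(a) {
  if (methods::is(a, "LocusAlignmentSet")) alignments(a)
  else if (methods::is(a, "DNAStringSet")) list(locus_1 = a)
  else stop("expected a LocusAlignmentSet or DNAStringSet")
}

#' Nucleotide diversity
#'
#' Per-site nucleotide diversity pooled across loci: the sum over loci of
#' mean pairwise differences, divided by the total alignment length.
#'
#' @param a a [LocusAlignmentSet-class] or a single
#'   [Biostrings::DNAStringSet].
#' @return List with `pi` (pooled per-site), `perLocus` (mean pairwise
#'   differences per locus, absolute), `totalLength` (bp).
#' @export
nucleotideDiversity <- function(a) {
  alns <- .asAlignmentList(a)
  if (!length(alns)) stop("empty alignment set")
  perLocus <- vapply(alns, function(x) .pairwiseDiffs(.alnMatrix(x))$mean,
                     numeric(1))
  lens <- vapply(alns, function(x) Biostrings::width(x)[1], numeric(1))
  list(pi = sum(perLocus) / sum(lens), perLocus = perLocus,
       totalLength = sum(lens))
}

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.segSites <- function(m) {
  valid <- m %in% c("A", "C", "G", "T"); dim(valid) <- dim(m)
  sum(apply(m, 2, function(col) {
    b <- unique(col[col %in% c("A", "C", "G", "T")])
    length(b) > 1
  }))
}

#' Tajima's D
#'
#' Standard Tajima (1989) statistic per locus and pooled across loci
#' (totals of segregating sites and mean pairwise differences; all loci
#' must share the same haplotype count for the pooled value). Loci with no
#' segregating sites have undefined D (`NA`) and are excluded from pooling
#' totals only through their zero contribution.
#'
#' @inheritParams nucleotideDiversity
#' @return List with `perLocus` (named numeric, `NA` where S = 0), `pooled`
#'   (single D over totals) and `S` (total segregating sites).
#' @export
tajimasD <- function(a) {
  alns <- .asAlignmentList(a)
  ns <- vapply(alns, base::length, numeric(1))
  S <- numeric(length(alns)); piTot <- numeric(length(alns))
  for (k in seq_along(alns)) {
    m <- .alnMatrix(alns[[k]])
    S[k] <- .segSites(m)
    piTot[k] <- .pairwiseDiffs(m)$mean
  }
  dOne <- function(S, piT, n) {
    if (S < 1 || n < 3) return(NA_real_)
    cst <- .tajimaConstants(n)
    (piT - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  }
  perLocus <- mapply(dOne, S, piTot, ns)
  names(perLocus) <- names(alns)
  pooled <- if (length(unique(ns)) == 1) {
    unname(dOne(sum(S), sum(piTot), ns[[1]]))
  } else {
    warning("unequal haplotype counts across loci; pooled D not computed")
    NA_real_
  }
  list(perLocus = perLocus, pooled = pooled, S = sum(S))
}

#' Sequence summary table
#'
#' Mirrors the sequence-based diversity table layout: total length,
#' pooled per-site nucleotide diversity, pooled Tajima's D, segregating
#' sites.
#'
#' @inheritParams nucleotideDiversity
#' @return A one-row data.frame.
#' @export
seqSummary <- function(a) {
  nd <- nucleotideDiversity(a)
  td <- tajimasD(a)
  data.frame(totalLength = nd$totalLength, pi = nd$pi,
             tajimasD = td$pooled, S = td$S)
}

.haplotypeGroups <- function(aln, groups) {
  ids <- sub("_[ab]$", "", names(aln))
  if (is.null(names(groups))) stop("groups must be named by individual id")
  grp <- groups[ids]
  if (anyNA(grp)) stop("haplotypes present with no group assignment")
  grp
}

#' Between-group sequence divergence (Dxy)
#'
#' Average number of nucleotide substitutions per site between populations:
#' the mean over all between-group haplotype pairs of pairwise differences,
#' pooled over the total alignment length.
#'
#' @param x a [LocusAlignmentSet-class] (haplotypes named `<id>_a`/`<id>_b`)
#'   or a [GenotypeMatrix-class]. For a genotype matrix, each SNP locus is
#'   treated as a 1-bp site, so the result is per SNP.
#' @param groups named character/factor: group per individual id.
#' @return Symmetric matrix of Dxy values over group pairs.
#' @export
dxy <- function(x, groups) {
  groups <- stats::setNames(as.character(groups), names(groups))
  levs <- unique(groups)
  out <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  if (methods::is(x, "GenotypeMatrix")) {
    gm <- genotypes(x)
    grp <- groups[rownames(gm)]
    for (i in seq_along(levs)) for (j in seq_along(levs)) {
      if (j <= i) next
      g1 <- gm[grp == levs[i], , drop = FALSE]
      g2 <- gm[grp == levs[j], , drop = FALSE]
      p1 <- colSums(g1, na.rm = TRUE) / (2 * colSums(!is.na(g1)))
      p2 <- colSums(g2, na.rm = TRUE) / (2 * colSums(!is.na(g2)))
      d <- p1 * (1 - p2) + p2 * (1 - p1)
      out[i, j] <- out[j, i] <- mean(d, na.rm = TRUE)
    }
    return(out)
  }
  alns <- .asAlignmentList(x)
  lens <- vapply(alns, function(s) Biostrings::width(s)[1], numeric(1))
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    tot <- 0
    for (k in seq_along(alns)) {
      grp <- .haplotypeGroups(alns[[k]], groups)
      m <- .alnMatrix(alns[[k]])
      m1 <- m[grp == levs[i], , drop = FALSE]
      m2 <- m[grp == levs[j], , drop = FALSE]
      if (!nrow(m1) || !nrow(m2)) stop("empty group in locus ", k)
      tot <- tot + .betweenDiffs(m1, m2)
    }
    out[i, j] <- out[j, i] <- tot / sum(lens)
  }
  out
}

#' Net p-distance between two groups of haplotypes
#'
#' `dA = Dxy - (piA + piB) / 2` on uncorrected p-distances, for two aligned
#' sets of equal-length sequences (e.g. the COI haplotypes of two species).
#' Within-group diversity uses the plug-in form (average over all ordered
#' haplotype pairs, self-pairs included), so a group compared against an
#' identical copy of itself has net distance exactly zero; for diverged
#' groups the difference from the distinct-pairs form is O(pi / n).
#'
#' @param a,b [Biostrings::DNAStringSet] objects, equal widths.
#' @return Net between-group distance per site (numeric scalar).
#' @export
netPDistance <- function(a, b) {
  if (Biostrings::width(a)[1] != Biostrings::width(b)[1])
    stop("alignments must have equal length")
  L <- Biostrings::width(a)[1]
  ma <- .alnMatrix(a); mb <- .alnMatrix(b)
  dxyAB <- .betweenDiffs(ma, mb) / L
  plug <- function(m) {
    n <- nrow(m)
    if (n < 2) return(0)
    .pairwiseDiffs(m)$mean * (n - 1) / n / L
  }
  dxyAB - (plug(ma) + plug(mb)) / 2
}
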