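# Independent brute-force oracles. These re-derive each statistic from
# first principles with a different code path than the package and are the
# reference values for exactness tests.

# Tajima (1989) D, written straight from the published constants
oracle_tajima_d <- function(n, S, pi_total) {
  if (S < 1) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# mean pairwise differences by exhaustive enumeration over combn pairs
oracle_mean_pairwise_diffs <- function(seqs) {
  prs <- utils::combn(length(seqs), 2)
  diffs <- apply(prs, 2, function(ij) {
    a <- strsplit(seqs[ij[1]], "")[[1]]
    b <- strsplit(seqs[ij[2]], "")[[1]]
    sum(a != b)
  })
  mean(diffs)
}

oracle_seg_sites <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

# mean between-group differences by exhaustive pair enumeration
oracle_between_diffs <- function(seqsA, seqsB) {
  tot <- 0
  for (a in seqsA) for (b in seqsB) {
    tot <- tot + sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  tot / (length(seqsA) * length(seqsB))
}

# Weir & Cockerham (1984) single-locus theta from genotype vectors of two
# samples, computing a, b, c exactly as printed in Weir & Cockerham (1984)
oracle_wc84 <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  nbar <- mean(n)
  CV2 <- sum((n - nbar)^2) / ((r) * nbar^2)  # unused; kept for clarity
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Nei (1972) identity/distance from explicit allele-frequency vectors
oracle_nei_d <- function(p1, p2) {
  j12 <- sum(p1 * p2 + (1 - p1) * (1 - p2))
  j11 <- sum(p1^2 + (1 - p1)^2)
  j22 <- sum(p2^2 + (1 - p2)^2)
  -log(j12 / sqrt(j11 * j22))
}

# discrete-generation Wright-Fisher coalescent for tiny N: at each
# generation back in time every pair of the j active lineages coalesces
# with probability 1/(2N(t)); multiple mergers resolved sequentially.
# Returns the TMRCA in generations.
oracle_wf_tmrca <- function(n, N_of_t) {
  j <- n
  t <- 0
  repeat {
    t <- t + 1
    N <- N_of_t(t)
    # probability some pair among j coalesces this generation
    pr <- 1 - prod(1 - (seq_len(j - 1)) / (2 * N))
    if (stats::runif(1) < pr) j <- j - 1
    if (j == 1) return(t)
  }
}

# neutral site-frequency spectrum for a sample of n: P(derived count = i)
# proportional to 1/i
oracle_sfs_probs <- function(n) {
  p <- 1 / seq_len(n - 1)
  p / sum(p)
}

# PIC for a biallelic locus (Botstein et al. 1980 general formula)
oracle_pic <- function(p) {
  q <- 1 - p
  f <- c(p, q)
  s2 <- sum(f^2)
  cross <- 0
  for (i in 1:2) for (j in 1:2) if (i < j)
    cross <- cross + 2 * f[i]^2 * f[j]^2
  1 - s2 - cross
}
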