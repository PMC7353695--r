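# Population-structure diagnostics: PCoA, individual-based Mantel test,
# Evanno delta-K, mutual k-nearest-neighbour graphs.

.checkSquareSym <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > tol) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix must have zero diagonal")
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres `-D^2 / 2` and eigendecomposes (via [stats::cmdscale()]);
#' coordinates are eigenvectors scaled by the square root of the positive
#' eigenvalues. Negative eigenvalues are reported but contribute no axes,
#' and percent explained is relative to the sum of positive eigenvalues.
#'
#' @param d square symmetric distance matrix (zero diagonal).
#' @return List with `coordinates` (units x axes), `eigenvalues` (all, in
#'   decreasing order) and `percentExplained` (per positive axis).
#' @export
pcoa <- function(d) {
  d <- .checkSquareSym(d)
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; we report
  # the full eigenvalue spectrum ourselves
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(abs(eig)) * 1e-12
  k <- min(sum(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  if (k > 0) colnames(coords) <- paste0("Axis", seq_len(k))
  list(coordinates = coords, eigenvalues = eig,
       percentExplained = if (k > 0)
         100 * eig[seq_len(k)] / sum(eig[pos]) else numeric(0))
}

#' Individual-based Mantel test
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices, with significance from joint row/column permutations of one
#' matrix: `p = (# permuted r >= observed + 1) / (nPerm + 1)` (one-sided,
#' positive association).
#'
#' @param dg genetic distance matrix.
#' @param dx geographic (or any second) distance matrix, same units order.
#' @param nPerm permutations (default 999).
#' @param seed optional integer seed.
#' @return List with `r` and `p`.
#' @export
mantelTest <- function(dg, dx, nPerm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dg <- .checkSquareSym(dg); dx <- .checkSquareSym(dx)
  stopifnot(nrow(dg) == nrow(dx))
  ut <- upper.tri(dg)
  x <- dg[ut]; y <- dx[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r <- stats::cor(x, y)
  cnt <- 0L
  n <- nrow(dg)
  for (b in seq_len(nPerm)) {
    o <- sample.int(n)
    rp <- stats::cor(x, dx[o, o][ut])
    if (rp >= r) cnt <- cnt + 1L
  }
  list(r = r, p = (cnt + 1) / (nPerm + 1))
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances (km) between individuals, from `lat`/`lon` columns.
#'
#' @param sampleSheet data.frame with `id`, `lat`, `lon`.
#' @return Symmetric matrix of distances in kilometres.
#' @export
geoDistance <- function(sampleSheet) {
  stopifnot(all(c("id", "lat", "lon") %in% colnames(sampleSheet)))
  xy <- as.matrix(sampleSheet[, c("lon", "lat")])
  n <- nrow(xy)
  out <- matrix(0, n, n, dimnames = list(sampleSheet$id, sampleSheet$id))
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                  xy[(i + 1):n, , drop = FALSE]) / 1000
    out[i, (i + 1):n] <- d
    out[(i + 1):n, i] <- d
  }
  out
}

#' Evanno delta-K from STRUCTURE log-likelihood runs
#'
#' For replicate runs of a Bayesian clustering program at successive K,
#' computes `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`
#' for interior K, and reports the K maximising it. Positions where the
#' across-run sd is zero are flagged undefined (`NA`).
#'
#' @param runs data.frame with columns `K`, `run`, `lnP`.
#' @return List with `table` (data.frame: K, meanLnP, sdLnP, deltaK) and
#'   `bestK`.
#' @export
evannoDeltaK <- function(runs) {
  stopifnot(all(c("K", "run", "lnP") %in% colnames(runs)))
  Ks <- sort(unique(runs$K))
  if (length(Ks) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(Ks) != 1)) stop("K values must be consecutive")
  mean_l <- tapply(runs$lnP, runs$K, mean)[as.character(Ks)]
  sd_l <- tapply(runs$lnP, runs$K, stats::sd)[as.character(Ks)]
  nrun <- tapply(runs$lnP, runs$K, base::length)[as.character(Ks)]
  if (any(nrun < 2)) stop("need >= 2 runs per K")
  dk <- rep(NA_real_, length(Ks))
  for (i in seq(2, length(Ks) - 1)) {
    num <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
    dk[i] <- if (sd_l[i] > 0) num / sd_l[i] else NA_real_
  }
  tab <- data.frame(K = Ks, meanLnP = as.numeric(mean_l),
                    sdLnP = as.numeric(sd_l), deltaK = dk)
  best <- if (all(is.na(dk))) NA_integer_ else Ks[which.max(dk)]
  list(table = tab, bestK = best)
}

#' Mutual k-nearest-neighbour graph
#'
#' Undirected graph joining individuals `i` and `j` when each is among the
#' other's `k` nearest neighbours by the supplied distance; distance ties
#' are broken by index order.
#'
#' @param d square symmetric distance matrix.
#' @param k neighbourhood size, `1 <= k < n`.
#' @return An [igraph::igraph] graph with vertex names from the matrix
#'   dimnames.
#' @export
mutualKnn <- function(d, k) {
  d <- .checkSquareSym(d)
  n <- nrow(d)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # ties by index
    nn[i, (seq_len(n)[-i])[ord[seq_len(k)]]] <- TRUE
  }
  adj <- nn & t(nn)
  nms <- rownames(d)
  if (is.null(nms)) nms <- as.character(seq_len(n))
  dimnames(adj) <- list(nms, nms)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
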