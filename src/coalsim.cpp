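#include <Rcpp.h>
using namespace Rcpp;

// Demographic model codes shared with R/coalsim.R:
//   0 = constant size Nc
//   1 = expansion: (backwards in time) size Npost for t < Texp, Nanc for t >= Texp
// All sizes are diploid Ne; time in generations; pairwise coalescence rate
// for j lineages is choose(j,2) / (2 Ne(t)).

static inline double coal_wait(double t, double cj, int kind,
                               double Nc, double Nanc, double Npost,
                               double Texp) {
  double E = R::exp_rand();
  if (kind == 0) return E * 2.0 * Nc / cj;
  if (t >= Texp) return E * 2.0 * Nanc / cj;
  double w = E * 2.0 * Npost / cj;
  if (t + w < Texp) return w;
  // piecewise rescaling across the size change, never rejection
  double used = (Texp - t) * cj / (2.0 * Npost);
  return (Texp - t) + (E - used) * 2.0 * Nanc / cj;
}

// Draw the number of tips subtended by a uniformly chosen branch present
// while j of n lineages remain: P(i | j) = C(n-i-1, j-2) / C(n-1, j-1)
// (Fu 1995, exchangeable coalescent topology), i = 1 .. n-j+1.
static inline int fu_draw(int n, int j) {
  double u = unif_rand();
  double p = (double)(j - 1) / (double)(n - 1);  // P(1 | j)
  double cum = p;
  int i = 1;
  int imax = n - j + 1;
  while (u > cum && i < imax) {
    p *= (double)(n - i - j + 1) / (double)(n - i - 1);
    ++i;
    cum += p;
  }
  return i;
}

// SNP loci are retained conditional on being variable in the sample. In the
// mutation-rate -> 0 limit this tilts the genealogy measure by total branch
// length L, so the level j carrying the mutation has probability
//   p_j = j E[T_j] / sum_k k E[T_k],
// and given the level the subtended tip count is Fu's distribution (topology
// is independent of branch lengths). E[T_j] under a two-epoch history is
// computed exactly: in coalescent-scaled time u (du = dt / (2 Ne)) the level
// durations are independent Exp(c_j); with the epoch boundary at
// u* = Texp / (2 Npost),
//   E[T_j] = 2 Npost (1/c_j - d_j) + 2 Nanc d_j,
// where d_j, the expected scaled level-j time spent beyond u*, follows from
// a stable recursion on q_j = P(A_j >= u*) and the Laplace functionals
// phi_j(c) = E[ exp(-c (u* - A_j)) 1{A_j < u*} ] of the level start time
// A_j (A_n = 0):
//   d_j = (q_j + phi_j(c_j)) / c_j
//   q_{j-1} = q_j + phi_j(c_j)
//   phi_{j-1}(c) = c_j (phi_j(c) - phi_j(c_j)) / (c_j - c).
// Fills cdf[0..n-2] with the cumulative level distribution (level = j at
// index j-2).
static void level_cdf(int n, int kind, double Nc, double Nanc, double Npost,
                      double Texp, std::vector<double> &cdf) {
  double N1 = (kind == 0) ? Nc : Npost;
  double N2 = (kind == 0) ? Nc : Nanc;
  double ustar = (kind == 0) ? R_PosInf : Texp / (2.0 * N1);
  std::vector<double> phi(n + 1), w(n + 1);
  for (int k = 2; k <= n; ++k) {
    double ck = 0.5 * k * (k - 1);
    phi[k] = (R_FINITE(ustar)) ? std::exp(-ck * ustar) : 0.0;
  }
  double q = 0.0;
  for (int j = n; j >= 2; --j) {
    double cj = 0.5 * j * (j - 1);
    double d = (q + phi[j]) / cj;
    w[j] = j * (2.0 * N1 * (1.0 / cj - d) + 2.0 * N2 * d);
    q += phi[j];
    for (int k = 2; k < j; ++k) {
      double ck = 0.5 * k * (k - 1);
      double v = cj * (phi[k] - phi[j]) / (cj - ck);
      phi[k] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  }
  double tot = 0.0;
  for (int j = 2; j <= n; ++j) tot += w[j];
  double acc = 0.0;
  for (int j = 2; j <= n; ++j) {
    acc += w[j] / tot;
    cdf[j - 2] = acc;
  }
  cdf[n - 2] = 1.0;
}

static inline int level_draw(int n, const std::vector<double> &cdf) {
  double u = unif_rand();
  int lo = 0, hi = n - 2;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo + 2;
}

// [[Rcpp::export]]
IntegerVector cpp_snp_counts(int n_hap, int n_loci, int kind, double Nc,
                             double Nanc, double Npost, double Texp) {
  std::vector<double> cdf(n_hap - 1);
  level_cdf(n_hap, kind, Nc, Nanc, Npost, Texp, cdf);
  IntegerVector out(n_loci);
  for (int l = 0; l < n_loci; ++l)
    out[l] = fu_draw(n_hap, level_draw(n_hap, cdf));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tmrca(int n_hap, int reps, int kind, double Nc,
                        double Nanc, double Npost, double Texp) {
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0;
    for (int j = n_hap; j >= 2; --j) {
      double cj = 0.5 * j * (j - 1);
      t += coal_wait(t, cj, kind, Nc, Nanc, Npost, Texp);
    }
    out[r] = t;
  }
  return out;
}

// Reference-table kernel: one row per parameter draw; returns the four
// single-population DIYABC-style SNP statistics computed from per-locus
// derived-allele counts (no missing data in simulated rows):
//   col 0: proportion of monomorphic loci (0 by construction, kept for
//          symmetry with observed data after projection/missingness)
//   col 1: mean per-locus unbiased gene diversity  n/(n-1) * (1 - p^2 - q^2)
//   col 2: sample variance of per-locus gene diversity
//   col 3: mean minor-allele frequency
// [[Rcpp::export]]
NumericMatrix cpp_ref_stats(int n_hap, int n_loci, IntegerVector kind,
                            NumericVector Nc, NumericVector Nanc,
                            NumericVector Npost, NumericVector Texp) {
  int nsim = kind.size();
  NumericMatrix out(nsim, 4);
  double bias = (double)n_hap / (double)(n_hap - 1);
  std::vector<double> cdf(n_hap - 1);
  for (int s = 0; s < nsim; ++s) {
    level_cdf(n_hap, kind[s], Nc[s], Nanc[s], Npost[s], Texp[s], cdf);
    double sumH = 0.0, sumH2 = 0.0, sumMaf = 0.0;
    for (int l = 0; l < n_loci; ++l) {
      int i = fu_draw(n_hap, level_draw(n_hap, cdf));
      double p = (double)i / (double)n_hap;
      double H = bias * (1.0 - p * p - (1.0 - p) * (1.0 - p));
      double maf = p < 0.5 ? p : 1.0 - p;
      sumH += H;
      sumH2 += H * H;
      sumMaf += maf;
    }
    double mH = sumH / n_loci;
    double vH = n_loci > 1 ? (sumH2 - n_loci * mH * mH) / (n_loci - 1) : 0.0;
    if (vH < 0) vH = 0;
    out(s, 0) = 0.0;
    out(s, 1) = mH;
    out(s, 2) = vH;
    out(s, 3) = sumMaf / n_loci;
  }
  return out;
}

// Full Kingman tree with topology (for sequence loci and the tree API).
// Internal nodes are numbered ape-style: tips 1..n, root n+1, then in
// reverse coalescence order so the k-th event (k = 1..n-1) is node 2n-k.
// [[Rcpp::export]]
List cpp_sim_tree(int n_hap, int kind, double Nc, double Nanc, double Npost,
                  double Texp) {
  int n = n_hap;
  int n_edge = 2 * (n - 1);
  IntegerMatrix edge(n_edge, 2);
  NumericVector edge_length(n_edge);
  NumericVector node_time(2 * n - 1);  // 1-based node id - 1
  std::vector<int> active(n);
  std::vector<double> atime(n);
  for (int i = 0; i < n; ++i) { active[i] = i + 1; atime[i] = 0.0; }
  double t = 0.0;
  int e = 0;
  for (int j = n; j >= 2; --j) {
    double cj = 0.5 * j * (j - 1);
    t += coal_wait(t, cj, kind, Nc, Nanc, Npost, Texp);
    int a = (int)(unif_rand() * j); if (a == j) a = j - 1;
    int b = (int)(unif_rand() * (j - 1)); if (b == j - 1) b = j - 2;
    if (b >= a) ++b;
    int k = n - j + 1;               // event index
    int parent = 2 * n - k;          // ape numbering, root = n+1
    edge(e, 0) = parent; edge(e, 1) = active[a];
    edge_length[e] = t - atime[a]; ++e;
    edge(e, 0) = parent; edge(e, 1) = active[b];
    edge_length[e] = t - atime[b]; ++e;
    node_time[parent - 1] = t;
    int lo = a < b ? a : b, hi = a < b ? b : a;
    active[lo] = parent; atime[lo] = t;
    active.erase(active.begin() + hi); atime.erase(atime.begin() + hi);
  }
  return List::create(_["edge"] = edge, _["edge.length"] = edge_length,
                      _["node.time"] = node_time);
}
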