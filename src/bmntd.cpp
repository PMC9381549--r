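#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance (betaMNTD) between all
// sample pairs, given a taxon-by-taxon patristic distance matrix D and a
// sample-by-taxon relative abundance matrix F (rows sum to 1).
//
// `perm` maps taxon index -> tip index (0-based). The identity permutation
// gives the observed betaMNTD; a random permutation gives one tip-shuffle
// null draw (names and abundances move together across tips; topology and
// branch lengths stay fixed).
//
// Strategy: for one permutation, first build M(i, s) = distance from taxon i
// to its nearest taxon present in sample s (0 if i itself is present), then
// betaMNTD(k, m) = 0.5 * ( sum_{i in k} F(k,i) M(i,m) +
//                          sum_{j in m} F(m,j) M(j,k) ).
// This costs O(n_taxa * sum richness) per permutation instead of the naive
// O(pairs * richness^2).

static void bmntd_one_perm(const NumericMatrix &D, const NumericMatrix &F,
                           const std::vector<std::vector<int>> &members,
                           const int *perm, NumericMatrix &out,
                           std::vector<double> &Mbuf) {
  const int S = F.nrow(), n = F.ncol();
  // Mbuf is n x S, column-major
  for (int s = 0; s < S; ++s) {
    const std::vector<int> &mem = members[s];
    const int nm = (int)mem.size();
    double *Mcol = &Mbuf[(size_t)s * n];
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      const int pi = perm[i];
      for (int t = 0; t < nm; ++t) {
        const double d = D(pi, perm[mem[t]]);
        if (d < best) best = d;
      }
      Mcol[i] = (nm > 0) ? best : NA_REAL;
    }
  }
  for (int k = 0; k < S; ++k) {
    out(k, k) = 0.0;
    for (int m = k + 1; m < S; ++m) {
      double acc = 0.0;
      const double *Mm = &Mbuf[(size_t)m * n];
      const double *Mk = &Mbuf[(size_t)k * n];
      for (size_t t = 0; t < members[k].size(); ++t) {
        const int i = members[k][t];
        acc += F(k, i) * Mm[i];
      }
      for (size_t t = 0; t < members[m].size(); ++t) {
        const int j = members[m][t];
        acc += F(m, j) * Mk[j];
      }
      out(k, m) = out(m, k) = 0.5 * acc;
    }
  }
}

static std::vector<std::vector<int>> presence_sets(const NumericMatrix &F) {
  const int S = F.nrow(), n = F.ncol();
  std::vector<std::vector<int>> members(S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i)
      if (F(s, i) > 0) members[s].push_back(i);
  return members;
}

// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd(NumericMatrix D, NumericMatrix F,
                            IntegerVector perm) {
  const int S = F.nrow(), n = F.ncol();
  if (D.nrow() != n || D.ncol() != n)
    stop("distance matrix does not match the number of taxa");
  if (perm.size() != n) stop("permutation length does not match taxa");
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = perm[i] - 1; // R is 1-based
  NumericMatrix out(S, S);
  std::vector<double> Mbuf((size_t)n * S);
  std::vector<std::vector<int>> members = presence_sets(F);
  bmntd_one_perm(D, F, members, p.data(), out, Mbuf);
  return out;
}

// Null mean and standard deviation of betaMNTD per sample pair over the
// supplied tip-shuffle permutations (one row of `perms` per null draw,
// 1-based). SD uses the n-1 denominator over the null draws.
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix D, NumericMatrix F, IntegerMatrix perms) {
  const int S = F.nrow(), n = F.ncol(), R = perms.nrow();
  if (perms.ncol() != n) stop("permutation width does not match taxa");
  NumericMatrix sum(S, S), sumsq(S, S), draw(S, S);
  std::vector<double> Mbuf((size_t)n * S);
  std::vector<std::vector<int>> members = presence_sets(F);
  std::vector<int> p(n);
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) p[i] = perms(r, i) - 1;
    bmntd_one_perm(D, F, members, p.data(), draw, Mbuf);
    for (int k = 0; k < S; ++k)
      for (int m = 0; m < S; ++m) {
        sum(k, m) += draw(k, m);
        sumsq(k, m) += draw(k, m) * draw(k, m);
      }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(S, S), sd(S, S);
  for (int k = 0; k < S; ++k)
    for (int m = 0; m < S; ++m) {
      mean(k, m) = sum(k, m) / R;
      double v = (R > 1) ? (sumsq(k, m) - sum(k, m) * sum(k, m) / R) / (R - 1)
                         : 0.0;
      sd(k, m) = v > 0 ? std::sqrt(v) : 0.0;
    }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
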