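#include <Rcpp.h>
#include <algorithm>
#include <string>
using namespace Rcpp;

static double jaro(const std::string &a, const std::string &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int window = std::max(0, std::max(la, lb) / 2 - 1);
  std::vector<bool> am(la, false), bm(lb, false);
  int matches = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window), hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] = bm[j] = true;
        ++matches;
        break;
      }
    }
  }
  if (matches == 0) return 0.0;
  // transpositions: compare matched characters in order
  int t = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (!am[i]) continue;
    while (!bm[j]) ++j;
    if (a[i] != b[j]) ++t;
    ++j;
  }
  const double m = matches;
  return (m / la + m / lb + (m - t / 2.0) / m) / 3.0;
}

// [[Rcpp::export]]
NumericVector jaro_winkler_sim(CharacterVector a, CharacterVector b,
                               double prefix_weight = 0.1,
                               int max_prefix = 4) {
  const R_xlen_t n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string sa = as<std::string>(a[i % a.size()]);
    const std::string sb = as<std::string>(b[i % b.size()]);
    const double j = jaro(sa, sb);
    int prefix = 0;
    const int lim = std::min((int)std::min(sa.size(), sb.size()), max_prefix);
    while (prefix < lim && sa[prefix] == sb[prefix]) ++prefix;
    out[i] = j + prefix * prefix_weight * (1.0 - j);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix jaro_winkler_matrix(CharacterVector a, CharacterVector b,
                                  double prefix_weight = 0.1,
                                  int max_prefix = 4) {
  NumericMatrix out(a.size(), b.size());
  std::vector<std::string> sb(b.size());
  for (R_xlen_t j = 0; j < b.size(); ++j) sb[j] = as<std::string>(b[j]);
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const std::string sa = as<std::string>(a[i]);
    for (R_xlen_t j = 0; j < b.size(); ++j) {
      if (sa == sb[j]) { out(i, j) = 1.0; continue; }
      const double jr = jaro(sa, sb[j]);
      int prefix = 0;
      const int lim = std::min((int)std::min(sa.size(), sb[j].size()),
                               max_prefix);
      while (prefix < lim && sa[prefix] == sb[j][prefix]) ++prefix;
      out(i, j) = jr + prefix * prefix_weight * (1.0 - jr);
    }
  }
  return out;
}
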