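#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair scores of the bundled base-pair-maximisation surrogate:
// GC = -3, AU = -2, GU = -1 (wobble); N never pairs. Returns +1 sentinel
// for non-pairable bases.
static inline double pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0;
}

// Nussinov-style dynamic program over nested pairings with a minimum
// hairpin loop of `min_loop` unpaired nucleotides; minimises the summed
// pair score (scores are negative, so this maximises weighted pairing).
static double nussinov_one(const std::string &s, int min_loop) {
  int n = (int)s.size();
  if (n == 0) return 0.0;
  std::vector<double> M((size_t)n * n, 0.0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = M[(size_t)(i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double sc = pair_score(s[i], s[k]);
        if (sc > 0) continue;
        double inner = (k - 1 >= i + 1) ? M[(size_t)(i + 1) * n + (k - 1)]
                                        : 0.0;
        double outer = (k + 1 <= j) ? M[(size_t)(k + 1) * n + j] : 0.0;
        double cand = sc + inner + outer;
        if (cand < best) best = cand;
      }
      M[(size_t)i * n + j] = best;
    }
  }
  return M[(size_t)0 * n + (n - 1)];
}

// [[Rcpp::export(name = ".nussinov_mfe")]]
NumericVector nussinov_mfe(CharacterVector seqs, int min_loop = 3) {
  int m = seqs.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    if (CharacterVector::is_na(seqs[q])) {
      out[q] = NA_REAL;
      continue;
    }
    std::string s = as<std::string>(seqs[q]);
    for (size_t i = 0; i < s.size(); ++i) {
      char c = toupper(s[i]);
      if (c == 'T') c = 'U';
      s[i] = c;
    }
    out[q] = nussinov_one(s, min_loop);
  }
  return out;
}
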