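#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive all-pairs Hamming scan between query tags and library keys.
// Returns every (query, key) pair with distance <= maxd (1-based indices).
// Strings of unequal length are treated as infinitely distant.
// [[Rcpp::export]]
List cpp_all_pairs_hamming(CharacterVector queries, CharacterVector keys,
                           int maxd) {
  const int nq = queries.size(), nk = keys.size();
  std::vector<std::string> ks(nk);
  for (int j = 0; j < nk; ++j) ks[j] = as<std::string>(keys[j]);
  std::vector<int> out_q, out_k, out_d;
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    const int L = q.size();
    for (int j = 0; j < nk; ++j) {
      if ((int)ks[j].size() != L) continue;
      int d = 0;
      const char *a = q.c_str(), *b = ks[j].c_str();
      for (int p = 0; p < L; ++p) {
        if (a[p] != b[p] && ++d > maxd) break;
      }
      if (d <= maxd) {
        out_q.push_back(i + 1);
        out_k.push_back(j + 1);
        out_d.push_back(d);
      }
    }
  }
  return List::create(_["query"] = wrap(out_q), _["key"] = wrap(out_k),
                      _["dist"] = wrap(out_d));
}
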