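#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick plus G:U wobble; T treated as U.
static inline bool can_pair(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum base-pair structure (Nussinov-style DP) with minimum loop size 3,
// i.e. a pair (i, j) requires j - i >= 4. Traceback is deterministic: at each
// subproblem position i is left unpaired whenever that attains the optimum,
// otherwise i is paired with the LARGEST admissible partner. Returns the
// dot-bracket string.
// [[Rcpp::export]]
std::string nussinov_db(std::string s) {
  const int n = s.size();
  std::string db(n, '.');
  if (n < 5) return db;
  std::vector<int> N(n * n, 0);
#define NN(i, j) N[(i) * n + (j)]
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = NN(i + 1, j);
      for (int k = i + 4; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int v = 1;
        if (k - 1 > i + 1) v += NN(i + 1, k - 1);
        if (k + 1 <= j - 1) v += NN(k + 1, j);
        if (v > best) best = v;
      }
      NN(i, j) = best;
    }
  }
  // traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 4) continue;
    if (NN(i, j) == NN(i + 1, j)) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    int chosen = -1;
    for (int k = j; k >= i + 4; --k) {
      if (!can_pair(s[i], s[k])) continue;
      int v = 1;
      if (k - 1 > i + 1) v += NN(i + 1, k - 1);
      if (k + 1 <= j - 1) v += NN(k + 1, j);
      if (v == NN(i, j)) { chosen = k; break; }
    }
    if (chosen < 0) { // should not happen; fall back to unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    db[i] = '(';
    db[chosen] = ')';
    if (chosen - 1 > i + 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
    if (chosen + 1 <= j - 1) stack.push_back(std::make_pair(chosen + 1, j));
  }
#undef NN
  return db;
}

// Hamming distance of `tag` against every offset of `ref`; out[o] is the
// number of mismatches when the tag starts at 0-based offset o.
// [[Rcpp::export]]
IntegerVector hamming_counts(std::string tag, std::string ref) {
  const int L = ref.size(), l = tag.size();
  if (l > L || l == 0) return IntegerVector(0);
  IntegerVector out(L - l + 1);
  for (int o = 0; o + l <= L; ++o) {
    int m = 0;
    for (int i = 0; i < l; ++i)
      if (tag[i] != ref[o + i]) ++m;
    out[o] = m;
  }
  return out;
}

// 3' adapter scan, conventional trimmer contract: the best occurrence of the
// adapter (or of an adapter prefix at the read end) with error rate <=
// max_error_rate and overlap >= min_overlap. Returns the 0-based position
// where the adapter starts (= insert length), or -1 if no occurrence.
// Best = most matching bases; ties broken by the earliest start.
// [[Rcpp::export]]
IntegerVector adapter_insert_len(CharacterVector seqs, std::string adapter,
                                 double max_error_rate, int min_overlap) {
  const int alen = adapter.size();
  const int nseq = seqs.size();
  IntegerVector out(nseq);
  for (int r = 0; r < nseq; ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int rlen = s.size();
    int best_score = -1, best_start = -1;
    for (int start = 0; start + min_overlap <= rlen; ++start) {
      int ov = std::min(alen, rlen - start);
      int allowed = (int)std::floor(max_error_rate * ov);
      int mm = 0;
      for (int i = 0; i < ov && mm <= allowed; ++i)
        if (s[start + i] != adapter[i]) ++mm;
      if (mm > allowed) continue;
      int score = ov - mm;
      if (score > best_score) { best_score = score; best_start = start; }
    }
    out[r] = best_start;
  }
  return out;
}
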