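// DUST-style low-complexity scoring: S = sum_t c_t (c_t - 1) / 2 / (#triplets)
// over overlapping 3-mers in a window; windows above threshold are merged into
// maximal intervals.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {
inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
}

// [[Rcpp::export(name = ".dust_intervals")]]
IntegerMatrix dust_intervals(std::string seq, int window, double threshold, int step) {
  const int n = (int)seq.size();
  std::vector<std::pair<int,int> > flagged;
  std::vector<int> cnt(64, 0);
  for (int start = 0; start < n; start += step) {
    int end = start + window;
    if (end > n) end = n;
    int wlen = end - start;
    if (wlen < 3) break;
    std::fill(cnt.begin(), cnt.end(), 0);
    int ntrip = 0;
    for (int i = start; i + 3 <= end; ++i) {
      int a = base_code(seq[i]), b = base_code(seq[i + 1]), c = base_code(seq[i + 2]);
      if (a < 0 || b < 0 || c < 0) continue;
      ++cnt[(a << 4) | (b << 2) | c];
      ++ntrip;
    }
    if (ntrip == 0) { if (end >= n) break; else continue; }
    double s = 0.0;
    for (int t = 0; t < 64; ++t) s += 0.5 * cnt[t] * (cnt[t] - 1);
    s /= ntrip;
    if (s > threshold) flagged.push_back(std::make_pair(start, end));
    if (end >= n) break;
  }
  // merge overlapping/adjacent flagged windows
  std::vector<std::pair<int,int> > merged;
  for (size_t i = 0; i < flagged.size(); ++i) {
    if (!merged.empty() && flagged[i].first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, flagged[i].second);
    else
      merged.push_back(flagged[i]);
  }
  IntegerMatrix out((int)merged.size(), 2);
  colnames(out) = CharacterVector::create("start", "end");
  for (int i = 0; i < (int)merged.size(); ++i) {
    out(i, 0) = merged[i].first;
    out(i, 1) = merged[i].second;
  }
  return out;
}
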