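// Core primitives of the tandem repeat detector:
//  - period candidates from the distance histogram of exact k-mer re-occurrences
//  - wraparound dynamic programming of a read against a circular consensus
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <climits>
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

// Candidate repeat periods within one read.  For every exact k-mer, distances
// between consecutive occurrences are histogrammed; local maxima (+-2 bp) with
// support >= min_support become candidates.  Returns a matrix with columns
// period, support, region_start, region_end (0-based half-open span of the
// supporting k-mer pairs).
// [[Rcpp::export(name = ".period_candidates")]]
IntegerMatrix period_candidates(std::string seq, int k, int min_period,
                                int max_period, int min_support) {
  const int n = (int)seq.size();
  IntegerMatrix empty(0, 4);
  colnames(empty) = CharacterVector::create("period", "support", "region_start", "region_end");
  if (n < k || max_period < min_period) return empty;
  if (max_period > n - 1) max_period = n - 1;

  std::vector<int> hist(max_period + 1, 0);
  std::vector<int> lo(max_period + 1, INT_MAX), hi(max_period + 1, -1);
  std::unordered_map<uint64_t, int> last;
  last.reserve((size_t)n * 2);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t h = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid < k) continue;
    int pos = i - k + 1;
    auto it = last.find(h);
    if (it != last.end()) {
      int d = pos - it->second;
      if (d >= min_period && d <= max_period) {
        ++hist[d];
        if (it->second < lo[d]) lo[d] = it->second;
        if (i + 1 > hi[d]) hi[d] = i + 1;
      }
      it->second = pos;
    } else {
      last.emplace(h, pos);
    }
  }

  std::vector<int> periods;
  for (int d = min_period; d <= max_period; ++d) {
    if (hist[d] < min_support) continue;
    bool is_max = true;
    for (int e = d - 2; e <= d + 2; ++e) {
      if (e < min_period || e > max_period || e == d) continue;
      if (hist[e] > hist[d] || (hist[e] == hist[d] && e < d)) { is_max = false; break; }
    }
    if (is_max) periods.push_back(d);
  }
  IntegerMatrix out((int)periods.size(), 4);
  colnames(out) = CharacterVector::create("period", "support", "region_start", "region_end");
  for (int r = 0; r < (int)periods.size(); ++r) {
    int d = periods[r];
    out(r, 0) = d;
    out(r, 1) = hist[d];
    out(r, 2) = lo[d] == INT_MAX ? 0 : lo[d];
    out(r, 3) = hi[d] < 0 ? 0 : hi[d];
  }
  return out;
}

// Wraparound local alignment of `seq` against the circular consensus `cons`
// (match/mismatch/indel scores, linear gaps).  Two passes per row propagate
// horizontal moves across the wrap column.  Returns the best local span, its
// score, match/column counts, per-consensus-column base counts from the
// traceback (for consensus refinement), and read positions where a new
// consensus cycle starts (unit boundaries).
// [[Rcpp::export(name = ".wraparound_align")]]
List wraparound_align(std::string seq, std::string cons, int match,
                      int mismatch, int indel) {
  const int n = (int)seq.size(), p = (int)cons.size();
  if (n == 0 || p == 0) stop("empty sequence or consensus");
  std::vector<int> acode(n), ccode(p);
  for (int i = 0; i < n; ++i) acode[i] = base_code(seq[i]);
  for (int j = 0; j < p; ++j) ccode[j] = base_code(cons[j]);

  // H[i][j]: best local score of alignment ending with seq[0..i) consumed and
  // consensus column j (0-based, circular) just consumed / current.
  // traceback codes: 0 stop, 1 diag, 2 up (gap in consensus), 3 left (gap in read)
  std::vector<int> Hrow(p, 0), Hprev(p, 0);
  std::vector<unsigned char> tb((size_t)n * p, 0);
  // per-base score row against the consensus (base code -1..3 -> rows 0..4)
  std::vector<int> srows(5 * p);
  for (int j = 0; j < p; ++j) {
    for (int b = -1; b < 4; ++b)
      srows[(b + 1) * p + j] = (b >= 0 && b == ccode[j]) ? match : mismatch;
  }
  int best = 0, bi = -1, bj = -1;
  int* Hc = Hrow.data();
  int* Hp = Hprev.data();
  for (int i = 0; i < n; ++i) {
    unsigned char* tbi = &tb[(size_t)i * p];
    const int* srow = &srows[(acode[i] + 1) * p];
    const bool first_row = (i == 0);
    for (int pass = 0; pass < 2; ++pass) {
      // j = 0 wraps to column p-1
      {
        int s = srow[0];
        int diag = (first_row ? 0 : Hp[p - 1]) + s;
        int up   = (first_row ? 0 : Hp[0]) + indel;
        int left = Hc[p - 1] + indel;  // pass 0: stale (previous row) at start; fixed in pass 1
        int v = s; unsigned char t = 0;
        if (diag > v) { v = diag; t = 1; }
        if (!first_row && up > v) { v = up; t = 2; }
        if (pass > 0 && left > v) { v = left; t = 3; }
        if (v < 0) { v = 0; t = 0; }
        if (pass == 0 || v > Hc[0]) { Hc[0] = v; tbi[0] = t; }
      }
      for (int j = 1; j < p; ++j) {
        int s = srow[j];
        int diag = (first_row ? 0 : Hp[j - 1]) + s;
        int up   = (first_row ? 0 : Hp[j]) + indel;
        int left = Hc[j - 1] + indel;
        int v = s; unsigned char t = 0;
        if (diag > v) { v = diag; t = 1; }
        if (!first_row && up > v) { v = up; t = 2; }
        if (left > v) { v = left; t = 3; }
        if (v < 0) { v = 0; t = 0; }
        if (pass == 0) { Hc[j] = v; tbi[j] = t; }
        else if (v > Hc[j]) { Hc[j] = v; tbi[j] = t; }
        else break;  // pass 2 propagation stops once nothing improves
      }
      // second pass only needed when a left move could cross the wrap column
      if (pass == 0 && Hc[p - 1] + indel <= Hc[0]) break;
    }
    for (int j = 0; j < p; ++j) {
      if (Hc[j] > best) { best = Hc[j]; bi = i; bj = j; }
    }
    std::swap(Hc, Hp);
    std::fill(Hc, Hc + p, 0);
  }

  IntegerMatrix counts(4, p);
  std::vector<int> boundaries;
  int matches = 0, cols = 0;
  int i = bi, j = bj;
  int a_end = bi + 1, a_start = bi;
  if (bi >= 0) {
    while (i >= 0) {
      unsigned char t = tb[(size_t)i * p + j];
      int jp = (j == 0) ? p - 1 : j - 1;
      if (t == 0 || t == 1) {
        ++cols;
        if (acode[i] >= 0 && acode[i] == ccode[j]) ++matches;
        if (acode[i] >= 0) counts(acode[i], j) += 1;
        if (j == 0) boundaries.push_back(i);
        a_start = i;
        if (t == 0) break;
        --i; j = jp;
      } else if (t == 2) {  // read base aligned to gap
        ++cols;
        a_start = i;
        --i;
      } else {              // consensus column skipped
        ++cols;
        if (j == 0) boundaries.push_back(i + 1);
        j = jp;
      }
      if (i < 0) break;
    }
  }
  std::reverse(boundaries.begin(), boundaries.end());
  return List::create(_["score"] = best, _["start"] = a_start, _["end"] = bi < 0 ? 0 : a_end,
                      _["matches"] = matches, _["cols"] = cols,
                      _["counts"] = counts,
                      _["boundaries"] = IntegerVector(boundaries.begin(), boundaries.end()));
}
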