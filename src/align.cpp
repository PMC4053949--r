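// Local alignment (Gotoh affine gaps) with traceback statistics.
// Gap of length g costs gap_open + g * gap_ext (WU-BLAST Q/R convention).
#include <Rcpp.h>
#include <vector>
#include <climits>
#include <cstring>
using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N etc: never matches
  }
}

// traceback byte layout: bits 0-1 M-source (0 stop, 1 from M, 2 from Ix, 3 from Iy)
//                        bit 2 Ix-source (0 open from M, 1 extend)
//                        bit 3 Iy-source (0 open from M, 1 extend)
}  // namespace

// [[Rcpp::export(name = ".sw_stats")]]
List sw_stats(std::string a, std::string b, int match, int mismatch,
              int gap_open, int gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0, _["matches"] = 0, _["cols"] = 0,
                        _["cols_a"] = 0, _["cols_b"] = 0, _["max_run"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  const int open_cost = gap_open + gap_ext;  // first gapped residue
  std::vector<int> Mrow(n + 1, 0), Ixrow(n + 1, INT_MIN / 2), Iyrow(n + 1, INT_MIN / 2);
  std::vector<int> Mprev(n + 1, 0), Ixprev(n + 1, INT_MIN / 2), Iyprev(n + 1, INT_MIN / 2);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  std::vector<int> acode(m), bcode(n);
  for (int i = 0; i < m; ++i) acode[i] = base_code(a[i]);
  for (int j = 0; j < n; ++j) bcode[j] = base_code(b[j]);

  for (int i = 1; i <= m; ++i) {
    std::swap(Mrow, Mprev); std::swap(Ixrow, Ixprev); std::swap(Iyrow, Iyprev);
    Mrow[0] = 0; Ixrow[0] = INT_MIN / 2; Iyrow[0] = INT_MIN / 2;
    unsigned char* tbi = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      // Ix: gap in b (consume a, vertical)
      int ix_open = Mprev[j] - open_cost;
      int ix_ext  = Ixprev[j] - gap_ext;
      int ix = ix_open >= ix_ext ? ix_open : ix_ext;
      unsigned char t = 0;
      if (ix_ext > ix_open) t |= 4;
      Ixrow[j] = ix;
      // Iy: gap in a (consume b, horizontal)
      int iy_open = Mrow[j - 1] - open_cost;
      int iy_ext  = Iyrow[j - 1] - gap_ext;
      int iy = iy_open >= iy_ext ? iy_open : iy_ext;
      if (iy_ext > iy_open) t |= 8;
      Iyrow[j] = iy;
      // M
      int s = (acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1]) ? match : mismatch;
      int from_m = Mprev[j - 1], from_ix = Ixprev[j - 1], from_iy = Iyprev[j - 1];
      int diag = from_m; unsigned char src = 1;
      if (from_ix > diag) { diag = from_ix; src = 2; }
      if (from_iy > diag) { diag = from_iy; src = 3; }
      if (diag <= 0) { diag = 0; src = 0; }  // restart: this pair opens the alignment
      int mm = diag + s;
      if (mm <= 0) { mm = 0; src = 0; }      // dead cell; never entered in traceback
      Mrow[j] = mm;
      t |= src;
      tbi[j] = t;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state M
  int matches = 0, cols = 0, cols_a = 0, cols_b = 0, run = 0, max_run = 0;
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  int a_end = bi, b_end = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      bool is_match = (acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1]);
      ++cols; ++cols_a; ++cols_b;
      if (is_match) { ++matches; if (++run > max_run) max_run = run; }
      else run = 0;
      unsigned char src = t & 3;
      --i; --j;
      if (src == 0) break;          // alignment start
      state = (src == 1) ? 0 : (src == 2 ? 1 : 2);
    } else if (state == 1) {        // Ix: consumed a[i-1], gap in b
      ++cols; ++cols_a; run = 0;
      bool ext = (t & 4) != 0;
      --i;
      state = ext ? 1 : 0;
    } else {                        // Iy
      ++cols; ++cols_b; run = 0;
      bool ext = (t & 8) != 0;
      --j;
      state = ext ? 2 : 0;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches, _["cols"] = cols,
                      _["cols_a"] = cols_a, _["cols_b"] = cols_b,
                      _["max_run"] = max_run,
                      _["a_start"] = i, _["a_end"] = a_end,
                      _["b_start"] = j, _["b_end"] = b_end);
}

// Batch version: many `a` strings against one subject `b`; returns a matrix with
// one row per query: score, matches, cols, cols_a, max_run.
// [[Rcpp::export(name = ".sw_stats_batch")]]
IntegerMatrix sw_stats_batch(CharacterVector a, std::string b, int match,
                             int mismatch, int gap_open, int gap_ext) {
  int nq = a.size();
  IntegerMatrix out(nq, 5);
  colnames(out) = CharacterVector::create("score", "matches", "cols", "cols_a", "max_run");
  for (int q = 0; q < nq; ++q) {
    List r = sw_stats(as<std::string>(a[q]), b, match, mismatch, gap_open, gap_ext);
    out(q, 0) = as<int>(r["score"]);
    out(q, 1) = as<int>(r["matches"]);
    out(q, 2) = as<int>(r["cols"]);
    out(q, 3) = as<int>(r["cols_a"]);
    out(q, 4) = as<int>(r["max_run"]);
  }
  return out;
}
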