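// Canonical k-mer counting, de Bruijn cycle search (the short-read monomer
// reconstructor), and a k-mer prefilter for read-vs-monomer matching.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
using namespace Rcpp;

namespace {

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

const char BASES[4] = {'A', 'C', 'G', 'T'};

inline uint64_t revcomp_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return r;
}

inline uint64_t canonical(uint64_t x, int k) {
  uint64_t r = revcomp_kmer(x, k);
  return x < r ? x : r;
}

void count_seq(const char* s, int len, int k, uint64_t mask, KmerMap& map) {
  uint64_t h = 0;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) ++map[canonical(h, k)];
  }
}

std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = BASES[x & 3]; x >>= 2; }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".kgraph_build")]]
SEXP kgraph_build(CharacterVector reads, int k, int min_count) {
  if (k < 15 || k > 31 || k % 2 == 0) stop("k must be odd, within [15, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  XPtr<KmerMap> ptr(new KmerMap(), true);
  KmerMap& map = *ptr;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    if (len < k) continue;
    count_seq(s, len, k, mask, map);
  }
  if (min_count > 1) {
    for (KmerMap::iterator it = map.begin(); it != map.end();) {
      if (it->second < (uint32_t)min_count) it = map.erase(it);
      else ++it;
    }
  }
  return ptr;
}

// [[Rcpp::export(name = ".kgraph_size")]]
double kgraph_size(SEXP graph) {
  XPtr<KmerMap> ptr(graph);
  return (double)ptr->size();
}

// [[Rcpp::export(name = ".kgraph_median_coverage")]]
double kgraph_median_coverage(SEXP graph) {
  XPtr<KmerMap> ptr(graph);
  if (ptr->empty()) return 0.0;
  std::vector<uint32_t> v;
  v.reserve(ptr->size());
  for (KmerMap::const_iterator it = ptr->begin(); it != ptr->end(); ++it)
    v.push_back(it->second);
  size_t mid = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double m = v[mid];
  if (v.size() % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + mid - 1, v.end());
    m = 0.5 * (m + v[mid - 1]);
  }
  return m;
}

// [[Rcpp::export(name = ".kgraph_count")]]
NumericVector kgraph_count(SEXP graph, CharacterVector kmers, int k) {
  XPtr<KmerMap> ptr(graph);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) { out[i] = NA_REAL; continue; }
    uint64_t h = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { ok = false; break; }
      h = ((h << 2) | (uint64_t)c) & mask;
    }
    if (!ok) { out[i] = NA_REAL; continue; }
    KmerMap::const_iterator it = ptr->find(canonical(h, k));
    out[i] = (it == ptr->end()) ? 0.0 : (double)it->second;
  }
  return out;
}

// Greedy max-coverage walks among high-coverage k-mers; a revisit of a node on
// the current walk closes a cycle.  SNP bubbles resolve to the majority branch
// because the consensus successor dominates in coverage.
// [[Rcpp::export(name = ".kgraph_cycles")]]
List kgraph_cycles(SEXP graph, int k, double cov_threshold, int min_cycle,
                   int max_cycle, int max_cycles) {
  XPtr<KmerMap> ptr(graph);
  const KmerMap& map = *ptr;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  // high-coverage canonical nodes, sorted by coverage descending
  std::vector<std::pair<uint32_t, uint64_t> > high;
  for (KmerMap::const_iterator it = map.begin(); it != map.end(); ++it)
    if (it->second >= cov_threshold) high.push_back(std::make_pair(it->second, it->first));
  std::sort(high.begin(), high.end(), std::greater<std::pair<uint32_t, uint64_t> >());

  std::unordered_set<uint64_t> in_high;
  for (size_t i = 0; i < high.size(); ++i) in_high.insert(high[i].second);
  std::unordered_set<uint64_t> visited;  // canonical, across walks

  std::vector<std::string> cycles;
  std::vector<double> cycle_cov;
  for (size_t hstart = 0; hstart < high.size() && (int)cycles.size() < max_cycles; ++hstart) {
    uint64_t start_canon = high[hstart].second;
    if (visited.count(start_canon)) continue;
    uint64_t cur = start_canon;  // oriented = its canonical form
    std::unordered_map<uint64_t, int> seen_at;  // oriented kmer -> step
    std::vector<uint64_t> path;                 // oriented kmers
    int guard = max_cycle + 2 * k + 64;
    bool closed = false;
    for (int step = 0; step <= guard; ++step) {
      std::unordered_map<uint64_t, int>::iterator sit = seen_at.find(cur);
      if (sit != seen_at.end()) {
        int s = sit->second;
        int len = (int)path.size() - s;
        if (len >= min_cycle && len <= max_cycle) {
          std::string cyc;
          cyc.reserve(len);
          double covsum = 0.0;
          for (int i = s; i < (int)path.size(); ++i) {
            cyc.push_back(BASES[path[i] & 3]);
            KmerMap::const_iterator cit = map.find(canonical(path[i], k));
            covsum += (cit == map.end()) ? 0.0 : cit->second;
          }
          cycles.push_back(cyc);
          cycle_cov.push_back(covsum / len);
        }
        closed = true;
        break;
      }
      seen_at[cur] = (int)path.size();
      path.push_back(cur);
      visited.insert(canonical(cur, k));
      // best successor among high-coverage nodes
      uint64_t best_next = 0;
      uint32_t best_cov = 0;
      bool found = false;
      for (int b = 0; b < 4; ++b) {
        uint64_t nxt = ((cur << 2) | (uint64_t)b) & mask;
        uint64_t cn = canonical(nxt, k);
        if (!in_high.count(cn)) continue;
        KmerMap::const_iterator cit = map.find(cn);
        uint32_t cov = (cit == map.end()) ? 0 : cit->second;
        if (!found || cov > best_cov) { best_next = nxt; best_cov = cov; found = true; }
      }
      if (!found) break;  // dead end
      cur = best_next;
    }
    (void)closed;
  }
  return List::create(_["cycle"] = wrap(cycles), _["coverage"] = wrap(cycle_cov));
}

// Which reads share at least one exact k-mer (either strand) with `target`?
// [[Rcpp::export(name = ".reads_sharing_kmer")]]
LogicalVector reads_sharing_kmer(CharacterVector reads, std::string target, int k) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::unordered_set<uint64_t> tset;
  {
    uint64_t h = 0; int valid = 0;
    for (size_t i = 0; i < target.size(); ++i) {
      int c = base_code(target[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++valid >= k) tset.insert(canonical(h, k));
    }
  }
  LogicalVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    bool hit = false;
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < len && !hit; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++valid >= k && tset.count(canonical(h, k))) hit = true;
    }
    out[r] = hit;
  }
  return out;
}
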