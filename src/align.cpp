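#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Ungapped seed-and-extend read placement against a transcript/consensus
// reference. Scoring: match +1, mismatch -1; 'N' (either side) never
// matches. Only full-length placements are considered, so the aligned span
// always equals the read length.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char base_comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct Hit {
  int ref;
  int pos;
};

// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector reads, CharacterVector refs,
                          int k, double min_frac) {
  if (k < 1 || k > 31) stop("seed length must be in [1, 31]");
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  // forward-strand k-mer index; seeds containing N are never indexed
  std::unordered_map<uint64_t, std::vector<Hit> > index;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  {
    size_t total = 0;
    for (int r = 0; r < nref; ++r) total += R[r].size();
    index.reserve(total + 1);
  }
  for (int r = 0; r < nref; ++r) {
    const std::string& s = R[r];
    const int n = (int)s.size();
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[key].push_back(Hit{r, i - k + 1});
    }
  }

  std::vector<int> o_read, o_ref, o_start, o_strand, o_score, o_match, o_mm;

  const int nreads = reads.size();
  for (int q = 0; q < nreads; ++q) {
    const std::string fwd = as<std::string>(reads[q]);
    const int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = base_comp(fwd[i]);
    const double thr = min_frac * (double)L - 1e-9;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = (strand == 0) ? fwd : rev;

      // collect candidate (ref, start) diagonals from exact seed hits
      std::unordered_set<uint64_t> seen;
      std::vector<std::pair<int, int> > cand;
      uint64_t key = 0;
      int run = 0;
      for (int i = 0; i < L; ++i) {
        const int c = base_code(s[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run < k) continue;
        std::unordered_map<uint64_t, std::vector<Hit> >::const_iterator it =
            index.find(key);
        if (it == index.end()) continue;
        const int p = i - k + 1;
        for (size_t h = 0; h < it->second.size(); ++h) {
          const int r = it->second[h].ref;
          const int start = it->second[h].pos - p;
          if (start < 0 || start + L > (int)R[r].size()) continue;
          const uint64_t ck = ((uint64_t)r << 40) | (uint64_t)start;
          if (seen.insert(ck).second) cand.push_back(std::make_pair(r, start));
        }
      }

      // full ungapped extension over the read's extent
      for (size_t j = 0; j < cand.size(); ++j) {
        const std::string& t = R[cand[j].first];
        const int start = cand[j].second;
        int m = 0;
        for (int i = 0; i < L; ++i) {
          const char a = s[i];
          if (a == t[start + i] && base_code(a) >= 0) ++m;
        }
        const int score = 2 * m - L;
        if ((double)score >= thr) {
          o_read.push_back(q + 1);
          o_ref.push_back(cand[j].first + 1);
          o_start.push_back(start);
          o_strand.push_back(strand);
          o_score.push_back(score);
          o_match.push_back(m);
          o_mm.push_back(L - m);
        }
      }
    }
  }

  return DataFrame::create(
      _["read"] = o_read, _["ref"] = o_ref, _["start"] = o_start,
      _["strand"] = o_strand, _["score"] = o_score, _["matches"] = o_match,
      _["mismatches"] = o_mm);
}
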