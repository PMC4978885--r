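#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char cb(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = cb(c);
  return r;
}

// Forward k-mer set of the reference, 2-bit encoded (k <= 32).
static void ref_kmer_set(const std::vector<std::string>& refs, int k,
                         std::unordered_set<uint64_t>& set) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (const auto& s : refs) {
    uint64_t f = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      const int b = b2(s[i]);
      if (b < 0) { valid = 0; f = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      if (++valid >= k) set.insert(f);
    }
  }
}

// Fraction of a read's k-mers (either strand) present in the reference
// forward k-mer set.  Reads shorter than k, or with no valid k-mer, score 0.
// [[Rcpp::export]]
NumericVector cpp_kmer_hit_fraction(CharacterVector reads,
                                    CharacterVector ref_seqs, int k) {
  if (k < 4 || k > 32) stop("k must be between 4 and 32");
  std::vector<std::string> refs(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i)
    refs[i] = as<std::string>(ref_seqs[i]);
  std::unordered_set<uint64_t> set;
  ref_kmer_set(refs, k, set);

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  NumericVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    const std::string s = as<std::string>(reads[r]);
    uint64_t f = 0, rcv = 0;
    int valid = 0, total = 0, hits = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      const int b = b2(s[i]);
      if (b < 0) { valid = 0; f = 0; rcv = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      rcv = (rcv >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++valid >= k) {
        ++total;
        if (set.count(f) || set.count(rcv)) ++hits;
      }
    }
    out[r] = total == 0 ? 0.0 : (double)hits / (double)total;
  }
  return out;
}

// Ungapped mismatch-counting read mapper.  Candidate (element, offset)
// placements come from exact seed_k-mer matches; each read is assigned to
// the panel element giving the fewest mismatches over the aligned region
// (both strands), provided the aligned region covers >= min_aligned_frac of
// the read and mismatches <= floor(max_mismatches * aligned_len / 100).
// Ties: fewest mismatches, then forward strand, then lowest element index,
// then lowest offset.  Returns the 1-based panel index, 0 if unassigned.
// [[Rcpp::export]]
IntegerVector cpp_map_reads(CharacterVector reads, CharacterVector panel,
                            int max_mismatches, double min_aligned_frac,
                            int seed_k) {
  if (seed_k < 4 || seed_k > 32) stop("seed_k must be between 4 and 32");
  const int ne = panel.size();
  std::vector<std::string> elems(ne);
  for (int e = 0; e < ne; ++e) elems[e] = as<std::string>(panel[e]);

  const uint64_t mask =
      (seed_k == 32) ? ~0ULL : ((1ULL << (2 * seed_k)) - 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int e = 0; e < ne; ++e) {
    const std::string& s = elems[e];
    uint64_t f = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      const int b = b2(s[i]);
      if (b < 0) { valid = 0; f = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_k)
        index[f].push_back({e, (int)i - seed_k + 1});
    }
  }

  IntegerVector out(reads.size());
  std::unordered_set<uint64_t> seen;
  for (int r = 0; r < reads.size(); ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    int best_mm = INT32_MAX, best_e = -1;
    seen.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string s = strand == 0 ? fwd : rc(fwd);
      uint64_t f = 0; int valid = 0;
      for (int i = 0; i < L; ++i) {
        const int b = b2(s[i]);
        if (b < 0) { valid = 0; f = 0; continue; }
        f = ((f << 2) | (uint64_t)b) & mask;
        if (++valid < seed_k) continue;
        auto it = index.find(f);
        if (it == index.end()) continue;
        const int p = i - seed_k + 1;
        for (const auto& hit : it->second) {
          const int e = hit.first;
          const int off = hit.second - p; // element position of read base 0
          const int elen = (int)elems[e].size();
          const int astart = std::max(0, -off);
          const int aend = std::min(L, elen - off);
          const int alen = aend - astart;
          if (alen < (int)(min_aligned_frac * L - 1e-9)) continue;
          const uint64_t key =
              ((uint64_t)(uint32_t)e << 33) |
              ((uint64_t)(uint32_t)(off + L) << 1) | (uint64_t)strand;
          if (!seen.insert(key).second) continue;
          const int allowed =
              (int)((double)max_mismatches * (double)alen / 100.0 + 1e-9);
          int mm = 0;
          const std::string& el = elems[e];
          for (int q = astart; q < aend; ++q) {
            if (s[q] != el[q + off]) {
              if (++mm > allowed && mm >= best_mm) break;
            }
          }
          if (mm <= allowed && mm < best_mm) {
            best_mm = mm;
            best_e = e;
            if (best_mm == 0 && strand == 0) { /* keep scanning ties cheaply */ }
          } else if (mm <= allowed && mm == best_mm && e < best_e) {
            best_e = e;
          }
        }
      }
    }
    out[r] = best_e < 0 ? 0 : best_e + 1;
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
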