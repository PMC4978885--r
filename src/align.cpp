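#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Overlap (free-end-gap) alignment with linear gap costs:
// match +1, mismatch -2, gap -3.  Identity is matches / alignment columns,
// columns counted over the traceback path (internal gaps included, terminal
// free gaps excluded).  Edges of the read-similarity graph require
// identity >= 0.90 over >= 0.55 * min(len_a, len_b) columns.

struct AlnRes {
  int score;
  int matches;
  int columns;
};

static const int MATCH = 1;
static const int MISMATCH = -2;
static const int GAP = -3;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Score-only semi-global DP over two rolling rows; no traceback.  Used as
// an exact pre-test: an alignment meeting identity >= min_id over w
// columns scores at least w * (min_id * 1 + (1 - min_id) * (-3)), so a
// best score below that bound for w = min_overlap rules the edge out.
static int overlap_score_only(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  static thread_local std::vector<int> prev, cur;
  prev.assign(m + 1, 0);
  cur.assign(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = (ai == b[j - 1] && ai != 'N') ? MATCH : MISMATCH;
      int v = prev[j - 1] + s;
      const int up = prev[j] + GAP;
      if (up > v) v = up;
      const int left = cur[j - 1] + GAP;
      if (left > v) v = left;
      cur[j] = v;
    }
    if (cur[m] > best) best = cur[m];
    std::swap(prev, cur);
  }
  for (int j = 0; j <= m; ++j)
    if (prev[j] > best) best = prev[j];
  return best;
}

// Semi-global DP over the full matrix with traceback.  Deterministic
// tie-breaking: diagonal > up > left in the recurrence; the best end cell is
// the first maximum met scanning the last column top-to-bottom, then the
// last row left-to-right.
static AlnRes overlap_dp(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnRes res = {0, 0, 0};
  if (n == 0 || m == 0) return res;
  if ((double)(n + 1) * (double)(m + 1) > 6.4e7)
    stop("sequences too long for dense overlap alignment");

  static thread_local std::vector<int> H;
  static thread_local std::vector<uint8_t> D; // 0 stop, 1 diag, 2 up, 3 left
  H.assign((size_t)(n + 1) * (m + 1), 0);
  D.assign((size_t)(n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) { H[idx(0, j)] = 0; D[idx(0, j)] = 0; }
  for (int i = 0; i <= n; ++i) { H[idx(i, 0)] = 0; D[idx(i, 0)] = 0; }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = (ai == b[j - 1] && ai != 'N') ? MATCH : MISMATCH;
      int best = H[idx(i - 1, j - 1)] + s;
      uint8_t d = 1;
      const int up = H[idx(i - 1, j)] + GAP;
      if (up > best) { best = up; d = 2; }
      const int left = H[idx(i, j - 1)] + GAP;
      if (left > best) { best = left; d = 3; }
      H[idx(i, j)] = best;
      D[idx(i, j)] = d;
    }
  }

  int bi = 0, bj = 0, bscore = INT32_MIN;
  for (int i = 0; i <= n; ++i)
    if (H[idx(i, m)] > bscore) { bscore = H[idx(i, m)]; bi = i; bj = m; }
  for (int j = 0; j <= m; ++j)
    if (H[idx(n, j)] > bscore) { bscore = H[idx(n, j)]; bi = n; bj = j; }

  if (bscore <= 0) return res; // no positive-scoring overlap

  int i = bi, j = bj, matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    const uint8_t d = D[idx(i, j)];
    if (d == 1) {
      ++columns;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      --i; --j;
    } else if (d == 2) {
      ++columns; --i;
    } else if (d == 3) {
      ++columns; --j;
    } else {
      break;
    }
  }
  res.score = bscore;
  res.matches = matches;
  res.columns = columns;
  return res;
}

static inline bool meets_thresholds(const AlnRes& r, int la, int lb,
                                    double min_id, double min_ov_frac) {
  if (r.columns <= 0) return false;
  const double min_ov = min_ov_frac * (double)std::min(la, lb);
  if ((double)r.columns < min_ov - 1e-9) return false;
  return (double)r.matches >= min_id * (double)r.columns - 1e-9;
}

struct PairBest {
  bool found;
  AlnRes aln;
  int strand; // +1 forward, -1 reverse-complement
};

static PairBest best_pair(const std::string& a, const std::string& b,
                          double min_id, double min_ov_frac) {
  const int la = (int)a.size(), lb = (int)b.size();
  // necessary score bound for any alignment meeting the thresholds
  const double min_ov = min_ov_frac * (double)std::min(la, lb);
  const double bound =
      min_ov * (min_id * MATCH + (1.0 - min_id) * GAP) - 1e-9;
  const std::string brc = revcomp(b);
  const bool try_f = (double)overlap_score_only(a, b) >= bound;
  const bool try_r = (double)overlap_score_only(a, brc) >= bound;
  AlnRes f = try_f ? overlap_dp(a, b) : AlnRes{0, 0, 0};
  AlnRes r = try_r ? overlap_dp(a, brc) : AlnRes{0, 0, 0};
  const bool mf = meets_thresholds(f, la, lb, min_id, min_ov_frac);
  const bool mr = meets_thresholds(r, la, lb, min_id, min_ov_frac);
  PairBest out{false, {0, 0, 0}, 1};
  if (mf && mr) {
    if (r.score > f.score) { out = {true, r, -1}; }
    else { out = {true, f, 1}; }
  } else if (mf) {
    out = {true, f, 1};
  } else if (mr) {
    out = {true, r, -1};
  }
  return out;
}

// [[Rcpp::export]]
List cpp_overlap_align(std::string a, std::string b) {
  AlnRes r = overlap_dp(a, b);
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["columns"] = r.columns);
}

// [[Rcpp::export]]
List cpp_pair_similarity(std::string a, std::string b, double min_identity,
                         double min_overlap_frac) {
  PairBest p = best_pair(a, b, min_identity, min_overlap_frac);
  if (!p.found) return List::create(_["edge"] = false);
  return List::create(
      _["edge"] = true,
      _["identity"] = (double)p.aln.matches / (double)p.aln.columns,
      _["overlap"] = p.aln.columns, _["score"] = p.aln.score,
      _["strand"] = p.strand == 1 ? "+" : "-");
}

// ---- canonical k-mer machinery for the shared-kmer prescreen -------------

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// All canonical (min of forward / reverse-complement encoding) k-mers of s,
// one entry per position; positions containing non-ACGT bases are skipped.
static void canonical_kmers(const std::string& s, int k,
                            std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    const int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) out.push_back(std::min(fwd, rev));
  }
}

// Canonical k-mers with their 0-based start position and an orientation
// flag (1 when the canonical form is the reverse complement of the
// occurrence).  Encoded as (kmer << 17) | (pos << 1) | flag, sorted by
// kmer value; positions must fit 16 bits.
static void canonical_kmers_pos(const std::string& s, int k,
                                std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  if (n > 60000) stop("sequences longer than 60 kb are not supported here");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    const int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      const int pos = i - k + 1;
      const uint64_t canon = std::min(fwd, rev);
      const uint64_t flag = (rev < fwd) ? 1 : 0;
      out.push_back((canon << 17) | ((uint64_t)pos << 1) | flag);
    }
  }
  std::sort(out.begin(), out.end());
}

// Banded score-only semi-global DP: alignments are restricted to cells
// whose diagonal d = (row - col) lies in [dlo, dhi].  Returns an upper
// bound that is exact for any alignment inside the band, which suffices as
// a necessary-score test when the band provably contains every
// threshold-meeting alignment.
static int overlap_score_banded(const std::string& a, const std::string& b,
                                int dlo, int dhi, double early_bound = 0) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  dlo = std::max(dlo, -m);
  dhi = std::min(dhi, n);
  if (dlo > dhi) return 0;
  const int W = dhi - dlo + 1;
  if ((long long)W * 4 >= (long long)(n + m)) // band nearly dense
    return overlap_score_only(a, b);
  const int NEG = -1000000;
  static thread_local std::vector<int> prev, cur;
  prev.assign(W, NEG);
  cur.assign(W, NEG);
  // row 0: cells (0, j) with d = -j in band -> score 0
  for (int d = dlo; d <= dhi; ++d)
    if (d <= 0 && -d <= m) prev[d - dlo] = 0;
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int rowbest = NEG;
    for (int d = dhi; d >= dlo; --d) {
      const int j = i - d;
      if (j < 0 || j > m) { cur[d - dlo] = NEG; continue; }
      if (j == 0) { cur[d - dlo] = 0; continue; } // free leading gap in b
      int v = NEG;
      // diagonal step from (i-1, j-1): same d, previous row
      {
        const int p = prev[d - dlo];
        if (p > NEG) {
          const int s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N')
                            ? MATCH : MISMATCH;
          v = p + s;
        }
      }
      // up step from (i-1, j): diagonal d-1, previous row
      if (d - 1 >= dlo) {
        const int p = prev[d - 1 - dlo];
        if (p > NEG && p + GAP > v) v = p + GAP;
      }
      // left step from (i, j-1): diagonal d+1, current row
      if (d + 1 <= dhi) {
        const int p = cur[d + 1 - dlo];
        if (p > NEG && p + GAP > v) v = p + GAP;
      }
      cur[d - dlo] = v;
      if (v > rowbest) rowbest = v;
      if ((i == n || j == m) && v > best) best = v;
    }
    // no path through this row (or a fresh start below it) can still reach
    // early_bound: matches gain at most +1 per remaining row
    if (early_bound > 0 && (double)best < early_bound &&
        (double)(std::max(rowbest, 0) + (n - i)) < early_bound)
      return best;
    std::swap(prev, cur);
  }
  return best;
}

// Multiset intersection size of two sorted k-mer vectors.
static int shared_kmer_count(const std::vector<uint64_t>& x,
                             const std::vector<uint64_t>& y, int cap) {
  int c = 0; size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (y[j] < x[i]) ++j;
    else { ++c; if (c >= cap) return c; ++i; ++j; }
  }
  return c;
}

// [[Rcpp::export]]
DataFrame cpp_all_pair_edges(CharacterVector seqs, double min_identity,
                             double min_overlap_frac, bool prefilter,
                             int prefilter_k, int min_shared) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);

  std::vector<std::vector<uint64_t>> kms;
  if (prefilter) {
    kms.resize(n);
    for (int i = 0; i < n; ++i) {
      canonical_kmers(ss[i], prefilter_k, kms[i]);
      std::sort(kms[i].begin(), kms[i].end());
    }
  }

  std::vector<int> ia, ja, ov;
  std::vector<double> id;
  std::vector<std::string> str;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (prefilter &&
          shared_kmer_count(kms[i], kms[j], min_shared) < min_shared)
        continue;
      PairBest p = best_pair(ss[i], ss[j], min_identity, min_overlap_frac);
      if (p.found) {
        ia.push_back(i + 1); ja.push_back(j + 1);
        id.push_back((double)p.aln.matches / (double)p.aln.columns);
        ov.push_back(p.aln.columns);
        str.push_back(p.strand == 1 ? "+" : "-");
      }
    }
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ja, _["identity"] = id,
                           _["overlap"] = ov, _["strand"] = str,
                           _["stringsAsFactors"] = false);
}

// ---- union-find ----------------------------------------------------------

struct UnionFind {
  std::vector<int> parent, sz;
  explicit UnionFind(int n) : parent(n), sz(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
    return r;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a; sz[a] += sz[b];
  }
};

// Single-linkage connected components under the similarity-edge rule.
// Sequences are processed in input order against an index of canonical
// prefilter k-mers of the sequences already seen.  A pair is aligned only
// when it shares >= min_shared k-mer occurrences and its two members are not
// already in the same component; failed pairs are memoised.  Because every
// pair that satisfies the edge thresholds is guaranteed to share at least
// min_shared k-mers (pigeonhole over matched runs, for sequences >= 80
// bases at k = 8), the resulting components equal those of the brute-force
// all-pairs graph.
// [[Rcpp::export]]
IntegerVector cpp_cluster_components(CharacterVector seqs, double min_identity,
                                     double min_overlap_frac, int prefilter_k,
                                     int min_shared, bool verbose = false) {
  long long n_visits = 0, n_cand = 0, n_band = 0, n_aln = 0;
  const int n = seqs.size();
  const int k = prefilter_k;
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);

  UnionFind uf(n);
  if (prefilter_k > 15) stop("prefilter_k must be <= 15");
  const size_t nvals = 1ULL << (2 * k);
  // kmer value -> entries (j << 17 | pos << 1 | orientation flag);
  // entries of one j are contiguous because each sequence appends its
  // (value-sorted) kmers in one pass.  The canonical value space at k = 8
  // is small, so a flat array replaces a hash map.
  std::vector<std::vector<uint64_t>> buckets(nvals);
  std::unordered_set<uint64_t> failed;

  const int BIG = 1 << 29;
  // per-candidate-j accumulators: shared-kmer counts (min multiplicity per
  // value) and observed diagonal ranges, per relative strand
  struct Acc {
    int32_t cf, cr, dminf, dmaxf, dminr, dmaxr;
  };
  std::vector<Acc> acc(n, Acc{0, 0, BIG, -BIG, BIG, -BIG});
  std::vector<int> touched, cand;
  std::vector<uint64_t> kms;

  for (int i = 0; i < n; ++i) {
    canonical_kmers_pos(ss[i], k, kms);

    touched.clear();
    for (size_t a = 0; a < kms.size();) {
      const uint64_t val = kms[a] >> 17;
      size_t b = a + 1;
      while (b < kms.size() && (kms[b] >> 17) == val) ++b;
      // i's occurrences of this value, by orientation flag
      int aF = 0, aR = 0, minPiF = BIG, maxPiF = -BIG, minPiR = BIG,
          maxPiR = -BIG;
      for (size_t t = a; t < b; ++t) {
        const int pos = (int)((kms[t] >> 1) & 0xFFFF);
        if (kms[t] & 1) {
          ++aR;
          if (pos < minPiR) minPiR = pos;
          if (pos > maxPiR) maxPiR = pos;
        } else {
          ++aF;
          if (pos < minPiF) minPiF = pos;
          if (pos > maxPiF) maxPiF = pos;
        }
      }
      const std::vector<uint64_t>& v = buckets[val];
      n_visits += (long long)v.size();
      for (size_t p = 0; p < v.size();) {
        const int j = (int)(v[p] >> 17);
        size_t q = p;
        int bF = 0, bR = 0, minPjF = BIG, maxPjF = -BIG, minPjR = BIG,
            maxPjR = -BIG;
        while (q < v.size() && (int)(v[q] >> 17) == j) {
          const int pos = (int)((v[q] >> 1) & 0xFFFF);
          if (v[q] & 1) {
            ++bR;
            if (pos < minPjR) minPjR = pos;
            if (pos > maxPjR) maxPjR = pos;
          } else {
            ++bF;
            if (pos < minPjF) minPjF = pos;
            if (pos > maxPjF) maxPjF = pos;
          }
          ++q;
        }
        Acc& A = acc[j];
        if (A.cf == 0 && A.cr == 0) touched.push_back(j);
        // same relative strand: F-F and R-R occurrence pairs
        const int mFF = std::min(aF, bF), mRR = std::min(aR, bR);
        if (mFF + mRR > 0) {
          A.cf += mFF + mRR;
          if (mFF > 0) {
            if (minPiF - maxPjF < A.dminf) A.dminf = minPiF - maxPjF;
            if (maxPiF - minPjF > A.dmaxf) A.dmaxf = maxPiF - minPjF;
          }
          if (mRR > 0) {
            if (minPiR - maxPjR < A.dminf) A.dminf = minPiR - maxPjR;
            if (maxPiR - minPjR > A.dmaxf) A.dmaxf = maxPiR - minPjR;
          }
        }
        // opposite relative strand: F-R and R-F; diagonal in revcomp(b)
        // coordinates is pi + pj - (len_b - k)
        const int mFR = std::min(aF, bR), mRF = std::min(aR, bF);
        if (mFR + mRF > 0) {
          A.cr += mFR + mRF;
          if (mFR > 0) {
            if (minPiF + minPjR < A.dminr) A.dminr = minPiF + minPjR;
            if (maxPiF + maxPjR > A.dmaxr) A.dmaxr = maxPiF + maxPjR;
          }
          if (mRF > 0) {
            if (minPiR + minPjF < A.dminr) A.dminr = minPiR + minPjF;
            if (maxPiR + maxPjF > A.dmaxr) A.dmaxr = maxPiR + maxPjF;
          }
        }
        p = q;
      }
      a = b;
    }

    cand.clear();
    for (int j : touched)
      if (acc[j].cf >= min_shared || acc[j].cr >= min_shared)
        cand.push_back(j);
    std::sort(cand.begin(), cand.end());
    n_cand += (long long)cand.size();

    for (int j : cand) {
      if (uf.find(j) == uf.find(i)) continue;
      const uint64_t key = ((uint64_t)j << 32) | (uint64_t)i;
      if (failed.count(key)) continue;

      const std::string& a = ss[i];
      const std::string& b = ss[j];
      const int la = (int)a.size(), lb = (int)b.size();
      const int minlen = std::min(la, lb);
      const double bound =
          min_overlap_frac * (double)minlen *
              (min_identity * MATCH + (1.0 - min_identity) * GAP) - 1e-9;
      const int pad =
          (int)((1.0 - min_identity) / min_identity * (double)minlen) + 2;

      // banded necessary-score test around the observed seed diagonals;
      // a threshold-meeting alignment lies within `pad` diagonals of its
      // own seed kmers, all of which were observed above
      bool promising = false;
      ++n_band;
      const Acc& A = acc[j];
      if (A.cf >= min_shared) {
        const int sc = overlap_score_banded(a, b, A.dminf - pad,
                                            A.dmaxf + pad, bound);
        if ((double)sc >= bound) promising = true;
      }
      if (!promising && A.cr >= min_shared) {
        const std::string brc = revcomp(b);
        const int off = lb - k;
        const int sc = overlap_score_banded(a, brc, A.dminr - off - pad,
                                            A.dmaxr - off + pad, bound);
        if ((double)sc >= bound) promising = true;
      }
      if (promising) {
        ++n_aln;
        PairBest p = best_pair(a, b, min_identity, min_overlap_frac);
        if (p.found) { uf.unite(i, j); continue; }
      }
      failed.insert(key);
    }

    for (int j : touched) acc[j] = Acc{0, 0, BIG, -BIG, BIG, -BIG};
    for (uint64_t km : kms)
      buckets[km >> 17].push_back(((uint64_t)i << 17) | (km & 0x1FFFF));
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  if (verbose)
    Rprintf("cluster_components: %lld visits, %lld candidates, %lld banded, %lld full alignments\n",
            n_visits, n_cand, n_band, n_aln);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = uf.find(i) + 1;
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
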