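#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// All randomness is drawn from R's RNG so that set.seed() at the R level
// makes every simulator byte-reproducible.

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
std::string cpp_random_dna(int len) {
  std::string s(len, 'A');
  for (int i = 0; i < len; ++i) s[i] = BASES[runif_int(4)];
  return s;
}

// Substitution-only mutation: each site is replaced, with probability rate,
// by one of the three other bases chosen uniformly.
// [[Rcpp::export]]
std::string cpp_mutate_seq(std::string seq, double rate) {
  if (rate <= 0) return seq;
  for (size_t i = 0; i < seq.size(); ++i) {
    if (unif_rand() < rate) {
      const char old = seq[i];
      int oi;
      switch (old) { case 'A': oi = 0; break; case 'C': oi = 1; break;
                     case 'G': oi = 2; break; case 'T': oi = 3; break;
                     default:  oi = -1; }
      if (oi < 0) { seq[i] = BASES[runif_int(4)]; continue; }
      int pick = runif_int(3);
      if (pick >= oi) ++pick;
      seq[i] = BASES[pick];
    }
  }
  return seq;
}

// Uniform single-end reads: start positions uniform over valid starts,
// strand uniform, per-base substitution errors at error_rate.
// [[Rcpp::export]]
List cpp_simulate_reads(std::string genome, int n_reads, int read_len,
                        double error_rate) {
  const int G = (int)genome.size();
  if (G < read_len) stop("genome shorter than read length");
  const int nstart = G - read_len + 1;
  CharacterVector seqs(n_reads);
  IntegerVector starts(n_reads);
  CharacterVector strands(n_reads);
  std::string buf(read_len, 'A');
  for (int r = 0; r < n_reads; ++r) {
    const int s0 = runif_int(nstart);
    const bool rev = unif_rand() < 0.5;
    if (!rev) {
      for (int i = 0; i < read_len; ++i) buf[i] = genome[s0 + i];
    } else {
      for (int i = 0; i < read_len; ++i)
        buf[i] = comp(genome[s0 + read_len - 1 - i]);
    }
    if (error_rate > 0) {
      for (int i = 0; i < read_len; ++i) {
        if (unif_rand() < error_rate) {
          const char old = buf[i];
          int oi;
          switch (old) { case 'A': oi = 0; break; case 'C': oi = 1; break;
                         case 'G': oi = 2; break; case 'T': oi = 3; break;
                         default:  oi = -1; }
          if (oi < 0) { buf[i] = BASES[runif_int(4)]; continue; }
          int pick = runif_int(3);
          if (pick >= oi) ++pick;
          buf[i] = BASES[pick];
        }
      }
    }
    seqs[r] = buf;
    starts[r] = s0 + 1; // 1-based
    strands[r] = rev ? "-" : "+";
    if (r % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["bases"] = seqs, _["start"] = starts,
                      _["strand"] = strands);
}
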