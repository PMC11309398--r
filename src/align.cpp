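#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Ungapped alignment with Hamming mismatches only: the synthetic read model
// emits exact substrings with substitution errors, so gapped alignment is
// deliberately out of scope.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Minimum Hamming distance of `read` over all full-length ungapped placements
// within `ref`, restricted to start offsets in [lo, hi]; early exit once a
// placement with <= cap mismatches is found. Returns cap+1 if none.
static int best_hamming(const std::string& read, const std::string& ref,
                        int lo, int hi, int cap) {
  const int L = (int)read.size();
  int best = cap + 1;
  for (int s = lo; s <= hi; ++s) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      if (read[i] != ref[s + i] && ++mm >= best) break;
    }
    if (mm < best) {
      best = mm;
      if (best == 0) return 0;
    }
  }
  return best;
}

// [[Rcpp::export]]
LogicalVector cpp_map_reads(CharacterVector reads, CharacterVector refs,
                            int max_mismatch) {
  const int n = reads.size(), m = refs.size();
  std::vector<std::string> R(m);
  for (int j = 0; j < m; ++j) R[j] = as<std::string>(refs[j]);
  LogicalVector mapped(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::string rc = revcomp(rd);
    const int L = (int)rd.size();
    bool hit = false;
    for (int j = 0; j < m && !hit; ++j) {
      const int hi = (int)R[j].size() - L;
      if (hi < 0) continue;
      if (max_mismatch == 0) {
        hit = R[j].find(rd) != std::string::npos ||
              R[j].find(rc) != std::string::npos;
      } else {
        hit = best_hamming(rd, R[j], 0, hi, max_mismatch) <= max_mismatch ||
              best_hamming(rc, R[j], 0, hi, max_mismatch) <= max_mismatch;
      }
    }
    mapped[i] = hit;
  }
  return mapped;
}

// Best linear assignment used to derive per-transcript counts from simulated
// reads: index (1-based) of the reference with the fewest mismatches, NA when
// no reference admits a placement within max_mismatch. Ties take the first
// reference in input order (assignment feeds count totals, not inference).
// [[Rcpp::export]]
IntegerVector cpp_assign_reads(CharacterVector reads, CharacterVector refs,
                               int max_mismatch) {
  const int n = reads.size(), m = refs.size();
  std::vector<std::string> R(m);
  for (int j = 0; j < m; ++j) R[j] = as<std::string>(refs[j]);
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::string rc = revcomp(rd);
    const int L = (int)rd.size();
    int best = max_mismatch + 1, best_j = NA_INTEGER;
    for (int j = 0; j < m; ++j) {
      const int hi = (int)R[j].size() - L;
      if (hi < 0) continue;
      int cap = best - 1;
      if (cap < 0) break;
      int mmf = best_hamming(rd, R[j], 0, hi, cap);
      int mmr = best_hamming(rc, R[j], 0, hi, cap);
      int mm = mmf < mmr ? mmf : mmr;
      if (mm < best) { best = mm; best_j = j + 1; if (best == 0) break; }
    }
    if (best <= max_mismatch) out[i] = best_j;
  }
  return out;
}

// Back-splice junction assignment. A read counts toward a junction iff it has
// a full-length ungapped placement in junction_seq (either orientation) with
// <= max_mismatch mismatches that covers >= min_anchor nt on each side of the
// breakpoint. Among qualifying junctions the unique mismatch-minimum wins;
// ties across distinct junctions discard the read as ambiguous.
// Returns: 0 = no hit, -1 = ambiguous, otherwise 1-based junction index.
// [[Rcpp::export]]
IntegerVector cpp_assign_junction_reads(CharacterVector reads,
                                        CharacterVector junc_seqs,
                                        IntegerVector breakpoints,
                                        int min_anchor, int max_mismatch) {
  const int n = reads.size(), m = junc_seqs.size();
  std::vector<std::string> J(m);
  for (int j = 0; j < m; ++j) J[j] = as<std::string>(junc_seqs[j]);
  IntegerVector out(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::string rc = revcomp(rd);
    const int L = (int)rd.size();
    int best = max_mismatch + 1, best_j = 0;
    bool tie = false;
    for (int j = 0; j < m; ++j) {
      const int Jlen = (int)J[j].size();
      const int bp = breakpoints[j];
      // anchor rule: start s must satisfy s <= bp - min_anchor and
      // s + L >= bp + min_anchor, within [0, Jlen - L]
      int lo = bp + min_anchor - L; if (lo < 0) lo = 0;
      int hi = bp - min_anchor; if (hi > Jlen - L) hi = Jlen - L;
      if (hi < lo) continue;
      int mmf = best_hamming(rd, J[j], lo, hi, max_mismatch);
      int mmr = best_hamming(rc, J[j], lo, hi, max_mismatch);
      int mm = mmf < mmr ? mmf : mmr;
      if (mm > max_mismatch) continue;
      if (mm < best) { best = mm; best_j = j + 1; tie = false; }
      else if (mm == best) tie = true;
    }
    if (best <= max_mismatch) out[i] = tie ? -1 : best_j;
  }
  return out;
}
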