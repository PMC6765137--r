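#include <Rcpp.h>
#include <cstring>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// ---- encoding helpers -------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// IUPAC bitmask: A=1, C=2, G=4, T=8
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
  case 'U': return 8;
  case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
  case 'K': return 4|8; case 'M': return 1|2;
  case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
  case 'N': return 15;
  default: return 0;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S'; case 'W': return 'W';
  case 'K': return 'M'; case 'M': return 'K'; case 'B': return 'V'; case 'V': return 'B';
  case 'D': return 'H'; case 'H': return 'D'; case 'U': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = comp_char(s[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector C_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// ---- IUPAC primer scan ------------------------------------------------------

// Best ungapped match of a degenerate primer against seq at offsets [lo, hi]
// (0-based, inclusive). Returns c(offset, mismatches) or c(-1, -1).
// Fewest mismatches wins; ties -> smallest offset.
// [[Rcpp::export]]
IntegerVector C_iupac_best(std::string primer, std::string seq, int max_mismatch,
                           int lo, int hi) {
  int plen = primer.size(), slen = seq.size();
  std::vector<int> pmask(plen);
  for (int i = 0; i < plen; ++i) pmask[i] = iupac_mask(primer[i]);
  if (hi > slen - plen) hi = slen - plen;
  if (lo < 0) lo = 0;
  int best_off = -1, best_mm = max_mismatch + 1;
  for (int off = lo; off <= hi; ++off) {
    int mm = 0;
    for (int i = 0; i < plen; ++i) {
      int bm = iupac_mask(seq[off + i]);
      // match iff the primer set contains the read base
      if (bm == 0 || (pmask[i] & bm) != bm) {
        if (++mm >= best_mm) break;
      }
    }
    if (mm < best_mm) { best_mm = mm; best_off = off; }
    if (best_mm == 0) break;
  }
  if (best_off < 0) return IntegerVector::create(-1, -1);
  return IntegerVector::create(best_off, best_mm);
}

// Primer detection / orientation for a batch of reads.
// Returns a matrix with one row per read:
//   status, orient (0 fwd / 1 rc), start, end (insert, 0-based half-open,
//   in oriented-read coordinates), mismatches.
// status: 0 kept, 1 no forward primer, 2 no reverse primer, 3 ambiguous orientation
// [[Rcpp::export]]
IntegerMatrix C_remove_primers(CharacterVector seqs, std::string fwd, std::string rev,
                               int max_mismatch, int window) {
  int n = seqs.size();
  std::string rcrev = revcomp_str(rev);
  int flen = fwd.size(), rlen = rcrev.size();
  IntegerMatrix out(n, 5);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string s_rc = revcomp_str(s);
    int slen = s.size();
    // search each orientation
    int off_f[2], mm_f[2], off_r[2], mm_r[2];
    bool full[2];
    bool fwd_found_any = false;
    for (int o = 0; o < 2; ++o) {
      const std::string &x = (o == 0) ? s : s_rc;
      IntegerVector hf = C_iupac_best(fwd, x, max_mismatch, 0, window - flen);
      off_f[o] = hf[0]; mm_f[o] = hf[1];
      if (hf[0] >= 0) fwd_found_any = true;
      IntegerVector hr = (hf[0] >= 0)
        ? C_iupac_best(rcrev, x, max_mismatch, slen - window, slen - rlen)
        : IntegerVector::create(-1, -1);
      off_r[o] = hr[0]; mm_r[o] = hr[1];
      full[o] = (hf[0] >= 0 && hr[0] >= 0 && hr[0] >= hf[0] + flen);
    }
    int status, orient = 0, start = 0, end = 0, mm = 0;
    if (full[0] && full[1]) {
      int t0 = mm_f[0] + mm_r[0], t1 = mm_f[1] + mm_r[1];
      if (t0 == t1) { status = 3; }
      else { orient = (t1 < t0) ? 1 : 0; status = 0; }
    } else if (full[0]) { status = 0; orient = 0; }
    else if (full[1]) { status = 0; orient = 1; }
    else status = fwd_found_any ? 2 : 1;
    if (status == 0) {
      start = off_f[orient] + flen;
      end = off_r[orient];
      mm = mm_f[orient] + mm_r[orient];
    }
    out(r, 0) = status; out(r, 1) = orient; out(r, 2) = start; out(r, 3) = end;
    out(r, 4) = mm;
  }
  return out;
}

// ---- kmer screen ------------------------------------------------------------

// Sequence-ordered kmer code array (2 bits/base); non-ACGT bases force code 0.
// [[Rcpp::export]]
List C_kmer_arrays(CharacterVector seqs, int k) {
  if (k <= 0) stop("k must be positive");
  int n = seqs.size();
  List ord(n), srt(n);
  int mask = (1 << (2 * k)) - 1;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int L = s.size();
    int nk = L - k + 1;
    if (nk < 1) stop("sequence shorter than k");
    IntegerVector kv(nk);
    int code = 0;
    for (int i = 0; i < L; ++i) {
      int b = base_code(s[i]);
      if (b < 0) b = 0;
      code = ((code << 2) | b) & mask;
      if (i >= k - 1) kv[i - k + 1] = code;
    }
    IntegerVector ks = clone(kv);
    std::sort(ks.begin(), ks.end());
    ord[r] = kv; srt[r] = ks;
  }
  return List::create(_["ordered"] = ord, _["sorted"] = srt);
}

// kdist = 1 - (multiset overlap of sorted arrays)/min(n_a, n_b);
// ungapped shortcut flag = (in-order overlap == multiset overlap).
// [[Rcpp::export]]
NumericVector C_kmer_compare(IntegerVector orda, IntegerVector srta,
                             IntegerVector ordb, IntegerVector srtb) {
  int na = srta.size(), nb = srtb.size();
  int i = 0, j = 0, unordered = 0;
  while (i < na && j < nb) {
    if (srta[i] == srtb[j]) { ++unordered; ++i; ++j; }
    else if (srta[i] < srtb[j]) ++i;
    else ++j;
  }
  int m = std::min(na, nb), ordered = 0;
  for (int t = 0; t < m; ++t) if (orda[t] == ordb[t]) ++ordered;
  double kdist = 1.0 - (double)unordered / (double)m;
  return NumericVector::create(kdist, (ordered == unordered) ? 1.0 : 0.0);
}

// Batch kdist/ungapped of one query against many subjects.
// [[Rcpp::export]]
NumericMatrix C_kmer_compare_many(IntegerVector ordq, IntegerVector srtq,
                                  List ords, List srts) {
  int n = ords.size();
  NumericMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    NumericVector v = C_kmer_compare(ordq, srtq, ords[r], srts[r]);
    out(r, 0) = v[0]; out(r, 1) = v[1];
  }
  return out;
}

// ---- banded Needleman-Wunsch ------------------------------------------------

#define NEG_INF (-1000000000)

// Pointers: 1 diagonal, 2 up (consume s1, gap in s2), 3 left (consume s2, gap in s1).
// Tie preference during DP: diagonal > up > left (so traceback is deterministic).
// End gaps are penalized. Cells with |i - j| > band are unreachable.
static int nw_banded_core(const std::string &s1, const std::string &s2,
                          int match, int mismatch, int gap, int band,
                          std::string &a1, std::string &a2) {
  int n1 = s1.size(), n2 = s2.size();
  int width = 2 * band + 1;
  std::vector<int> prev(width + 2), cur(width + 2);
  std::vector<unsigned char> ptr((size_t)(n1 + 1) * width, 0);
  // row i holds cells j in [i-band, i+band]; slot = j - (i - band)
  for (int sl = 0; sl < width; ++sl) {
    int j = sl - band;  // i = 0
    if (j >= 0 && j <= n2 && j <= band) {
      prev[sl] = j * gap;
      ptr[sl] = (j == 0) ? 0 : 3;
    } else prev[sl] = NEG_INF;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int sl = 0; sl < width; ++sl) cur[sl] = NEG_INF;
    int jlo = std::max(0, i - band), jhi = std::min(n2, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int sl = j - (i - band);
      int best = NEG_INF; unsigned char p = 0;
      if (j > 0) {  // diagonal from (i-1, j-1): slot in prev = (j-1) - (i-1-band) = sl
        int d = prev[sl];
        if (d > NEG_INF) {
          int sc = d + ((s1[i-1] == s2[j-1]) ? match : mismatch);
          if (sc > best) { best = sc; p = 1; }
        }
      } else { // j == 0: only up is possible
      }
      {  // up from (i-1, j): slot in prev = j - (i-1-band) = sl + 1
        if (sl + 1 < width) {
          int u = prev[sl + 1];
          if (u > NEG_INF) {
            int sc = u + gap;
            if (sc > best) { best = sc; p = 2; }
          }
        }
      }
      if (j > jlo) {  // left from (i, j-1): slot sl - 1 in cur
        int l = cur[sl - 1];
        if (l > NEG_INF) {
          int sc = l + gap;
          if (sc > best) { best = sc; p = 3; }
        }
      }
      if (i == 0 && j == 0) { best = 0; p = 0; }
      cur[sl] = best;
      ptr[(size_t)i * width + sl] = p;
    }
    std::swap(prev, cur);
  }
  int slend = n2 - (n1 - band);
  if (slend < 0 || slend >= width) return NEG_INF;
  int score = prev[slend];
  if (score <= NEG_INF) return NEG_INF;
  // traceback
  a1.clear(); a2.clear();
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    int sl = j - (i - band);
    unsigned char p = ptr[(size_t)i * width + sl];
    if (p == 1) { a1.push_back(s1[i-1]); a2.push_back(s2[j-1]); --i; --j; }
    else if (p == 2) { a1.push_back(s1[i-1]); a2.push_back('-'); --i; }
    else if (p == 3) { a1.push_back('-'); a2.push_back(s2[j-1]); --j; }
    else break;
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return score;
}

// [[Rcpp::export]]
List C_nwalign_banded(std::string s1, std::string s2, int match, int mismatch,
                      int gap, int band) {
  int n1 = s1.size(), n2 = s2.size();
  if (band < 1) stop("band must be >= 1");
  if (std::abs(n1 - n2) >= band)
    return List::create(_["refused"] = true);
  std::string a1, a2;
  int score = nw_banded_core(s1, s2, match, mismatch, gap, band, a1, a2);
  if (score <= NEG_INF) return List::create(_["refused"] = true);
  return List::create(_["refused"] = false, _["score"] = score,
                      _["al1"] = a1, _["al2"] = a2);
}

// ---- lambda: error-model likelihood of a member given a center --------------

// rates indexed [true*4*94 + obs*94 + q] with true/obs in 0..3, q in 0..93.
static double lambda_from_alignment(const std::string &ac, const std::string &am,
                                    const IntegerVector &qual, const double *rates,
                                    double log_indel) {
  double ll = 0.0;
  int mpos = 0;  // position in member sequence
  int L = ac.size();
  for (int c = 0; c < L; ++c) {
    char tc = ac[c], mc = am[c];
    if (tc != '-' && mc != '-') {
      int t = base_code(tc), o = base_code(mc);
      if (t < 0 || o < 0) return 0.0;
      int q = qual[mpos];
      ll += std::log(rates[(t * 4 + o) * 94 + q]);
      ++mpos;
    } else if (mc != '-') {  // insertion in member relative to center
      ll += log_indel;
      ++mpos;
    } else {                 // deletion in member relative to center
      ll += log_indel;
    }
  }
  return std::exp(ll);
}

// Batch lambda of many unique sequences against one center.
// ungapped[i]: the kmer screen certified the positional alignment as optimal.
// Returns lambda (0 where the banded alignment is refused).
// [[Rcpp::export]]
NumericVector C_lambda_batch(std::string center, CharacterVector seqs, List quals,
                             LogicalVector ungapped, int band, int match,
                             int mismatch, int gap, NumericVector rates,
                             double indel_rate) {
  int n = seqs.size();
  NumericVector out(n);
  double log_indel = std::log(indel_rate);
  const double *rr = REAL(rates);
  int nc = center.size();
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    IntegerVector q = quals[r];
    int ns = s.size();
    if (ungapped[r] && ns == nc) {
      double ll = 0.0;
      bool ok = true;
      for (int i = 0; i < ns; ++i) {
        int t = base_code(center[i]), o = base_code(s[i]);
        if (t < 0 || o < 0) { ok = false; break; }
        ll += std::log(rr[(t * 4 + o) * 94 + q[i]]);
      }
      out[r] = ok ? std::exp(ll) : 0.0;
    } else {
      if (std::abs(ns - nc) >= band) { out[r] = 0.0; continue; }
      std::string a1, a2;
      int score = nw_banded_core(center, s, match, mismatch, gap, band, a1, a2);
      if (score <= NEG_INF) { out[r] = 0.0; continue; }
      out[r] = lambda_from_alignment(a1, a2, q, rr, log_indel);
    }
  }
  return out;
}

// Batch alignment of many sequences against one center (for transition counting).
// Returns a list with al1 (center, gapped) and al2 per sequence; refused -> NULL.
// [[Rcpp::export]]
List C_align_batch(std::string center, CharacterVector seqs, LogicalVector ungapped,
                   int band, int match, int mismatch, int gap) {
  int n = seqs.size(), nc = center.size();
  List out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int ns = s.size();
    if (ungapped[r] && ns == nc) {
      out[r] = CharacterVector::create(center, s);
    } else {
      if (std::abs(ns - nc) >= band) { out[r] = R_NilValue; continue; }
      std::string a1, a2;
      int score = nw_banded_core(center, s, match, mismatch, gap, band, a1, a2);
      if (score <= NEG_INF) { out[r] = R_NilValue; continue; }
      out[r] = CharacterVector::create(a1, a2);
    }
  }
  return out;
}

// Alignment score only (used to pick the best truth for error profiling).
// Returns NA_INTEGER when refused.
// [[Rcpp::export]]
IntegerVector C_score_batch(std::string query, CharacterVector subjects, int band,
                            int match, int mismatch, int gap) {
  int n = subjects.size(), nq = query.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(subjects[r]);
    if (std::abs((int)s.size() - nq) >= band) { out[r] = NA_INTEGER; continue; }
    std::string a1, a2;
    int score = nw_banded_core(query, s, match, mismatch, gap, band, a1, a2);
    out[r] = (score <= NEG_INF) ? NA_INTEGER : score;
  }
  return out;
}
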