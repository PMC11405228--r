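#include <Rcpp.h>
#include <vector>

// Maximal repeat-pair scan under the fixed-pair Hamming model.
//
// Forward pairs: for every offset d, positions p where seq[p] == seq[p+d]
// form a binary match string; the maximal windows containing at most max_mm
// mismatches are exactly the windows delimited by consecutive mismatch
// sentinels.  Palindromic pairs: for every antidiagonal c = start1 + start2 +
// length - 1, position p of copy 1 pairs with c - p of copy 2 and matching
// means complementarity; the copy-1 domain is clipped at floor((c-1)/2) so
// that the copies never overlap.  Bases are coded 0..3 (A,C,G,T); negative
// codes (N or anything non-ACGT) never match, including each other.

static inline void emit_windows(const std::vector<int>& z, int Ld, int max_mm,
                                int min_len, int dom_off, int pair_c, int d,
                                bool palindromic, std::vector<int>& out) {
  // z holds sentinel 0, the 1-based mismatch positions within the domain,
  // and sentinel Ld + 1
  const int K = static_cast<int>(z.size()) - 2;
  if (K <= max_mm) {
    if (Ld >= min_len) {
      int a = 1, b = Ld;
      int p1 = dom_off + a - 1;
      int p2 = palindromic ? pair_c - (dom_off + b - 1) : p1 + d;
      out.push_back(p1); out.push_back(p2);
      out.push_back(b - a + 1); out.push_back(K);
    }
    return;
  }
  for (int t = 0; t + max_mm + 1 <= K + 1; ++t) {
    int a = z[t] + 1;
    int b = z[t + max_mm + 1] - 1;
    int len = b - a + 1;
    if (len < min_len) continue;
    int p1 = dom_off + a - 1;
    int p2 = palindromic ? pair_c - (dom_off + b - 1) : p1 + d;
    out.push_back(p1); out.push_back(p2);
    out.push_back(len); out.push_back(max_mm);
  }
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix scan_repeat_pairs(Rcpp::IntegerVector code, int min_len,
                                      int max_mm, bool palindromic) {
  const int n = code.size();
  std::vector<int> out;
  std::vector<int> z;
  if (n >= 2 * min_len || (!palindromic && n > min_len)) {
    if (!palindromic) {
      for (int d = 1; d <= n - 1; ++d) {
        const int Ld = n - d;
        if (Ld < min_len) break;
        z.clear();
        z.push_back(0);
        for (int p = 1; p <= Ld; ++p) {
          const int a = code[p - 1], b = code[p - 1 + d];
          if (a < 0 || b < 0 || a != b) z.push_back(p);
        }
        z.push_back(Ld + 1);
        emit_windows(z, Ld, max_mm, min_len, 1, 0, d, false, out);
      }
    } else {
      for (int c = 3; c <= 2 * n - 1; ++c) {
        const int pmin = std::max(1, c - n);
        const int pmax = (c - 1) / 2;
        const int Ld = pmax - pmin + 1;
        if (Ld < min_len) continue;
        z.clear();
        z.push_back(0);
        for (int p = pmin; p <= pmax; ++p) {
          const int a = code[p - 1], b = code[c - p - 1];
          if (a < 0 || b < 0 || a + b != 3) z.push_back(p - pmin + 1);
        }
        z.push_back(Ld + 1);
        emit_windows(z, Ld, max_mm, min_len, pmin, c, 0, true, out);
      }
    }
  }
  const int nr = static_cast<int>(out.size()) / 4;
  Rcpp::IntegerMatrix res(nr, 4);
  for (int i = 0; i < nr; ++i) {
    res(i, 0) = out[4 * i];
    res(i, 1) = out[4 * i + 1];
    res(i, 2) = out[4 * i + 2];
    res(i, 3) = out[4 * i + 3];
  }
  colnames(res) = Rcpp::CharacterVector::create("start1", "start2", "length",
                                                "mismatches");
  return res;
}
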