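#ifndef SAXSEARCH_NARROW_H
#define SAXSEARCH_NARROW_H

#include <Rcpp.h>
#include <string>

// Rank of the symbol at offset `depth` past the suffix starting at sa[i]-1.
// A suffix that ends exactly at the requested depth has no symbol there and
// sorts before every suffix that does, hence rank -1.
inline int char_rank_at(const std::string& text, const Rcpp::IntegerVector& sa,
                        int i /* 0-based rank */, int depth,
                        const Rcpp::IntegerVector& rank256) {
  const long pos = (long)sa[i] - 1 + depth;
  if (pos >= (long)text.size()) return -1;
  return rank256[(unsigned char)text[pos]];
}

// Maximal sub-interval of the half-open rank interval [sp, ep) (1-based)
// whose suffixes carry a symbol of rank r at offset `depth`. Two binary
// searches; empty in -> empty out.
inline void narrow_core(const std::string& text, const Rcpp::IntegerVector& sa,
                        int sp, int ep, int depth, int r,
                        const Rcpp::IntegerVector& rank256,
                        int& out_sp, int& out_ep) {
  int lo = sp, hi = ep;  // first rank with char rank >= r
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (char_rank_at(text, sa, mid - 1, depth, rank256) < r) lo = mid + 1;
    else hi = mid;
  }
  out_sp = lo;
  hi = ep;               // first rank with char rank > r
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (char_rank_at(text, sa, mid - 1, depth, rank256) <= r) lo = mid + 1;
    else hi = mid;
  }
  out_ep = lo;
}

#endif
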