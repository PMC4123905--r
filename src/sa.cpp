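#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "narrow.h"
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)); positions returned 1-based.
// [[Rcpp::export]]
IntegerVector cpp_build_sa(const std::string& text, const IntegerVector& rank256) {
  const int n = (int)text.size();
  if (n < 1) stop("text must be non-empty");
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) {
    int r = rank256[(unsigned char)text[i]];
    if (r < 0) stop("symbol '%s' not in alphabet", std::string(1, text[i]));
    sa[i] = i;
    rnk[i] = r;
  }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_narrow(const std::string& text, const IntegerVector& sa,
                         int sp, int ep, int depth, const std::string& ch,
                         const IntegerVector& rank256) {
  if (ch.size() != 1) stop("expected a single symbol");
  int r = rank256[(unsigned char)ch[0]];
  if (r < 0) stop("symbol '%s' not in alphabet", ch);
  int nsp, nep;
  narrow_core(text, sa, sp, ep, depth, r, rank256, nsp, nep);
  return IntegerVector::create(nsp, nep);
}

namespace {

struct PtabBuilder {
  const std::string& text;
  const IntegerVector& sa;
  const IntegerVector& rank256;
  const std::string& residues;
  int max_depth;
  std::vector<std::vector<int>> sp_tab, ep_tab;

  PtabBuilder(const std::string& t, const IntegerVector& s,
              const IntegerVector& r2, const std::string& res, int md)
      : text(t), sa(s), rank256(r2), residues(res), max_depth(md) {
    sp_tab.resize(md);
    ep_tab.resize(md);
    long sz = 1;
    for (int d = 0; d < md; ++d) {
      sz *= (long)residues.size();
      sp_tab[d].assign(sz, 0);
      ep_tab[d].assign(sz, 0);
    }
  }

  void fill(int depth, long idx, int sp, int ep) {
    const int R = (int)residues.size();
    for (int r = 0; r < R; ++r) {
      long cidx = idx * R + r;
      int nsp, nep;
      if (sp == ep) {  // narrowing an empty interval leaves it untouched
        nsp = sp;
        nep = ep;
      } else {
        int rk = rank256[(unsigned char)residues[r]];
        narrow_core(text, sa, sp, ep, depth, rk, rank256, nsp, nep);
      }
      sp_tab[depth][cidx] = nsp;
      ep_tab[depth][cidx] = nep;
      if (depth + 1 < max_depth) fill(depth + 1, cidx, nsp, nep);
    }
  }
};

}  // namespace

// Lookup table of SA intervals for every residue string of length 1..max_depth.
// Entry for key c1..cd lives at flat index ((r1*R + r2)*R + ...)+1 where ri is
// the 0-based index of ci in `residues`.
// [[Rcpp::export]]
List cpp_build_ptable(const std::string& text, const IntegerVector& sa,
                      const IntegerVector& rank256, const std::string& residues,
                      int max_depth) {
  if (max_depth < 1) stop("max_depth must be >= 1");
  PtabBuilder b(text, sa, rank256, residues, max_depth);
  b.fill(0, 0, 1, (int)sa.size() + 1);
  List sp(max_depth), ep(max_depth);
  for (int d = 0; d < max_depth; ++d) {
    sp[d] = IntegerVector(b.sp_tab[d].begin(), b.sp_tab[d].end());
    ep[d] = IntegerVector(b.ep_tab[d].begin(), b.ep_tab[d].end());
  }
  return List::create(_["sp"] = sp, _["ep"] = ep);
}
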