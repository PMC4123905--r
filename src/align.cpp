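#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {
const int NEG = INT_MIN / 4;
}

// X-drop ungapped extension. Each row of `seeds` is (q_pos, db_pos, length,
// score), 1-based. Left and right extensions are independent; a direction
// stops at a text boundary, at a delimiter, or once the running score falls
// below best - x_drop. Returns (q_start, q_end, db_start, db_end, score),
// 1-based inclusive, always containing the seed.
// [[Rcpp::export]]
IntegerMatrix cpp_ungapped_extend(const std::string& q_text, const std::string& db_text,
                                  const IntegerMatrix& seeds,
                                  const IntegerMatrix& score256, int x_drop,
                                  const std::string& delim) {
  const unsigned char dl = (unsigned char)delim[0];
  const long nq = (long)q_text.size(), ndb = (long)db_text.size();
  IntegerMatrix out(seeds.nrow(), 5);
  for (int r = 0; r < seeds.nrow(); ++r) {
    const long q0 = seeds(r, 0) - 1, d0 = seeds(r, 1) - 1;
    const int len = seeds(r, 2);
    int seed_score = 0;
    for (int k = 0; k < len; ++k)
      seed_score += score256((unsigned char)q_text[q0 + k],
                             (unsigned char)db_text[d0 + k]);
    // right
    int run = seed_score, best_r = seed_score, ext_r = 0;
    for (long t = 1;; ++t) {
      const long qi = q0 + len - 1 + t, di = d0 + len - 1 + t;
      if (qi >= nq || di >= ndb) break;
      const unsigned char cq = (unsigned char)q_text[qi],
                          cd = (unsigned char)db_text[di];
      if (cq == dl || cd == dl) break;
      run += score256(cq, cd);
      if (run > best_r) {
        best_r = run;
        ext_r = (int)t;
      } else if (run < best_r - x_drop) {
        break;
      }
    }
    // left
    run = seed_score;
    int best_l = seed_score, ext_l = 0;
    for (long t = 1;; ++t) {
      const long qi = q0 - t, di = d0 - t;
      if (qi < 0 || di < 0) break;
      const unsigned char cq = (unsigned char)q_text[qi],
                          cd = (unsigned char)db_text[di];
      if (cq == dl || cd == dl) break;
      run += score256(cq, cd);
      if (run > best_l) {
        best_l = run;
        ext_l = (int)t;
      } else if (run < best_l - x_drop) {
        break;
      }
    }
    out(r, 0) = (int)(q0 - ext_l) + 1;
    out(r, 1) = (int)(q0 + len - 1 + ext_r) + 1;
    out(r, 2) = (int)(d0 - ext_l) + 1;
    out(r, 3) = (int)(d0 + len - 1 + ext_r) + 1;
    out(r, 4) = best_l + best_r - seed_score;
  }
  colnames(out) = CharacterVector::create("q_start", "q_end", "db_start",
                                          "db_end", "score");
  return out;
}

namespace {

struct HalfResult {
  int score = 0;
  int qi = 0, sj = 0;           // consumed lengths at the best cell
  int ident = 0, mism = 0, gapopen = 0, len = 0;
};

// Affine-gap extension DP from a fixed corner: H[i][j] is the best score of
// an alignment consuming exactly q[0..i) and s[0..j). Cells falling more
// than x_drop below the running best are removed from the frontier. If
// `force` the answer must consume at least one residue of each side (used so
// the anchor pair itself is always aligned). Full traceback for statistics;
// instances here are one query frame vs one subject, so quadratic tables are
// cheap.
HalfResult xdrop_half(const std::string& q, const std::string& s,
                      const IntegerMatrix& S, int go, int ge, double x_drop,
                      bool force) {
  const int n = (int)q.size(), m = (int)s.size();
  const int W = m + 1;
  std::vector<int> H((long)(n + 1) * W, NEG), E((long)(n + 1) * W, NEG),
      F((long)(n + 1) * W, NEG);
  // move codes: 0 stop, 1 diag, 2 from E (gap in q), 3 from F (gap in s)
  std::vector<unsigned char> mv((long)(n + 1) * W, 0), mvE((long)(n + 1) * W, 0),
      mvF((long)(n + 1) * W, 0);
  const bool finite = R_finite(x_drop);
  H[0] = 0;
  int best = force ? NEG : 0, bi = 0, bj = 0;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      const long c = (long)i * W + j;
      int e = NEG, f = NEG, h = NEG;
      if (j > 0) {
        const long l = c - 1;
        if (H[l] > NEG) e = H[l] - go - ge;
        if (E[l] > NEG && E[l] - ge > e) {
          e = E[l] - ge;
          mvE[c] = 1;  // extend
        }
      }
      if (i > 0) {
        const long u = c - W;
        if (H[u] > NEG) f = H[u] - go - ge;
        if (F[u] > NEG && F[u] - ge > f) {
          f = F[u] - ge;
          mvF[c] = 1;
        }
      }
      if (i > 0 && j > 0) {
        const long d = c - W - 1;
        if (H[d] > NEG)
          h = H[d] + S((unsigned char)q[i - 1], (unsigned char)s[j - 1]);
      }
      int v = h;
      unsigned char move = 1;
      if (e > v) {
        v = e;
        move = 2;
      }
      if (f > v) {
        v = f;
        move = 3;
      }
      if (v <= NEG) {
        mv[c] = 0;
        continue;
      }
      if (finite && v < best - x_drop) {
        // whole cell leaves the frontier, gap states included
        H[c] = NEG;
        E[c] = NEG;
        F[c] = NEG;
        mv[c] = 0;
        continue;
      }
      H[c] = v;
      E[c] = e;
      F[c] = f;
      mv[c] = move;
      const bool ok = !force || (i > 0 && j > 0);
      if (ok && v > best) {
        best = v;
        bi = i;
        bj = j;
      }
    }
  }
  HalfResult res;
  if (best <= NEG) {  // force requested but nothing alignable
    res.score = NEG;
    return res;
  }
  res.score = best;
  res.qi = bi;
  res.sj = bj;
  // traceback
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    const long c = (long)i * W + j;
    if (state == 0) {
      const unsigned char move = mv[c];
      if (move == 1) {
        ++res.len;
        if (q[i - 1] == s[j - 1]) ++res.ident;
        else ++res.mism;
        --i;
        --j;
      } else if (move == 2) {
        state = 1;
      } else if (move == 3) {
        state = 2;
      } else {
        break;  // reached an unreachable/start cell
      }
    } else if (state == 1) {
      ++res.len;
      if (!mvE[c]) {
        ++res.gapopen;
        state = 0;
      }
      --j;
    } else {
      ++res.len;
      if (!mvF[c]) {
        ++res.gapopen;
        state = 0;
      }
      --i;
    }
  }
  return res;
}

}  // namespace

// Gapped X-drop extension outward from an anchor cell (q_anchor, s_anchor,
// both 1-based): the anchor pair is always aligned, the left half runs on
// the reversed prefixes including the anchor, the right half on the suffixes
// beyond it. With an infinite dropoff this is the optimal local alignment
// through the anchor.
// [[Rcpp::export]]
List cpp_gapped_extend(const std::string& q, const std::string& s, int q_anchor,
                       int s_anchor, const IntegerMatrix& score256, int gap_open,
                       int gap_extend, double x_drop) {
  std::string ql(q.begin(), q.begin() + q_anchor);
  std::string sl(s.begin(), s.begin() + s_anchor);
  std::reverse(ql.begin(), ql.end());
  std::reverse(sl.begin(), sl.end());
  HalfResult L =
      xdrop_half(ql, sl, score256, gap_open, gap_extend, x_drop, true);
  HalfResult R = xdrop_half(q.substr(q_anchor), s.substr(s_anchor), score256,
                            gap_open, gap_extend, x_drop, false);
  if (L.score <= NEG)
    return List::create(_["score"] = NA_INTEGER);
  return List::create(
      _["score"] = L.score + R.score,
      _["q_start"] = q_anchor - L.qi + 1, _["q_end"] = q_anchor + R.qi,
      _["s_start"] = s_anchor - L.sj + 1, _["s_end"] = s_anchor + R.sj,
      _["n_ident"] = L.ident + R.ident, _["n_mismatch"] = L.mism + R.mism,
      _["n_gapopen"] = L.gapopen + R.gapopen, _["length"] = L.len + R.len);
}
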