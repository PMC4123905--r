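#include <Rcpp.h>
#include <vector>
#include "narrow.h"
using namespace Rcpp;

namespace {

struct SeedRec {
  int q_pos, db_pos, len, score;
};

struct Ctx {
  const std::string& q_text;
  const IntegerVector& q_sa;
  const std::string& db_text;
  const IntegerVector& db_sa;
  const IntegerMatrix& S;       // 256 x 256 byte-indexed scores
  const IntegerVector& rank256; // collation ranks
  const std::string& alphabet;  // symbols in collation order
  int t_seed, d_bound, length_max;
  long max_pairs;               // per-state cap on emitted seeds, -1 = none
  unsigned char delim;
  // optional prefix table for database-side narrowing
  bool has_ptab;
  int ptab_depth;
  std::vector<IntegerVector> ptab_sp, ptab_ep;
  const IntegerVector* resix256; // residue -> 0..19, -1 otherwise
  std::vector<SeedRec> out;
};

inline void emit(Ctx& c, int spq, int epq, int spdb, int epdb, int len, int score) {
  long emitted = 0;
  for (int rq = spq; rq < epq; ++rq) {
    for (int rdb = spdb; rdb < epdb; ++rdb) {
      if (c.max_pairs >= 0 && emitted >= c.max_pairs) return;
      c.out.push_back({c.q_sa[rq - 1], c.db_sa[rdb - 1], len, score});
      ++emitted;
    }
  }
}

// Simultaneous depth-first descent of the two suffix arrays. A state is a
// pair of SA intervals sharing a matched depth; children extend both sides
// by one symbol each (at most |alphabet|^2 children). Emission at
// score >= T_seed stops extension of that state; pruning on score <= 0,
// score <= score_max - D, or depth = length_max.
void dfs(Ctx& c, int spq, int epq, int spdb, int epdb, int depth, int score,
         int score_max, long dbkey, bool dbkey_ok) {
  const int A = (int)c.alphabet.size();
  for (int a = 0; a < A; ++a) {
    const unsigned char cq = (unsigned char)c.alphabet[a];
    if (cq == c.delim) continue;
    int nspq, nepq;
    narrow_core(c.q_text, c.q_sa, spq, epq, depth, c.rank256[cq], c.rank256,
                nspq, nepq);
    if (nspq == nepq) continue;
    const int sm = score_max + c.S(cq, cq);
    for (int b = 0; b < A; ++b) {
      const unsigned char cdb = (unsigned char)c.alphabet[b];
      if (cdb == c.delim) continue;
      int nspdb, nepdb;
      long nkey = -1;
      bool nkey_ok = false;
      int ri = c.has_ptab ? (*c.resix256)[cdb] : -1;
      if (c.has_ptab && dbkey_ok && ri >= 0 && depth < c.ptab_depth) {
        nkey = dbkey * 20 + ri;
        nkey_ok = true;
        nspdb = c.ptab_sp[depth][nkey];
        nepdb = c.ptab_ep[depth][nkey];
      } else {
        narrow_core(c.db_text, c.db_sa, spdb, epdb, depth, c.rank256[cdb],
                    c.rank256, nspdb, nepdb);
      }
      if (nspdb == nepdb) continue;
      const int sc = score + c.S(cq, cdb);
      if (sc >= c.t_seed) {
        emit(c, nspq, nepq, nspdb, nepdb, depth + 1, sc);
      } else if (sc <= 0) {
        // dead: a higher-scoring sub-pair would be found from a later start
      } else if (sc <= sm - c.d_bound) {
        // lags the exact-match score of the query substring by >= D
      } else if (depth + 1 >= c.length_max) {
        // length budget exhausted without reaching T_seed
      } else {
        dfs(c, nspq, nepq, nspdb, nepdb, depth + 1, sc, sm, nkey, nkey_ok);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_seed_search(const std::string& q_text, const IntegerVector& q_sa,
                              const std::string& db_text, const IntegerVector& db_sa,
                              const IntegerMatrix& score256,
                              const IntegerVector& rank256,
                              const std::string& alphabet, int t_seed, int d_bound,
                              int length_max, double max_pairs,
                              const std::string& delim, Nullable<List> ptable,
                              const IntegerVector& resix256) {
  Ctx c{q_text, q_sa, db_text, db_sa, score256, rank256, alphabet,
        t_seed,  d_bound, length_max,
        (max_pairs < 0 || !R_finite(max_pairs)) ? -1L : (long)max_pairs,
        (unsigned char)delim[0], false, 0, {}, {}, &resix256, {}};
  if (ptable.isNotNull()) {
    List pt(ptable);
    List sp = pt["sp"], ep = pt["ep"];
    c.ptab_depth = sp.size();
    for (int d = 0; d < c.ptab_depth; ++d) {
      c.ptab_sp.push_back(sp[d]);
      c.ptab_ep.push_back(ep[d]);
    }
    c.has_ptab = true;
  }
  dfs(c, 1, (int)q_sa.size() + 1, 1, (int)db_sa.size() + 1, 0, 0, 0, 0, true);
  IntegerMatrix out((int)c.out.size(), 4);
  for (int i = 0; i < (int)c.out.size(); ++i) {
    out(i, 0) = c.out[i].q_pos;
    out(i, 1) = c.out[i].db_pos;
    out(i, 2) = c.out[i].len;
    out(i, 3) = c.out[i].score;
  }
  colnames(out) = CharacterVector::create("q_pos", "db_pos", "length", "score");
  return out;
}

// Independent per-pair walk: for every coordinate pair, accumulate the pair
// score one residue at a time, applying the emission test then the pruning
// tests in the same order as the DFS. Used as the brute-force reference.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_oracle(const std::string& q_text, const std::string& db_text,
                              const IntegerMatrix& score256, int t_seed, int d_bound,
                              int length_max, const std::string& delim) {
  const unsigned char dl = (unsigned char)delim[0];
  const long nq = (long)q_text.size(), ndb = (long)db_text.size();
  std::vector<SeedRec> out;
  for (long j = 0; j < nq; ++j) {
    if ((unsigned char)q_text[j] == dl) continue;
    for (long i = 0; i < ndb; ++i) {
      if ((unsigned char)db_text[i] == dl) continue;
      int score = 0, score_max = 0;
      for (int k = 0; k < length_max; ++k) {
        if (j + k >= nq || i + k >= ndb) break;
        const unsigned char cq = (unsigned char)q_text[j + k];
        const unsigned char cdb = (unsigned char)db_text[i + k];
        if (cq == dl || cdb == dl) break;
        score += score256(cq, cdb);
        score_max += score256(cq, cq);
        if (score >= t_seed) {
          out.push_back({(int)j + 1, (int)i + 1, k + 1, score});
          break;
        }
        if (score <= 0) break;
        if (score <= score_max - d_bound) break;
      }
    }
  }
  IntegerMatrix m((int)out.size(), 4);
  for (int i = 0; i < (int)out.size(); ++i) {
    m(i, 0) = out[i].q_pos;
    m(i, 1) = out[i].db_pos;
    m(i, 2) = out[i].len;
    m(i, 3) = out[i].score;
  }
  colnames(m) = CharacterVector::create("q_pos", "db_pos", "length", "score");
  return m;
}
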