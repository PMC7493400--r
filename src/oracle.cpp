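// Independent full-matrix Smith-Waterman/Gotoh oracle used for validation.
//
// Deliberately shares no code with the wavefront kernel: it stores the
// complete padded (m+1) x (n+1) E/F/H tables, fills them row by row (or
// column by column, for a self-consistency check), locates the maximum under
// the same tie-break as the engine's reduction (smallest query column, then
// smallest reference row), counts how many cells attain the maximum, and
// recovers the start by walking the optimal path back until a zero H cell.
//
// Traceback tie-break: when several optimal paths leave the best cell, the
// reported start is the lexicographic maximum of (query_start, ref_start)
// over all of them -- the path that begins latest in the query, then latest
// in the reference. This is the unique well-defined choice consistent with
// a column-then-row minimising reduction applied to the reversed-prefix
// problem, so starts are directly comparable with reverse scoring on
// unique-optimum instances. Implemented as a memoised walk of the
// optimal-move graph (every predecessor whose value re-derives the cell).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>

using namespace Rcpp;

namespace {

struct OracleScoring {
  bool dna;
  int match_score, mismatch_penalty, n_plain;
  std::vector<int> mat;
  int k;
  int gap_init, gap_ext;
  inline int sub(int a, int b) const {
    if (dna) return (a == b && a < n_plain) ? match_score : -mismatch_penalty;
    return mat[(size_t)a * k + b];
  }
};

std::vector<int> enc_or_stop(const std::string& s, const int* lut,
                             const char* role) {
  std::vector<int> out(s.size());
  for (size_t p = 0; p < s.size(); ++p) {
    const int c = lut[(unsigned char)s[p]];
    if (c < 0)
      stop("invalid residue '%c' at position %d in %s", s[p], (int)p + 1, role);
    out[p] = c;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_oracle")]]
List cpp_oracle(std::string query, std::string reference, IntegerVector lut,
                bool dna_mode, int match_score, int mismatch_penalty,
                int n_plain, IntegerMatrix submat, int gap_init, int gap_ext,
                bool column_major) {
  if (query.empty() || reference.empty()) stop("empty sequence");
  OracleScoring sc;
  sc.dna = dna_mode;
  sc.match_score = match_score;
  sc.mismatch_penalty = mismatch_penalty;
  sc.n_plain = n_plain;
  sc.gap_init = gap_init;
  sc.gap_ext = gap_ext;
  sc.k = 0;
  if (!dna_mode) {
    if (submat.nrow() != submat.ncol()) stop("substitution matrix must be square");
    sc.k = submat.nrow();
    sc.mat.resize((size_t)sc.k * sc.k);
    for (int a = 0; a < sc.k; ++a)
      for (int b = 0; b < sc.k; ++b) sc.mat[(size_t)a * sc.k + b] = submat(a, b);
  }

  const std::vector<int> q = enc_or_stop(query, INTEGER(lut), "query");
  const std::vector<int> r = enc_or_stop(reference, INTEGER(lut), "reference");
  const int n = (int)q.size(), m = (int)r.size();

  // padded tables, row 0 / column 0 are the zero boundary
  const size_t W = (size_t)n + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<int> E((size_t)(m + 1) * W, 0);
  std::vector<int> F((size_t)(m + 1) * W, 0);
  auto at = [W](std::vector<int>& T, int i, int j) -> int& {
    return T[(size_t)i * W + j];
  };

  auto fill_cell = [&](int i, int j) {
    const int e = std::max(at(E, i, j - 1) - sc.gap_ext,
                           at(H, i, j - 1) - sc.gap_init);
    const int f = std::max(at(F, i - 1, j) - sc.gap_ext,
                           at(H, i - 1, j) - sc.gap_init);
    const int d = at(H, i - 1, j - 1) + sc.sub(q[j - 1], r[i - 1]);
    at(E, i, j) = e;
    at(F, i, j) = f;
    at(H, i, j) = std::max(std::max(std::max(e, f), d), 0);
  };

  if (column_major) {
    for (int j = 1; j <= n; ++j)
      for (int i = 1; i <= m; ++i) fill_cell(i, j);
  } else {
    for (int i = 1; i <= m; ++i)
      for (int j = 1; j <= n; ++j) fill_cell(i, j);
  }

  // maximum under the engine tie-break: smallest column j, then smallest row i
  int best = 0, bi = -1, bj = -1, n_opt = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int h = at(H, i, j);
      if (h <= 0) continue;
      if (h > best) {
        best = h; bi = i; bj = j; n_opt = 1;
      } else if (h == best) {
        ++n_opt;
        if (j < bj || (j == bj && i < bi)) { bi = i; bj = j; }
      }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["query_start"] = -1,
                        _["query_end"] = -1, _["ref_start"] = -1,
                        _["ref_end"] = -1, _["n_optimal_cells"] = 0);
  }

  // Traceback until a zero H cell, maximising (query_start, ref_start)
  // lexicographically over all optimal paths. States are (layer, i, j) with
  // layers H/E/F; memo holds the best start encoded as qs * (m + 2) + rs
  // (1-based padded coordinates), or -1 for unvisited.
  const long long ENC = m + 2;
  std::vector<long long> memo(3 * (size_t)(m + 1) * W, -1);
  auto midx = [&](int layer, int i, int j) -> long long& {
    return memo[((size_t)layer * (m + 1) + i) * W + j];
  };

  std::function<long long(int, int, int)> walk = [&](int layer, int i,
                                                     int j) -> long long {
    long long& slot = midx(layer, i, j);
    if (slot >= 0) return slot;
    long long res = -1;
    if (layer == 0) {                       // H, value > 0 on any path
      const int h = at(H, i, j);
      if (h == at(H, i - 1, j - 1) + sc.sub(q[j - 1], r[i - 1])) {
        res = (at(H, i - 1, j - 1) == 0)
                  ? (long long)j * ENC + i  // the path starts at this cell
                  : walk(0, i - 1, j - 1);
      }
      if (h == at(E, i, j)) res = std::max(res, walk(1, i, j));
      if (h == at(F, i, j)) res = std::max(res, walk(2, i, j));
    } else if (layer == 1) {                // E: gap over the reference
      const int e = at(E, i, j);
      if (j > 1 && e == at(H, i, j - 1) - sc.gap_init && at(H, i, j - 1) > 0)
        res = walk(0, i, j - 1);
      if (j > 1 && e == at(E, i, j - 1) - sc.gap_ext)
        res = std::max(res, walk(1, i, j - 1));
    } else {                                // F: gap over the query
      const int f = at(F, i, j);
      if (i > 1 && f == at(H, i - 1, j) - sc.gap_init && at(H, i - 1, j) > 0)
        res = walk(0, i - 1, j);
      if (i > 1 && f == at(F, i - 1, j) - sc.gap_ext)
        res = std::max(res, walk(2, i - 1, j));
    }
    if (res < 0) stop("oracle traceback inconsistency at (%d, %d)", i, j);
    slot = res;
    return res;
  };

  const long long start = walk(0, bi, bj);
  const int qs = (int)(start / ENC), rs = (int)(start % ENC);

  return List::create(_["score"] = best, _["query_start"] = qs - 1,
                      _["query_end"] = bj - 1, _["ref_start"] = rs - 1,
                      _["ref_end"] = bi - 1, _["n_optimal_cells"] = n_opt);
}
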