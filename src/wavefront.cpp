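// Forward wavefront kernel and reverse-scoring start recovery.
//
// Geometry: query residues index the columns j = 0..n-1, reference residues
// the rows i = 0..m-1; anti-diagonal I = i + j runs 0..n+m-2. The kernel
// requires n <= m (callers swap roles and transpose coordinates). Only the
// two most recent H anti-diagonals are kept, plus per-column E/F carries and
// per-column running maxima, so working state is O(n) integers.
//
// Gotoh recurrences with penalties stored as non-negative magnitudes:
//   E(i,j) = max(E(i,j-1) - gap_ext, H(i,j-1) - gap_init)
//   F(i,j) = max(F(i-1,j) - gap_ext, H(i-1,j) - gap_init)
//   H(i,j) = max(E(i,j), F(i,j), H(i-1,j-1) + S(q_j, r_i), 0)
// First row/column of E, F, H are zero; E and F are not floored at zero.
//
// Tie-break: within a column the running maximum keeps the smallest row
// (strict-greater update); the final reduction keeps the smallest column.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Scoring {
  bool dna;               // true: match/mismatch scalars, false: matrix lookup
  int match_score;        // dna mode
  int mismatch_penalty;   // dna mode, applied negated
  int n_plain;            // dna mode: codes >= n_plain are ambiguity codes
  const int* mat;         // protein mode: row-major k x k score table
  int k;                  // protein mode: matrix dimension
  int gap_init;           // non-negative magnitude, subtracted
  int gap_ext;            // non-negative magnitude, subtracted

  inline int sub(int a, int b) const {
    if (dna) {
      if (a == b && a < n_plain) return match_score;
      return -mismatch_penalty;
    }
    return mat[a * k + b];
  }
};

struct Ends {
  int score;
  int q_end;   // column (query index), -1 sentinel when score == 0
  int r_end;   // row (reference index), -1 sentinel
  long long work_ints;  // allocated working-state integers (instrumentation)
};

// Forward scoring by anti-diagonal sweep. Valid for any (n, m); the public
// forward contract maps the shorter sequence to the columns, which callers
// arrange via forward_any().
Ends wave_forward(const std::vector<int>& q, const std::vector<int>& r,
                  const Scoring& sc) {
  const int n = (int)q.size(), m = (int)r.size();
  // two H diagonals; the new diagonal overwrites the older one in place
  // (descending-j fill: slot j-1 of the old diagonal is still unread)
  std::vector<int> h_a(n, 0), h_b(n, 0);        // rotating H diagonals
  std::vector<int> e_prev(n, 0), f_prev(n, 0);  // E/F of previous diagonal
  std::vector<int> col_max(n, 0), col_max_row(n, -1);

  int* h_prev = h_a.data();   // diagonal I-1
  int* h_new = h_b.data();    // receives diagonal I (holds I-2 on entry)

  const int n_diag = n + m - 1;
  for (int I = 0; I < n_diag; ++I) {
    const int lo = std::max(0, I - m + 1);
    const int hi = std::min(I, n - 1);
    for (int j = hi; j >= lo; --j) {
      const int i = I - j;
      // cell (i, j-1) lies on diagonal I-1 at column j-1
      const int e_left = (j > 0) ? e_prev[j - 1] : 0;
      const int h_left = (j > 0) ? h_prev[j - 1] : 0;
      // cell (i-1, j) lies on diagonal I-1 at column j
      const int f_up = (i > 0) ? f_prev[j] : 0;
      const int h_up = (i > 0) ? h_prev[j] : 0;
      // cell (i-1, j-1) lies on diagonal I-2 at column j-1
      const int h_diag = (i > 0 && j > 0) ? h_new[j - 1] : 0;

      const int e = std::max(e_left - sc.gap_ext, h_left - sc.gap_init);
      const int f = std::max(f_up - sc.gap_ext, h_up - sc.gap_init);
      int h = std::max(std::max(e, f), h_diag + sc.sub(q[j], r[i]));
      if (h < 0) h = 0;

      h_new[j] = h;
      e_prev[j] = e;
      f_prev[j] = f;
      if (h > col_max[j]) { col_max[j] = h; col_max_row[j] = i; }
    }
    std::swap(h_prev, h_new);  // h_prev now holds diagonal I
  }

  Ends out;
  out.work_ints = 6LL * n;
  out.score = 0; out.q_end = -1; out.r_end = -1;
  for (int j = 0; j < n; ++j) {           // smallest column wins ties
    if (col_max[j] > out.score) {
      out.score = col_max[j];
      out.q_end = j;
      out.r_end = col_max_row[j];
    }
  }
  if (out.score == 0) { out.q_end = -1; out.r_end = -1; }
  return out;
}

// Forward scoring with automatic role swap so the shorter sequence maps to
// the columns; coordinates are reported in the original (q, r) orientation.
Ends forward_any(const std::vector<int>& q, const std::vector<int>& r,
                 const Scoring& sc) {
  if (q.size() <= r.size()) return wave_forward(q, r, sc);
  Ends e = wave_forward(r, q, sc);
  std::swap(e.q_end, e.r_end);
  return e;
}

// Reverse-scoring phase: re-score the reversed prefixes ending at the
// forward best cell; by symmetry of the optimal alignment the reverse best
// cell yields the start coordinates. The kernel is run with the query on
// the columns even when the query prefix is the longer one: the sweep is
// valid for any (n, m), and keeping the orientation fixed keeps the
// tie-break (smallest query column, then smallest reference row) identical
// across all pairs, so reported starts never depend on prefix lengths.
void reverse_starts(const std::vector<int>& q, const std::vector<int>& r,
                    const Scoring& sc, int score, int q_end, int r_end,
                    int* q_start, int* r_start) {
  std::vector<int> qrev(q.begin(), q.begin() + q_end + 1);
  std::vector<int> rrev(r.begin(), r.begin() + r_end + 1);
  std::reverse(qrev.begin(), qrev.end());
  std::reverse(rrev.begin(), rrev.end());
  Ends rev = wave_forward(qrev, rrev, sc);
  if (rev.score != score)
    stop("internal consistency error: reverse-phase maximum (%d) != forward-phase maximum (%d)",
         rev.score, score);
  *q_start = q_end - rev.q_end;
  *r_start = r_end - rev.r_end;
}

Scoring make_scoring(bool dna_mode, int match_score, int mismatch_penalty,
                     int n_plain, const IntegerMatrix& submat,
                     int gap_init, int gap_ext) {
  Scoring sc;
  sc.dna = dna_mode;
  sc.match_score = match_score;
  sc.mismatch_penalty = mismatch_penalty;
  sc.n_plain = n_plain;
  sc.mat = nullptr;
  sc.k = 0;
  if (!dna_mode) {
    if (submat.nrow() != submat.ncol()) stop("substitution matrix must be square");
    sc.k = submat.nrow();
  }
  sc.gap_init = gap_init;
  sc.gap_ext = gap_ext;
  return sc;
}

// Encode one residue string through a 256-entry lookup (-1 = invalid).
// On an invalid residue, fills *bad_pos (1-based) and *bad_char and returns
// false instead of throwing, so callers can report the pair index.
bool encode_string(const char* s, R_xlen_t len, const int* lut,
                   std::vector<int>* out, int* bad_pos, char* bad_char) {
  out->resize(len);
  for (R_xlen_t p = 0; p < len; ++p) {
    const int code = lut[(unsigned char)s[p]];
    if (code < 0) { *bad_pos = (int)p + 1; *bad_char = s[p]; return false; }
    (*out)[p] = code;
  }
  return true;
}

// row-major copy of the matrix so Scoring::sub avoids IntegerMatrix indexing
std::vector<int> flatten(const IntegerMatrix& m) {
  const int k = m.nrow();
  std::vector<int> v((size_t)k * k);
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b) v[(size_t)a * k + b] = m(a, b);
  return v;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(std::string query, std::string reference, IntegerVector lut,
                 bool dna_mode, int match_score, int mismatch_penalty,
                 int n_plain, IntegerMatrix submat, int gap_init, int gap_ext) {
  if (query.empty() || reference.empty()) stop("empty sequence");
  if (query.size() > reference.size())
    stop("role-order contract violation: |Q| (%d) > |R| (%d); swap roles first",
         (int)query.size(), (int)reference.size());
  Scoring sc = make_scoring(dna_mode, match_score, mismatch_penalty, n_plain,
                            submat, gap_init, gap_ext);
  std::vector<int> flat;
  if (!dna_mode) { flat = flatten(submat); sc.mat = flat.data(); }
  std::vector<int> q, r;
  int bp; char bc;
  if (!encode_string(query.c_str(), query.size(), INTEGER(lut), &q, &bp, &bc))
    stop("invalid residue '%c' at position %d in query", bc, bp);
  if (!encode_string(reference.c_str(), reference.size(), INTEGER(lut), &r, &bp, &bc))
    stop("invalid residue '%c' at position %d in reference", bc, bp);
  Ends e = wave_forward(q, r, sc);
  return List::create(_["score"] = e.score, _["query_end"] = e.q_end,
                      _["ref_end"] = e.r_end,
                      _["work_ints"] = (double)e.work_ints);
}

// [[Rcpp::export(name = ".cpp_reverse")]]
List cpp_reverse(std::string query, std::string reference, int score,
                 int q_end, int r_end, IntegerVector lut, bool dna_mode,
                 int match_score, int mismatch_penalty, int n_plain,
                 IntegerMatrix submat, int gap_init, int gap_ext) {
  Scoring sc = make_scoring(dna_mode, match_score, mismatch_penalty, n_plain,
                            submat, gap_init, gap_ext);
  std::vector<int> flat;
  if (!dna_mode) { flat = flatten(submat); sc.mat = flat.data(); }
  std::vector<int> q, r;
  int bp; char bc;
  if (!encode_string(query.c_str(), query.size(), INTEGER(lut), &q, &bp, &bc))
    stop("invalid residue '%c' at position %d in query", bc, bp);
  if (!encode_string(reference.c_str(), reference.size(), INTEGER(lut), &r, &bp, &bc))
    stop("invalid residue '%c' at position %d in reference", bc, bp);
  if (q_end < 0 || r_end < 0 || q_end >= (int)q.size() || r_end >= (int)r.size())
    stop("end coordinates out of range");
  int qs, rs;
  reverse_starts(q, r, sc, score, q_end, r_end, &qs, &rs);
  return List::create(_["query_start"] = qs, _["ref_start"] = rs);
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector queries, CharacterVector references,
                     IntegerVector lut, bool dna_mode, int match_score,
                     int mismatch_penalty, int n_plain, IntegerMatrix submat,
                     int gap_init, int gap_ext, bool with_start,
                     bool swap_roles, bool permissive, int index_offset) {
  const R_xlen_t N = queries.size();
  if (references.size() != N) stop("query and reference sets differ in length");
  Scoring sc = make_scoring(dna_mode, match_score, mismatch_penalty, n_plain,
                            submat, gap_init, gap_ext);
  std::vector<int> flat;
  if (!dna_mode) { flat = flatten(submat); sc.mat = flat.data(); }

  IntegerVector score(N), q_start(N), q_end(N), r_start(N), r_end(N), status(N);
  double total_cells = 0.0;
  const int* L = INTEGER(lut);
  std::vector<int> q, r;

  for (R_xlen_t p = 0; p < N; ++p) {
    const int pair_index = index_offset + (int)p;  // 0-based, batch-global
    status[p] = 0;
    score[p] = NA_INTEGER; q_start[p] = NA_INTEGER; q_end[p] = NA_INTEGER;
    r_start[p] = NA_INTEGER; r_end[p] = NA_INTEGER;

    const char* qs_ = CHAR(STRING_ELT(queries, p));
    const char* rs_ = CHAR(STRING_ELT(references, p));
    const R_xlen_t ql = LENGTH(STRING_ELT(queries, p));
    const R_xlen_t rl = LENGTH(STRING_ELT(references, p));

    if (ql == 0 || rl == 0) {
      if (!permissive)
        stop("pair %d: empty %s sequence", pair_index, ql == 0 ? "query" : "reference");
      status[p] = 1;
      continue;
    }
    int bp; char bc;
    if (!encode_string(qs_, ql, L, &q, &bp, &bc)) {
      if (!permissive)
        stop("pair %d: invalid residue '%c' at position %d in query", pair_index, bc, bp);
      status[p] = 1;
      continue;
    }
    if (!encode_string(rs_, rl, L, &r, &bp, &bc)) {
      if (!permissive)
        stop("pair %d: invalid residue '%c' at position %d in reference", pair_index, bc, bp);
      status[p] = 1;
      continue;
    }
    if (!swap_roles && q.size() > r.size()) {
      if (!permissive)
        stop("pair %d: query longer than reference (%d > %d) and role enforcement is off",
             pair_index, (int)q.size(), (int)r.size());
      status[p] = 1;
      continue;
    }

    total_cells += (double)q.size() * (double)r.size();
    Ends e = forward_any(q, r, sc);
    score[p] = e.score;
    q_end[p] = e.q_end; r_end[p] = e.r_end;
    q_start[p] = -1; r_start[p] = -1;
    if (with_start && e.score > 0) {
      int a, b;
      reverse_starts(q, r, sc, e.score, e.q_end, e.r_end, &a, &b);
      q_start[p] = a; r_start[p] = b;
    }
  }

  return List::create(
      _["score"] = score, _["query_start"] = q_start, _["query_end"] = q_end,
      _["ref_start"] = r_start, _["ref_end"] = r_end, _["status"] = status,
      _["total_cells"] = total_cells);
}
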