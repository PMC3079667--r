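#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Semi-global ("glocal") affine-gap alignment of a read against a reference
// insert: the read is consumed in full, unaligned reference ends are free.
// A gap of length L costs gap_open + (L - 1) * gap_extend.
//
// Convention relative to the reference:
//   deletion  = reference base absent from the read (gap in the read)
//   insertion = read base absent from the reference (gap in the reference)
//
// Ties are broken deterministically: match/mismatch over deletion over
// insertion, and among equal-scoring end columns the leftmost is taken, so
// alignments are reproducible across platforms.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// predecessor codes for traceback
enum { FROM_START = 0, FROM_M = 1, FROM_D = 2, FROM_I = 3 };

// [[Rcpp::export]]
List cpp_glocal_align(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int) read.size();   // rows: read
  const int m = (int) ref.size();    // cols: reference
  if (n == 0) stop("empty read");
  if (m == 0) stop("empty reference");

  const size_t W = (size_t) m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> D((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> I((size_t)(n + 1) * W, NEG_INF);
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> tbD((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> tbI((size_t)(n + 1) * W, 0);

#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  // row 0: no read consumed; skipping reference prefix is free.  We model the
  // free skip by allowing M at row 1 to start from score 0 at any column.
  // Column 0: read bases before the reference starts are a penalized
  // insertion run.
  for (int i = 1; i <= n; ++i) {
    I[IDX(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    tbI[IDX(i, 0)] = (i == 1) ? FROM_START : FROM_I;
  }

  for (int i = 1; i <= n; ++i) {
    const char rc = read[(size_t) i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = (rc == ref[(size_t) j - 1]) ? match : mismatch;

      // M: diagonal move; predecessor is best of {start (i==1), M, D, I}
      double best; unsigned char from;
      if (i == 1) { best = 0.0; from = FROM_START; }
      else { best = NEG_INF; from = FROM_START; }
      const size_t pd = IDX(i - 1, j - 1);
      // strict > keeps the preference order M > D > I on score ties
      if (M[pd] > best) { best = M[pd]; from = FROM_M; }
      if (D[pd] > best) { best = D[pd]; from = FROM_D; }
      if (I[pd] > best) { best = I[pd]; from = FROM_I; }
      M[IDX(i, j)] = (best == NEG_INF) ? NEG_INF : best + s;
      tbM[IDX(i, j)] = from;

      // D: gap in read, consumes ref base j (move left in the same row)
      const size_t pl = IDX(i, j - 1);
      double bd = NEG_INF; unsigned char fd = FROM_M;
      if (M[pl] != NEG_INF && M[pl] - gap_open > bd) { bd = M[pl] - gap_open; fd = FROM_M; }
      if (D[pl] != NEG_INF && D[pl] - gap_extend > bd) { bd = D[pl] - gap_extend; fd = FROM_D; }
      if (I[pl] != NEG_INF && I[pl] - gap_open > bd) { bd = I[pl] - gap_open; fd = FROM_I; }
      D[IDX(i, j)] = bd; tbD[IDX(i, j)] = fd;

      // I: gap in ref, consumes read base i (move up in the same column)
      const size_t pu = IDX(i - 1, j);
      double bi = NEG_INF; unsigned char fi = FROM_M;
      if (M[pu] != NEG_INF && M[pu] - gap_open > bi) { bi = M[pu] - gap_open; fi = FROM_M; }
      if (D[pu] != NEG_INF && D[pu] - gap_open > bi) { bi = D[pu] - gap_open; fi = FROM_D; }
      if (I[pu] != NEG_INF && I[pu] - gap_extend > bi) { bi = I[pu] - gap_extend; fi = FROM_I; }
      I[IDX(i, j)] = bi; tbI[IDX(i, j)] = fi;
    }
  }

  // end: best of M(n, j) / I(n, j) over all columns; trailing reference is
  // skipped free.  Leftmost maximal column, M preferred over I.
  double score = NEG_INF; int end_j = 0; unsigned char end_state = FROM_M;
  for (int j = 0; j <= m; ++j) {
    const double sm = M[IDX(n, j)], si = I[IDX(n, j)];
    if (sm > score) { score = sm; end_j = j; end_state = FROM_M; }
    if (si > score) { score = si; end_j = j; end_state = FROM_I; }
  }
  if (score == NEG_INF) stop("alignment failed");

  // traceback
  std::vector<int> ops, rpos, qpos;
  int i = n, j = end_j;
  unsigned char st = end_state;
  while (i > 0) {
    if (st == FROM_M) {
      const char rc = read[(size_t) i - 1];
      const char fc = ref[(size_t) j - 1];
      ops.push_back(rc == fc ? 0 : 1);      // 0 = match, 1 = mismatch
      rpos.push_back(j); qpos.push_back(i);
      st = tbM[IDX(i, j)];
      --i; --j;
      if (st == FROM_START) break;
    } else if (st == FROM_D) {
      ops.push_back(2);                     // deletion: ref base, no read base
      rpos.push_back(j); qpos.push_back(0);
      st = tbD[IDX(i, j)];
      --j;
    } else {                                // FROM_I
      ops.push_back(3);                     // insertion: read base, after ref j
      rpos.push_back(j); qpos.push_back(i);
      st = tbI[IDX(i, j)];
      --i;
      if (st == FROM_START) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(rpos.begin(), rpos.end());
  std::reverse(qpos.begin(), qpos.end());

  int ref_start = 0, ref_end = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] != 3) { if (ref_start == 0) ref_start = rpos[k]; ref_end = rpos[k]; }
  }

  return List::create(_["score"] = score,
                      _["op"] = IntegerVector(ops.begin(), ops.end()),
                      _["rpos"] = IntegerVector(rpos.begin(), rpos.end()),
                      _["qpos"] = IntegerVector(qpos.begin(), qpos.end()),
                      _["ref_start"] = ref_start, _["ref_end"] = ref_end);
}

// Minimum edit distance between `pattern` and any prefix of `text`, with the
// prefix end that achieves it.  Ties prefer the end closest to the pattern
// length (then the shorter prefix), so barcode/primer boundaries stay stable
// under terminal indels.
// [[Rcpp::export]]
IntegerVector cpp_prefix_edit(std::string pattern, std::string text) {
  const int m = (int) pattern.size();
  const int t = (int) text.size();
  if (m == 0) stop("empty pattern");
  std::vector<int> prev(t + 1), cur(t + 1);
  // classic DP: rows = pattern, cols = text; D[m][j] is the full edit
  // distance between the pattern and text[1..j]
  for (int j = 0; j <= t; ++j) prev[(size_t) j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= t; ++j) {
      const int sub = prev[(size_t) j - 1] +
        (pattern[(size_t) i - 1] == text[(size_t) j - 1] ? 0 : 1);
      const int del = prev[(size_t) j] + 1;   // skip pattern char
      const int ins = cur[(size_t) j - 1] + 1; // skip text char
      int v = sub;
      if (del < v) v = del;
      if (ins < v) v = ins;
      cur[(size_t) j] = v;
    }
    std::swap(prev, cur);
  }
  int best = prev[0], best_j = 0;
  for (int j = 1; j <= t; ++j) {
    const int d = prev[(size_t) j];
    if (d < best ||
        (d == best && std::abs(j - m) < std::abs(best_j - m)) ||
        (d == best && std::abs(j - m) == std::abs(best_j - m) && j < best_j)) {
      best = d; best_j = j;
    }
  }
  return IntegerVector::create(best, best_j);
}
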