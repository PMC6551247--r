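// Banded local alignment with affine gaps (Smith-Waterman-Gotoh).
//
// The band is defined on the diagonal offset d = i - j (i: 1-based query
// row, j: 1-based subject column): only cells with |d - center| <= width are
// computed. A gap of length g costs open + g * extend. Score units follow the
// supplied substitution matrix (BLOSUM62 by default upstream).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export(name = ".banded_sw_cpp")]]
List banded_sw_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                   int gap_open, int gap_extend, int band_center,
                   int band_width) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  if (band_width < 1) stop("band_width must be >= 1");
  const int NEG = -(1 << 28);
  const int go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const int ge = gap_extend;

  // full (m+1) x (n+1) tables; out-of-band cells stay at NEG / 0
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in query (consumes s)
  std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in subject (consumes q)
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0);  // 0 stop,1 diag,2 E,3 F
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - band_center - band_width);
    int jhi = std::min(n, i - band_center + band_width);
    for (int j = jlo; j <= jhi; ++j) {
      int e = std::max(H[at(i, j - 1)] - go, E[at(i, j - 1)] - ge);
      int f = std::max(H[at(i - 1, j)] - go, F[at(i - 1, j)] - ge);
      int d = H[at(i - 1, j - 1)] + mat(q[i - 1] - 1, s[j - 1] - 1);
      int h = 0;
      unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      // H at out-of-band predecessor cells is 0 (init); forbid using cells
      // outside the band as diagonal/gap sources by checking band membership
      H[at(i, j)] = h;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      tb[at(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback: explicit H/E/F state machine, preferring gap-open on ties so
  // gaps are as short as the optimum allows
  std::string ops;
  int i = bi, j = bj;
  int nmatch = 0, nmis = 0;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      if (H[at(i, j)] == 0) break;
      unsigned char t = tb[at(i, j)];
      if (t == 1) {
        bool eq = q[i - 1] == s[j - 1];
        ops.push_back(eq ? 'M' : 'X');
        if (eq) ++nmatch; else ++nmis;
        --i; --j;
      } else if (t == 2) {
        state = 'E';
      } else if (t == 3) {
        state = 'F';
      } else {
        break;
      }
    } else if (state == 'E') {
      ops.push_back('I');
      state = (E[at(i, j)] == H[at(i, j - 1)] - go) ? 'H' : 'E';
      --j;
    } else {  // 'F'
      ops.push_back('D');
      state = (F[at(i, j)] == H[at(i - 1, j)] - go) ? 'H' : 'F';
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::string rle;
  size_t p = 0;
  while (p < ops.size()) {
    size_t r = p;
    while (r < ops.size() && ops[r] == ops[p]) ++r;
    rle += std::to_string(r - p);
    rle.push_back(ops[p]);
    p = r;
  }

  return List::create(
    _["score"] = best,
    _["q_lo"] = i, _["q_hi"] = bi,   // 0-based half-open on query
    _["s_lo"] = j, _["s_hi"] = bj,   // 0-based half-open on subject
    _["edit"] = rle,
    _["nmatch"] = nmatch,
    _["nmismatch"] = nmis,
    _["align_cols"] = (int) ops.size());
}
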