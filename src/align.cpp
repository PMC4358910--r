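#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Banded local alignment with affine gaps (Gotoh), traceback included.
// q, s: 0-based integer codes indexing `mat` (substitution scores).
// Band restricts diagonals d = j - i (0-based) to [dlo, dhi]; a full
// alignment is obtained with dlo = -len(q), dhi = len(s).
// A gap of length L costs gap_open + L * gap_ext (BLAST existence/extension).
// Codes >= ambig_from never count as identical even when equal.
//
// Returns the single best local alignment: score, 0-based half-open
// intervals on q and s, identity count and alignment column count.

static const int NEG = -(1 << 29);

// [[Rcpp::export]]
List c_sw_align(IntegerVector q, IntegerVector s, NumericMatrix mat,
                double gap_open_, double gap_ext_, int dlo, int dhi,
                int ambig_from) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["q_begin"] = 0, _["q_end"] = 0,
                        _["s_begin"] = 0, _["s_end"] = 0,
                        _["n_identical"] = 0, _["aln_len"] = 0);
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  if (dlo > dhi) stop("empty diagonal band");
  const int go = (int) gap_open_, ge = (int) gap_ext_;
  const int bw = dhi - dlo + 1;

  // integer copy of the scoring matrix
  const int na = mat.nrow();
  std::vector<int> sub((size_t) na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) sub[(size_t) a * na + b] = (int) mat(a, b);

  // Rolling Gotoh rows over the band; the full matrix keeps only one
  // packed traceback byte per cell: bits 0-1 = H move (0 stop, 1 diag,
  // 2 from E, 3 from F), bit 2 = E opened from H, bit 3 = F opened from H.
  const size_t ncell = (size_t) (m + 1) * bw;
  std::vector<uint8_t> tb(ncell, 0);
  std::vector<int> h_prev(bw + 2, 0), h_cur(bw + 2, 0);
  std::vector<int> f_prev(bw + 2, NEG), f_cur(bw + 2, NEG);
  // index shift by 1 so b-1 / b+1 never leave the arrays

  int best = 0, bi = 0, bb = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t) i * bw;
    const int *srow = &sub[(size_t) q[i - 1] * na];
    const int jmin = std::max(1, i + dlo), jmax = std::min(n, i + dhi);
    std::fill(h_cur.begin(), h_cur.end(), 0);
    std::fill(f_cur.begin(), f_cur.end(), NEG);
    int e = NEG;
    for (int j = jmin; j <= jmax; ++j) {
      const int b = j - i - dlo;
      uint8_t t = 0;
      // E: from cell (i, j-1) = band b-1 (current row)
      const int hl = (b > 0) ? h_cur[b] : 0;  // h_cur[b] == H[i][b-1]
      int e_new;
      if (b > 0 && hl - go - ge >= e - ge) { e_new = hl - go - ge; t |= 4; }
      else e_new = (b > 0) ? e - ge : NEG;
      e = (b > 0) ? e_new : NEG;
      // F: from cell (i-1, j) = band b+1 (previous row)
      const int hu = h_prev[b + 2], fu = f_prev[b + 2];
      int f;
      if (hu - go - ge >= fu - ge) { f = hu - go - ge; t |= 8; }
      else f = fu - ge;
      if (f < NEG) f = NEG;
      f_cur[b + 1] = f;
      // H: diagonal from (i-1, j-1) = same band index
      const int hd = h_prev[b + 1] + srow[s[j - 1]];
      int h = 0;
      if (hd > h) { h = hd; t = (uint8_t)((t & 12) | 1); }
      if (e > h)  { h = e;  t = (uint8_t)((t & 12) | 2); }
      if (f > h)  { h = f;  t = (uint8_t)((t & 12) | 3); }
      h_cur[b + 1] = h;
      tb[row + b] = t;
      if (h > best) { best = h; bi = i; bb = b; }
    }
    std::swap(h_prev, h_cur);
    std::swap(f_prev, f_cur);
  }

  // traceback from the best cell
  int i = bi, b = bb, nid = 0, alen = 0;
  int qe = bi, se = bi + bb + dlo;  // 1-based inclusive ends
  int state = 0;                    // 0 = H, 1 = E, 2 = F
  while (i > 0) {
    const uint8_t t = tb[(size_t) i * bw + b];
    if (state == 0) {
      const uint8_t th = t & 3;
      if (th == 0) break;
      if (th == 1) {
        const int j = i + b + dlo;
        if (q[i - 1] == s[j - 1] && q[i - 1] < ambig_from) ++nid;
        ++alen; --i;                     // b unchanged on diagonal move
      } else state = (th == 2) ? 1 : 2;
    } else if (state == 1) {             // E: consumed s[j-1]
      ++alen; --b;                       // move to (i, j-1)
      if (t & 4) state = 0;
    } else {                             // F: consumed q[i-1]
      ++alen; --i; ++b;                  // move to (i-1, j)
      if (t & 8) state = 0;
    }
  }
  const int qb = i, sb = i + b + dlo;    // 0-based starts
  return List::create(_["score"] = (double) best,
                      _["q_begin"] = qb, _["q_end"] = qe,
                      _["s_begin"] = sb, _["s_end"] = se,
                      _["n_identical"] = nid, _["aln_len"] = alen);
}

// Score-only local alignment (full matrix, rolling rows): used where only
// the optimal score is needed, e.g. oracle top-hit scans in tests.
// [[Rcpp::export]]
double c_sw_score(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double gap_open_, double gap_ext_) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) return 0.0;
  const int go = (int) gap_open_, ge = (int) gap_ext_;
  const int na = mat.nrow();
  std::vector<int> sub((size_t) na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) sub[(size_t) a * na + b] = (int) mat(a, b);
  std::vector<int> h0(n + 1, 0), h1(n + 1, 0), f(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int *srow = &sub[(size_t) q[i - 1] * na];
    int e = NEG;
    h1[0] = 0;
    for (int j = 1; j <= n; ++j) {
      e = std::max(h1[j - 1] - go - ge, e - ge);
      f[j] = std::max(h0[j] - go - ge, f[j] - ge);
      int h = h0[j - 1] + srow[s[j - 1]];
      if (e > h) h = e;
      if (f[j] > h) h = f[j];
      if (h < 0) h = 0;
      h1[j] = h;
      if (h > best) best = h;
    }
    std::swap(h0, h1);
  }
  return (double) best;
}

// Maximum ungapped segment score over a set of diagonals (Kadane along
// each diagonal d = j - i, 0-based). Used as a cheap prefilter deciding
// whether a seeded diagonal cluster deserves gapped extension.
// [[Rcpp::export]]
double c_diag_kadane(IntegerVector q, IntegerVector s, NumericMatrix mat,
                     IntegerVector diags) {
  const int m = q.size(), n = s.size();
  const int na = mat.nrow();
  std::vector<int> sub((size_t) na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) sub[(size_t) a * na + b] = (int) mat(a, b);
  int best = 0;
  for (int k = 0; k < diags.size(); ++k) {
    const int d = diags[k];
    int i = d < 0 ? -d : 0;        // first query index on this diagonal
    int j = d < 0 ? 0 : d;
    int run = 0;
    for (; i < m && j < n; ++i, ++j) {
      run += sub[(size_t) q[i] * na + s[j]];
      if (run < 0) run = 0;
      else if (run > best) best = run;
    }
  }
  return (double) best;
}
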