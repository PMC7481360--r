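#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Global nucleotide alignment with free terminal gaps ("overlap" alignment).
// Affine internal gaps: a gap of length L costs gap_open + L * gap_ext
// (both parameters negative). Returns the optimal score, the identity over
// alignment columns excluding terminal-gap columns, and a per-position match
// indicator for sequence `a` (true where a[i] is aligned to an identical
// character of `b`).
// [[Rcpp::export]]
List cpp_align_overlap(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence in overlap alignment");
  // state matrices: 0 = M (diag), 1 = Ix (gap in b, consumes a), 2 = Iy
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  // traceback pointers: previous state, or -1 for an alignment start
  std::vector<signed char> pM((m + 1) * (n + 1), -1);
  std::vector<signed char> pX((m + 1) * (n + 1), 0);
  std::vector<signed char> pY((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  // Terminal gaps are free only on the longer sequence's side, so the
  // shorter sequence must be aligned end to end (a corner overlap of two
  // divergent equal-length sequences is not an alignment of them).
  bool free_a = m > n, free_b = n > m;
  M[at(0, 0)] = 0.0;
  if (free_a) {
    for (int i = 1; i <= m; ++i) M[at(i, 0)] = 0.0;
    for (int j = 1; j <= n; ++j) { Iy[at(0, j)] = gap_open + j * gap_ext; pY[at(0, j)] = 2; }
  } else if (free_b) {
    for (int j = 1; j <= n; ++j) M[at(0, j)] = 0.0;
    for (int i = 1; i <= m; ++i) { Ix[at(i, 0)] = gap_open + i * gap_ext; pX[at(i, 0)] = 1; }
  } else {
    for (int i = 1; i <= m; ++i) { Ix[at(i, 0)] = gap_open + i * gap_ext; pX[at(i, 0)] = 1; }
    for (int j = 1; j <= n; ++j) { Iy[at(0, j)] = gap_open + j * gap_ext; pY[at(0, j)] = 2; }
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dm = M[at(i - 1, j - 1)], dx = Ix[at(i - 1, j - 1)],
             dy = Iy[at(i - 1, j - 1)];
      int from = 0; double best = dm;
      if (dx > best) { best = dx; from = 1; }
      if (dy > best) { best = dy; from = 2; }
      M[at(i, j)] = best + s;
      pM[at(i, j)] = (signed char)from;
      double xo = M[at(i - 1, j)] + gap_open + gap_ext;
      double xe = Ix[at(i - 1, j)] + gap_ext;
      if (xo >= xe) { Ix[at(i, j)] = xo; pX[at(i, j)] = 0; }
      else          { Ix[at(i, j)] = xe; pX[at(i, j)] = 1; }
      double yo = M[at(i, j - 1)] + gap_open + gap_ext;
      double ye = Iy[at(i, j - 1)] + gap_ext;
      if (yo >= ye) { Iy[at(i, j)] = yo; pY[at(i, j)] = 0; }
      else          { Iy[at(i, j)] = ye; pY[at(i, j)] = 2; }
    }
  }
  // best end: (m, n) always; plus the last column (skipping a's suffix)
  // when a's terminal gaps are free, or the last row when b's are
  double bestScore = NEG_INF;
  int bi = m, bj = n, bstate = 0;
  {
    double vs[3] = { M[at(m, n)], Ix[at(m, n)], Iy[at(m, n)] };
    for (int st = 0; st < 3; ++st)
      if (vs[st] > bestScore) { bestScore = vs[st]; bstate = st; }
  }
  if (free_a) {
    for (int i = 0; i < m; ++i) {
      double vs[3] = { M[at(i, n)], Ix[at(i, n)], Iy[at(i, n)] };
      for (int st = 0; st < 3; ++st)
        if (vs[st] > bestScore) { bestScore = vs[st]; bi = i; bj = n; bstate = st; }
    }
  }
  if (free_b) {
    for (int j = 0; j < n; ++j) {
      double vs[3] = { M[at(m, j)], Ix[at(m, j)], Iy[at(m, j)] };
      for (int st = 0; st < 3; ++st)
        if (vs[st] > bestScore) { bestScore = vs[st]; bi = m; bj = j; bstate = st; }
    }
  }
  // traceback; columns are recorded so that gap runs at either end of the
  // path (terminal gaps) can be excluded from the identity denominator
  LogicalVector matchA(m);
  for (int k = 0; k < m; ++k) matchA[k] = false;
  std::vector<signed char> opv;   // 0 = diagonal, 1/2 = gap column
  std::vector<signed char> hitv;  // for diagonal columns: 1 if identical
  int i = bi, j = bj, state = bstate;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) break;  // reached a free-end boundary start
      int from = pM[at(i, j)];
      bool hit = a[i - 1] == b[j - 1];
      if (hit) matchA[i - 1] = true;
      opv.push_back(0); hitv.push_back(hit ? 1 : 0);
      --i; --j;
      state = from;
    } else if (state == 1) {
      if (i == 0) break;
      int from = pX[at(i, j)];
      opv.push_back(1); hitv.push_back(0);
      --i;
      state = from;
    } else {
      if (j == 0) break;
      int from = pY[at(i, j)];
      opv.push_back(2); hitv.push_back(0);
      --j;
      state = from;
    }
  }
  // trim leading/trailing gap runs (opv is in reverse path order; trimming
  // both ends is symmetric so orientation does not matter)
  int lo = 0, hi = (int)opv.size() - 1;
  while (lo <= hi && opv[lo] != 0) ++lo;
  while (hi >= lo && opv[hi] != 0) --hi;
  long nmatch = 0, ncols = 0;
  for (int k = lo; k <= hi; ++k) {
    ++ncols;
    if (hitv[k]) ++nmatch;
  }
  double identity = ncols > 0 ? (double)nmatch / (double)ncols : 0.0;
  return List::create(_["score"] = bestScore,
                      _["identity"] = identity,
                      _["ncols"] = (double)ncols,
                      _["nmatch"] = (double)nmatch,
                      _["match_a"] = matchA);
}

// Smith-Waterman local alignment with affine gaps; a gap of length L costs
// gap_open + L * gap_ext (positive penalties). Deterministic traceback: the
// maximum-scoring cell with smallest row index, then smallest column index.
// [[Rcpp::export]]
List cpp_align_local(std::string q, std::string s,
                     NumericMatrix submat, std::string alphabet,
                     double gap_open, double gap_ext) {
  int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence in local alignment");
  std::vector<int> code(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    code[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> qi(m), si(n);
  for (int i = 0; i < m; ++i) {
    qi[i] = code[(unsigned char)q[i]];
    if (qi[i] < 0) stop("residue outside alphabet: '%s'", std::string(1, q[i]));
  }
  for (int j = 0; j < n; ++j) {
    si[j] = code[(unsigned char)s[j]];
    if (si[j] < 0) stop("residue outside alphabet: '%s'", std::string(1, s[j]));
  }
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG_INF); // gap in q (horizontal)
  std::vector<double> F((m + 1) * (n + 1), NEG_INF); // gap in s (vertical)
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e1 = H[at(i, j - 1)] - gap_open - gap_ext;
      double e2 = E[at(i, j - 1)] - gap_ext;
      E[at(i, j)] = e1 >= e2 ? e1 : e2;
      double f1 = H[at(i - 1, j)] - gap_open - gap_ext;
      double f2 = F[at(i - 1, j)] - gap_ext;
      F[at(i, j)] = f1 >= f2 ? f1 : f2;
      double d = H[at(i - 1, j - 1)] + submat(qi[i - 1], si[j - 1]);
      double h = d;
      if (E[at(i, j)] > h) h = E[at(i, j)];
      if (F[at(i, j)] > h) h = F[at(i, j)];
      if (h < 0) h = 0;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  long nmatch = 0, ncols = 0;
  int i = bi, j = bj;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  // traceback preferring diagonal, then vertical, then horizontal
  while (i > 0 && j > 0 && H[at(i, j)] > 0) {
    double h = H[at(i, j)];
    double d = H[at(i - 1, j - 1)] + submat(qi[i - 1], si[j - 1]);
    if (h == d) {
      ++ncols;
      if (qi[i - 1] == si[j - 1]) ++nmatch;
      qstart = i; sstart = j;
      --i; --j;
    } else if (h == F[at(i, j)]) {
      // walk the whole vertical gap
      int len = 1;
      while (F[at(i - len + 1, j)] != H[at(i - len, j)] - gap_open - gap_ext)
        ++len;
      ncols += len;
      qstart = i - len + 1;
      i -= len;
    } else {
      int len = 1;
      while (E[at(i, j - len + 1)] != H[at(i, j - len)] - gap_open - gap_ext)
        ++len;
      ncols += len;
      sstart = j - len + 1;
      j -= len;
    }
  }
  double pid = ncols > 0 ? 100.0 * (double)nmatch / (double)ncols : 0.0;
  return List::create(_["score"] = best,
                      _["q_start"] = qstart, _["q_end"] = qend,
                      _["s_start"] = sstart, _["s_end"] = send,
                      _["n_id"] = (double)nmatch, _["n_aln"] = (double)ncols,
                      _["pct_identity"] = pid);
}

// Profile-profile global alignment with affine gaps for progressive MSA.
// Profiles are 4 x L count matrices (rows A, C, G, T; gaps and ambiguous
// residues contribute nothing). Column substitution score is the
// sum-of-pairs average over residue pairs. Returns an op vector in forward
// order: 0 = column from both profiles, 1 = column from A with a gap
// inserted in B, 2 = gap in A.
// [[Rcpp::export]]
IntegerVector cpp_align_profiles(NumericMatrix profA, NumericMatrix profB,
                                 double nA, double nB,
                                 double match, double mismatch,
                                 double gap_open, double gap_ext) {
  int m = profA.ncol(), n = profB.ncol();
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) Ix[at(i, 0)] = gap_open + i * gap_ext;
  for (int j = 1; j <= n; ++j) Iy[at(0, j)] = gap_open + j * gap_ext;
  // precompute column totals
  std::vector<double> tA(m), tB(n);
  for (int i = 0; i < m; ++i) {
    double t = 0; for (int r = 0; r < 4; ++r) t += profA(r, i);
    tA[i] = t;
  }
  for (int j = 0; j < n; ++j) {
    double t = 0; for (int r = 0; r < 4; ++r) t += profB(r, j);
    tB[j] = t;
  }
  double denom = nA * nB;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double same = 0;
      for (int r = 0; r < 4; ++r) same += profA(r, i - 1) * profB(r, j - 1);
      double cross = tA[i - 1] * tB[j - 1] - same;
      double s = (same * match + cross * mismatch) / denom;
      double prev = std::max(M[at(i - 1, j - 1)],
                             std::max(Ix[at(i - 1, j - 1)], Iy[at(i - 1, j - 1)]));
      M[at(i, j)] = prev + s;
      double xo = std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) + gap_open + gap_ext;
      double xe = Ix[at(i - 1, j)] + gap_ext;
      Ix[at(i, j)] = xo >= xe ? xo : xe;
      double yo = std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) + gap_open + gap_ext;
      double ye = Iy[at(i, j - 1)] + gap_ext;
      Iy[at(i, j)] = yo >= ye ? yo : ye;
    }
  }
  // traceback; tie order: diagonal, then gap-in-B (vertical), then gap-in-A
  std::vector<int> ops;
  int i = m, j = n;
  double vm = M[at(i, j)], vx = Ix[at(i, j)], vy = Iy[at(i, j)];
  int state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      ops.push_back(0);
      double dm = M[at(i - 1, j - 1)], dx = Ix[at(i - 1, j - 1)],
             dy = Iy[at(i - 1, j - 1)];
      --i; --j;
      state = (dm >= dx && dm >= dy) ? 0 : (dx >= dy ? 1 : 2);
    } else if (state == 1) {
      ops.push_back(1);
      double open = std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) + gap_open + gap_ext;
      double ext = Ix[at(i - 1, j)] + gap_ext;
      --i;
      if (open >= ext)
        state = (M[at(i, j)] >= Iy[at(i, j)]) ? 0 : 2;
      else state = 1;
    } else {
      ops.push_back(2);
      double open = std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) + gap_open + gap_ext;
      double ext = Iy[at(i, j - 1)] + gap_ext;
      --j;
      if (open >= ext)
        state = (M[at(i, j)] >= Ix[at(i, j)]) ? 0 : 1;
      else state = 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

// Hamming-mismatch scan of a degenerate primer over a read encoded as
// bitmasks. Returns the 1-based start of the leftmost window whose mismatch
// count is <= max_mm, or 0 when none qualifies.
// [[Rcpp::export]]
int cpp_primer_scan(IntegerVector read_mask, IntegerVector pat_mask, int max_mm) {
  int n = read_mask.size(), k = pat_mask.size();
  if (k > n) return 0;
  for (int start = 0; start + k <= n; ++start) {
    int mm = 0;
    for (int p = 0; p < k; ++p) {
      if ((read_mask[start + p] & pat_mask[p]) == 0) {
        ++mm;
        if (mm > max_mm) break;
      }
    }
    if (mm <= max_mm) return start + 1;
  }
  return 0;
}
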