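#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recursion).
// A gap of length L costs gapOpen + L * gapExtend (BLAST convention).
// Sequences arrive as 1-based integer codes into the scoring matrix.
//
// mode local  : Smith-Waterman; alignment may start/end anywhere.
// mode global : full Needleman-Wunsch (terminal gaps penalized like any
//               other gap); identity is reported over the columns between
//               the first and last aligned residue pair, i.e. terminal-gap
//               columns are excluded from the identity denominator. This is
//               the identity notion used for fixed-threshold centroid
//               clustering.
//
// Tie preference is fixed (M over X over Y; gap open over extend) so runs
// are deterministic and reproducible by the pure-R oracle in the tests.
// Scores are integer fast-path (usual match/mismatch and BLOSUM schemes)
// with a double fallback for fractional schemes.

struct AlnOut {
  double score;
  int matches, columns;
  int qs, qe, ss, se;
  std::vector<int> ai, bi;  // aligned 1-based positions, NA for gap columns
  bool empty;
};

// packed traceback byte: bits 0-1 = M-predecessor (0 M, 1 X, 2 Y, 3 start),
// bit 2 = X from X (else from M), bit 3 = Y from Y (else from M)
template <typename T>
static void dp_core(const std::vector<int>& a, const std::vector<int>& b,
                    const std::vector<T>& smat, int nl, T go, T ge,
                    bool global, const T NEGV, std::vector<uint8_t>& tb,
                    T& best, int& bi_, int& bj_, int& bstate, bool& found) {
  const int n = (int)a.size(), m = (int)b.size();
  static thread_local std::vector<T> pm, px, py;
  pm.resize(m + 1); px.resize(m + 1); py.resize(m + 1);
  tb.resize((size_t)(n + 1) * (m + 1));

  pm[0] = global ? (T)0 : NEGV;
  px[0] = NEGV; py[0] = NEGV;
  for (int j = 1; j <= m; ++j) {
    pm[j] = NEGV; px[j] = NEGV;
    py[j] = global ? (T)(-(go + j * ge)) : NEGV;
    tb[j] = (j == 1) ? 0 : 8;
  }

  best = global ? NEGV : (T)0;
  bi_ = 0; bj_ = 0; bstate = 0; found = false;
  const T goe = go + ge;

  for (int i = 1; i <= n; ++i) {
    T diagM = pm[0], diagX = px[0], diagY = py[0];
    T cm0, cx0, cy0;
    cm0 = NEGV; cy0 = NEGV;
    cx0 = global ? (T)(-(go + i * ge)) : NEGV;
    pm[0] = cm0; px[0] = cx0; py[0] = cy0;
    T yprev = cy0, mprev = cm0;
    uint8_t* trow = &tb[(size_t)i * (m + 1)];
    trow[0] = (i == 1) ? 0 : 4;
    const T* srow = &smat[(size_t)(a[i - 1] - 1) * nl];
    const int* bp = b.data();
    for (int j = 1; j <= m; ++j) {
      const T s = srow[bp[j - 1] - 1];
      // M: a_i aligned to b_j (diag* hold row i-1, col j-1 values);
      // branchless selection with fixed tie preference M > X > Y > start
      T vm = diagM; uint8_t t = 0;
      vm = (diagX > vm) ? (t = 1, diagX) : vm;
      vm = (diagY > vm) ? (t = 2, diagY) : vm;
      if (!global) vm = ((T)0 > vm) ? (t = 3, (T)0) : vm;
      const T M = s + vm;
      // X: gap consuming a_i (from row i-1, col j)
      diagM = pm[j]; diagX = px[j]; diagY = py[j];  // save before overwrite
      // ties prefer extension so that a gap run stays contiguous and a
      // trailing run is trimmed as a terminal gap rather than split
      const T xo = diagM - goe, xe = diagX - ge;
      const bool xext = xe >= xo;
      const T X = xext ? xe : xo;
      // Y: gap consuming b_j (from current row, col j-1)
      const T yo = mprev - goe, ye = yprev - ge;
      const bool yext = ye >= yo;
      const T Y = yext ? ye : yo;
      t |= ((uint8_t)xext << 2) | ((uint8_t)yext << 3);
      pm[j] = M; px[j] = X; py[j] = Y;
      mprev = M; yprev = Y;
      trow[j] = t;
      if (!global && M > best) { best = M; bi_ = i; bj_ = j; found = true; }
    }
  }
  if (global) {
    // ties at the final cell prefer the gap states so that a trailing gap
    // is reported terminally (and excluded from the identity denominator)
    best = pm[m]; bstate = 0;
    if (px[m] >= best) { best = px[m]; bstate = 1; }
    if (py[m] >= best) { best = py[m]; bstate = 2; }
    bi_ = n; bj_ = m; found = true;
  }
}

template <typename T>
static void do_align_t(const std::vector<int>& a, const std::vector<int>& b,
                       const std::vector<T>& smat, int nl, T go, T ge,
                       bool global, AlnOut& out) {
  const int n = (int)a.size(), m = (int)b.size();
  out.score = 0.0; out.matches = 0; out.columns = 0;
  out.qs = out.qe = out.ss = out.se = 0; out.empty = true;
  out.ai.clear(); out.bi.clear();

  static thread_local std::vector<uint8_t> tb;
  const T NEGV = std::is_integral<T>::value ? (T)(-(1 << 28)) : (T)-1e30;
  T best; int bi_, bj_, bstate; bool found;
  dp_core<T>(a, b, smat, nl, go, ge, global, NEGV, tb, best, bi_, bj_,
             bstate, found);
  out.score = (double)best;
  if (!global && !found) { out.score = 0.0; return; }

  out.empty = false;
  int i = bi_, j = bj_, state = global ? bstate : 0;
  while (true) {
    if (i == 0 && j == 0) break;
    const uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      out.ai.push_back(i); out.bi.push_back(j);
      const uint8_t tm = t & 3;
      --i; --j;
      if (tm == 3) break;  // local start
      if (!global && (i == 0 || j == 0)) break;
      state = tm;
    } else if (state == 1) {
      out.ai.push_back(i); out.bi.push_back(NA_INTEGER);
      --i;
      state = (t & 4) ? 1 : 0;
    } else {
      out.ai.push_back(NA_INTEGER); out.bi.push_back(j);
      --j;
      state = (t & 8) ? 2 : 0;
    }
  }
  std::reverse(out.ai.begin(), out.ai.end());
  std::reverse(out.bi.begin(), out.bi.end());

  // trim terminal gap columns (global mode); local alignments have none
  int lo = 0, hi = (int)out.ai.size() - 1;
  while (lo <= hi && (out.ai[lo] == NA_INTEGER || out.bi[lo] == NA_INTEGER))
    ++lo;
  while (hi >= lo && (out.ai[hi] == NA_INTEGER || out.bi[hi] == NA_INTEGER))
    --hi;
  if (lo > hi) {  // no aligned residue pair at all
    out.ai.clear(); out.bi.clear();
    out.matches = 0; out.columns = 0;
    out.empty = true;
    return;
  }
  out.ai.assign(out.ai.begin() + lo, out.ai.begin() + hi + 1);
  out.bi.assign(out.bi.begin() + lo, out.bi.begin() + hi + 1);
  out.columns = (int)out.ai.size();
  out.matches = 0;
  out.qs = n + 1; out.qe = 0; out.ss = m + 1; out.se = 0;
  for (size_t k = 0; k < out.ai.size(); ++k) {
    if (out.ai[k] != NA_INTEGER && out.bi[k] != NA_INTEGER &&
        a[out.ai[k] - 1] == b[out.bi[k] - 1])
      out.matches++;
    if (out.ai[k] != NA_INTEGER) {
      if (out.ai[k] < out.qs) out.qs = out.ai[k];
      if (out.ai[k] > out.qe) out.qe = out.ai[k];
    }
    if (out.bi[k] != NA_INTEGER) {
      if (out.bi[k] < out.ss) out.ss = out.bi[k];
      if (out.bi[k] > out.se) out.se = out.bi[k];
    }
  }
}

static bool integral_scheme(const NumericMatrix& smat, double go, double ge) {
  if (go != std::floor(go) || ge != std::floor(ge)) return false;
  for (int i = 0; i < smat.nrow(); ++i)
    for (int j = 0; j < smat.ncol(); ++j)
      if (smat(i, j) != std::floor(smat(i, j))) return false;
  return true;
}

template <typename T>
static std::vector<T> flat_smat(const NumericMatrix& m) {
  std::vector<T> out((size_t)m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      out[(size_t)i * m.ncol() + j] = (T)m(i, j);
  return out;
}

static void do_align(const std::vector<int>& a, const std::vector<int>& b,
                     const NumericMatrix& smat, double go, double ge,
                     bool global, AlnOut& out) {
  if (integral_scheme(smat, go, ge)) {
    std::vector<int> sm = flat_smat<int>(smat);
    do_align_t<int>(a, b, sm, smat.ncol(), (int)go, (int)ge, global, out);
  } else {
    std::vector<double> sm = flat_smat<double>(smat);
    do_align_t<double>(a, b, sm, smat.ncol(), go, ge, global, out);
  }
}

static std::vector<int> as_codes(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export(name = ".alignPairC")]]
List align_pair_c(IntegerVector a, IntegerVector b, NumericMatrix smat,
                  double gapOpen, double gapExtend, bool global) {
  AlnOut out;
  std::vector<int> av = as_codes(a), bv = as_codes(b);
  do_align(av, bv, smat, gapOpen, gapExtend, global, out);
  IntegerVector ai(out.ai.size()), bi(out.bi.size());
  for (size_t k = 0; k < out.ai.size(); ++k) { ai[k] = out.ai[k]; bi[k] = out.bi[k]; }
  return List::create(
      _["score"] = out.score, _["matches"] = out.matches,
      _["columns"] = out.columns,
      _["qstart"] = out.empty ? NA_INTEGER : out.qs,
      _["qend"] = out.empty ? NA_INTEGER : out.qe,
      _["sstart"] = out.empty ? NA_INTEGER : out.ss,
      _["send"] = out.empty ? NA_INTEGER : out.se,
      _["ai"] = ai, _["bi"] = bi);
}

// Hot path for greedy clustering: compare a query against centroids in
// creation order, return the first with identity >= threshold.
// [[Rcpp::export(name = ".firstAcceptC")]]
List first_accept_c(IntegerVector q, List cents, NumericMatrix smat,
                    double gapOpen, double gapExtend, double threshold) {
  std::vector<int> qv = as_codes(q);
  AlnOut out;
  for (int k = 0; k < cents.size(); ++k) {
    IntegerVector cv = cents[k];
    std::vector<int> c = as_codes(cv);
    do_align(qv, c, smat, gapOpen, gapExtend, true, out);
    const double id = (out.columns > 0) ?
        (double)out.matches / (double)out.columns : 0.0;
    if (id >= threshold - 1e-12)
      return List::create(_["index"] = k + 1, _["identity"] = id);
  }
  return List::create(_["index"] = 0, _["identity"] = NA_REAL);
}
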