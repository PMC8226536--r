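#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

// Global (Needleman-Wunsch) pairwise alignment with affine gaps restricted to
// a diagonal band.  A gap of length L costs gap_open + L * gap_extend
// (blastn convention; matches Biostrings' gapOpening/gapExtension accounting).
// The band half-width is widened by |n - m| so the corner (n, m) is always
// reachable; with band >= max(n, m) this degenerates to full DP.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List banded_align_cpp(std::string q, std::string s, int band,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int) q.size();
  const int m = (int) s.size();
  if (n == 0 || m == 0)
    stop("banded_align_cpp: empty sequence");
  int B = band + std::abs(n - m);
  if (B < 1) B = 1;
  const int maxdim = std::max(n, m);
  if (B > maxdim) B = maxdim;
  const int W = 2 * B + 1;

  // state matrices: M diagonal, X gap in subject (consumes query),
  // Y gap in query (consumes subject); band-compressed on j - i + B
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> Y((size_t)(n + 1) * W, NEG_INF);
  // traceback: which state each cell's max came from (0=M,1=X,2=Y)
  std::vector<signed char> tM((size_t)(n + 1) * W, -1);
  std::vector<signed char> tX((size_t)(n + 1) * W, -1);
  std::vector<signed char> tY((size_t)(n + 1) * W, -1);

  auto off = [&](int i, int j) -> long { return (long) i * W + (j - i + B); };
  auto inband = [&](int i, int j) -> bool {
    return j >= 0 && j <= m && j - i >= -B && j - i <= B;
  };

  M[off(0, 0)] = 0.0;
  for (int j = 1; j <= m && j <= B; ++j) {
    Y[off(0, j)] = gap_open + gap_extend * j;
    tY[off(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    if (inband(i, 0)) {
      X[off(i, 0)] = gap_open + gap_extend * i;
      tX[off(i, 0)] = (i == 1) ? 0 : 1;
    }
    const int jlo = std::max(1, i - B);
    const int jhi = std::min(m, i + B);
    for (int j = jlo; j <= jhi; ++j) {
      const long c = off(i, j);
      // M: diagonal from (i-1, j-1)
      if (inband(i - 1, j - 1)) {
        const long p = off(i - 1, j - 1);
        double best = M[p]; signed char tb = 0;
        if (X[p] > best) { best = X[p]; tb = 1; }
        if (Y[p] > best) { best = Y[p]; tb = 2; }
        if (best > NEG_INF / 2) {
          const double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
          M[c] = best + sub; tM[c] = tb;
        }
      }
      // X: from (i-1, j), query base against gap
      if (inband(i - 1, j)) {
        const long p = off(i - 1, j);
        double bopen = std::max(M[p], Y[p]);
        signed char topen = (M[p] >= Y[p]) ? 0 : 2;
        double vopen = (bopen > NEG_INF / 2) ? bopen + gap_open + gap_extend : NEG_INF;
        double vext = (X[p] > NEG_INF / 2) ? X[p] + gap_extend : NEG_INF;
        if (vopen >= vext && vopen > NEG_INF / 2) { X[c] = vopen; tX[c] = topen; }
        else if (vext > NEG_INF / 2) { X[c] = vext; tX[c] = 1; }
      }
      // Y: from (i, j-1), subject base against gap
      if (inband(i, j - 1)) {
        const long p = off(i, j - 1);
        double bopen = std::max(M[p], X[p]);
        signed char topen = (M[p] >= X[p]) ? 0 : 1;
        double vopen = (bopen > NEG_INF / 2) ? bopen + gap_open + gap_extend : NEG_INF;
        double vext = (Y[p] > NEG_INF / 2) ? Y[p] + gap_extend : NEG_INF;
        if (vopen >= vext && vopen > NEG_INF / 2) { Y[c] = vopen; tY[c] = topen; }
        else if (vext > NEG_INF / 2) { Y[c] = vext; tY[c] = 2; }
      }
    }
  }

  const long e = off(n, m);
  double score = M[e]; int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  if (score < NEG_INF / 2)
    stop("banded_align_cpp: band too narrow, no alignment path");

  // traceback
  std::string qa, sa;
  qa.reserve(n + m); sa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const long c = off(i, j);
    if (state == 0) {
      signed char tb = tM[c];
      qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
      --i; --j; state = tb;
    } else if (state == 1) {
      signed char tb = tX[c];
      qa.push_back(q[i - 1]); sa.push_back('-');
      --i; state = tb;
    } else {
      signed char tb = tY[c];
      qa.push_back('-'); sa.push_back(s[j - 1]);
      --j; state = tb;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  int matches = 0;
  for (size_t k = 0; k < qa.size(); ++k)
    if (qa[k] == sa[k] && qa[k] != '-') ++matches;

  return List::create(_["score"] = score,
                      _["q_aln"] = qa,
                      _["s_aln"] = sa,
                      _["matches"] = matches,
                      _["columns"] = (int) qa.size());
}

// Ungapped X-drop extension used to refine hit boundaries beyond the outermost
// seeds.  Walks outward from (qpos, spos) in the given direction, accumulating
// match/mismatch scores, and reports the best-scoring endpoint; stops when the
// running score falls x_drop below the best seen.
// Returns the number of bases extended (0 if extension is immediately
// unprofitable).  max_len < 0 means unbounded.
// [[Rcpp::export]]
int xdrop_extend_cpp(std::string q, std::string s, int qpos, int spos,
                     int dir, double match, double mismatch, double x_drop,
                     int max_len = -1) {
  const int n = (int) q.size(), m = (int) s.size();
  double cur = 0.0, best = 0.0;
  int best_len = 0, len = 0;
  int i = qpos, j = spos;
  while (max_len < 0 || len < max_len) {
    i += dir; j += dir;
    if (i < 1 || j < 1 || i > n || j > m) break;
    cur += (q[i - 1] == s[j - 1]) ? match : mismatch;
    ++len;
    if (cur > best) { best = cur; best_len = len; }
    if (cur < best - x_drop) break;
  }
  return best_len;
}
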