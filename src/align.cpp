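// Glocal (global-in-read, local-in-reference) affine-gap alignment.
//
// Three-state Gotoh DP. The read must be consumed end to end; the
// reference contributes a window with free end gaps on both sides.
// Gap of length L costs gap_open + L * gap_extend (both negative).
//
// Traceback is stored as one byte per cell and state; score rows are
// rolled, so memory is ~3*n*m bytes. Ties prefer, in order, the
// diagonal (M), reference-consuming (D) and read-consuming (I) states,
// and the smallest reference end column, giving a deterministic
// alignment that the R layer then left-normalises.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {
const double NEG_INF = -1e30;
// predecessor codes
enum Pred : unsigned char { P_NONE = 0, P_M = 1, P_I = 2, P_D = 3, P_START = 4 };
}

// [[Rcpp::export(name = ".align_glocal_cpp")]]
List align_glocal_cpp(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int)read.size();
  const int m = (int)ref.size();
  if (n < 1) stop("empty read");
  if (m < 1) stop("empty reference");
  if ((double)n * (double)m > 2.5e8) stop("alignment problem too large");

  const double go = gap_open + gap_extend;  // first gap base
  const double ge = gap_extend;

  // rolling score rows (index 0..m over reference prefix length)
  std::vector<double> Mp(m + 1), Ip(m + 1), Dp(m + 1);
  std::vector<double> Mc(m + 1), Ic(m + 1), Dc(m + 1);
  // traceback bytes, row-major [i-1][j-1] for i=1..n, j=1..m
  std::vector<unsigned char> tbM((size_t)n * m), tbI((size_t)n * m),
      tbD((size_t)n * m);
  // I-state also defined at j = 0 (insertions before the window)
  std::vector<unsigned char> tbI0(n);

  // i = 0: no read consumed; can start at any reference prefix for free
  for (int j = 0; j <= m; ++j) {
    Mp[j] = 0.0;        // "start here" marker handled via P_START
    Ip[j] = NEG_INF;
    Dp[j] = NEG_INF;
  }

  for (int i = 1; i <= n; ++i) {
    // j = 0 column: only insertions possible
    Mc[0] = NEG_INF;
    Dc[0] = NEG_INF;
    if (i == 1) {
      Ic[0] = go;           // first read base inserted before the window
      tbI0[i - 1] = P_START;
    } else {
      Ic[0] = Ip[0] + ge;
      tbI0[i - 1] = P_I;
    }
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)(i - 1) * m + (j - 1);
      const double s =
          (read[i - 1] == ref[j - 1]) ? match : mismatch;

      // M: read[i] aligned to ref[j]
      double bm;
      unsigned char pm;
      if (i == 1) {
        bm = 0.0;  // free leading reference gap: start fresh
        pm = P_START;
      } else {
        bm = Mp[j - 1];
        pm = P_M;
        if (Ip[j - 1] > bm) { bm = Ip[j - 1]; pm = P_I; }
        if (Dp[j - 1] > bm) { bm = Dp[j - 1]; pm = P_D; }
      }
      Mc[j] = bm + s;
      tbM[idx] = pm;

      // I: read[i] aligned to a gap (insertion relative to reference)
      {
        double bi = Mp[j] + go;
        unsigned char pi = P_M;
        if (Ip[j] + ge > bi) { bi = Ip[j] + ge; pi = P_I; }
        if (Dp[j] + go > bi) { bi = Dp[j] + go; pi = P_D; }
        if (i == 1) {
          // starting the read with an insertion inside the window is
          // dominated by starting later; still allow via M row 0
          double alt = 0.0 + go;
          if (alt >= bi) { bi = alt; pi = P_START; }
        }
        Ic[j] = bi;
        tbI[idx] = pi;
      }

      // D: ref[j] aligned to a gap (deletion relative to reference)
      {
        double bd = Mc[j - 1] + go;
        unsigned char pd = P_M;
        if (Dc[j - 1] + ge > bd) { bd = Dc[j - 1] + ge; pd = P_D; }
        if (Ic[j - 1] + go > bd) { bd = Ic[j - 1] + go; pd = P_I; }
        Dc[j] = bd;
        tbD[idx] = pd;
      }
    }
    std::swap(Mp, Mc);
    std::swap(Ip, Ic);
    std::swap(Dp, Dc);
  }

  // best end: max over j of M[n][j], I[n][j]; smallest j on ties,
  // M preferred over I
  double best = NEG_INF;
  int bj = -1;
  unsigned char bstate = P_M;
  for (int j = 0; j <= m; ++j) {
    if (Mp[j] > best) { best = Mp[j]; bj = j; bstate = P_M; }
    if (Ip[j] > best) { best = Ip[j]; bj = j; bstate = P_I; }
  }

  // traceback
  std::vector<int> op_kind;   // 0 match, 1 mismatch, 2 insertion, 3 deletion
  std::vector<int> op_refpos; // 0-based reference position (col for M/D,
                              // insertion point for I)
  int i = n, j = bj;
  unsigned char state = bstate;
  int ref_end = bj;           // 0-based half-open end of the aligned span
  int ref_start = bj;
  while (true) {
    if (state == P_M) {
      const size_t idx = (size_t)(i - 1) * m + (j - 1);
      op_kind.push_back(read[i - 1] == ref[j - 1] ? 0 : 1);
      op_refpos.push_back(j - 1);
      unsigned char p = tbM[idx];
      --i; --j;
      ref_start = j;
      if (p == P_START) break;
      state = p;
    } else if (state == P_I) {
      unsigned char p = (j == 0) ? tbI0[i - 1]
                                 : tbI[(size_t)(i - 1) * m + (j - 1)];
      op_kind.push_back(2);
      op_refpos.push_back(j);
      --i;
      ref_start = j;
      if (p == P_START) break;
      state = p;
    } else {  // P_D
      const size_t idx = (size_t)(i - 1) * m + (j - 1);
      op_kind.push_back(3);
      op_refpos.push_back(j - 1);
      unsigned char p = tbD[idx];
      --j;
      ref_start = j;
      state = p;
    }
  }
  std::reverse(op_kind.begin(), op_kind.end());
  std::reverse(op_refpos.begin(), op_refpos.end());

  return List::create(_["score"] = best,
                      _["op_kind"] = op_kind,
                      _["op_refpos"] = op_refpos,
                      _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end);
}
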