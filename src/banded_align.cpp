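#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Banded global alignment with affine gaps, maximising
//   match * n_match + mismatch * n_mismatch - sum_gaps(gap_open + len * gap_extend).
// The band is taken around the diagonals [min(0, m-n) - extra, max(0, m-n) + extra],
// which always contains the main diagonal and the end cell. Amplicon reads are
// full-length products, so the optimal path never strays far from the diagonal
// once length-shifted (SV) reads have been routed to the split-read caller.
//
// Traceback prefers, on ties, M over D over I and terminating a gap over
// extending it; indel left-normalisation for variant reporting is done by the
// caller against the reference, so tie-breaking here only needs to be
// deterministic.

static const int NEG_INF = -1000000000;

// [[Rcpp::export]]
List banded_align_cpp(std::string read, std::string ref,
                      int band_extra = 60,
                      int match = 2, int mismatch = -4,
                      int gap_open = -4, int gap_extend = -2) {
  const int n = (int) read.size();   // rows, read
  const int m = (int) ref.size();    // implicit cols, ref
  const int klo = std::min(0, m - n) - band_extra;
  const int khi = std::max(0, m - n) + band_extra;
  const int W = khi - klo + 1;

  // score matrices, row-major (n+1) x W; k = j - i, w = k - klo
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> X(M), Y(M);
  // traceback: 2 bits per state would do; use bytes. value = predecessor state
  // 0=M,1=X,2=Y, 3=start, 255=unset
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 255), tX(tM), tY(tM);

  const int open1 = gap_open + gap_extend;  // cost of opening a length-1 gap

  auto idx = [W](int i, int w) { return (size_t)i * W + w; };

  // row 0: only deletions from read (consume ref), state Y
  if (0 - klo >= 0 && 0 - klo < W) { M[idx(0, -klo)] = 0; tM[idx(0, -klo)] = 3; }
  for (int w = -klo + 1; w < W; ++w) {
    int j = klo + w;           // i = 0
    if (j < 1 || j > m) continue;
    Y[idx(0, w)] = open1 + (j - 1) * gap_extend;
    tY[idx(0, w)] = (j == 1) ? 0 : 2;  // from M at origin or extend Y
  }

  for (int i = 1; i <= n; ++i) {
    for (int w = 0; w < W; ++w) {
      int j = i + klo + w;
      if (j < 0 || j > m) continue;
      size_t c = idx(i, w);
      // X: consume read base i (gap in ref); predecessor (i-1, j) -> w+1
      if (w + 1 < W) {
        size_t p = idx(i - 1, w + 1);
        int fromM = (M[p] == NEG_INF) ? NEG_INF : M[p] + open1;
        int fromX = (X[p] == NEG_INF) ? NEG_INF : X[p] + gap_extend;
        if (fromM >= fromX) { X[c] = fromM; if (fromM > NEG_INF) tX[c] = 0; }
        else { X[c] = fromX; tX[c] = 1; }
      }
      // Y: consume ref base j (gap in read); predecessor (i, j-1) -> w-1
      if (j >= 1 && w - 1 >= 0) {
        size_t p = idx(i, w - 1);
        int fromM = (M[p] == NEG_INF) ? NEG_INF : M[p] + open1;
        int fromY = (Y[p] == NEG_INF) ? NEG_INF : Y[p] + gap_extend;
        if (fromM >= fromY) { Y[c] = fromM; if (fromM > NEG_INF) tY[c] = 0; }
        else { Y[c] = fromY; tY[c] = 2; }
      }
      // M: consume both; predecessor (i-1, j-1) -> same w
      if (j >= 1) {
        size_t p = idx(i - 1, w);
        int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        int best = NEG_INF; unsigned char tb = 255;
        if (M[p] > NEG_INF && M[p] >= X[p] && M[p] >= Y[p]) { best = M[p]; tb = 0; }
        else if (X[p] > NEG_INF && X[p] >= Y[p]) { best = X[p]; tb = 1; }
        else if (Y[p] > NEG_INF) { best = Y[p]; tb = 2; }
        if (tb != 255) { M[c] = best + s; tM[c] = tb; }
      }
    }
  }

  int wend = m - n - klo;
  if (wend < 0 || wend >= W) stop("band does not contain the end cell");
  size_t e = idx(n, wend);
  int best = M[e]; int state = 0;
  if (X[e] > best) { best = X[e]; state = 1; }
  if (Y[e] > best) { best = Y[e]; state = 2; }
  if (best <= NEG_INF) stop("no alignment within band");

  // traceback
  std::vector<int> ops;  // 0=M,1=I(read insertion),2=D(deletion from read)
  int i = n, w = wend;
  int nmatch = 0, nmm = 0;
  while (true) {
    size_t c = idx(i, w);
    if (state == 0) {
      unsigned char tb = tM[c];
      if (tb == 3) break;
      int j = i + klo + w;
      if (read[i - 1] == ref[j - 1]) nmatch++; else nmm++;
      ops.push_back(0);
      i -= 1;  // w unchanged
      state = tb;
    } else if (state == 1) {
      ops.push_back(1);
      state = tX[c];
      i -= 1; w += 1;
    } else {
      ops.push_back(2);
      state = tY[c];
      w -= 1;
      if (i == 0 && state == 0 && i + klo + w == 0) { /* reaches origin next */ }
    }
    if (i == 0 && i + klo + w == 0 && state == 0) break;
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::vector<int> op, len;
  for (size_t t = 0; t < ops.size(); ++t) {
    if (!op.empty() && op.back() == ops[t]) len.back()++;
    else { op.push_back(ops[t]); len.push_back(1); }
  }

  return List::create(_["op"] = wrap(op), _["len"] = wrap(len),
                      _["score"] = best, _["nmatch"] = nmatch,
                      _["nmismatch"] = nmm);
}
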