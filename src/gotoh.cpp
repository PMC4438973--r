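#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over SHAPE reactivity profiles.
//
// D[i][j]: best score aligning x[1..i] with y[1..j].
// P[i][j]: best such score with x_i aligned to a gap (gap run in y).
// Q[i][j]: best such score with y_j aligned to a gap (gap run in x).
// A gap of length L costs GOP + L*GEP (GOP charged once, on opening).
//
// Traceback pointers are stored at fill time, so traceback never compares
// floating-point scores. Tie order in D: diagonal, then P, then Q; within
// P/Q, extending an open gap is preferred over re-opening.

static inline double col_score(double rx, double ry, bool combined,
                               int bx, int by,
                               double m, double b, double match,
                               double mismatch) {
  double s;
  if (ISNAN(rx) || ISNAN(ry)) {
    s = 0.0; // missing reactivity: neutral
  } else {
    double lin = m * std::fabs(rx - ry) + b;
    double floorv = m + b;
    s = lin > floorv ? lin : floorv;
  }
  if (combined) {
    // base codes: 0..3 = ACGU, 4 = N (never matches)
    s += (bx == by && bx != 4) ? match : mismatch;
  }
  return s;
}

// [[Rcpp::export(name = ".gotoh_core")]]
List gotoh_core(NumericVector rx, NumericVector ry,
                IntegerVector bx, IntegerVector by,
                double m, double b, double gop, double gep,
                double match, double mismatch, bool combined,
                bool free_endgaps) {
  const int nx = rx.size(), ny = ry.size();
  const size_t w = (size_t)ny + 1;
  // sentinel well below any achievable score
  const double maxcol = std::fabs(b) + std::fabs(match) + std::fabs(mismatch);
  const double worst = -4.0 * ((maxcol + std::fabs(gop) + std::fabs(gep)) *
                               (double)(nx + ny + 1) + 1.0);

  std::vector<double> D((nx + 1) * w), P((nx + 1) * w), Q((nx + 1) * w);
  // pointer codes - tbD: 0 diag, 1 P, 2 Q, 3 border-gap
  // tbP/tbQ: 0 extend (stay in P/Q), 1 open (come from D)
  std::vector<unsigned char> tbD((nx + 1) * w), tbP((nx + 1) * w),
      tbQ((nx + 1) * w);

  D[0] = 0.0;
  for (int i = 1; i <= nx; ++i) {
    D[i * w] = free_endgaps ? 0.0 : gop + i * gep;
    P[i * w] = D[i * w]; // a border row is one long gap run in y
    Q[i * w] = worst;
    tbD[i * w] = 3;
  }
  for (int j = 1; j <= ny; ++j) {
    D[j] = free_endgaps ? 0.0 : gop + j * gep;
    Q[j] = D[j];
    P[j] = worst;
    tbD[j] = 3;
  }
  P[0] = Q[0] = worst;

  for (int i = 1; i <= nx; ++i) {
    const size_t row = i * w, prow = (i - 1) * w;
    for (int j = 1; j <= ny; ++j) {
      // P: x_i against a gap (advance i)
      double ext = P[prow + j] + gep;
      double open = D[prow + j] + gop + gep;
      if (ext >= open) { P[row + j] = ext; tbP[row + j] = 0; }
      else             { P[row + j] = open; tbP[row + j] = 1; }
      // Q: y_j against a gap (advance j)
      ext = Q[row + j - 1] + gep;
      open = D[row + j - 1] + gop + gep;
      if (ext >= open) { Q[row + j] = ext; tbQ[row + j] = 0; }
      else             { Q[row + j] = open; tbQ[row + j] = 1; }
      // D: diagonal vs gap states, tie order diag > P > Q
      double diag = D[prow + j - 1] +
          col_score(rx[i - 1], ry[j - 1], combined, bx[i - 1], by[j - 1], m, b,
                    match, mismatch);
      double best = diag;
      unsigned char tb = 0;
      if (P[row + j] > best) { best = P[row + j]; tb = 1; }
      if (Q[row + j] > best) { best = Q[row + j]; tb = 2; }
      D[row + j] = best;
      tbD[row + j] = tb;
    }
  }

  // with free end gaps the alignment may end anywhere on the last row or
  // column; otherwise it ends at (nx, ny)
  int ei = nx, ej = ny;
  if (free_endgaps) {
    double best = D[(size_t)nx * w + ny];
    for (int i2 = nx - 1; i2 >= 0; --i2)
      if (D[(size_t)i2 * w + ny] > best) { best = D[(size_t)i2 * w + ny]; ei = i2; ej = ny; }
    for (int j2 = ny - 1; j2 >= 0; --j2)
      if (D[(size_t)nx * w + j2] > best) { best = D[(size_t)nx * w + j2]; ei = nx; ej = j2; }
  }

  // traceback, tracking the current matrix state
  std::vector<int> colx, coly;
  colx.reserve(nx + ny);
  coly.reserve(nx + ny);
  // unpenalized terminal gap columns past the end cell
  for (int j2 = ny; j2 > ej; --j2) { colx.push_back(NA_INTEGER); coly.push_back(j2); }
  for (int i2 = nx; i2 > ei; --i2) { colx.push_back(i2); coly.push_back(NA_INTEGER); }
  int i = ei, j = ej;
  int state = 0; // 0 = D, 1 = P, 2 = Q
  while (i > 0 || j > 0) {
    if (i == 0) { colx.push_back(NA_INTEGER); coly.push_back(j); --j; continue; }
    if (j == 0) { colx.push_back(i); coly.push_back(NA_INTEGER); --i; continue; }
    const size_t at = (size_t)i * w + j;
    if (state == 0) {
      switch (tbD[at]) {
      case 0:
        colx.push_back(i); coly.push_back(j); --i; --j; break;
      case 1: state = 1; break;
      case 2: state = 2; break;
      default: // border: only reachable at i==0 or j==0, handled above
        stop("internal error: bad traceback pointer");
      }
    } else if (state == 1) {
      colx.push_back(i); coly.push_back(NA_INTEGER);
      state = (tbP[at] == 0) ? 1 : 0;
      --i;
    } else {
      colx.push_back(NA_INTEGER); coly.push_back(j);
      state = (tbQ[at] == 0) ? 2 : 0;
      --j;
    }
  }
  std::reverse(colx.begin(), colx.end());
  std::reverse(coly.begin(), coly.end());

  double score = D[(size_t)ei * w + ej];
  return List::create(_["score"] = score,
                      _["x"] = IntegerVector(colx.begin(), colx.end()),
                      _["y"] = IntegerVector(coly.begin(), coly.end()));
}
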