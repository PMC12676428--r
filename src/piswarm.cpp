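#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Mismatch count between equal-width string pairs. 'N' never matches anything.
// [[Rcpp::export]]
IntegerVector hamming_pairs_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *pa = CHAR(STRING_ELT(a, i));
    const char *pb = CHAR(STRING_ELT(b, i));
    const size_t la = std::strlen(pa);
    if (la != std::strlen(pb)) stop("hamming_pairs_cpp: unequal lengths");
    int mm = 0;
    for (size_t j = 0; j < la; ++j)
      if (pa[j] != pb[j] || pa[j] == 'N') ++mm;
    out[i] = mm;
  }
  return out;
}

// Verify seed-hit candidates: for candidate i, compare window[i] against
// transcripts[tx_idx[i]] starting at start[i] (1-based). Returns a matrix
// with one row per candidate: mismatch count (capped at max_mm + 1) followed
// by up to max_mm mismatch offsets (1-based within the window, 0-padded).
// [[Rcpp::export]]
IntegerMatrix verify_candidates_cpp(CharacterVector windows, CharacterVector transcripts,
                                    IntegerVector tx_idx, IntegerVector start, int max_mm) {
  const R_xlen_t n = windows.size();
  IntegerMatrix out(n, 1 + std::max(max_mm, 1));
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *w = CHAR(STRING_ELT(windows, i));
    const char *t = CHAR(STRING_ELT(transcripts, tx_idx[i] - 1));
    const int L = (int) std::strlen(w);
    const int tlen = (int) std::strlen(t);
    const int s = start[i] - 1;
    int mm = 0;
    if (s < 0 || s + L > tlen) { out(i, 0) = max_mm + 1; continue; }
    for (int j = 0; j < L; ++j) {
      const char cw = w[j], ct = t[s + j];
      if (cw != ct || cw == 'N' || ct == 'N') {
        ++mm;
        if (mm > max_mm) break;
        out(i, mm) = j + 1;
      }
    }
    out(i, 0) = mm;
  }
  return out;
}

// Smith-Waterman local alignment with affine gaps (Gotoh), full traceback.
// A gap of length k costs gap_open + k * gap_ext. Returns the single optimal
// alignment (ties: prefer the cell found first scanning row-major, and
// diagonal > up > left during traceback, giving deterministic output).
// Coordinates are 1-based inclusive; aligned column vectors give the a- and
// b-positions per column with 0 marking a gap.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("sw_align_cpp: empty sequence");
  // DP over three states: M (match/mismatch), X (gap in b / a-insertion), Y (gap in a)
  std::vector<double> M((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> X((size_t)(n + 1) * (m + 1), R_NegInf);
  std::vector<double> Y((size_t)(n + 1) * (m + 1), R_NegInf);
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0); // 0 stop,1 diagM,2 diagX,3 diagY
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1), 0); // 1 openM, 2 extX
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t) i * (m + 1) + j;
      const size_t kd = (size_t)(i - 1) * (m + 1) + (j - 1);
      const size_t ku = (size_t)(i - 1) * (m + 1) + j;
      const size_t kl = k - 1;
      // X: gap in b (consume a[i])
      double xo = M[ku] - gap_open - gap_ext, xe = X[ku] - gap_ext;
      if (xo >= xe) { X[k] = xo; tbX[k] = 1; } else { X[k] = xe; tbX[k] = 2; }
      // Y: gap in a (consume b[j])
      double yo = M[kl] - gap_open - gap_ext, ye = Y[kl] - gap_ext;
      if (yo >= ye) { Y[k] = yo; tbY[k] = 1; } else { Y[k] = ye; tbY[k] = 2; }
      // M
      const char cb = b[j - 1];
      const double s = (ca == cb && ca != 'N') ? match : mismatch;
      double dM = M[kd] + s, dX = X[kd] + s, dY = Y[kd] + s;
      double mb = dM; unsigned char tb = 1;
      if (dX > mb) { mb = dX; tb = 2; }
      if (dY > mb) { mb = dY; tb = 3; }
      // local alignment can also restart
      double cell = mb; unsigned char tbc = tb;
      if (X[k] > cell) { cell = X[k]; tbc = 4; }
      if (Y[k] > cell) { cell = Y[k]; tbc = 5; }
      if (cell <= 0.0) { cell = 0.0; tbc = 0; }
      M[k] = cell; tbM[k] = tbc;
      if (cell > best) { best = cell; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["a_pos"] = IntegerVector(0),
                        _["b_pos"] = IntegerVector(0));
  }
  // traceback
  std::vector<int> ap, bp;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = X, 2 = Y
  while (i > 0 && j > 0) {
    const size_t k = (size_t) i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbM[k];
      if (t == 0) break;
      if (t == 4) { state = 1; continue; }
      if (t == 5) { state = 2; continue; }
      ap.push_back(i); bp.push_back(j);
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      unsigned char t = tbX[k];
      ap.push_back(i); bp.push_back(0);
      state = (t == 1) ? 0 : 1;
      --i;
    } else {
      unsigned char t = tbY[k];
      ap.push_back(0); bp.push_back(j);
      state = (t == 1) ? 0 : 2;
      --j;
    }
  }
  std::reverse(ap.begin(), ap.end());
  std::reverse(bp.begin(), bp.end());
  int a0 = 0, a1 = 0, b0 = 0, b1 = 0;
  for (size_t q = 0; q < ap.size(); ++q) {
    if (ap[q] > 0) { if (a0 == 0) a0 = ap[q]; a1 = ap[q]; }
    if (bp[q] > 0) { if (b0 == 0) b0 = bp[q]; b1 = bp[q]; }
  }
  return List::create(_["score"] = best, _["a_start"] = a0, _["a_end"] = a1,
                      _["b_start"] = b0, _["b_end"] = b1,
                      _["a_pos"] = IntegerVector(ap.begin(), ap.end()),
                      _["b_pos"] = IntegerVector(bp.begin(), bp.end()));
}
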