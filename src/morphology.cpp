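#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, 8-connectivity,
// hybrid raster/anti-raster scan followed by a FIFO propagation queue
// (Vincent-style).  Operates on integer images so the fixed point is
// reached deterministically.  marker must be <= mask pointwise.
// [[Rcpp::export]]
IntegerMatrix cpp_reconstruct_dilate(IntegerMatrix marker, IntegerMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  IntegerMatrix J = clone(marker);
  for (int i = 0; i < nr * nc; i++)
    if (J[i] > mask[i]) stop("marker must be <= mask pointwise");

  // forward scan, column-major raster order
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      int v = J[r + c * nr];
      for (int dc = -1; dc <= 0; dc++) {
        for (int dr = -1; dr <= 1; dr++) {
          if (dc == 0 && dr >= 0) continue;  // only already-scanned neighbors
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int w = J[rr + cc * nr];
          if (w > v) v = w;
        }
      }
      int m = mask[r + c * nr];
      J[r + c * nr] = v < m ? v : m;
    }
  }

  // backward scan + queue initialization
  std::queue<int> q;
  for (int c = nc - 1; c >= 0; c--) {
    for (int r = nr - 1; r >= 0; r--) {
      int v = J[r + c * nr];
      for (int dc = 0; dc <= 1; dc++) {
        for (int dr = -1; dr <= 1; dr++) {
          if (dc == 0 && dr <= 0) continue;  // neighbors later in raster order
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int w = J[rr + cc * nr];
          if (w > v) v = w;
        }
      }
      int m = mask[r + c * nr];
      v = v < m ? v : m;
      J[r + c * nr] = v;
      bool push = false;
      for (int dc = 0; dc <= 1 && !push; dc++) {
        for (int dr = -1; dr <= 1 && !push; dr++) {
          if (dc == 0 && dr <= 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int p2 = rr + cc * nr;
          if (J[p2] < v && J[p2] < mask[p2]) push = true;
        }
      }
      if (push) q.push(r + c * nr);
    }
  }

  while (!q.empty()) {
    int p = q.front(); q.pop();
    int r = p % nr, c = p / nr;
    int vp = J[p];
    for (int dc = -1; dc <= 1; dc++) {
      for (int dr = -1; dr <= 1; dr++) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int p2 = rr + cc * nr;
        if (J[p2] < vp && J[p2] < mask[p2]) {
          J[p2] = vp < mask[p2] ? vp : mask[p2];
          q.push(p2);
        }
      }
    }
  }
  return J;
}

// Connected-component labeling of a binary image by breadth-first
// search in column-major scan order; labels are consecutive 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix bin, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      int p = r + c * nr;
      if (bin[p] == 0 || lab[p] != 0) continue;
      next++;
      lab[p] = next;
      stack.push_back(p);
      while (!stack.empty()) {
        int s = stack.back(); stack.pop_back();
        int sr = s % nr, sc = s / nr;
        for (int dc = -1; dc <= 1; dc++) {
          for (int dr = -1; dr <= 1; dr++) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int rr = sr + dr, cc = sc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int p2 = rr + cc * nr;
            if (bin[p2] != 0 && lab[p2] == 0) {
              lab[p2] = next;
              stack.push_back(p2);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Circularly-closed optimal path across a polar cost grid (rows =
// radii, columns = angles): one radius per angle, consecutive radii
// (including the wrap-around pair) differing by at most maxStep.
// Minimizes total cost; maximization is handled by the caller through
// negation.  The closure constraint is enforced by solving the DP once
// per admissible starting radius and keeping the best closed path.
// lo/hi give per-angle admissible radius ranges (1-based, inclusive).
// Ties broken toward smaller radii (starting radius, then final
// radius, then predecessors), scanning in ascending order with strict
// improvement.  Returns 1-based path indices and the total cost, or
// path = NULL when no admissible closed path exists.
// [[Rcpp::export]]
List cpp_circular_dp(NumericMatrix g, int maxStep, IntegerVector lo,
                     IntegerVector hi) {
  int R = g.nrow(), A = g.ncol();
  if ((int)lo.size() != A || (int)hi.size() != A)
    stop("lo/hi must have one entry per angle");
  if (maxStep < 0) stop("maxStep must be >= 0");

  double bestTotal = R_PosInf;
  std::vector<int> bestPath;
  std::vector<double> dp(R), ndp(R);
  std::vector<std::vector<int>> back(A, std::vector<int>(R, -1));

  int lo0 = std::max(1, (int)lo[0]), hi0 = std::min(R, (int)hi[0]);
  for (int r0 = lo0 - 1; r0 <= hi0 - 1; r0++) {
    for (int r = 0; r < R; r++) dp[r] = R_PosInf;
    dp[r0] = g(r0, 0);
    for (int a = 1; a < A; a++) {
      int loa = std::max(1, (int)lo[a]) - 1, hia = std::min(R, (int)hi[a]) - 1;
      for (int r = 0; r < R; r++) { ndp[r] = R_PosInf; back[a][r] = -1; }
      for (int r = loa; r <= hia; r++) {
        double best = R_PosInf; int barg = -1;
        int p0 = std::max(0, r - maxStep), p1 = std::min(R - 1, r + maxStep);
        for (int p = p0; p <= p1; p++) {
          if (dp[p] < best) { best = dp[p]; barg = p; }
        }
        if (barg >= 0 && best < R_PosInf) {
          ndp[r] = best + g(r, a);
          back[a][r] = barg;
        }
      }
      dp = ndp;
    }
    int loA = std::max(1, (int)lo[A - 1]) - 1;
    int hiA = std::min(R, (int)hi[A - 1]) - 1;
    for (int rA = loA; rA <= hiA; rA++) {
      if (A > 1 && std::abs(rA - r0) > maxStep) continue;
      if (A > 1 && back[A - 1][rA] < 0) continue;
      if (dp[rA] < bestTotal) {
        bestTotal = dp[rA];
        bestPath.assign(A, 0);
        int r = rA;
        for (int a = A - 1; a >= 1; a--) {
          bestPath[a] = r + 1;
          r = back[a][r];
        }
        bestPath[0] = r + 1;
      }
    }
  }

  if (!R_finite(bestTotal))
    return List::create(Named("path") = R_NilValue,
                        Named("cost") = NA_REAL);
  return List::create(Named("path") = IntegerVector(bestPath.begin(), bestPath.end()),
                      Named("cost") = bestTotal);
}
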