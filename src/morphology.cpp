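// Low-level raster morphology and geometry kernels.
// Matrices are indexed [row = x pixel, col = y pixel]; logical TRUE marks the
// foreground (extracellular space for masks, solid for rasterised discs).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Zhang-Suen iterative thinning. Pixels outside the matrix count as
// background, so skeletons never attach to the image border.
// [[Rcpp::export]]
LogicalMatrix thin_mask_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<int> del;
  del.reserve(1024);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c) ? 1 : 0;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(r + nr * c);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) img[del[k]] = false;
      }
    }
  }
  return img;
}

// Connected-component labelling (BFS). diag = TRUE uses 8-connectivity.
// Background pixels get label 0; components are numbered from 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool diag = false) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(4096);
  int cur = 0;
  const int dr4[4] = {1, -1, 0, 0}, dc4[4] = {0, 0, 1, -1};
  const int dr8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dc8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nn = diag ? 8 : 4;
  const int* dr = diag ? dr8 : dr4;
  const int* dc = diag ? dc8 : dc4;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++cur;
      lab(r0, c0) = cur;
      stack.push_back(r0 + nr * c0);
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        int r = id % nr, c = id / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
          lab(rr, cc) = cur;
          stack.push_back(rr + nr * cc);
        }
      }
    }
  }
  return lab;
}

// Rasterise discs onto a pixel grid by the pixel-centre inclusion test.
// Pixel (i, j) (1-based in R) has centre ((i-0.5) res, (j-0.5) res).
// Returns TRUE where the pixel centre lies inside some disc.
// [[Rcpp::export]]
LogicalMatrix rasterize_discs_cpp(NumericVector x, NumericVector y,
                                  NumericVector r, int nx, int ny,
                                  double res) {
  LogicalMatrix solid(nx, ny);
  int n = x.size();
  for (int k = 0; k < n; ++k) {
    double r2 = r[k] * r[k];
    int i0 = std::max(0, (int)std::floor((x[k] - r[k]) / res - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((x[k] + r[k]) / res - 0.5));
    int j0 = std::max(0, (int)std::floor((y[k] - r[k]) / res - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((y[k] + r[k]) / res - 0.5));
    for (int j = j0; j <= j1; ++j) {
      double dy = (j + 0.5) * res - y[k];
      double dy2 = dy * dy;
      for (int i = i0; i <= i1; ++i) {
        double dx = (i + 0.5) * res - x[k];
        if (dx * dx + dy2 <= r2) solid(i, j) = true;
      }
    }
  }
  return solid;
}

// Smallest surface gap (centre distance minus radii sum) over all disc
// pairs; large positive sentinel when fewer than two discs.
// [[Rcpp::export]]
double min_gap_cpp(NumericVector x, NumericVector y, NumericVector r) {
  int n = x.size();
  if (n < 2) return 1e30;
  double best = 1e30;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double g = std::sqrt(dx * dx + dy * dy) - r[i] - r[j];
      if (g < best) best = g;
    }
  }
  return best;
}

// Disc pairs whose surface gap is below `cutoff`; returns a 3-column
// matrix (i, j, gap) with 1-based indices.
// [[Rcpp::export]]
NumericMatrix close_pairs_cpp(NumericVector x, NumericVector y,
                              NumericVector r, double cutoff) {
  int n = x.size();
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double lim = r[i] + r[j] + cutoff;
      if (dx * dx + dy * dy >= lim * lim) continue;
      double g = std::sqrt(dx * dx + dy * dy) - r[i] - r[j];
      out.push_back(i + 1);
      out.push_back(j + 1);
      out.push_back(g);
    }
  }
  int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[3 * k];
    res(k, 1) = out[3 * k + 1];
    res(k, 2) = out[3 * k + 2];
  }
  colnames(res) = CharacterVector::create("i", "j", "gap");
  return res;
}

// Minimum clearance from each query point to the disc surfaces:
// min_k (|p - c_k| - r_k). Used for sizing void-filling insertions.
// [[Rcpp::export]]
NumericVector point_clearance_cpp(NumericVector px, NumericVector py,
                                  NumericVector x, NumericVector y,
                                  NumericVector r) {
  int m = px.size(), n = x.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double best = 1e30;
    for (int k = 0; k < n; ++k) {
      double dx = px[q] - x[k], dy = py[q] - y[k];
      double d = std::sqrt(dx * dx + dy * dy) - r[k];
      if (d < best) best = d;
    }
    out[q] = best;
  }
  return out;
}
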