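// Exhaustive block matching inside a Chebyshev window, on complex
// multi-contrast images.  Distance between two patches is the squared l2
// norm of the complex difference summed over all patch voxels and all
// contrasts.  Ties are broken by scan order (column-major linear index of
// the candidate corner, x fastest); the reference corner is always first.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double patch_dist(const cx_cube& X, int rx, int ry,
                                int cx_, int cy, int edge) {
  double d = 0.0;
  const uword L = X.n_slices;
  for (uword l = 0; l < L; ++l) {
    for (int j = 0; j < edge; ++j) {
      for (int i = 0; i < edge; ++i) {
        const cx_double diff = X(rx + i, ry + j, l) - X(cx_ + i, cy + j, l);
        d += std::norm(diff);
      }
    }
  }
  return d;
}

// refs: n x 2 matrix of 0-based patch corners.  Returns an n*K x 2 matrix of
// 0-based corners, K rows per reference, in ascending (distance, scan-order)
// with the reference first.  K must not exceed the smallest candidate window.
// [[Rcpp::export(name = ".bm_all")]]
Rcpp::IntegerMatrix bm_all(const arma::cx_cube& X,
                           const Rcpp::IntegerMatrix& refs,
                           int edge, int K, int radius) {
  const int Mx = (int)X.n_rows, My = (int)X.n_cols;
  const int cxmax = Mx - edge, cymax = My - edge;
  const int nref = refs.nrow();
  Rcpp::IntegerMatrix out(nref * K, 2);

  std::vector<std::pair<double, long long> > cand;
  for (int r = 0; r < nref; ++r) {
    const int rx = refs(r, 0), ry = refs(r, 1);
    if (rx < 0 || ry < 0 || rx > cxmax || ry > cymax)
      Rcpp::stop("reference patch outside image bounds");
    const int x0 = std::max(0, rx - radius), x1 = std::min(cxmax, rx + radius);
    const int y0 = std::max(0, ry - radius), y1 = std::min(cymax, ry + radius);
    cand.clear();
    for (int cy = y0; cy <= y1; ++cy) {
      for (int cx_ = x0; cx_ <= x1; ++cx_) {
        if (cx_ == rx && cy == ry) continue;
        const double d = patch_dist(X, rx, ry, cx_, cy, edge);
        cand.push_back(std::make_pair(d, (long long)cy * Mx + cx_));
      }
    }
    if ((int)cand.size() < K - 1)
      Rcpp::stop("candidate window smaller than K");
    std::stable_sort(cand.begin(), cand.end());
    out(r * K, 0) = rx;
    out(r * K, 1) = ry;
    for (int k = 1; k < K; ++k) {
      const long long lin = cand[k - 1].second;
      out(r * K + k, 0) = (int)(lin % Mx);
      out(r * K + k, 1) = (int)(lin / Mx);
    }
  }
  return out;
}
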