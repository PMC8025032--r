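// Rotational-SVD texture directionality.
//
// For each analysis window the normalized SVD dominancy
//   N_SVD(theta) = sigma_1(theta) / sum_i sigma_i(theta)
// is evaluated on the window rotated by theta (bilinear interpolation, zero
// fill), and the directionality is D = max_theta N_SVD - min_theta N_SVD.
// The per-pixel map is the package's hot loop, hence compiled: rotations use
// precomputed bilinear gather tables (the mapping is the same for every
// window); singular values come from LAPACK, the same backend base::svd
// uses, so the compiled path agrees with the pure-R oracle to rounding.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Rotate an n x n matrix about its center by theta (radians), bilinear
// interpolation, zero fill. Output has the same size. Matches the pure-R
// reference implementation formula exactly.
static arma::mat rotate_bilinear(const arma::mat& w, double theta) {
  const int n = w.n_rows;
  const double cc = (n + 1) / 2.0;  // 1-based center
  const double ct = std::cos(theta), st = std::sin(theta);
  arma::mat out(n, n, arma::fill::zeros);
  for (int c = 0; c < n; ++c) {
    const double xc = (c + 1) - cc;
    for (int r = 0; r < n; ++r) {
      const double yc = (r + 1) - cc;
      // inverse rotation of the output coordinate
      const double xs = ct * xc + st * yc;
      const double ys = -st * xc + ct * yc;
      const double sr = ys + cc, sc = xs + cc;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double fr = sr - r0, fc = sc - c0;
      double v = 0.0;
      for (int dr = 0; dr <= 1; ++dr) {
        const int rr = r0 + dr;
        if (rr < 1 || rr > n) continue;
        const double wr = dr ? fr : 1.0 - fr;
        for (int dc = 0; dc <= 1; ++dc) {
          const int ccx = c0 + dc;
          if (ccx < 1 || ccx > n) continue;
          const double wc = dc ? fc : 1.0 - fc;
          v += wr * wc * w(rr - 1, ccx - 1);
        }
      }
      out(r, c) = v;
    }
  }
  return out;
}

// Singular values via LAPACK (the same backend base::svd uses).
static double nsvd_lapack(const arma::mat& m, arma::vec& s) {
  arma::svd(s, m);
  const double tot = arma::accu(s);
  if (tot <= 0.0) return 1.0;
  return s(0) / tot;
}

// [[Rcpp::export(name = "cpp_nsvd")]]
double cpp_nsvd(const arma::mat& window, double theta_deg) {
  arma::vec s(std::min(window.n_rows, window.n_cols));
  if (std::fabs(theta_deg) < 1e-12) return nsvd_lapack(window, s);
  return nsvd_lapack(rotate_bilinear(window, theta_deg * M_PI / 180.0), s);
}

// [[Rcpp::export(name = "cpp_directionality")]]
double cpp_directionality(const arma::mat& window, const arma::vec& thetas_deg) {
  double lo = 2.0, hi = -1.0;
  for (arma::uword i = 0; i < thetas_deg.n_elem; ++i) {
    const double v = cpp_nsvd(window, thetas_deg(i));
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  return hi - lo;
}

// Precomputed bilinear gather table for rotating a wp x wp patch: for each
// output cell, up to 4 source indices and weights (index -1 = outside).
struct RotTable {
  std::vector<int> idx;      // 4 per cell
  std::vector<double> wgt;   // 4 per cell
};

static RotTable make_table(int wp, double theta) {
  RotTable T;
  T.idx.assign(4 * wp * wp, -1);
  T.wgt.assign(4 * wp * wp, 0.0);
  const double cc = (wp + 1) / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int c = 0; c < wp; ++c) {
    const double xc = (c + 1) - cc;
    for (int r = 0; r < wp; ++r) {
      const double yc = (r + 1) - cc;
      const double xs = ct * xc + st * yc;
      const double ys = -st * xc + ct * yc;
      const double sr = ys + cc, sc = xs + cc;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double fr = sr - r0, fc = sc - c0;
      const int cell = r + c * wp;
      int k = 0;
      for (int dc = 0; dc <= 1; ++dc) {
        const int ccx = c0 + dc;
        const double wc = dc ? fc : 1.0 - fc;
        for (int dr = 0; dr <= 1; ++dr) {
          const int rr = r0 + dr;
          const double wr = dr ? fr : 1.0 - fr;
          if (rr >= 1 && rr <= wp && ccx >= 1 && ccx <= wp) {
            T.idx[4 * cell + k] = (rr - 1) + (ccx - 1) * wp;
            T.wgt[4 * cell + k] = wr * wc;
          }
          ++k;
        }
      }
    }
  }
  return T;
}

// Per-pixel directionality map. Each window of side w is extracted with an
// extra margin (zero-filled outside the image), rotated, center-cropped back
// to w x w, and decomposed. All-zero neighborhoods short-circuit to D = 0
// (N_SVD = 1 at every angle by the rank-0 convention).
// [[Rcpp::export(name = "cpp_directionality_map")]]
arma::mat cpp_directionality_map(const arma::mat& img, int w, int margin,
                                 const arma::vec& thetas_deg) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int half = w / 2;          // w odd
  const int wp = w + 2 * margin;
  const int off = half + margin;   // patch reach from the center pixel
  const int nth = thetas_deg.n_elem;
  arma::mat D(nr, nc, arma::fill::zeros);

  std::vector<RotTable> tables;
  std::vector<bool> is_zero_theta(nth);
  for (int i = 0; i < nth; ++i) {
    const double th = thetas_deg(i) * M_PI / 180.0;
    is_zero_theta[i] = std::fabs(th) < 1e-15;
    tables.push_back(is_zero_theta[i] ? RotTable() : make_table(wp, th));
  }

  arma::mat patch(wp, wp), rot(wp, wp), win(w, w);
  arma::vec svals(w);
  const double* P = patch.memptr();
  double* Q = rot.memptr();

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      patch.zeros();
      bool any = false;
      const int r0 = std::max(0, r - off), r1 = std::min(nr - 1, r + off);
      const int c0 = std::max(0, c - off), c1 = std::min(nc - 1, c + off);
      for (int cj = c0; cj <= c1; ++cj)
        for (int ri = r0; ri <= r1; ++ri) {
          const double v = img(ri, cj);
          if (v != 0.0) {
            patch(ri - r + off, cj - c + off) = v;
            any = true;
          }
        }
      if (!any) { D(r, c) = 0.0; continue; }
      double lo = 2.0, hi = -1.0;
      for (int i = 0; i < nth; ++i) {
        if (is_zero_theta[i]) {
          rot = patch;
        } else {
          const RotTable& T = tables[i];
          const int ncell = wp * wp;
          for (int cell = 0; cell < ncell; ++cell) {
            double v = 0.0;
            for (int k = 0; k < 4; ++k) {
              const int id = T.idx[4 * cell + k];
              if (id >= 0) v += T.wgt[4 * cell + k] * P[id];
            }
            Q[cell] = v;
          }
        }
        win = rot.submat(margin, margin, margin + w - 1, margin + w - 1);
        const double v = nsvd_lapack(win, svals);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      D(r, c) = hi - lo;
    }
  }
  return D;
}
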