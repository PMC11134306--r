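#include <Rcpp.h>
using namespace Rcpp;

// Horn-Schunck optic flow between two frames.
//
// Classic formulation: spatiotemporal derivatives estimated over the 2x2x2
// cube (Horn & Schunck 1981), Jacobi iteration
//   u <- ubar - Ex (Ex ubar + Ey vbar + Et) / (alpha^2 + Ex^2 + Ey^2)
// with the 8-neighbour weighted local average (1/6 edge, 1/12 corner).
// Iterates until the mean absolute update falls below `tol` or `n_iter`
// sweeps. Matrix rows are y, columns are x; u is the x-velocity, v the
// y-velocity, in pixels/frame.

static inline double at(const NumericMatrix &m, int i, int j, int h, int w) {
  if (i < 0) i = 0; if (i >= h) i = h - 1;
  if (j < 0) j = 0; if (j >= w) j = w - 1;
  return m(i, j);
}

// [[Rcpp::export]]
List horn_schunck_cpp(NumericMatrix f1, NumericMatrix f2, double alpha,
                      int n_iter, double tol) {
  const int h = f1.nrow(), w = f1.ncol();
  NumericMatrix Ex(h, w), Ey(h, w), Et(h, w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      // derivative estimates averaged over the 2x2x2 cube at (i..i+1, j..j+1)
      Ex(i, j) = 0.25 * (at(f1, i, j + 1, h, w) - at(f1, i, j, h, w) +
                         at(f1, i + 1, j + 1, h, w) - at(f1, i + 1, j, h, w) +
                         at(f2, i, j + 1, h, w) - at(f2, i, j, h, w) +
                         at(f2, i + 1, j + 1, h, w) - at(f2, i + 1, j, h, w));
      Ey(i, j) = 0.25 * (at(f1, i + 1, j, h, w) - at(f1, i, j, h, w) +
                         at(f1, i + 1, j + 1, h, w) - at(f1, i, j + 1, h, w) +
                         at(f2, i + 1, j, h, w) - at(f2, i, j, h, w) +
                         at(f2, i + 1, j + 1, h, w) - at(f2, i, j + 1, h, w));
      Et(i, j) = 0.25 * (at(f2, i, j, h, w) - at(f1, i, j, h, w) +
                         at(f2, i + 1, j, h, w) - at(f1, i + 1, j, h, w) +
                         at(f2, i, j + 1, h, w) - at(f1, i, j + 1, h, w) +
                         at(f2, i + 1, j + 1, h, w) - at(f1, i + 1, j + 1, h, w));
    }
  }
  NumericMatrix u(h, w), v(h, w);
  std::vector<double> ub(h * w), vb(h * w);
  // precompute per-pixel gain terms: gx = Ex/den, gy = Ey/den, gt = Et/den
  std::vector<double> gx(h * w), gy(h * w), gt(h * w);
  const double a2 = alpha * alpha;
  for (int k = 0; k < h * w; ++k) {
    double ex = Ex[k], ey = Ey[k];
    double den = a2 + ex * ex + ey * ey;
    gx[k] = ex / den; gy[k] = ey / den; gt[k] = Et[k] / den;
  }
  // clamped neighbour offsets (branch-free inner loop)
  std::vector<int> im1(h), ip1(h), jm1(w), jp1(w);
  for (int i = 0; i < h; ++i) { im1[i] = std::max(i - 1, 0); ip1[i] = std::min(i + 1, h - 1); }
  for (int j = 0; j < w; ++j) { jm1[j] = std::max(j - 1, 0); jp1[j] = std::min(j + 1, w - 1); }
  double *pu = REAL(u), *pv = REAL(v);
  int iter = 0;
  for (iter = 0; iter < n_iter; ++iter) {
    for (int j = 0; j < w; ++j) {
      const int c0 = j * h, cl = jm1[j] * h, cr = jp1[j] * h;
      for (int i = 0; i < h; ++i) {
        const int iu = im1[i], id = ip1[i];
        ub[c0 + i] = (pu[c0 + iu] + pu[c0 + id] + pu[cl + i] + pu[cr + i]) / 6.0 +
                     (pu[cl + iu] + pu[cl + id] + pu[cr + iu] + pu[cr + id]) / 12.0;
        vb[c0 + i] = (pv[c0 + iu] + pv[c0 + id] + pv[cl + i] + pv[cr + i]) / 6.0 +
                     (pv[cl + iu] + pv[cl + id] + pv[cr + iu] + pv[cr + id]) / 12.0;
      }
    }
    double delta = 0.0;
    for (int k = 0; k < h * w; ++k) {
      double num = Ex[k] * ub[k] + Ey[k] * vb[k] + Et[k];
      double un = ub[k] - gx[k] * num;
      double vn = vb[k] - gy[k] * num;
      delta += std::abs(un - pu[k]) + std::abs(vn - pv[k]);
      pu[k] = un; pv[k] = vn;
    }
    if (delta / (2.0 * h * w) < tol) { ++iter; break; }
  }
  (void)gt;
  return List::create(_["u"] = u, _["v"] = v, _["iterations"] = iter);
}

// Per-pixel 3-frame running median over time, then non-overlapping 2-frame
// mean binning. `movie` is T x P (time in rows). Endpoints of the median use
// the 2-frame median (mean). An odd trailing frame is dropped by the caller.
// [[Rcpp::export]]
NumericMatrix median3_bin2_cpp(NumericMatrix movie) {
  const int tn = movie.nrow(), p = movie.ncol();
  const int tb = tn / 2;
  NumericMatrix out(tb, p);
  for (int j = 0; j < p; ++j) {
    for (int t = 0; t < 2 * tb; ++t) {
      double m;
      if (t == 0 || t == tn - 1) {
        m = movie(t, j);  // endpoints pass through unchanged
      } else {
        double a = movie(t - 1, j), b = movie(t, j), c = movie(t + 1, j);
        m = a + b + c - std::max(a, std::max(b, c)) - std::min(a, std::min(b, c));
      }
      out(t / 2, j) += 0.5 * m;
    }
  }
  return out;
}
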