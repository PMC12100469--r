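// Numeric kernels: 3D convolution forward/backward via per-offset shifted
// GEMM (a small shift buffer that stays cache-resident, instead of a full
// im2col patches matrix), 2x max-pooling, nearest-neighbour 2x upsampling,
// and the gamma-index search.  Arrays follow R's column-major layout with
// dims (D, H, W, C) = (SI, AP, RL, channels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill buf(n_out, C) with the input translated by kernel offset
// (di,dj,dk) on the (possibly strided) output lattice, zero outside.
static void fill_shift(const double* x, int D, int H, int W, int C,
                       int k, int s, int di, int dj, int dk, arma::mat& buf) {
  const int p = (k - 1) / 2;
  const int Do = out_len(D, k, s, p), Ho = out_len(H, k, s, p),
            Wo = out_len(W, k, s, p);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)D * H * W * c;
    double* bc = buf.colptr(c);
    for (int ok = 0; ok < Wo; ++ok) {
      const int kk = ok * s - p + dk;
      const bool in_k = kk >= 0 && kk < W;
      for (int oj = 0; oj < Ho; ++oj) {
        const int jj = oj * s - p + dj;
        double* brow = bc + (long)Do * (oj + (long)Ho * ok);
        if (!in_k || jj < 0 || jj >= H) {
          std::fill(brow, brow + Do, 0.0);
          continue;
        }
        const double* xrow = xc + (long)D * (jj + (long)H * kk);
        if (s == 1) {
          const int lo = std::max(0, p - di);        // ii = oi - p + di
          const int hi = std::min(Do, D + p - di);
          if (lo > 0) std::fill(brow, brow + lo, 0.0);
          if (hi > lo) std::copy(xrow + lo - p + di, xrow + hi - p + di,
                                 brow + lo);
          if (hi < Do) std::fill(brow + std::max(hi, lo), brow + Do, 0.0);
        } else {
          for (int oi = 0; oi < Do; ++oi) {
            const int ii = oi * s - p + di;
            brow[oi] = (ii >= 0 && ii < D) ? xrow[ii] : 0.0;
          }
        }
      }
    }
  }
}

// Weight sub-matrix (Cin x Cout) for one kernel offset; w rows are ordered
// di + k*(dj + k*(dk + k*c)).
static arma::mat offset_weights(const arma::mat& Wm, int k, int C,
                                int di, int dj, int dk) {
  const int k3 = k * k * k;
  arma::mat Wd(C, Wm.n_cols);
  const int d = di + k * (dj + k * dk);
  for (int c = 0; c < C; ++c) Wd.row(c) = Wm.row(d + (long)k3 * c);
  return Wd;
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector dims,
                         NumericMatrix w, NumericVector b, int k, int stride) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int p = (k - 1) / 2;
  const int Do = out_len(D, k, stride, p), Ho = out_len(H, k, stride, p),
            Wo = out_len(W, k, stride, p);
  const int Cout = w.ncol();
  const long n_out = (long)Do * Ho * Wo;
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat O(n_out, Cout);
  O.each_row() = arma::rowvec(b.begin(), b.size(), false);
  if (k == 1 && stride == 1) {
    arma::mat X((double*)x.begin(), n_out, C, false);
    O += X * Wm;
  } else {
    arma::mat buf(n_out, C);
    for (int dk = 0; dk < k; ++dk)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          fill_shift(x.begin(), D, H, W, C, k, stride, di, dj, dk, buf);
          O += buf * offset_weights(Wm, k, C, di, dj, dk);
        }
  }
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// Scatter-add T(n_out, C) into gx with one kernel offset (adjoint of
// fill_shift).
static void scatter_shift(const arma::mat& T, double* gx,
                          int D, int H, int W, int C,
                          int k, int s, int di, int dj, int dk) {
  const int p = (k - 1) / 2;
  const int Do = out_len(D, k, s, p), Ho = out_len(H, k, s, p),
            Wo = out_len(W, k, s, p);
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (long)D * H * W * c;
    const double* tc = T.colptr(c);
    for (int ok = 0; ok < Wo; ++ok) {
      const int kk = ok * s - p + dk;
      if (kk < 0 || kk >= W) continue;
      for (int oj = 0; oj < Ho; ++oj) {
        const int jj = oj * s - p + dj;
        if (jj < 0 || jj >= H) continue;
        const double* trow = tc + (long)Do * (oj + (long)Ho * ok);
        double* grow = gc + (long)D * (jj + (long)H * kk);
        if (s == 1) {
          const int lo = std::max(0, p - di);
          const int hi = std::min(Do, D + p - di);
          for (int oi = lo; oi < hi; ++oi) grow[oi - p + di] += trow[oi];
        } else {
          for (int oi = 0; oi < Do; ++oi) {
            const int ii = oi * s - p + di;
            if (ii >= 0 && ii < D) grow[ii] += trow[oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                NumericVector gout, int k, int stride) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int p = (k - 1) / 2;
  const int Do = out_len(D, k, stride, p), Ho = out_len(H, k, stride, p),
            Wo = out_len(W, k, stride, p);
  const int Cout = w.ncol();
  const int k3 = k * k * k;
  const long n_out = (long)Do * Ho * Wo;
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat G((double*)gout.begin(), n_out, Cout, false);
  arma::mat gW((long)k3 * C, Cout, arma::fill::zeros);
  arma::rowvec gB = arma::sum(G, 0);
  NumericVector gx((long)D * H * W * C);
  if (k == 1 && stride == 1) {
    arma::mat X((double*)x.begin(), n_out, C, false);
    arma::mat gWd = X.t() * G;
    for (int c = 0; c < C; ++c) gW.row(c) = gWd.row(c);
    arma::mat T = G * Wm.t();
    std::copy(T.begin(), T.end(), gx.begin());
  } else {
    arma::mat buf(n_out, C);
    for (int dk = 0; dk < k; ++dk)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          fill_shift(x.begin(), D, H, W, C, k, stride, di, dj, dk, buf);
          arma::mat gWd = buf.t() * G;
          const int d = di + k * (dj + k * dk);
          for (int c = 0; c < C; ++c) gW.row(d + (long)k3 * c) = gWd.row(c);
          arma::mat T = G * offset_weights(Wm, k, C, di, dj, dk).t();
          scatter_shift(T, gx.begin(), D, H, W, C, k, stride, di, dj, dk);
        }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(gW.n_rows, gW.n_cols, gW.begin()),
                      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// 2x max pooling (dims must be even).  Returns pooled values and 1-based
// argmax linear indices into the input.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const long n_out = (long)Do * Ho * Wo * C;
  NumericVector out(n_out);
  IntegerVector arg(n_out);
  const double* xp = x.begin();
  long o = 0;
  for (int c = 0; c < C; ++c)
    for (int ok = 0; ok < Wo; ++ok)
      for (int oj = 0; oj < Ho; ++oj)
        for (int oi = 0; oi < Do; ++oi, ++o) {
          double best = -INFINITY; long bidx = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const long idx = (2 * oi + di) +
                  (long)D * ((2 * oj + dj) + (long)H * ((2 * ok + dk) + (long)W * c));
                if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
              }
          out[o] = best; arg[o] = (int)(bidx + 1);
        }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(IntegerVector argmax, NumericVector gout,
                          IntegerVector dims_in) {
  NumericVector gx((long)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  for (long o = 0; o < gout.size(); ++o) gx[argmax[o] - 1] += gout[o];
  gx.attr("dim") = dims_in;
  return gx;
}

// [[Rcpp::export(name = ".upsample_fwd")]]
NumericVector upsample_fwd(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector out((long)Do * Ho * Wo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < Wo; ++kk)
      for (int jj = 0; jj < Ho; ++jj) {
        const long ibase = (long)D * ((jj / 2) + (long)H * ((kk / 2) + (long)W * c));
        const long obase = (long)Do * (jj + (long)Ho * (kk + (long)Wo * c));
        for (int ii = 0; ii < Do; ++ii)
          op[ii + obase] = xp[(ii / 2) + ibase];
      }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
NumericVector upsample_bwd(NumericVector gout, IntegerVector dims_out) {
  const int Do = dims_out[0], Ho = dims_out[1], Wo = dims_out[2], C = dims_out[3];
  const int D = Do / 2, H = Ho / 2, W = Wo / 2;
  NumericVector gx((long)D * H * W * C);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < Wo; ++kk)
      for (int jj = 0; jj < Ho; ++jj) {
        const long ibase = (long)D * ((jj / 2) + (long)H * ((kk / 2) + (long)W * c));
        const long obase = (long)Do * (jj + (long)Ho * (kk + (long)Wo * c));
        for (int ii = 0; ii < Do; ++ii)
          xp[(ii / 2) + ibase] += gp[ii + obase];
      }
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  return gx;
}

// ---------------------------------------------------------------------------
// Gamma index search.  For each voxel of the reference inside the analysis
// mask with reference dose >= threshold, minimize over candidate spatial
// offsets o (mm, pre-sorted by |o|):
//   gamma^2 = (Deval(r + o) - Dref(r))^2 / dd^2 + |o|^2 / dta^2
// with Deval trilinearly interpolated.  Early exit: once |o|^2/dta^2
// exceeds the current best gamma^2 no later candidate can win.
// ---------------------------------------------------------------------------

static inline double trilin(const double* v, const int* d,
                            double x, double y, double z) {
  // x,y,z are continuous 0-based voxel coords; caller guarantees in-range.
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > d[0] - 2) i0 = d[0] - 2; if (i0 < 0) i0 = 0;
  if (j0 > d[1] - 2) j0 = d[1] - 2; if (j0 < 0) j0 = 0;
  if (k0 > d[2] - 2) k0 = d[2] - 2; if (k0 < 0) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const long s1 = d[0], s2 = (long)d[0] * d[1];
  const double* p = v + i0 + s1 * j0 + s2 * k0;
  const double c00 = p[0] * (1 - fx) + p[1] * fx;
  const double c10 = p[s1] * (1 - fx) + p[s1 + 1] * fx;
  const double c01 = p[s2] * (1 - fx) + p[s2 + 1] * fx;
  const double c11 = p[s2 + s1] * (1 - fx) + p[s2 + s1 + 1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

// [[Rcpp::export(name = ".gamma_search")]]
NumericVector gamma_search(NumericVector ref, NumericVector eval,
                           IntegerVector dims, NumericVector spacing,
                           LogicalVector mask, double dose_denom,
                           double dta, double threshold,
                           NumericMatrix offsets, NumericVector off_dist2) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const long n = (long)d[0] * d[1] * d[2];
  const int n_off = offsets.nrow();
  NumericVector out(n, NA_REAL);
  const double* rp = ref.begin();
  const double* ep = eval.begin();
  const double dd2 = dose_denom * dose_denom;
  const double dta2 = dta * dta;
  long idx = 0;
  for (int kk = 0; kk < d[2]; ++kk)
    for (int jj = 0; jj < d[1]; ++jj)
      for (int ii = 0; ii < d[0]; ++ii, ++idx) {
        if (!mask[idx] || rp[idx] < threshold) continue;
        const double dref = rp[idx];
        double best = INFINITY;
        for (int t = 0; t < n_off; ++t) {
          const double geo = off_dist2[t] / dta2;
          if (geo >= best) break;  // offsets sorted by distance
          const double x = ii + offsets(t, 0) / spacing[0];
          const double y = jj + offsets(t, 1) / spacing[1];
          const double z = kk + offsets(t, 2) / spacing[2];
          if (x < 0 || x > d[0] - 1 || y < 0 || y > d[1] - 1 ||
              z < 0 || z > d[2] - 1) continue;
          const double de = trilin(ep, d, x, y, z);
          const double g = (de - dref) * (de - dref) / dd2 + geo;
          if (g < best) best = g;
        }
        out[idx] = std::sqrt(best);
      }
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2]);
  return out;
}
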