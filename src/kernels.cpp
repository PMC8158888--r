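// Low-level numerical kernels for the segmentation network and resampling.
//
// Feature maps are stored the R way (column-major): 2D features as
// (H, W, C) arrays, depth-bearing features as (H, W, D, C). Convolution
// weights are flattened to a (k^d * C_in, C_out) matrix whose row order is
// fixed by the im2col routines below; forward and backward share that order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- im2col / col2im (2D, stride 1, "same" zero padding) -------------------

static arma::mat im2col2d(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  arma::mat cols(static_cast<size_t>(H) * W, static_cast<size_t>(k) * k * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = (c * k + dj) * k + di;
        const int oi = di - p, oj = dj - p;
        const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W - 1, W - 1 - oj);
        if (i0 > i1 || j0 > j1) continue;
        for (int j = j0; j <= j1; ++j) {
          std::memcpy(cols.colptr(q) + i0 + static_cast<size_t>(H) * j,
                      x.slice_colptr(c, 0) + (i0 + oi) + static_cast<size_t>(H) * (j + oj),
                      sizeof(double) * (i1 - i0 + 1));
        }
      }
    }
  }
  return cols;
}

static void col2im2d(const arma::mat& dcols, arma::cube& dx, int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = (c * k + dj) * k + di;
        const int oi = di - p, oj = dj - p;
        const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W - 1, W - 1 - oj);
        if (i0 > i1 || j0 > j1) continue;
        for (int j = j0; j <= j1; ++j) {
          double* dst = dx.slice_colptr(c, 0) + (i0 + oi) + static_cast<size_t>(H) * (j + oj);
          const double* src = dcols.colptr(q) + i0 + static_cast<size_t>(H) * j;
          for (int i = 0; i <= i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// Forward pass; optionally also returns the im2col matrix so the backward
// pass can reuse it instead of rebuilding it.
// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
List cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                   const arma::mat& W, const arma::vec& b, int k,
                   bool keep_cols) {
  const int H = xdim[0], Wd = xdim[1], C = xdim[2];
  const arma::cube xc(const_cast<double*>(x.begin()), H, Wd, C, false, true);
  arma::mat cols = im2col2d(xc, k);
  arma::mat out = cols * W;                      // (H*W, Cout)
  out.each_row() += b.t();
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, Wd, (int)W.n_cols);
  if (!keep_cols) return List::create(_["out"] = res);
  return List::create(_["out"] = res, _["cols"] = cols);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(const arma::mat& cols, IntegerVector xdim,
                   const arma::mat& W, NumericVector gy, int k) {
  const int H = xdim[0], Wd = xdim[1], C = xdim[2];
  const int Cout = W.n_cols;
  const arma::mat G(const_cast<double*>(gy.begin()),
                    static_cast<size_t>(H) * Wd, Cout, false, true);
  arma::mat dW = cols.t() * G;
  arma::vec db = arma::sum(G, 0).t();
  arma::mat dcols = G * W.t();
  arma::cube dx(H, Wd, C, arma::fill::zeros);
  col2im2d(dcols, dx, k);
  NumericVector dxv(dx.begin(), dx.end());
  dxv.attr("dim") = xdim;
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}

// ---- im2col / col2im (3D, depth-preserving padding) -------------------------

static arma::mat im2col3d(const double* x, int H, int W, int D, int C, int k) {
  const int p = (k - 1) / 2;
  const size_t HW = static_cast<size_t>(H) * W;
  arma::mat cols(HW * D, static_cast<size_t>(k) * k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dd = 0; dd < k; ++dd) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int q = ((c * k + dd) * k + dj) * k + di;
          const int oi = di - p, oj = dj - p, od = dd - p;
          const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
          const int j0 = std::max(0, -oj), j1 = std::min(W - 1, W - 1 - oj);
          const int d0 = std::max(0, -od), d1 = std::min(D - 1, D - 1 - od);
          if (i0 > i1 || j0 > j1 || d0 > d1) continue;
          for (int d = d0; d <= d1; ++d) {
            for (int j = j0; j <= j1; ++j) {
              std::memcpy(cols.colptr(q) + i0 + static_cast<size_t>(H) * j + HW * d,
                          x + (i0 + oi) + static_cast<size_t>(H) * (j + oj) +
                              HW * (d + od) + HW * D * c,
                          sizeof(double) * (i1 - i0 + 1));
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im3d(const arma::mat& dcols, double* dx,
                     int H, int W, int D, int C, int k) {
  const int p = (k - 1) / 2;
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c) {
    for (int dd = 0; dd < k; ++dd) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int q = ((c * k + dd) * k + dj) * k + di;
          const int oi = di - p, oj = dj - p, od = dd - p;
          const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
          const int j0 = std::max(0, -oj), j1 = std::min(W - 1, W - 1 - oj);
          const int d0 = std::max(0, -od), d1 = std::min(D - 1, D - 1 - od);
          if (i0 > i1 || j0 > j1 || d0 > d1) continue;
          for (int d = d0; d <= d1; ++d) {
            for (int j = j0; j <= j1; ++j) {
              double* dst = dx + (i0 + oi) + static_cast<size_t>(H) * (j + oj) +
                            HW * (d + od) + HW * D * c;
              const double* src = dcols.colptr(q) + i0 + static_cast<size_t>(H) * j + HW * d;
              for (int i = 0; i <= i1 - i0; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3d_fw")]]
List cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                   const arma::mat& W, const arma::vec& b, int k,
                   bool keep_cols) {
  const int H = xdim[0], Wd = xdim[1], D = xdim[2], C = xdim[3];
  arma::mat cols = im2col3d(x.begin(), H, Wd, D, C, k);
  arma::mat out = cols * W;
  out.each_row() += b.t();
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, Wd, D, (int)W.n_cols);
  if (!keep_cols) return List::create(_["out"] = res);
  return List::create(_["out"] = res, _["cols"] = cols);
}

// [[Rcpp::export(name = ".cpp_conv3d_bw")]]
List cpp_conv3d_bw(const arma::mat& cols, IntegerVector xdim,
                   const arma::mat& W, NumericVector gy, int k) {
  const int H = xdim[0], Wd = xdim[1], D = xdim[2], C = xdim[3];
  const int Cout = W.n_cols;
  const arma::mat G(const_cast<double*>(gy.begin()),
                    static_cast<size_t>(H) * Wd * D, Cout, false, true);
  arma::mat dW = cols.t() * G;
  arma::vec db = arma::sum(G, 0).t();
  arma::mat dcols = G * W.t();
  NumericVector dxv(static_cast<R_xlen_t>(H) * Wd * D * C);
  std::fill(dxv.begin(), dxv.end(), 0.0);
  col2im3d(dcols, dxv.begin(), H, Wd, D, C, k);
  dxv.attr("dim") = xdim;
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}

// ---- 2x2 max pooling over the first two dims (any trailing slices) ---------

// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1];
  int S = 1;
  for (int t = 2; t < xdim.size(); ++t) S *= xdim[t];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<size_t>(Ho) * Wo * S);
  IntegerVector arg(out.size());
  const double* xp = x.begin();
  for (int s = 0; s < S; ++s) {
    const size_t xoff = static_cast<size_t>(H) * W * s;
    const size_t ooff = static_cast<size_t>(Ho) * Wo * s;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bidx = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const size_t idx = xoff + (2 * i + di) + static_cast<size_t>(H) * (2 * j + dj);
            if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
          }
        }
        out[ooff + i + static_cast<size_t>(Ho) * j] = best;
        arg[ooff + i + static_cast<size_t>(Ho) * j] = static_cast<int>(bidx);
      }
    }
  }
  IntegerVector odim = clone(xdim);
  odim[0] = Ho; odim[1] = Wo;
  out.attr("dim") = odim;
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector arg, int n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t t = 0; t < gy.size(); ++t) dx[arg[t]] += gy[t];
  return dx;
}

// ---- bilinear resampling (half-pixel centers) -------------------------------

static void lin_index(int n_out, int n_in, std::vector<int>& i0,
                      std::vector<int>& i1, std::vector<double>& w) {
  const double scale = static_cast<double>(n_in) / n_out;
  i0.resize(n_out); i1.resize(n_out); w.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    double f = std::floor(s);
    double ww = s - f;
    int a = static_cast<int>(f), b = a + 1;
    if (a < 0) { a = 0; }
    if (b > n_in - 1) { b = n_in - 1; }
    if (a > n_in - 1) { a = n_in - 1; }
    i0[i] = a; i1[i] = b; w[i] = ww < 0 ? 0.0 : (ww > 1 ? 1.0 : ww);
    if (a == b) w[i] = 0.0;
  }
}

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim,
                                  int ho, int wo) {
  const int H = xdim[0], W = xdim[1];
  int S = 1;
  for (int t = 2; t < xdim.size(); ++t) S *= xdim[t];
  std::vector<int> r0, r1, c0, c1; std::vector<double> rw, cw;
  lin_index(ho, H, r0, r1, rw);
  lin_index(wo, W, c0, c1, cw);
  NumericVector out(static_cast<size_t>(ho) * wo * S);
  const double* xp = x.begin();
  for (int s = 0; s < S; ++s) {
    const size_t xoff = static_cast<size_t>(H) * W * s;
    const size_t ooff = static_cast<size_t>(ho) * wo * s;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        const double a = xp[xoff + r0[i] + static_cast<size_t>(H) * c0[j]];
        const double b = xp[xoff + r1[i] + static_cast<size_t>(H) * c0[j]];
        const double c = xp[xoff + r0[i] + static_cast<size_t>(H) * c1[j]];
        const double d = xp[xoff + r1[i] + static_cast<size_t>(H) * c1[j]];
        const double top = a * (1 - rw[i]) + b * rw[i];
        const double bot = c * (1 - rw[i]) + d * rw[i];
        out[ooff + i + static_cast<size_t>(ho) * j] = top * (1 - cw[j]) + bot * cw[j];
      }
    }
  }
  IntegerVector odim = clone(xdim);
  odim[0] = ho; odim[1] = wo;
  out.attr("dim") = odim;
  return out;
}

// Adjoint of cpp_resize_bilinear (scatter gradients back to input grid).
// [[Rcpp::export(name = ".cpp_resize_bilinear_bw")]]
NumericVector cpp_resize_bilinear_bw(NumericVector gy, IntegerVector ydim,
                                     int hi, int wi) {
  const int ho = ydim[0], wo = ydim[1];
  int S = 1;
  for (int t = 2; t < ydim.size(); ++t) S *= ydim[t];
  std::vector<int> r0, r1, c0, c1; std::vector<double> rw, cw;
  lin_index(ho, hi, r0, r1, rw);
  lin_index(wo, wi, c0, c1, cw);
  NumericVector dx(static_cast<size_t>(hi) * wi * S);
  std::fill(dx.begin(), dx.end(), 0.0);
  const double* gp = gy.begin();
  for (int s = 0; s < S; ++s) {
    const size_t xoff = static_cast<size_t>(hi) * wi * s;
    const size_t ooff = static_cast<size_t>(ho) * wo * s;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        const double g = gp[ooff + i + static_cast<size_t>(ho) * j];
        dx[xoff + r0[i] + static_cast<size_t>(hi) * c0[j]] += g * (1 - rw[i]) * (1 - cw[j]);
        dx[xoff + r1[i] + static_cast<size_t>(hi) * c0[j]] += g * rw[i] * (1 - cw[j]);
        dx[xoff + r0[i] + static_cast<size_t>(hi) * c1[j]] += g * (1 - rw[i]) * cw[j];
        dx[xoff + r1[i] + static_cast<size_t>(hi) * c1[j]] += g * rw[i] * cw[j];
      }
    }
  }
  IntegerVector idim = clone(ydim);
  idim[0] = hi; idim[1] = wi;
  dx.attr("dim") = idim;
  return dx;
}

// [[Rcpp::export(name = ".cpp_resize_nearest")]]
NumericVector cpp_resize_nearest(NumericVector x, IntegerVector xdim,
                                 int ho, int wo) {
  const int H = xdim[0], W = xdim[1];
  int S = 1;
  for (int t = 2; t < xdim.size(); ++t) S *= xdim[t];
  std::vector<int> ri(ho), ci(wo);
  const double sr = static_cast<double>(H) / ho, sc = static_cast<double>(W) / wo;
  for (int i = 0; i < ho; ++i)
    ri[i] = std::min(H - 1, std::max(0, static_cast<int>(std::floor((i + 0.5) * sr))));
  for (int j = 0; j < wo; ++j)
    ci[j] = std::min(W - 1, std::max(0, static_cast<int>(std::floor((j + 0.5) * sc))));
  NumericVector out(static_cast<size_t>(ho) * wo * S);
  const double* xp = x.begin();
  for (int s = 0; s < S; ++s) {
    const size_t xoff = static_cast<size_t>(H) * W * s;
    const size_t ooff = static_cast<size_t>(ho) * wo * s;
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i)
        out[ooff + i + static_cast<size_t>(ho) * j] =
            xp[xoff + ri[i] + static_cast<size_t>(H) * ci[j]];
  }
  IntegerVector odim = clone(xdim);
  odim[0] = ho; odim[1] = wo;
  out.attr("dim") = odim;
  return out;
}

// ---- 6-connected component labelling (for mask post-processing) -------------

// [[Rcpp::export(name = ".cpp_label6")]]
IntegerVector cpp_label6(NumericVector mask, IntegerVector mdim) {
  const int W = mdim[0], H = mdim[1], D = mdim[2];
  const size_t n = static_cast<size_t>(W) * H * D;
  IntegerVector lab(mask.size());
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<size_t> stack;
  int next = 0;
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] <= 0 || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int z = cur / (static_cast<size_t>(W) * H);
      const int rem = cur % (static_cast<size_t>(W) * H);
      const int y = rem / W, x = rem % W;
      for (int t = 0; t < 6; ++t) {
        const int nx = x + off[t][0], ny = y + off[t][1], nz = z + off[t][2];
        if (nx < 0 || nx >= W || ny < 0 || ny >= H || nz < 0 || nz >= D) continue;
        const size_t q = nx + static_cast<size_t>(W) * (ny + static_cast<size_t>(H) * nz);
        if (mask[q] > 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = mdim;
  return lab;
}
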