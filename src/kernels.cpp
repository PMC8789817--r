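// Hot tensor kernels for the convolutional backbone.
//
// Arrays follow R's column-major (H, W, C, N) layout.  The matrix products
// themselves stay in R (BLAS); these kernels cover the memory-bound
// gather/scatter and normalization passes that dominate training time when
// written with R-level temporaries.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// im2col: gather k x k patches (stride, zero padding) into a
// (k*k*C) x (P*N) matrix, patch entries ordered (di, dj, c), positions
// column-major over (outH, outW).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  const int K = k * k * C, P = outH * outW;
  NumericMatrix col(K, P * N);
  const double *px = x.begin();
  double *pc = col.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < outW; ++oj) {
      for (int oi = 0; oi < outH; ++oi) {
        const int p = oi + outH * oj;
        double *dst = pc + (size_t)K * (p + (size_t)P * n);
        const int i0 = oi * stride - pad, j0 = oj * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *plane = px + (size_t)H * W * (c + (size_t)C * n);
          for (int dj = 0; dj < k; ++dj) {
            const int jj = j0 + dj;
            const bool jok = jj >= 0 && jj < W;
            for (int di = 0; di < k; ++di) {
              const int ii = i0 + di;
              *dst++ = (jok && ii >= 0 && ii < H) ? plane[ii + (size_t)H * jj] : 0.0;
            }
          }
        }
      }
    }
  }
  return col;
}

// col2im: scatter-add the gradient of an im2col matrix back to the input.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix gcol, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  const int K = k * k * C, P = outH * outW;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double *pdx = dx.begin();
  const double *pg = gcol.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < outW; ++oj) {
      for (int oi = 0; oi < outH; ++oi) {
        const int p = oi + outH * oj;
        const double *src = pg + (size_t)K * (p + (size_t)P * n);
        const int i0 = oi * stride - pad, j0 = oj * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *plane = pdx + (size_t)H * W * (c + (size_t)C * n);
          for (int dj = 0; dj < k; ++dj) {
            const int jj = j0 + dj;
            const bool jok = jj >= 0 && jj < W;
            for (int di = 0; di < k; ++di, ++src) {
              const int ii = i0 + di;
              if (jok && ii >= 0 && ii < H) plane[ii + (size_t)H * jj] += *src;
            }
          }
        }
      }
    }
  }
  return dx;
}

// (C_out) x (P*N) matrix -> (outH, outW, C_out, N) array.
// [[Rcpp::export]]
NumericVector conv_out_to_array_cpp(NumericMatrix out, int outH, int outW,
                                    int C, int N) {
  const int P = outH * outW;
  NumericVector arr((size_t)P * C * N);
  arr.attr("dim") = IntegerVector::create(outH, outW, C, N);
  const double *src = out.begin();
  double *dst = arr.begin();
  for (int n = 0; n < N; ++n)
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < C; ++c)
        dst[p + (size_t)P * (c + (size_t)C * n)] =
          src[c + (size_t)C * (p + (size_t)P * n)];
  return arr;
}

// (outH, outW, C, N) array -> (C) x (P*N) matrix (inverse of the above).
// [[Rcpp::export]]
NumericMatrix conv_array_to_mat_cpp(NumericVector arr, int outH, int outW,
                                    int C, int N) {
  const int P = outH * outW;
  NumericMatrix out(C, P * N);
  double *dst = out.begin();
  const double *src = arr.begin();
  for (int n = 0; n < N; ++n)
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < C; ++c)
        dst[c + (size_t)C * (p + (size_t)P * n)] =
          src[p + (size_t)P * (c + (size_t)C * n)];
  return out;
}

// Max pooling (no padding); ties go to the first (lowest-index) window entry.
// Returns the pooled array and the 0-based argmax linear indices into x.
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                  int k, int stride) {
  const int outH = (H - k) / stride + 1;
  const int outW = (W - k) / stride + 1;
  NumericVector out((size_t)outH * outW * C * N);
  IntegerVector arg((size_t)outH * outW * C * N);
  out.attr("dim") = IntegerVector::create(outH, outW, C, N);
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = arg.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < outW; ++oj) {
        for (int oi = 0; oi < outH; ++oi) {
          const int i0 = oi * stride, j0 = oj * stride;
          double best = px[base + i0 + (size_t)H * j0];
          size_t bidx = base + i0 + (size_t)H * j0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di) {
              const size_t idx = base + (i0 + di) + (size_t)H * (j0 + dj);
              if (px[idx] > best) { best = px[idx]; bidx = idx; }
            }
          // (oi, oj, c, n) position in output layout
          const size_t op = (size_t)(oi + outH * (oj + (size_t)outW * (c + (size_t)C * n)));
          po[op] = best;
          pa[op] = (int)bidx;
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(NumericVector dout, IntegerVector arg,
                           int H, int W, int C, int N) {
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double *pdx = dx.begin();
  const double *pd = dout.begin();
  const int *pa = arg.begin();
  const size_t L = dout.size();
  for (size_t i = 0; i < L; ++i) pdx[pa[i]] += pd[i];
  return dx;
}

// Group normalization, fused.  x viewed as [spatial][C][N] (spatial fastest,
// channels grouped contiguously); per image and group the pre-affine output
// has mean 0 and variance 1 (up to eps).
// [[Rcpp::export]]
List gn_fwd_cpp(NumericVector x, int spatial, int C, int N, int groups,
                NumericVector gamma, NumericVector beta, double eps) {
  const int Cg = C / groups;
  const size_t m = (size_t)spatial * Cg;
  NumericVector out(x.size()), xhat(x.size());
  NumericVector s((size_t)groups * N);
  const double *px = x.begin();
  double *po = out.begin(), *ph = xhat.begin(), *ps = s.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const size_t off = (size_t)spatial * C * n + m * g;
      double sum = 0, sq = 0;
      for (size_t i = 0; i < m; ++i) { const double v = px[off + i]; sum += v; sq += v * v; }
      const double mu = sum / m;
      const double var = sq / m - mu * mu;
      const double sd = std::sqrt(var + eps);
      ps[g + (size_t)groups * n] = sd;
      for (int cc = 0; cc < Cg; ++cc) {
        const int c = g * Cg + cc;
        const double ga = gamma[c], be = beta[c];
        const size_t coff = off + (size_t)spatial * cc;
        for (int sp = 0; sp < spatial; ++sp) {
          const double h = (px[coff + sp] - mu) / sd;
          ph[coff + sp] = h;
          po[coff + sp] = ga * h + be;
        }
      }
    }
  }
  out.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["xhat"] = xhat, _["s"] = s);
}

// [[Rcpp::export]]
List gn_bwd_cpp(NumericVector dout, NumericVector xhat, NumericVector s,
                int spatial, int C, int N, int groups, NumericVector gamma) {
  const int Cg = C / groups;
  const size_t m = (size_t)spatial * Cg;
  NumericVector dx(dout.size());
  NumericVector dgamma(C), dbeta(C);
  const double *pd = dout.begin(), *ph = xhat.begin(), *ps = s.begin();
  const double *pg = gamma.begin();
  double *pdx = dx.begin(), *pdg = dgamma.begin(), *pdb = dbeta.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const size_t off = (size_t)spatial * C * n + m * g;
      const double sd = ps[g + (size_t)groups * n];
      double sum_d = 0, sum_dh = 0;
      for (int cc = 0; cc < Cg; ++cc) {
        const int c = g * Cg + cc;
        const double ga = pg[c];
        const size_t coff = off + (size_t)spatial * cc;
        double dg = 0, db = 0;
        for (int sp = 0; sp < spatial; ++sp) {
          const double d = pd[coff + sp], h = ph[coff + sp];
          dg += d * h; db += d;
          sum_d += d * ga; sum_dh += d * ga * h;
        }
        pdg[c] += dg; pdb[c] += db;
      }
      const double mean_d = sum_d / m, mean_dh = sum_dh / m;
      for (int cc = 0; cc < Cg; ++cc) {
        const int c = g * Cg + cc;
        const double ga = pg[c];
        const size_t coff = off + (size_t)spatial * cc;
        for (int sp = 0; sp < spatial; ++sp) {
          pdx[coff + sp] = (pd[coff + sp] * ga - mean_d -
                            ph[coff + sp] * mean_dh) / sd;
        }
      }
    }
  }
  dx.attr("dim") = dout.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
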