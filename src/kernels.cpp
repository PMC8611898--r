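// Low-level numeric kernels for the 3D CNN: convolution forward/backward,
// max-pooling with argmax bookkeeping, ReLU, batch-norm reductions, and
// connected-component labelling. Tensors are column-major R arrays laid out
// (D1, D2, D3, C, N). Convolution loops are organized per output row so each
// input channel streams through cache once per (ci, co) pair.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// 3D cross-correlation ("convolution" in the CNN sense) with zero padding
// that preserves the spatial size. Kernel dims must be odd.
// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], Ci = xd[3], N = xd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Co = wd[4];
  const int H1 = K1 / 2, H2 = K2 / 2, H3 = K3 / 2;
  const R_xlen_t S = (R_xlen_t)D1 * D2 * D3;
  NumericVector y(S * Co * N);
  const double *X = x.begin(), *W = w.begin(), *B = b.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; n++) {
    for (int co = 0; co < Co; co++) {
      double *__restrict yp = Y + ((R_xlen_t)n * Co + co) * S;
      const double bias = B[co];
      for (R_xlen_t i = 0; i < S; i++) yp[i] = bias;
      for (int ci = 0; ci < Ci; ci++) {
        const double *xp = X + ((R_xlen_t)n * Ci + ci) * S;
        const double *wk = W + (R_xlen_t)K1 * K2 * K3 * (ci + (R_xlen_t)Ci * co);
        for (int i3 = 0; i3 < D3; i3++) {
          for (int i2 = 0; i2 < D2; i2++) {
            double *__restrict yr = yp + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3);
            for (int k3 = 0; k3 < K3; k3++) {
              const int j3 = i3 + k3 - H3;
              if (j3 < 0 || j3 >= D3) continue;
              for (int k2 = 0; k2 < K2; k2++) {
                const int j2 = i2 + k2 - H2;
                if (j2 < 0 || j2 >= D2) continue;
                const double *__restrict xrow = xp + (R_xlen_t)D1 * (j2 + (R_xlen_t)D2 * j3);
                const double *wrow = wk + K1 * (k2 + K2 * k3);
                if (K1 == 3) {
                  const double w0 = wrow[0], w1 = wrow[1], w2 = wrow[2];
                  yr[0] += w1 * xrow[0] + w2 * xrow[1];
                  for (int i1 = 1; i1 < D1 - 1; i1++)
                    yr[i1] += w0 * xrow[i1 - 1] + w1 * xrow[i1] + w2 * xrow[i1 + 1];
                  yr[D1 - 1] += w0 * xrow[D1 - 2] + w1 * xrow[D1 - 1];
                } else {
                  for (int k1 = 0; k1 < K1; k1++) {
                    const int d1 = k1 - H1;
                    const double wv = wrow[k1];
                    const int lo = std::max(0, -d1), hi = std::min(D1, D1 - d1);
                    const double *xr = xrow + d1;
                    for (int i1 = lo; i1 < hi; i1++) yr[i1] += wv * xr[i1];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(D1, D2, D3, Co, N);
  return y;
}

// Gradient wrt the input: forward couples y[i] <- w[k] x[i + d(k)], hence
// dx[j] = sum_k w[k] dy[j - d(k)].
// [[Rcpp::export]]
NumericVector conv3d_bwd_data_cpp(NumericVector dy, NumericVector w, int Ci) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int D1 = yd[0], D2 = yd[1], D3 = yd[2], Co = yd[3], N = yd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2];
  const int H1 = K1 / 2, H2 = K2 / 2, H3 = K3 / 2;
  const R_xlen_t S = (R_xlen_t)D1 * D2 * D3;
  NumericVector dx(S * Ci * N);
  const double *DY = dy.begin(), *W = w.begin();
  double *DX = dx.begin();
  for (int n = 0; n < N; n++) {
    for (int ci = 0; ci < Ci; ci++) {
      double *xp = DX + ((R_xlen_t)n * Ci + ci) * S;
      for (int co = 0; co < Co; co++) {
        const double *yp = DY + ((R_xlen_t)n * Co + co) * S;
        const double *wk = W + (R_xlen_t)K1 * K2 * K3 * (ci + (R_xlen_t)Ci * co);
        for (int j3 = 0; j3 < D3; j3++) {
          for (int j2 = 0; j2 < D2; j2++) {
            double *__restrict xr = xp + (R_xlen_t)D1 * (j2 + (R_xlen_t)D2 * j3);
            for (int k3 = 0; k3 < K3; k3++) {
              const int i3 = j3 - (k3 - H3);
              if (i3 < 0 || i3 >= D3) continue;
              for (int k2 = 0; k2 < K2; k2++) {
                const int i2 = j2 - (k2 - H2);
                if (i2 < 0 || i2 >= D2) continue;
                const double *__restrict yrow = yp + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3);
                const double *wrow = wk + K1 * (k2 + K2 * k3);
                if (K1 == 3) {
                  const double w0 = wrow[0], w1 = wrow[1], w2 = wrow[2];
                  xr[0] += w1 * yrow[0] + w0 * yrow[1];
                  for (int j1 = 1; j1 < D1 - 1; j1++)
                    xr[j1] += w2 * yrow[j1 - 1] + w1 * yrow[j1] + w0 * yrow[j1 + 1];
                  xr[D1 - 1] += w2 * yrow[D1 - 2] + w1 * yrow[D1 - 1];
                } else {
                  for (int k1 = 0; k1 < K1; k1++) {
                    const int d1 = k1 - H1;
                    const double wv = wrow[k1];
                    const int lo = std::max(0, d1), hi = std::min(D1, D1 + d1);
                    const double *yr = yrow - d1;
                    for (int j1 = lo; j1 < hi; j1++) xr[j1] += wv * yr[j1];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(D1, D2, D3, Ci, N);
  return dx;
}

// Gradients wrt kernel weights and biases:
// dw[k] = sum_i dy[i] x[i + d(k)], db = sum_i dy[i].
// [[Rcpp::export]]
List conv3d_bwd_wb_cpp(NumericVector x, NumericVector dy, IntegerVector kdim) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], Ci = xd[3], N = xd[4];
  const int Co = yd[3];
  const int K1 = kdim[0], K2 = kdim[1], K3 = kdim[2];
  const int H1 = K1 / 2, H2 = K2 / 2, H3 = K3 / 2;
  const int KK = K1 * K2 * K3;
  const R_xlen_t S = (R_xlen_t)D1 * D2 * D3;
  NumericVector dw((R_xlen_t)KK * Ci * Co), db(Co);
  const double *X = x.begin(), *DY = dy.begin();
  double *DW = dw.begin(), *DB = db.begin();
  std::vector<double> acc(KK);
  for (int n = 0; n < N; n++) {
    for (int co = 0; co < Co; co++) {
      const double *yp = DY + ((R_xlen_t)n * Co + co) * S;
      double bsum = 0.0;
      for (R_xlen_t i = 0; i < S; i++) bsum += yp[i];
      DB[co] += bsum;
      for (int ci = 0; ci < Ci; ci++) {
        const double *xp = X + ((R_xlen_t)n * Ci + ci) * S;
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int i3 = 0; i3 < D3; i3++) {
          for (int i2 = 0; i2 < D2; i2++) {
            const double *yr = yp + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3);
            for (int k3 = 0; k3 < K3; k3++) {
              const int j3 = i3 + k3 - H3;
              if (j3 < 0 || j3 >= D3) continue;
              for (int k2 = 0; k2 < K2; k2++) {
                const int j2 = i2 + k2 - H2;
                if (j2 < 0 || j2 >= D2) continue;
                const double *__restrict xrow = xp + (R_xlen_t)D1 * (j2 + (R_xlen_t)D2 * j3);
                if (K1 == 3) {
                  double a0 = 0.0, a1 = yr[0] * xrow[0], a2 = yr[0] * xrow[1];
                  for (int i1 = 1; i1 < D1 - 1; i1++) {
                    const double v = yr[i1];
                    a0 += v * xrow[i1 - 1];
                    a1 += v * xrow[i1];
                    a2 += v * xrow[i1 + 1];
                  }
                  a0 += yr[D1 - 1] * xrow[D1 - 2];
                  a1 += yr[D1 - 1] * xrow[D1 - 1];
                  const int base = K1 * (k2 + K2 * k3);
                  acc[base] += a0; acc[base + 1] += a1; acc[base + 2] += a2;
                } else {
                  for (int k1 = 0; k1 < K1; k1++) {
                    const int d1 = k1 - H1;
                    const int lo = std::max(0, -d1), hi = std::min(D1, D1 - d1);
                    const double *xr = xrow + d1;
                    double a = 0.0;
                    for (int i1 = lo; i1 < hi; i1++) a += yr[i1] * xr[i1];
                    acc[k1 + K1 * (k2 + K2 * k3)] += a;
                  }
                }
              }
            }
          }
        }
        double *dwp = DW + (R_xlen_t)KK * (ci + (R_xlen_t)Ci * co);
        for (int k = 0; k < KK; k++) dwp[k] += acc[k];
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(K1, K2, K3, Ci, Co);
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Elementwise max(x, 0), preserving dim.
// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double *X = x.begin();
  double *Y = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; i++) Y[i] = X[i] > 0.0 ? X[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// In-place variant for freshly allocated intermediates the caller owns.
// [[Rcpp::export]]
NumericVector relu_inplace_cpp(NumericVector x) {
  double *X = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; i++) if (X[i] < 0.0) X[i] = 0.0;
  return x;
}

// Fused max-pool + ReLU backward: scatter dy to the argmax positions, but
// only where the post-ReLU activation r is positive.
// [[Rcpp::export]]
NumericVector maxpool3d_bwd_relu_cpp(NumericVector dy, IntegerVector am,
                                     NumericVector r) {
  IntegerVector yd = dy.attr("dim"), rd = r.attr("dim");
  const int O1 = yd[0], O2 = yd[1], O3 = yd[2], C = yd[3], N = yd[4];
  const R_xlen_t S = (R_xlen_t)rd[0] * rd[1] * rd[2];
  const R_xlen_t SO = (R_xlen_t)O1 * O2 * O3;
  NumericVector dx(r.size());
  const double *DY = dy.begin(), *R_ = r.begin();
  const int *A = am.begin();
  double *DX = dx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; cn++) {
    const double *yp = DY + cn * SO;
    const int *ap = A + cn * SO;
    const double *rp = R_ + cn * S;
    double *xp = DX + cn * S;
    for (R_xlen_t i = 0; i < SO; i++)
      if (rp[ap[i]] > 0.0) xp[ap[i]] += yp[i];
  }
  dx.attr("dim") = r.attr("dim");
  return dx;
}

// dy * (z > 0), preserving dim.
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector z) {
  NumericVector out(dy.size());
  const double *DY = dy.begin(), *Z = z.begin();
  double *O = out.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; i++) O[i] = Z[i] > 0.0 ? DY[i] : 0.0;
  out.attr("dim") = dy.attr("dim");
  return out;
}

// Per-channel mean and (biased) variance over all samples and voxels.
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const R_xlen_t S = (R_xlen_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  NumericVector m(C), v(C);
  const double *X = x.begin();
  for (int c = 0; c < C; c++) {
    double s = 0.0, ss = 0.0;
    for (int n = 0; n < N; n++) {
      const double *p = X + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; i++) { s += p[i]; ss += p[i] * p[i]; }
    }
    const double mu = s / (S * (double)N);
    m[c] = mu;
    v[c] = ss / (S * (double)N) - mu * mu;
    if (v[c] < 0) v[c] = 0;
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// Per-channel affine y = scale[c] * x + shift[c].
// [[Rcpp::export]]
NumericVector bn_apply_cpp(NumericVector x, NumericVector scale,
                           NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  const R_xlen_t S = (R_xlen_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  NumericVector y(x.size());
  const double *X = x.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double sc = scale[c], sh = shift[c];
      const double *p = X + ((R_xlen_t)n * C + c) * S;
      double *__restrict q = Y + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; i++) q[i] = sc * p[i] + sh;
    }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Batch-norm backward from the raw input x and the batch statistics:
// xhat = (x - mean) * istd;  dx = gamma*istd*(dy - mean(dy) - xhat*mean(dy*xhat)).
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector x, NumericVector mean_,
                NumericVector istd, NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const R_xlen_t S = (R_xlen_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  const double M = S * (double)N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double *DY = dy.begin(), *X = x.begin();
  double *DX = dx.begin();
  for (int c = 0; c < C; c++) {
    const double mu = mean_[c], is = istd[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; n++) {
      const double *d = DY + ((R_xlen_t)n * C + c) * S;
      const double *p = X + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; i++) {
        sdy += d[i];
        sdyx += d[i] * (p[i] - mu) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double m1 = sdy / M, m2 = sdyx / M, g = gamma[c] * is;
    for (int n = 0; n < N; n++) {
      const double *d = DY + ((R_xlen_t)n * C + c) * S;
      const double *p = X + ((R_xlen_t)n * C + c) * S;
      double *__restrict o = DX + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; i++)
        o[i] = g * (d[i] - m1 - (p[i] - mu) * is * m2);
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Non-overlapping p^3 max pooling with floor division of the spatial dims;
// trailing voxels that do not fill a window are dropped. The argmax records,
// per pooled voxel, the 0-based linear index inside the (D1,D2,D3) volume of
// its sample/channel; ties resolve to the lowest linear index (strict >).
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, int p) {
  IntegerVector xd = x.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int O1 = D1 / p, O2 = D2 / p, O3 = D3 / p;
  const R_xlen_t S = (R_xlen_t)D1 * D2 * D3, SO = (R_xlen_t)O1 * O2 * O3;
  NumericVector y(SO * C * N);
  IntegerVector am(SO * C * N);
  const double *X = x.begin();
  double *Y = y.begin();
  int *A = am.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; cn++) {
    const double *xp = X + cn * S;
    double *yp = Y + cn * SO;
    int *ap = A + cn * SO;
    for (int o3 = 0; o3 < O3; o3++) {
      for (int o2 = 0; o2 < O2; o2++) {
        for (int o1 = 0; o1 < O1; o1++) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int d3 = 0; d3 < p; d3++) {
            const int i3 = o3 * p + d3;
            for (int d2 = 0; d2 < p; d2++) {
              const int i2 = o2 * p + d2;
              for (int d1 = 0; d1 < p; d1++) {
                const int i1 = o1 * p + d1;
                const R_xlen_t idx = i1 + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3);
                const double v = xp[idx];
                if (v > best) { best = v; bidx = idx; }
              }
            }
          }
          const R_xlen_t oidx = o1 + (R_xlen_t)O1 * (o2 + (R_xlen_t)O2 * o3);
          yp[oidx] = best;
          ap[oidx] = (int)bidx;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(O1, O2, O3, C, N);
  am.attr("dim") = IntegerVector::create(O1, O2, O3, C, N);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// Scatter pooled-level values back to the argmax positions (used both for the
// pooling gradient and for winner-take-all relevance routing).
// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dy, IntegerVector am, IntegerVector xdim) {
  IntegerVector yd = dy.attr("dim");
  const int O1 = yd[0], O2 = yd[1], O3 = yd[2], C = yd[3], N = yd[4];
  const int D1 = xdim[0], D2 = xdim[1], D3 = xdim[2];
  const R_xlen_t S = (R_xlen_t)D1 * D2 * D3, SO = (R_xlen_t)O1 * O2 * O3;
  NumericVector dx(S * C * N);
  const double *DY = dy.begin();
  const int *A = am.begin();
  double *DX = dx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; cn++) {
    const double *yp = DY + cn * SO;
    const int *ap = A + cn * SO;
    double *xp = DX + cn * S;
    for (R_xlen_t i = 0; i < SO; i++) xp[ap[i]] += yp[i];
  }
  dx.attr("dim") = IntegerVector::create(D1, D2, D3, C, N);
  return dx;
}

// Connected components of a 3D logical mask under face (6) or full (26)
// adjacency; labels are assigned in scan order starting at 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int D1 = dim[0], D2 = dim[1], D3 = dim[2];
  const R_xlen_t S = (R_xlen_t)D1 * D2 * D3;
  IntegerVector lab(S);
  const int *M = mask.begin();
  int *L = lab.begin();
  std::vector<std::array<int, 3> > nb;
  for (int d3 = -1; d3 <= 1; d3++)
    for (int d2 = -1; d2 <= 1; d2++)
      for (int d1 = -1; d1 <= 1; d1++) {
        if (d1 == 0 && d2 == 0 && d3 == 0) continue;
        const int manh = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({{d1, d2, d3}});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < S; s++) {
    if (!M[s] || L[s] != 0) continue;
    next++;
    L[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i1 = (int)(cur % D1);
      const int i2 = (int)((cur / D1) % D2);
      const int i3 = (int)(cur / ((R_xlen_t)D1 * D2));
      for (size_t k = 0; k < nb.size(); k++) {
        const int j1 = i1 + nb[k][0], j2 = i2 + nb[k][1], j3 = i3 + nb[k][2];
        if (j1 < 0 || j1 >= D1 || j2 < 0 || j2 >= D2 || j3 < 0 || j3 >= D3) continue;
        const R_xlen_t j = j1 + (R_xlen_t)D1 * (j2 + (R_xlen_t)D2 * j3);
        if (M[j] && L[j] == 0) { L[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(D1, D2, D3);
  return lab;
}
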