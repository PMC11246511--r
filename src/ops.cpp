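// Low-level array kernels: patch extraction for convolution (im2col and its
// adjoint col2im, 2D and 3D), exact Euclidean distance transforms, and
// volume resampling.  All arrays are column-major with channels last:
// 2D feature maps are (H, W, C), volumes are (X, Y, Z) or (X, Y, Z, C).
#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector x, int k, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2];
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  NumericMatrix out(Ho * Wo, k * k * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        double* po = &out(0, col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = px[hi + H * (wi + W * c)];
            po[ho + Ho * wo] = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix cols, int H, int W, int C,
                           int k, int stride, int pad) {
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  NumericVector x(H * W * C);
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        const double* po = &cols(0, col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            px[hi + H * (wi + W * c)] += po[ho + Ho * wo];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, int k, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = dm[3];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  NumericMatrix out(no_init((R_xlen_t)Xo * Yo * Zo, (R_xlen_t)k * k * k * C));
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* pc = px + (R_xlen_t)X * Y * Z * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t col = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * c));
          double* po = &out(0, col);
          // in-bounds xo range: 0 <= xo*stride - pad + kx <= X-1
          int xo_lo = 0, xo_hi = Xo - 1;
          {
            const int off = kx - pad;
            while (xo_lo < Xo && xo_lo * stride + off < 0) ++xo_lo;
            while (xo_hi >= 0 && xo_hi * stride + off > X - 1) --xo_hi;
          }
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + kz;
            const bool zok = zi >= 0 && zi < Z;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              const bool yok = yi >= 0 && yi < Y;
              double* prow = po + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
              if (!zok || !yok) {
                std::fill(prow, prow + Xo, 0.0);
                continue;
              }
              const double* pin = pc + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi);
              for (int xo = 0; xo < xo_lo; ++xo) prow[xo] = 0.0;
              if (xo_hi >= xo_lo) {
                if (stride == 1) {
                  std::memcpy(prow + xo_lo, pin + xo_lo + kx - pad,
                              (size_t)(xo_hi - xo_lo + 1) * sizeof(double));
                } else {
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    prow[xo] = pin[xo * stride - pad + kx];
                }
              }
              for (int xo = xo_hi + 1; xo < Xo; ++xo) prow[xo] = 0.0;
            }
          }
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im3d(NumericMatrix cols, int X, int Y, int Z, int C,
                           int k, int stride, int pad) {
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  NumericVector x((R_xlen_t)X * Y * Z * C);
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    double* pc = px + (R_xlen_t)X * Y * Z * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t col = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * c));
          const double* po = &cols(0, col);
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + kz;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              if (yi < 0 || yi >= Y) continue;
              const double* prow = po + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
              double* pin = pc + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi);
              for (int xo = 0; xo < Xo; ++xo) {
                const int xi = xo * stride - pad + kx;
                if (xi >= 0 && xi < X) pin[xi] += prow[xo];
              }
            }
          }
        }
  }
  x.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return x;
}

// ---- fused 3D convolution (im2col into a reusable workspace + BLAS) -------

static void im2col3d_buf(const double* px, int X, int Y, int Z, int C,
                         int k, int stride, int pad, double* out,
                         int Xo, int Yo, int Zo) {
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    const double* pc = px + (R_xlen_t)X * Y * Z * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t col = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * c));
          double* po = out + N * col;
          int xo_lo = 0, xo_hi = Xo - 1;
          const int off = kx - pad;
          while (xo_lo < Xo && xo_lo * stride + off < 0) ++xo_lo;
          while (xo_hi >= 0 && xo_hi * stride + off > X - 1) --xo_hi;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + kz;
            const bool zok = zi >= 0 && zi < Z;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              const bool yok = yi >= 0 && yi < Y;
              double* prow = po + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
              if (!zok || !yok) {
                std::fill(prow, prow + Xo, 0.0);
                continue;
              }
              const double* pin = pc + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi);
              for (int xo = 0; xo < xo_lo; ++xo) prow[xo] = 0.0;
              if (xo_hi >= xo_lo) {
                if (stride == 1)
                  std::memcpy(prow + xo_lo, pin + xo_lo + off,
                              (size_t)(xo_hi - xo_lo + 1) * sizeof(double));
                else
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    prow[xo] = pin[xo * stride + off];
              }
              for (int xo = xo_hi + 1; xo < Xo; ++xo) prow[xo] = 0.0;
            }
          }
        }
  }
}

static void col2im3d_buf(const double* cols, int X, int Y, int Z, int C,
                         int k, int stride, int pad, double* px,
                         int Xo, int Yo, int Zo) {
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    double* pc = px + (R_xlen_t)X * Y * Z * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t col = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * c));
          const double* po = cols + N * col;
          int xo_lo = 0, xo_hi = Xo - 1;
          const int off = kx - pad;
          while (xo_lo < Xo && xo_lo * stride + off < 0) ++xo_lo;
          while (xo_hi >= 0 && xo_hi * stride + off > X - 1) --xo_hi;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + kz;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              if (yi < 0 || yi >= Y) continue;
              const double* prow = po + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
              double* pin = pc + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi);
              if (stride == 1) {
                double* pdst = pin + off;
                for (int xo = xo_lo; xo <= xo_hi; ++xo) pdst[xo] += prow[xo];
              } else {
                for (int xo = xo_lo; xo <= xo_hi; ++xo)
                  pin[xo * stride + off] += prow[xo];
              }
            }
          }
        }
  }
}

static std::vector<double> conv_ws1, conv_ws2;

static void gemm(char ta, char tb, int m, int n, int kk, double alpha,
                 const double* a, int lda, const double* b, int ldb,
                 double beta, double* c, int ldc) {
#ifdef FCONE
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, a, &lda, b, &ldb, &beta,
                  c, &ldc FCONE FCONE);
#else
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, a, &lda, b, &ldb, &beta,
                  c, &ldc);
#endif
}

// y = conv3d(x, W) + b; x (X,Y,Z,Cin), W (k,k,k,Cin,Cout), returns
// (Xo,Yo,Zo,Cout).
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector W,
                             NumericVector b, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = dm[3];
  const int k = wd[0], Cout = wd[4];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  const R_xlen_t K = (R_xlen_t)k * k * k * C;
  if ((R_xlen_t)conv_ws1.size() < N * K) conv_ws1.resize(N * K);
  im2col3d_buf(x.begin(), X, Y, Z, C, k, stride, pad, conv_ws1.data(),
               Xo, Yo, Zo);
  NumericVector y(no_init(N * Cout));
  double* py = y.begin();
  for (int m = 0; m < Cout; ++m) std::fill(py + N * m, py + N * (m + 1), b[m]);
  gemm('N', 'N', (int)N, Cout, (int)K, 1.0, conv_ws1.data(), (int)N,
       W.begin(), (int)K, 1.0, py, (int)N);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return y;
}

// Backward of the fused convolution: given x, W and dy, returns
// list(dx, dW, db).
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector W, NumericVector dy,
                    int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = dm[3];
  const int k = wd[0], Cout = wd[4];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  const R_xlen_t K = (R_xlen_t)k * k * k * C;
  if ((R_xlen_t)conv_ws1.size() < N * K) conv_ws1.resize(N * K);
  if ((R_xlen_t)conv_ws2.size() < N * K) conv_ws2.resize(N * K);
  im2col3d_buf(x.begin(), X, Y, Z, C, k, stride, pad, conv_ws1.data(),
               Xo, Yo, Zo);
  NumericVector dW(no_init(K * Cout));
  gemm('T', 'N', (int)K, Cout, (int)N, 1.0, conv_ws1.data(), (int)N,
       dy.begin(), (int)N, 0.0, dW.begin(), (int)K);
  dW.attr("dim") = wd;
  NumericVector db(Cout);
  const double* pdy = dy.begin();
  for (int m = 0; m < Cout; ++m) {
    double s = 0.0;
    const double* col = pdy + N * m;
    for (R_xlen_t i = 0; i < N; ++i) s += col[i];
    db[m] = s;
  }
  gemm('N', 'T', (int)N, (int)K, Cout, 1.0, pdy, (int)N, W.begin(), (int)K,
       0.0, conv_ws2.data(), (int)N);
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  col2im3d_buf(conv_ws2.data(), X, Y, Z, C, k, stride, pad, dx.begin(),
               Xo, Yo, Zo);
  dx.attr("dim") = dm;
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = db);
}

static const double DT_INF = 1e30;

// 1D lower-envelope-of-parabolas squared distance transform; samples sit at
// physical positions i * step.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double step) {
  int kk = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step, s;
    for (;;) {
      double xv = v[kk] * step;
      s = ((f[q] + xq * xq) - (f[v[kk]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[kk] && kk > 0) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = DT_INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[kk + 1] < xq) ++kk;
    double dx = xq - v[kk] * step;
    d[q] = dx * dx + f[v[kk]];
  }
}

// Exact Euclidean distance (in physical units given per-axis spacing) from
// every voxel to the nearest nonzero voxel of `feature`.  All-zero input
// yields Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector feature, NumericVector spacing) {
  IntegerVector dm = feature.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : DT_INF;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 0 (X)
  for (int zz = 0; zz < Z; ++zz)
    for (int yy = 0; yy < Y; ++yy) {
      double* line = &g[(R_xlen_t)X * (yy + (R_xlen_t)Y * zz)];
      for (int i = 0; i < X; ++i) f[i] = line[i];
      dt1d(f, d, v, z, X, spacing[0]);
      for (int i = 0; i < X; ++i) line[i] = d[i];
    }
  // axis 1 (Y)
  for (int zz = 0; zz < Z; ++zz)
    for (int xx = 0; xx < X; ++xx) {
      for (int i = 0; i < Y; ++i) f[i] = g[xx + (R_xlen_t)X * (i + (R_xlen_t)Y * zz)];
      dt1d(f, d, v, z, Y, spacing[1]);
      for (int i = 0; i < Y; ++i) g[xx + (R_xlen_t)X * (i + (R_xlen_t)Y * zz)] = d[i];
    }
  // axis 2 (Z)
  for (int yy = 0; yy < Y; ++yy)
    for (int xx = 0; xx < X; ++xx) {
      for (int i = 0; i < Z; ++i) f[i] = g[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y * i)];
      dt1d(f, d, v, z, Z, spacing[2]);
      for (int i = 0; i < Z; ++i) g[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y * i)] = d[i];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = g[i] >= DT_INF ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dm;
  return out;
}

// Resample a 3D volume onto a new grid.  Output voxel i maps to input
// coordinate i * ratio (0-based), ratio = new_spacing / old_spacing per axis.
// linear = trilinear interpolation (intensities); otherwise nearest neighbour
// (label volumes).  Out-of-range coordinates clamp to the border.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dims_out,
                             NumericVector ratio, bool linear) {
  IntegerVector dm = vol.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  const int Xo = dims_out[0], Yo = dims_out[1], Zo = dims_out[2];
  NumericVector out((R_xlen_t)Xo * Yo * Zo);
  const double* pv = vol.begin();
  auto at = [&](int x, int y, int z) {
    return pv[x + (R_xlen_t)X * (y + (R_xlen_t)Y * z)];
  };
  for (int zo = 0; zo < Zo; ++zo) {
    double cz = zo * ratio[2];
    for (int yo = 0; yo < Yo; ++yo) {
      double cy = yo * ratio[1];
      for (int xo = 0; xo < Xo; ++xo) {
        double cx = xo * ratio[0];
        double val;
        if (linear) {
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
          x0 = std::max(0, std::min(x0, X - 1));
          y0 = std::max(0, std::min(y0, Y - 1));
          z0 = std::max(0, std::min(z0, Z - 1));
          val =
            (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
            fx * (1 - fy) * (1 - fz) * at(x1, y0, z0) +
            (1 - fx) * fy * (1 - fz) * at(x0, y1, z0) +
            fx * fy * (1 - fz) * at(x1, y1, z0) +
            (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
            fx * (1 - fy) * fz * at(x1, y0, z1) +
            (1 - fx) * fy * fz * at(x0, y1, z1) +
            fx * fy * fz * at(x1, y1, z1);
        } else {
          int xn = std::max(0, std::min((int)std::lround(cx), X - 1));
          int yn = std::max(0, std::min((int)std::lround(cy), Y - 1));
          int zn = std::max(0, std::min((int)std::lround(cz), Z - 1));
          val = at(xn, yn, zn);
        }
        out[xo + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo)] = val;
      }
    }
  }
  out.attr("dim") = dims_out;
  return out;
}
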