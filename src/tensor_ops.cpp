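// Low-level numeric kernels for 2D convolutional layers and volume geometry.
// Tensor layout throughout: column-major R arrays (H, W, C, N).
// Convolution weights: (K, K, Cin, Cout); stride 1, same (zero) padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline NumericVector alloc3(int a, int b, int c) {
  NumericVector v((size_t)a * b * c);
  v.attr("dim") = IntegerVector::create(a, b, c);
  return v;
}

// Implicit-GEMM convolution: each sample is copied once into a
// zero-padded per-channel buffer; the K*K kernel taps become K*K
// accumulated GEMMs on constant-offset views of that buffer (no im2col
// data duplication, operands stay cache-resident). Pad rows of the
// padded output frame are computed and discarded. GEMMs run in single
// precision (inputs are unit-scale image features; weight updates are
// re-accumulated in double).

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_fwd: input has %d channels, weights expect %d", C, Cin);
  const int p = (K - 1) / 2;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t PP = (size_t)Hp * Wp, S = p + (size_t)p * Hp, B = PP + 2 * S;
  const size_t hw = (size_t)H * W;
  arma::fvec xpbuf(B * C + 2 * S + 1, arma::fill::zeros);
  arma::fmat yp(B, Cout);
  arma::fmat wk(C, Cout);
  NumericVector y = alloc4(H, W, Cout, N);
  const double* wp_ = w.begin();
  for (int n = 0; n < N; ++n) {
    // pack sample into padded channel buffers
    xpbuf.zeros();
    const double* xn = x.begin() + (size_t)n * hw * C;
    for (int c = 0; c < C; ++c) {
      float* dst = xpbuf.memptr() + (size_t)c * B + S;
      for (int j = 0; j < W; ++j) {
        const double* sj = xn + (size_t)c * hw + (size_t)j * H;
        float* dj = dst + (p + (size_t)(j + p) * Hp);
        for (int i = 0; i < H; ++i) dj[i] = (float)sj[i];
      }
    }
    yp.zeros();
    for (int kj = 0; kj < K; ++kj)
      for (int ki = 0; ki < K; ++ki) {
        const long s = (ki - p) + (long)(kj - p) * Hp;
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co)
            wk(c, co) = (float)wp_[ki + (size_t)K * kj + (size_t)K * K * c +
                                   (size_t)K * K * Cin * co];
        arma::fmat A(xpbuf.memptr() + (long)S + s, B, C, false, true);
        yp += A * wk;
      }
    double* yn = y.begin() + (size_t)n * hw * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float* src = yp.colptr(co);
      const double bc = b[co];
      for (int j = 0; j < W; ++j) {
        const float* sj = src + p + (size_t)(j + p) * Hp;
        double* dj = yn + (size_t)co * hw + (size_t)j * H;
        for (int i = 0; i < H; ++i) dj[i] = (double)sj[i] + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int p = (K - 1) / 2;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t PP = (size_t)Hp * Wp, S = p + (size_t)p * Hp, B = PP + 2 * S;
  const size_t hw = (size_t)H * W;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(K, K, C, Cout);
  NumericVector db(Cout);
  arma::fvec xpbuf(B * C + 2 * S + 1, arma::fill::zeros);
  arma::fvec dypbuf(B * Cout + 2 * S + 1, arma::fill::zeros);
  arma::fvec dxpbuf(B * C + 2 * S + 1, arma::fill::zeros);
  arma::fmat dwk(C, Cout);
  arma::fmat wk(C, Cout);
  for (int n = 0; n < N; ++n) {
    xpbuf.zeros(); dypbuf.zeros(); dxpbuf.zeros();
    const double* xn = x.begin() + (size_t)n * hw * C;
    for (int c = 0; c < C; ++c) {
      float* dst = xpbuf.memptr() + (size_t)c * B + S;
      for (int j = 0; j < W; ++j) {
        const double* sj = xn + (size_t)c * hw + (size_t)j * H;
        float* dj = dst + (p + (size_t)(j + p) * Hp);
        for (int i = 0; i < H; ++i) dj[i] = (float)sj[i];
      }
    }
    const double* dyn = dy.begin() + (size_t)n * hw * Cout;
    for (int co = 0; co < Cout; ++co) {
      float* dst = dypbuf.memptr() + (size_t)co * B + S;
      double acc = 0.0;
      for (int j = 0; j < W; ++j) {
        const double* sj = dyn + (size_t)co * hw + (size_t)j * H;
        float* dj = dst + (p + (size_t)(j + p) * Hp);
        for (int i = 0; i < H; ++i) { dj[i] = (float)sj[i]; acc += sj[i]; }
      }
      db[co] += acc;
    }
    arma::fmat DY(dypbuf.memptr() + S, B, Cout, false, true);
    for (int kj = 0; kj < K; ++kj)
      for (int ki = 0; ki < K; ++ki) {
        const long s = (ki - p) + (long)(kj - p) * Hp;
        arma::fmat A(xpbuf.memptr() + (long)S + s, B, C, false, true);
        dwk = A.t() * DY;
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co)
            dw[ki + (size_t)K * kj + (size_t)K * K * c +
               (size_t)K * K * C * co] += (double)dwk(c, co);
        // accumulate input gradient into the shifted view
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co)
            wk(c, co) = (float)w[ki + (size_t)K * kj + (size_t)K * K * c +
                                 (size_t)K * K * C * co];
        arma::fmat dA(dxpbuf.memptr() + (long)S + s, B, C, false, true);
        dA += DY * wk.t();
      }
    double* dxn = dx.begin() + (size_t)n * hw * C;
    for (int c = 0; c < C; ++c) {
      const float* src = dxpbuf.memptr() + (size_t)c * B + S;
      for (int j = 0; j < W; ++j) {
        const float* sj = src + p + (size_t)(j + p) * Hp;
        double* dj = dxn + (size_t)c * hw + (size_t)j * H;
        for (int i = 0; i < H; ++i) dj[i] = (double)sj[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even (callers pad).
// Indices stored as 0..3 = (di + 2*dj) offset inside the window.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2_fwd: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xs = xp + p * H * W;
    double* ys = yp + p * Ho * Wo;
    int* is = ip + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bidx = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = xs[(2 * i + di) + (size_t)(2 * j + dj) * H];
            if (v > best) { best = v; bidx = di + 2 * dj; }
          }
        }
        ys[i + (size_t)j * Ho] = best;
        is[i + (size_t)j * Ho] = bidx;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxunpool2(NumericVector y, IntegerVector idx, int H, int W) {
  IntegerVector yd = y.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector x = alloc4(H, W, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* ys = y.begin() + p * Ho * Wo;
    const int* is = idx.begin() + p * Ho * Wo;
    double* xs = x.begin() + p * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int b = is[i + (size_t)j * Ho];
        xs[(2 * i + b % 2) + (size_t)(2 * j + b / 2) * H] = ys[i + (size_t)j * Ho];
      }
  }
  return x;
}

// gradient of maxunpool2: gather dy at the recorded positions
// [[Rcpp::export]]
NumericVector maxunpool2_bwd(NumericVector dyfull, IntegerVector idx) {
  IntegerVector dd = idx.attr("dim"), fd = dyfull.attr("dim");
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  const int H = fd[0];
  NumericVector g = alloc4(Ho, Wo, C, N);
  const size_t planes = (size_t)C * N;
  const size_t fullplane = (size_t)fd[0] * fd[1];
  for (size_t p = 0; p < planes; ++p) {
    const double* ds = dyfull.begin() + p * fullplane;
    const int* is = idx.begin() + p * Ho * Wo;
    double* gs = g.begin() + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int b = is[i + (size_t)j * Ho];
        gs[i + (size_t)j * Ho] = ds[(2 * i + b % 2) + (size_t)(2 * j + b / 2) * H];
      }
  }
  return g;
}

// 2x2 average pooling with ceil semantics; partial windows average valid pixels.
// [[Rcpp::export]]
NumericVector avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xs = x.begin() + p * H * W;
    double* ys = y.begin() + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double s = 0; int cnt = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            if (ii < H && jj < W) { s += xs[ii + (size_t)jj * H]; ++cnt; }
          }
        ys[i + (size_t)j * Ho] = s / cnt;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd(NumericVector dy, int H, int W) {
  IntegerVector dd = dy.attr("dim");
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  NumericVector dx = alloc4(H, W, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* ds = dy.begin() + p * Ho * Wo;
    double* xs = dx.begin() + p * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int cnt = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            if (2 * i + di < H && 2 * j + dj < W) ++cnt;
        const double v = ds[i + (size_t)j * Ho] / cnt;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            if (ii < H && jj < W) xs[ii + (size_t)jj * H] += v;
          }
      }
  }
  return dx;
}

// nearest-neighbour 2x upsampling, cropped to (H, W)
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x, int H, int W) {
  IntegerVector xd = x.attr("dim");
  const int Hi = xd[0], Wi = xd[1], C = xd[2], N = xd[3];
  NumericVector y = alloc4(H, W, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xs = x.begin() + p * Hi * Wi;
    double* ys = y.begin() + p * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        ys[i + (size_t)j * H] = xs[(i / 2) + (size_t)(j / 2) * Hi];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy, int Hi, int Wi) {
  IntegerVector dd = dy.attr("dim");
  const int H = dd[0], W = dd[1], C = dd[2], N = dd[3];
  NumericVector dx = alloc4(Hi, Wi, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* ds = dy.begin() + p * H * W;
    double* xs = dx.begin() + p * Hi * Wi;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        xs[(i / 2) + (size_t)(j / 2) * Hi] += ds[i + (size_t)j * H];
  }
  return dx;
}

// Resample a 3D volume: for each output voxel index v (0-based), the input
// continuous voxel index is M %*% c(v, 1); trilinear or nearest interpolation,
// zero outside the input grid.
// [[Rcpp::export]]
NumericVector sample_volume(NumericVector vol, NumericMatrix M,
                            IntegerVector out_dim, std::string method) {
  IntegerVector vd = vol.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector out = alloc3(Xo, Yo, Zo);
  const bool nearest = (method == "nearest");
  const double* v = vol.begin();
  double* o = out.begin();
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i) {
        const double xs = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + M(0, 3);
        const double ys = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + M(1, 3);
        const double zs = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + M(2, 3);
        double val = 0.0;
        if (nearest) {
          const int xi = (int)std::lround(xs), yi = (int)std::lround(ys),
                    zi = (int)std::lround(zs);
          if (xi >= 0 && xi < X && yi >= 0 && yi < Y && zi >= 0 && zi < Z)
            val = v[xi + (size_t)yi * X + (size_t)zi * X * Y];
        } else {
          const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys),
                    z0 = (int)std::floor(zs);
          const double fx = xs - x0, fy = ys - y0, fz = zs - z0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                const int xi = x0 + dxx, yi = y0 + dyy, zi = z0 + dz;
                if (xi < 0 || xi >= X || yi < 0 || yi >= Y || zi < 0 || zi >= Z)
                  continue;
                const double wgt = (dxx ? fx : 1 - fx) * (dyy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                val += wgt * v[xi + (size_t)yi * X + (size_t)zi * X * Y];
              }
        }
        o[i + (size_t)j * Xo + (size_t)k * Xo * Yo] = val;
      }
  return out;
}

// For each point (row) of A, squared... no: Euclidean distance to nearest row of B.
// Points are n x 3 matrices in mm.
// [[Rcpp::export]]
NumericVector nearest_distances(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector d(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    d[i] = std::sqrt(best);
  }
  return d;
}

// ---- fused batch-norm / PReLU kernels (single pass per array) ----------

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mu(C), var(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * hw;
      double s = 0, ss = 0;
      for (size_t i = 0; i < hw; ++i) { s += xs[i]; ss += xs[i] * xs[i]; }
      mu[c] += s; var[c] += ss;
    }
  const double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = std::max(var[c] / m - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = x * a[ch] + b[ch]
// [[Rcpp::export]]
NumericVector scale_shift(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y = alloc4(xd[0], xd[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * hw;
      double* ys = y.begin() + ((size_t)n * C + c) * hw;
      const double ac = a[c], bc = b[c];
      for (size_t i = 0; i < hw; ++i) ys[i] = xs[i] * ac + bc;
    }
  return y;
}

// batch-norm backward from cached x, mu, istd; returns dx, dgamma, dbeta
// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector dy, NumericVector mu,
            NumericVector istd, NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx = alloc4(xd[0], xd[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * hw;
      const double* ds = dy.begin() + ((size_t)n * C + c) * hw;
      double s1 = 0, s2 = 0;
      const double mc = mu[c], ic = istd[c];
      for (size_t i = 0; i < hw; ++i) {
        s1 += ds[i];
        s2 += ds[i] * (xs[i] - mc) * ic;
      }
      dbeta[c] += s1; dgamma[c] += s2;
    }
  const double m = (double)hw * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * hw;
      const double* ds = dy.begin() + ((size_t)n * C + c) * hw;
      double* os = dx.begin() + ((size_t)n * C + c) * hw;
      const double gi = gamma[c] * istd[c];
      const double mb = dbeta[c] / m, mg = dgamma[c] / m;
      const double mc = mu[c], ic = istd[c];
      for (size_t i = 0; i < hw; ++i)
        os[i] = gi * (ds[i] - mb - (xs[i] - mc) * ic * mg);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector prelu_fwd_c(NumericVector x, NumericVector a) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y = alloc4(xd[0], xd[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * hw;
      double* ys = y.begin() + ((size_t)n * C + c) * hw;
      const double ac = a[c];
      for (size_t i = 0; i < hw; ++i)
        ys[i] = xs[i] > 0 ? xs[i] : ac * xs[i];
    }
  return y;
}

// [[Rcpp::export]]
List prelu_bwd_c(NumericVector x, NumericVector dy, NumericVector a) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector da(C);
  NumericVector dx = alloc4(xd[0], xd[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * hw;
      const double* ds = dy.begin() + ((size_t)n * C + c) * hw;
      double* os = dx.begin() + ((size_t)n * C + c) * hw;
      const double ac = a[c];
      double acc = 0;
      for (size_t i = 0; i < hw; ++i) {
        if (xs[i] > 0) os[i] = ds[i];
        else { os[i] = ac * ds[i]; acc += ds[i] * xs[i]; }
      }
      da[c] += acc;
    }
  return List::create(_["dx"] = dx, _["da"] = da);
}
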