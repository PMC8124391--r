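#include <Rcpp.h>
using namespace Rcpp;

// Activation arrays use dim (H, W, B, C), column-major. im2col rows are
// ordered h + H*w + H*W*b so that GEMM output reshapes to (H, W, B, F).

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int B, int C) {
  const int N = H * W * B;
  NumericMatrix out(N, 9 * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double *plane = px + (size_t)H * W * (b + (size_t)B * c);
      for (int kw = 0; kw < 3; ++kw) {
        for (int kh = 0; kh < 3; ++kh) {
          const int col = kh + 3 * kw + 9 * c;
          double *pout = &out(0, col);
          for (int w = 0; w < W; ++w) {
            const int sw = w + kw - 1;
            if (sw < 0 || sw >= W) continue;
            const double *src = plane + (size_t)H * sw;
            double *dst = pout + (size_t)H * w + (size_t)H * W * b;
            const int h0 = (kh == 0) ? 1 : 0;
            const int h1 = (kh == 2) ? H - 1 : H;
            for (int h = h0; h < h1; ++h) dst[h] = src[h + kh - 1];
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3_cpp: accumulate column gradients back onto the image grid
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix dcol, int H, int W, int B, int C) {
  NumericVector dx((size_t)H * W * B * C);
  double *pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      double *plane = pdx + (size_t)H * W * (b + (size_t)B * c);
      for (int kw = 0; kw < 3; ++kw) {
        for (int kh = 0; kh < 3; ++kh) {
          const int col = kh + 3 * kw + 9 * c;
          const double *pin = &dcol(0, col);
          for (int w = 0; w < W; ++w) {
            const int sw = w + kw - 1;
            if (sw < 0 || sw >= W) continue;
            double *dst = plane + (size_t)H * sw;
            const double *src = pin + (size_t)H * w + (size_t)H * W * b;
            const int h0 = (kh == 0) ? 1 : 0;
            const int h1 = (kh == 2) ? H - 1 : H;
            for (int h = h0; h < h1; ++h) dst[h + kh - 1] += src[h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// 2x2 max pooling on (H, W, B, C) arrays; returns pooled values and 1-based
// argmax indices into x
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * B * C);
  IntegerVector idx((size_t)Ho * Wo * B * C);
  const double *px = x.begin();
  size_t n = 0;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b) {
      const size_t off = (size_t)H * W * (b + (size_t)B * c);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = off + (size_t)H * (2 * w) + 2 * h;
          size_t best = i00;
          double v = px[i00];
          size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (px[cand[k]] > v) { v = px[cand[k]]; best = cand[k]; }
          out[n] = v;
          idx[n] = (int)(best + 1);
          ++n;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Transposed 3x3 stride-2 convolution (upsampling), direct form:
// out[2i+kh-1, 2j+kw-1, b, co] += x[i, j, b, ci] * K[kh + 3 kw + 9 ci, co],
// output size (2H, 2W). Equivalent to zero-interleaving followed by a padded
// 3x3 convolution, without materializing the zeros.
// [[Rcpp::export]]
NumericVector convt3_fw_cpp(NumericVector x, NumericMatrix K,
                            int H, int W, int B, int Cin) {
  const int Cout = K.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * B * Cout);
  const double *px = x.begin();
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      const double *kc = &K(9 * ci, co);
      for (int b = 0; b < B; ++b) {
        const double *xp = px + (size_t)H * W * (b + (size_t)B * ci);
        double *op = po + (size_t)Ho * Wo * (b + (size_t)B * co);
        for (int j = 0; j < W; ++j)
          for (int kw = 0; kw < 3; ++kw) {
            const int ow = 2 * j + kw - 1;
            if (ow < 0 || ow >= Wo) continue;
            double *ocol = op + (size_t)Ho * ow;
            const double *xcol = xp + (size_t)H * j;
            for (int kh = 0; kh < 3; ++kh) {
              const double kv = kc[kh + 3 * kw];
              if (kv == 0.0) continue;
              for (int i = 0; i < H; ++i) {
                const int oh = 2 * i + kh - 1;
                if (oh < 0 || oh >= Ho) continue;
                ocol[oh] += kv * xcol[i];
              }
            }
          }
      }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, Cout);
  return out;
}

// gradient of convt3 w.r.t. its input
// [[Rcpp::export]]
NumericVector convt3_bwx_cpp(NumericVector dy, NumericMatrix K,
                             int H, int W, int B, int Cin) {
  const int Cout = K.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * B * Cin);
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      const double *kc = &K(9 * ci, co);
      for (int b = 0; b < B; ++b) {
        double *xp = pdx + (size_t)H * W * (b + (size_t)B * ci);
        const double *op = pdy + (size_t)Ho * Wo * (b + (size_t)B * co);
        for (int j = 0; j < W; ++j)
          for (int kw = 0; kw < 3; ++kw) {
            const int ow = 2 * j + kw - 1;
            if (ow < 0 || ow >= Wo) continue;
            const double *ocol = op + (size_t)Ho * ow;
            double *xcol = xp + (size_t)H * j;
            for (int kh = 0; kh < 3; ++kh) {
              const double kv = kc[kh + 3 * kw];
              if (kv == 0.0) continue;
              for (int i = 0; i < H; ++i) {
                const int oh = 2 * i + kh - 1;
                if (oh < 0 || oh >= Ho) continue;
                xcol[i] += kv * ocol[oh];
              }
            }
          }
      }
    }
  dx.attr("dim") = IntegerVector::create(H, W, B, Cin);
  return dx;
}

// gradient of convt3 w.r.t. its kernel
// [[Rcpp::export]]
NumericMatrix convt3_bww_cpp(NumericVector x, NumericVector dy,
                             int H, int W, int B, int Cin, int Cout) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix dK(9 * Cin, Cout);
  const double *px = x.begin();
  const double *pdy = dy.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      double *kc = &dK(9 * ci, co);
      for (int b = 0; b < B; ++b) {
        const double *xp = px + (size_t)H * W * (b + (size_t)B * ci);
        const double *op = pdy + (size_t)Ho * Wo * (b + (size_t)B * co);
        for (int j = 0; j < W; ++j)
          for (int kw = 0; kw < 3; ++kw) {
            const int ow = 2 * j + kw - 1;
            if (ow < 0 || ow >= Wo) continue;
            const double *ocol = op + (size_t)Ho * ow;
            const double *xcol = xp + (size_t)H * j;
            for (int kh = 0; kh < 3; ++kh) {
              double acc = 0.0;
              for (int i = 0; i < H; ++i) {
                const int oh = 2 * i + kh - 1;
                if (oh < 0 || oh >= Ho) continue;
                acc += xcol[i] * ocol[oh];
              }
              kc[kh + 3 * kw] += acc;
            }
          }
      }
    }
  return dK;
}

// Normalized correlation of a template against every valid placement in an
// image. zero_mean = false gives the plain normalized form
// R = sum(T*I) / sqrt(sum(T^2) * sum(I^2)); zero_mean = true subtracts the
// local means first (zero-normalized cross-correlation).
// [[Rcpp::export]]
NumericMatrix ncc_match_cpp(NumericMatrix img, NumericMatrix tpl,
                            bool zero_mean) {
  const int H = img.nrow(), W = img.ncol();
  const int th = tpl.nrow(), tw = tpl.ncol();
  const int Ho = H - th + 1, Wo = W - tw + 1;
  NumericMatrix R(Ho, Wo);
  const double npx = (double)th * tw;
  double tsum = 0.0, tsum2 = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) { tsum += tpl(i, j); tsum2 += tpl(i, j) * tpl(i, j); }
  const double tmean = tsum / npx;
  const double tvar = zero_mean ? (tsum2 - tsum * tsum / npx) : tsum2;
  for (int x = 0; x < Wo; ++x) {
    for (int y = 0; y < Ho; ++y) {
      double s = 0.0, si = 0.0, si2 = 0.0;
      for (int j = 0; j < tw; ++j) {
        const double *pi = &img(y, x + j);
        const double *pt = &tpl(0, j);
        for (int i = 0; i < th; ++i) {
          s += pt[i] * pi[i];
          si += pi[i];
          si2 += pi[i] * pi[i];
        }
      }
      double num, den;
      if (zero_mean) {
        num = s - tmean * si;
        den = tvar * (si2 - si * si / npx);
      } else {
        num = s;
        den = tvar * si2;
      }
      R(y, x) = den > 0 ? num / std::sqrt(den) : 0.0;
    }
  }
  return R;
}

// Zero-normalized correlation between a reference frame and a moving frame
// over integer shifts (cy + dy, cx + dx) with (dy, dx) in [-radius, radius]^2,
// computed on the overlap region. Entry (dy + radius + 1, dx + radius + 1)
// scores the hypothesis that the moving frame content sits at
// +(cx + dx, cy + dy) relative to the reference.
// [[Rcpp::export]]
NumericMatrix ncc_shift_cpp(NumericMatrix ref, NumericMatrix mov, int radius,
                            int cx = 0, int cy = 0) {
  const int H = ref.nrow(), W = ref.ncol();
  const int n = 2 * radius + 1;
  NumericMatrix R(n, n);
  for (int ox = -radius; ox <= radius; ++ox) {
    for (int oy = -radius; oy <= radius; ++oy) {
      const int dx = cx + ox, dy = cy + oy;
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      if (y1 <= y0 || x1 <= x0) { R(oy + radius, ox + radius) = 0.0; continue; }
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      const double npx = (double)(y1 - y0) * (x1 - x0);
      for (int x = x0; x < x1; ++x) {
        const double *pa = &ref(y0, x);
        const double *pb = &mov(y0 + dy, x + dx);
        for (int y = 0; y < y1 - y0; ++y) {
          const double a = pa[y], b = pb[y];
          sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
        }
      }
      const double num = sab - sa * sb / npx;
      const double den = (saa - sa * sa / npx) * (sbb - sb * sb / npx);
      R(oy + radius, ox + radius) = den > 0 ? num / std::sqrt(den) : 0.0;
    }
  }
  return R;
}

static inline int at(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j);
}

// Zhang-Suen thinning to a one-pixel-wide skeleton
// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  IntegerMatrix img = clone(mask);
  const int H = img.nrow(), W = img.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!img(i, j)) continue;
          // neighbours p2..p9 clockwise from north
          int p[8] = {at(img, i - 1, j),     at(img, i - 1, j + 1),
                      at(img, i, j + 1),     at(img, i + 1, j + 1),
                      at(img, i + 1, j),     at(img, i + 1, j - 1),
                      at(img, i, j - 1),     at(img, i - 1, j - 1)};
          int bsum = 0, a = 0;
          for (int k = 0; k < 8; ++k) {
            bsum += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          }
          if (bsum < 2 || bsum > 6 || a != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = 0;
    }
  }
  return img;
}

// Remove redundant staircase pixels from a thinned skeleton: a non-endpoint
// pixel is deleted when its foreground neighbours already form a single
// 8-connected cluster without it, so deletion preserves connectivity. The
// result is minimally 8-thin, which makes the neighbour-count junction rule
// (3 = bifurcation, >3 = crossover) exact.
// [[Rcpp::export]]
IntegerMatrix minthin_cpp(IntegerMatrix skel) {
  IntegerMatrix img = clone(skel);
  const int H = img.nrow(), W = img.ncol();
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        if (!img(i, j)) continue;
        int nr[8], ncid[8], n = 0;
        for (int k = 0; k < 8; ++k) {
          if (at(img, i + dr[k], j + dc[k])) {
            nr[n] = dr[k];
            ncid[n] = dc[k];
            ++n;
          }
        }
        // endpoints and isolated pixels stay; pixels with 4+ neighbours are
        // candidate crossover centres and must not be dissolved
        if (n < 2 || n > 3) continue;
        // union-find over the neighbours, adjacency = chebyshev distance <= 1
        int comp[8];
        for (int a = 0; a < n; ++a) comp[a] = a;
        for (int a = 0; a < n; ++a)
          for (int b = a + 1; b < n; ++b) {
            if (std::abs(nr[a] - nr[b]) <= 1 && std::abs(ncid[a] - ncid[b]) <= 1) {
              int ca = comp[a], cb = comp[b];
              if (ca != cb)
                for (int t = 0; t < n; ++t)
                  if (comp[t] == cb) comp[t] = ca;
            }
          }
        bool single = true;
        for (int a = 1; a < n; ++a)
          if (comp[a] != comp[0]) { single = false; break; }
        if (single) {
          img(i, j) = 0;
          changed = true;
        }
      }
    }
  }
  return img;
}

// count of foreground pixels among the 8 neighbours, on foreground pixels only
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(IntegerMatrix skel) {
  const int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!skel(i, j)) continue;
      int s = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          s += at(skel, i + di, j + dj);
        }
      out(i, j) = s;
    }
  return out;
}

// 8-connected component labelling (BFS), labels 1..n in scan order
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > queue;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      queue.clear();
      queue.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      size_t head = 0;
      while (head < queue.size()) {
        int ci = queue[head].first, cj = queue[head].second;
        ++head;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              queue.push_back(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}

// fused batch-norm + ReLU forward on an (N x C) matrix seen as a vector;
// returns the rectified output and the normalized activations (for backprop)
// [[Rcpp::export]]
List bn_relu_fw_cpp(NumericVector x, int N, int C, NumericVector mu,
                    NumericVector istd, NumericVector gamma,
                    NumericVector beta) {
  NumericVector y((size_t)N * C), xhat((size_t)N * C);
  const double *px = x.begin();
  double *py = y.begin(), *ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = istd[c], g = gamma[c], b = beta[c];
    const double *xc = px + (size_t)N * c;
    double *yc = py + (size_t)N * c, *hc = ph + (size_t)N * c;
    for (int i = 0; i < N; ++i) {
      const double h = (xc[i] - m) * s;
      hc[i] = h;
      const double v = g * h + b;
      yc[i] = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// per-channel mean and variance of an (N x C) matrix
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, int N, int C) {
  NumericVector mu(C), var(C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (size_t)N * c;
    double s = 0, s2 = 0;
    for (int i = 0; i < N; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mu[c] = s / N;
    var[c] = s2 / N - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// fused ReLU + batch-norm backward: dy is masked by y > 0, then the standard
// batch-norm gradient is formed. Returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List bn_relu_bw_cpp(NumericVector dy, NumericVector y, NumericVector xhat,
                    int N, int C, NumericVector gamma, NumericVector istd) {
  NumericVector dx((size_t)N * C), dgamma(C), dbeta(C);
  const double *pdy = dy.begin(), *py = y.begin(), *ph = xhat.begin();
  double *pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double *dc = pdy + (size_t)N * c;
    const double *yc = py + (size_t)N * c;
    const double *hc = ph + (size_t)N * c;
    double *xc = pdx + (size_t)N * c;
    double s1 = 0, s2 = 0;
    for (int i = 0; i < N; ++i) {
      const double d = yc[i] > 0 ? dc[i] : 0.0;
      s1 += d;
      s2 += d * hc[i];
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double g = gamma[c], s = istd[c];
    const double m1 = s1 / N, m2 = s2 / N;
    for (int i = 0; i < N; ++i) {
      const double d = yc[i] > 0 ? dc[i] : 0.0;
      xc[i] = s * g * (d - m1 - hc[i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
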