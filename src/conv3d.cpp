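// 3D convolutional layer primitives for the autoencoder and CNN baseline.
// Tensors are R numeric arrays dim (D1, D2, D3, C), column-major; weights
// dim (3, 3, 3, Cin, Cout); zero padding 1 ("same" convolution).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline long tidx(int x, int y, int z, int c, const int* d) {
  return ((long)x) + (long)d[0] * (y + (long)d[1] * (z + (long)d[2] * c));
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector xd,
                            NumericVector w, int cin, int cout,
                            NumericVector b) {
  int d[3] = {xd[0], xd[1], xd[2]};
  long nsp = (long)d[0] * d[1] * d[2];
  NumericVector y(nsp * cout);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int co = 0; co < cout; ++co) {
    long yo = nsp * co;
    for (long i = 0; i < nsp; ++i) py[yo + i] = b[co];
    for (int ci = 0; ci < cin; ++ci) {
      long xo = nsp * ci;
      for (int kz = 0; kz < 3; ++kz)
        for (int ky = 0; ky < 3; ++ky)
          for (int kx = 0; kx < 3; ++kx) {
            double wv = pw[kx + 3 * (ky + 3 * (kz + 3 * (ci + (long)cin * co)))];
            if (wv == 0.0) continue;
            int ox = kx - 1, oy = ky - 1, oz = kz - 1;
            int z0 = std::max(0, -oz), z1 = std::min(d[2], d[2] - oz);
            int y0 = std::max(0, -oy), y1 = std::min(d[1], d[1] - oy);
            int x0 = std::max(0, -ox), x1 = std::min(d[0], d[0] - ox);
            for (int z = z0; z < z1; ++z)
              for (int yy = y0; yy < y1; ++yy) {
                long ybase = yo + (long)d[0] * (yy + (long)d[1] * z);
                long xbase = xo + (long)(x0 + ox) +
                             (long)d[0] * ((yy + oy) + (long)d[1] * (z + oz));
                double* yp = py + ybase + x0;
                const double* xp = px + xbase;
                int len = x1 - x0;
                for (int x = 0; x < len; ++x) yp[x] += wv * xp[x];
              }
          }
    }
  }
  y.attr("dim") = IntegerVector::create(d[0], d[1], d[2], cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector xd, NumericVector w,
                   int cin, int cout, NumericVector gy) {
  int d[3] = {xd[0], xd[1], xd[2]};
  long nsp = (long)d[0] * d[1] * d[2];
  NumericVector gx(nsp * cin), gw(w.size()), gb(cout);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pgy = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  for (int co = 0; co < cout; ++co) {
    long yo = nsp * co;
    double gbv = 0;
    for (long i = 0; i < nsp; ++i) gbv += pgy[yo + i];
    gb[co] = gbv;
    for (int ci = 0; ci < cin; ++ci) {
      long xo = nsp * ci;
      for (int kz = 0; kz < 3; ++kz)
        for (int ky = 0; ky < 3; ++ky)
          for (int kx = 0; kx < 3; ++kx) {
            long wi = kx + 3 * (ky + 3 * (kz + 3 * (ci + (long)cin * co)));
            double wv = pw[wi];
            double gwv = 0;
            int ox = kx - 1, oy = ky - 1, oz = kz - 1;
            int z0 = std::max(0, -oz), z1 = std::min(d[2], d[2] - oz);
            int y0 = std::max(0, -oy), y1 = std::min(d[1], d[1] - oy);
            int x0 = std::max(0, -ox), x1 = std::min(d[0], d[0] - ox);
            for (int z = z0; z < z1; ++z)
              for (int yy = y0; yy < y1; ++yy) {
                long ybase = yo + (long)d[0] * (yy + (long)d[1] * z) + x0;
                long xbase = xo + (long)(x0 + ox) +
                             (long)d[0] * ((yy + oy) + (long)d[1] * (z + oz));
                const double* gp = pgy + ybase;
                const double* xp = px + xbase;
                double* gxp = pgx + xbase;
                int len = x1 - x0;
                for (int x = 0; x < len; ++x) {
                  gwv += gp[x] * xp[x];
                  gxp[x] += gp[x] * wv;
                }
              }
            pgw[wi] += gwv;
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(d[0], d[1], d[2], cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2; dims must be even. Returns pooled values and
// flat argmax indices (1-based into the input array).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xd, int nc) {
  int d[3] = {xd[0], xd[1], xd[2]};
  int od[3] = {d[0] / 2, d[1] / 2, d[2] / 2};
  long osp = (long)od[0] * od[1] * od[2];
  NumericVector y(osp * nc);
  IntegerVector am(osp * nc);
  const double* px = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < od[2]; ++z)
      for (int yy = 0; yy < od[1]; ++yy)
        for (int xx = 0; xx < od[0]; ++xx) {
          double best = -1e300; long bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long i = tidx(2 * xx + dx, 2 * yy + dy, 2 * z + dz, c, d);
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          long o = ((long)xx) + (long)od[0] * (yy + (long)od[1] * (z + (long)od[2] * c));
          y[o] = best;
          am[o] = (int)(bi + 1);
        }
  y.attr("dim") = IntegerVector::create(od[0], od[1], od[2], nc);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector argmax, NumericVector gy,
                              IntegerVector xd, int nc) {
  long n = (long)xd[0] * xd[1] * xd[2] * nc;
  NumericVector gx(n);
  for (long i = 0; i < gy.size(); ++i)
    gx[argmax[i] - 1] += gy[i];
  gx.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], nc);
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector xd, int nc) {
  int d[3] = {xd[0], xd[1], xd[2]};
  int od[3] = {2 * d[0], 2 * d[1], 2 * d[2]};
  NumericVector y((long)od[0] * od[1] * od[2] * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < od[2]; ++z)
      for (int yy = 0; yy < od[1]; ++yy)
        for (int xx = 0; xx < od[0]; ++xx)
          y[tidx(xx, yy, z, c, od)] = x[tidx(xx / 2, yy / 2, z / 2, c, d)];
  y.attr("dim") = IntegerVector::create(od[0], od[1], od[2], nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector gy, IntegerVector yd, int nc) {
  int od[3] = {yd[0], yd[1], yd[2]};
  int d[3] = {od[0] / 2, od[1] / 2, od[2] / 2};
  NumericVector gx((long)d[0] * d[1] * d[2] * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < od[2]; ++z)
      for (int yy = 0; yy < od[1]; ++yy)
        for (int xx = 0; xx < od[0]; ++xx)
          gx[tidx(xx / 2, yy / 2, z / 2, c, d)] += gy[tidx(xx, yy, z, c, od)];
  gx.attr("dim") = IntegerVector::create(d[0], d[1], d[2], nc);
  return gx;
}
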