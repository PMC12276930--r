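#include <Rcpp.h>
using namespace Rcpp;

// Batched valid 2-D convolution on column-major channel-block tensors.
// x: B x (insize*insize*cin); K: (k*k*cin) x cout with kernel-position rows
// ordered (ki fastest, then kj, then input channel); output:
// B x (npix*cout) with column co*npix + pix, pix column-major over the
// (o x o) output grid. Plain loops, innermost over the batch (contiguous).

static void build_idx(std::vector<int>& idx, int insize, int k, int cin) {
  int o = insize - k + 1;
  int npix = o * o;
  int q = 0;
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        for (int oj = 0; oj < o; ++oj)
          for (int oi = 0; oi < o; ++oi) {
            int pix = oj * o + oi;
            idx[(size_t)q * npix + pix] =
              c * insize * insize + (oj + kj) * insize + (oi + ki);
          }
        ++q;
      }
}

// [[Rcpp::export]]
NumericMatrix gf_conv_fwd(const NumericMatrix& x, const NumericMatrix& K,
                          const NumericVector& b, int insize, int k, int cin) {
  const int B = x.nrow();
  const int o = insize - k + 1;
  const int npix = o * o;
  const int kkc = K.nrow();
  const int cout = K.ncol();
  std::vector<int> idx((size_t)npix * kkc);
  build_idx(idx, insize, k, cin);
  NumericMatrix y(B, npix * cout);
  const double* __restrict__ xp0 = x.begin();
  double* __restrict__ yp0 = y.begin();
  for (int co = 0; co < cout; ++co) {
    for (int kp = 0; kp < kkc; ++kp) {
      const double kv = K(kp, co);
      if (kv == 0.0) continue;
      const int* ix = &idx[(size_t)kp * npix];
      for (int pix = 0; pix < npix; ++pix) {
        double* yp = yp0 + (size_t)(co * npix + pix) * B;
        const double* xp = xp0 + (size_t)ix[pix] * B;
        for (int bi = 0; bi < B; ++bi) yp[bi] += kv * xp[bi];
      }
    }
    const double bv = b[co];
    double* yp = yp0 + (size_t)co * npix * B;
    for (size_t j = 0; j < (size_t)npix * B; ++j) yp[j] += bv;
  }
  return y;
}

// [[Rcpp::export]]
List gf_conv_bwd(const NumericMatrix& x, const NumericMatrix& K,
                 const NumericMatrix& dy, int insize, int k, int cin) {
  const int B = x.nrow();
  const int o = insize - k + 1;
  const int npix = o * o;
  const int kkc = K.nrow();
  const int cout = K.ncol();
  std::vector<int> idx((size_t)npix * kkc);
  build_idx(idx, insize, k, cin);
  NumericMatrix dx(B, x.ncol());
  NumericMatrix dK(kkc, cout);
  NumericVector db(cout);
  const double* __restrict__ xp0 = x.begin();
  const double* __restrict__ dyp0 = dy.begin();
  double* __restrict__ dxp0 = dx.begin();
  for (int co = 0; co < cout; ++co) {
    double dbacc = 0.0;
    const double* dyc = dyp0 + (size_t)co * npix * B;
    for (size_t j = 0; j < (size_t)npix * B; ++j) dbacc += dyc[j];
    db[co] = dbacc;
    for (int kp = 0; kp < kkc; ++kp) {
      const double kv = K(kp, co);
      const int* ix = &idx[(size_t)kp * npix];
      double dkacc = 0.0;
      for (int pix = 0; pix < npix; ++pix) {
        const double* dyp = dyp0 + (size_t)(co * npix + pix) * B;
        const double* xp = xp0 + (size_t)ix[pix] * B;
        double* dxp = dxp0 + (size_t)ix[pix] * B;
        for (int bi = 0; bi < B; ++bi) {
          dkacc += xp[bi] * dyp[bi];
          dxp[bi] += kv * dyp[bi];
        }
      }
      dK(kp, co) = dkacc;
    }
  }
  return List::create(Named("dx") = dx, Named("dK") = dK, Named("db") = db);
}

// 2x2 stride-2 average pooling, channel-blocked column-major layout
// [[Rcpp::export]]
NumericMatrix gf_pool_fwd(const NumericMatrix& x, int insize, int cin) {
  const int B = x.nrow();
  const int o = insize / 2;
  NumericMatrix y(B, o * o * cin);
  const double* __restrict__ xp0 = x.begin();
  double* __restrict__ yp0 = y.begin();
  for (int c = 0; c < cin; ++c)
    for (int pj = 0; pj < o; ++pj)
      for (int pi = 0; pi < o; ++pi) {
        double* yp = yp0 + (size_t)(c * o * o + pj * o + pi) * B;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double* xp = xp0 +
              (size_t)(c * insize * insize + (2 * pj + dj) * insize + 2 * pi + di) * B;
            for (int bi = 0; bi < B; ++bi) yp[bi] += 0.25 * xp[bi];
          }
      }
  return y;
}

// [[Rcpp::export]]
NumericMatrix gf_pool_bwd(const NumericMatrix& dy, int insize, int cin) {
  const int B = dy.nrow();
  const int o = insize / 2;
  NumericMatrix dx(B, insize * insize * cin);
  const double* __restrict__ dyp0 = dy.begin();
  double* __restrict__ dxp0 = dx.begin();
  for (int c = 0; c < cin; ++c)
    for (int pj = 0; pj < o; ++pj)
      for (int pi = 0; pi < o; ++pi) {
        const double* dyp = dyp0 + (size_t)(c * o * o + pj * o + pi) * B;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double* dxp = dxp0 +
              (size_t)(c * insize * insize + (2 * pj + dj) * insize + 2 * pi + di) * B;
            for (int bi = 0; bi < B; ++bi) dxp[bi] += 0.25 * dyp[bi];
          }
      }
  return dx;
}
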