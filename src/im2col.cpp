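#include <Rcpp.h>
using namespace Rcpp;

// Unrolls one sample of a (H, W, T, C) volume into a (kh*kw*kt*C) x
// (Ho*Wo*(to1-to0)) patch matrix for 3D convolution by matrix multiply.
// Row order: ih fastest, then iw, then it, then c (must match the weight
// matrix layout used on the R side). Column order: ho fastest, then wo,
// then to. [to0, to1) selects a temporal output slab so peak memory stays
// bounded for large feature maps.

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, int H, int W, int T, int C,
                       int kh, int kw, int kt,
                       int sh, int sw, int st,
                       int ph, int pw, int pt,
                       int Ho, int Wo, int to0, int to1) {
  const int K = kh * kw * kt * C;
  const int P = Ho * Wo * (to1 - to0);
  NumericMatrix col(K, P);
  double *pc = col.begin();
  const double *px = x.begin();
  for (int to = to0; to < to1; ++to) {
    const int tbase = to * st - pt;
    for (int wo = 0; wo < Wo; ++wo) {
      const int wbase = wo * sw - pw;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hbase = ho * sh - ph;
        double *colp = pc + (size_t)(ho + (size_t)Ho * (wo + (size_t)Wo * (to - to0))) * K;
        for (int c = 0; c < C; ++c) {
          for (int it = 0; it < kt; ++it) {
            const int t = tbase + it;
            const bool tok = (t >= 0 && t < T);
            for (int iw = 0; iw < kw; ++iw) {
              const int w = wbase + iw;
              const bool wok = tok && (w >= 0 && w < W);
              const size_t xoff = (size_t)H * (w + (size_t)W * (t + (size_t)T * c));
              for (int ih = 0; ih < kh; ++ih) {
                const int h = hbase + ih;
                const int r = ih + kh * (iw + kw * (it + kt * c));
                colp[r] = (wok && h >= 0 && h < H) ? px[h + xoff] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col3d: scatter-adds patch-matrix gradients back onto the
// (H, W, T, C) input gradient. Same index conventions as im2col3d.

// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix col, int H, int W, int T, int C,
                       int kh, int kw, int kt,
                       int sh, int sw, int st,
                       int ph, int pw, int pt,
                       int Ho, int Wo, int to0, int to1) {
  const int K = kh * kw * kt * C;
  NumericVector dx((size_t)H * W * T * C);
  double *pdx = dx.begin();
  const double *pc = col.begin();
  for (int to = to0; to < to1; ++to) {
    const int tbase = to * st - pt;
    for (int wo = 0; wo < Wo; ++wo) {
      const int wbase = wo * sw - pw;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hbase = ho * sh - ph;
        const double *colp = pc + (size_t)(ho + (size_t)Ho * (wo + (size_t)Wo * (to - to0))) * K;
        for (int c = 0; c < C; ++c) {
          for (int it = 0; it < kt; ++it) {
            const int t = tbase + it;
            if (t < 0 || t >= T) continue;
            for (int iw = 0; iw < kw; ++iw) {
              const int w = wbase + iw;
              if (w < 0 || w >= W) continue;
              const size_t xoff = (size_t)H * (w + (size_t)W * (t + (size_t)T * c));
              for (int ih = 0; ih < kh; ++ih) {
                const int h = hbase + ih;
                if (h < 0 || h >= H) continue;
                pdx[h + xoff] += colp[ih + kh * (iw + kw * (it + kt * c))];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}
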