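#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sliding-window GLCM statistics.
//
// img: quantized grey levels 0..levels-1; negative values are treated as
// missing and never participate in a pair. For every pixel the window
// (clipped at the image border, never padded) is scanned; for each offset
// (dr, dc) every pair of in-window pixels (p, p + offset) contributes
// symmetrically to the co-occurrence matrix P, which is normalised to sum 1
// before the eight statistics are computed.
//
// Returns an nr x nc x 8 array in the order:
// mean, variance, homogeneity, contrast, dissimilarity, entropy,
// second_moment, correlation.
// [[Rcpp::export]]
NumericVector glcm_stats_cpp(IntegerMatrix img, int window, int levels,
                             IntegerMatrix offsets) {
  const int nr = img.nrow(), nc = img.ncol();
  if (window < 3 || window % 2 == 0) stop("window must be odd and >= 3");
  if (window >= nr || window >= nc) stop("window exceeds image extent");
  if (levels < 2) stop("levels must be >= 2");
  const int half = window / 2;
  const int noff = offsets.nrow();
  const int L = levels;
  NumericVector out(nr * nc * 8, NA_REAL);
  std::vector<double> P(L * L);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int r0 = std::max(0, r - half), r1 = std::min(nr - 1, r + half);
      const int c0 = std::max(0, c - half), c1 = std::min(nc - 1, c + half);
      std::fill(P.begin(), P.end(), 0.0);
      double total = 0.0;
      for (int o = 0; o < noff; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        for (int cc = c0; cc <= c1; ++cc) {
          const int cc2 = cc + dc;
          if (cc2 < c0 || cc2 > c1) continue;
          for (int rr = r0; rr <= r1; ++rr) {
            const int rr2 = rr + dr;
            if (rr2 < r0 || rr2 > r1) continue;
            const int a = img(rr, cc), b = img(rr2, cc2);
            if (a < 0 || b < 0) continue;
            P[a * L + b] += 1.0;
            P[b * L + a] += 1.0;
            total += 2.0;
          }
        }
      }
      if (total <= 0.0) continue;  // all-missing window: stats stay NA
      double mean = 0, variance = 0, homog = 0, contrast = 0, dissim = 0,
             entropy = 0, asm_ = 0, corr_num = 0;
      // first pass: normalise implicitly and accumulate mean (row index)
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) {
          const double p = P[i * L + j] / total;
          if (p <= 0.0) continue;
          mean += i * p;
        }
      // marginal stats (P symmetric => row and column marginals equal)
      double sig2 = 0.0;
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) {
          const double p = P[i * L + j] / total;
          if (p <= 0.0) continue;
          const double di = i - mean, dj = j - mean, dij = double(i - j);
          variance += di * di * p;
          homog += p / (1.0 + dij * dij);
          contrast += dij * dij * p;
          dissim += std::fabs(dij) * p;
          entropy -= p * std::log(p);
          asm_ += p * p;
          corr_num += di * dj * p;
          sig2 += di * di * p;  // == variance for symmetric P
        }
      const double corr = (sig2 > 0.0) ? corr_num / sig2 : 0.0;
      const int base = c * nr + r, plane = nr * nc;
      out[base + 0 * plane] = mean;
      out[base + 1 * plane] = variance;
      out[base + 2 * plane] = homog;
      out[base + 3 * plane] = contrast;
      out[base + 4 * plane] = dissim;
      out[base + 5 * plane] = entropy;
      out[base + 6 * plane] = asm_;
      out[base + 7 * plane] = corr;
    }
  }
  out.attr("dim") = IntegerVector::create(nr, nc, 8);
  return out;
}
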