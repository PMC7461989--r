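#include <Rcpp.h>
#include <cfloat>
#include <cmath>

// Exhaustive gamma analysis: for every reference voxel, loop over every
// candidate voxel of the evaluated volume inside the distance-to-agreement
// ball and take the minimum combined index. Deliberately unoptimized; this
// is the validation oracle for the vectorized R implementation.
//
// dsuv_abs > 0 : global normalization, absolute SUV tolerance.
// dsuv_abs < 0 : local normalization; the tolerance is delta_suv_pct percent
//                of each reference voxel's own value (floored at DBL_EPSILON).
// [[Rcpp::export]]
Rcpp::NumericVector gamma_brute_cpp(Rcpp::NumericVector reference,
                                    Rcpp::NumericVector evaluated,
                                    Rcpp::NumericVector spacing,
                                    double dsuv_abs,
                                    double delta_suv_pct,
                                    double delta_d_mm,
                                    bool mode2d,
                                    double cap) {
  Rcpp::IntegerVector dims = reference.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int mx = (int)std::floor(delta_d_mm / sx);
  const int my = (int)std::floor(delta_d_mm / sy);
  const int mz = mode2d ? 0 : (int)std::floor(delta_d_mm / sz);
  const double dd2 = delta_d_mm * delta_d_mm;

  Rcpp::NumericVector out(reference.size());
  out.attr("dim") = dims;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const double rv = reference[i + nx * (j + (long long)ny * k)];
        double denom = dsuv_abs;
        if (dsuv_abs < 0) {
          denom = delta_suv_pct / 100.0 * rv;
          if (denom < DBL_EPSILON) denom = DBL_EPSILON;
        }
        double best = R_PosInf;
        for (int dk = -mz; dk <= mz; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -my; dj <= my; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -mx; di <= mx; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              const double dist2 = (di * sx) * (di * sx) +
                                   (dj * sy) * (dj * sy) +
                                   (dk * sz) * (dk * sz);
              if (dist2 > dd2) continue;
              const double ev = evaluated[ii + nx * (jj + (long long)ny * kk)];
              const double dv = (ev - rv) / denom;
              const double g2 = dv * dv + dist2 / dd2;
              if (g2 < best) best = g2;
            }
          }
        }
        double g = std::sqrt(best);
        if (g > cap) g = cap;
        out[i + nx * (j + (long long)ny * k)] = g;
      }
    }
  }
  return out;
}
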