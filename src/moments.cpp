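#include <Rcpp.h>
using namespace Rcpp;

// Rolling before/after window moments of every pixel time trace.
// stack: npix * nf values (pixel index fastest), navg: window length.
// For valid centers t (0-based t = navg .. nf-navg-1) the before block is
// [t-navg, t-1] and the after block [t, t+navg-1]. Returns npix x nvalid
// matrices of block means and unbiased block variances. Frames are walked
// in storage order (pixel-contiguous) with rolling per-pixel accumulators.
// [[Rcpp::export]]
List window_moments_cpp(NumericVector stack, int npix, int nf, int navg) {
  const int nvalid = nf - 2 * navg;
  if (nvalid < 1) stop("movie too short for navg");
  NumericMatrix mb(npix, nvalid), ma(npix, nvalid);
  NumericMatrix vb(npix, nvalid), va(npix, nvalid);
  const double *x = stack.begin();
  std::vector<double> sb(npix, 0.0), qb(npix, 0.0);
  std::vector<double> sa(npix, 0.0), qa(npix, 0.0);
  const double inv_n = 1.0 / navg;
  const double inv_nm1 = 1.0 / (navg - 1);
  for (int f = 0; f < navg; ++f) {
    const double *xf = x + (R_xlen_t)f * npix;
    for (int p = 0; p < npix; ++p) { sb[p] += xf[p]; qb[p] += xf[p] * xf[p]; }
  }
  for (int f = navg; f < 2 * navg; ++f) {
    const double *xf = x + (R_xlen_t)f * npix;
    for (int p = 0; p < npix; ++p) { sa[p] += xf[p]; qa[p] += xf[p] * xf[p]; }
  }
  for (int k = 0; k < nvalid; ++k) {
    double *mbk = &mb(0, k), *mak = &ma(0, k);
    double *vbk = &vb(0, k), *vak = &va(0, k);
    for (int p = 0; p < npix; ++p) {
      mbk[p] = sb[p] * inv_n;
      mak[p] = sa[p] * inv_n;
      double wb = qb[p] - sb[p] * sb[p] * inv_n;
      double wa = qa[p] - sa[p] * sa[p] * inv_n;
      vbk[p] = (wb > 0 ? wb : 0) * inv_nm1;
      vak[p] = (wa > 0 ? wa : 0) * inv_nm1;
    }
    if (k + 1 < nvalid) {
      int t = navg + k;
      const double *xob = x + (R_xlen_t)(t - navg) * npix;
      const double *xib = x + (R_xlen_t)t * npix;
      const double *xia = x + (R_xlen_t)(t + navg) * npix;
      for (int p = 0; p < npix; ++p) {
        sb[p] += xib[p] - xob[p];
        qb[p] += xib[p] * xib[p] - xob[p] * xob[p];
        sa[p] += xia[p] - xib[p];
        qa[p] += xia[p] * xia[p] - xib[p] * xib[p];
      }
    }
  }
  return List::create(_["mean_before"] = mb, _["mean_after"] = ma,
                      _["var_before"] = vb, _["var_after"] = va);
}

// Jump z statistic in one pass: z = (ma - mb) / max(s_pool, floor * |mb|),
// with the degenerate zero-noise conventions of the R reference.
// [[Rcpp::export]]
NumericMatrix jump_z_cpp(NumericMatrix mb, NumericMatrix ma,
                         NumericMatrix vb, NumericMatrix va,
                         double rel_floor) {
  const R_xlen_t n = mb.size();
  NumericMatrix z(mb.nrow(), mb.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = ma[i] - mb[i];
    double s = std::sqrt((vb[i] + va[i]) / 2.0);
    double fl = rel_floor * std::fabs(mb[i]);
    if (s < fl) s = fl;
    if (s <= 0) z[i] = (d == 0) ? 0.0 : (d > 0 ? R_PosInf : R_NegInf);
    else z[i] = d / s;
  }
  return z;
}
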