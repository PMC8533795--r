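#include <Rcpp.h>
using namespace Rcpp;

// Event-time simulation by numerical inversion of the total cumulative
// hazard on a daily grid (midpoint rule, linear interpolation within the
// crossing day). The background hazard is read from the life-table rate
// array with age/year floored to 1-year cells and clamped at the edges.
//
// h0: baseline excess hazard at daily midpoints (length >= max days)
// bt: EDI coefficient at daily midpoints (all equal => time-constant)
// iq: per-subject deprivation quintile indices (length 0 => common table)
// [[Rcpp::export]]
NumericVector simulate_event_times(NumericVector u, NumericVector t_adm,
                                   NumericVector h0, NumericVector bt,
                                   NumericVector edi,
                                   NumericVector subj_factor,
                                   NumericVector age, NumericVector dy,
                                   IntegerVector is, IntegerVector ir,
                                   IntegerVector iq, NumericVector rates,
                                   int na, int ny, int ns, int nr,
                                   int age_min, int year_min, double dt) {
  int n = u.size();
  bool has_q = iq.size() == n;
  bool td = false;
  for (int g = 1; g < bt.size(); ++g) {
    if (bt[g] != bt[0]) { td = true; break; }
  }
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    int ng = (int)std::ceil(t_adm[i] / dt);
    if (ng > h0.size()) ng = h0.size();
    double lam = 0.0;
    const double ui = u[i];
    double fi = subj_factor[i];
    if (!td) fi *= std::exp(bt[0] * edi[i]);
    R_xlen_t base = (R_xlen_t)(na * ny) * (is[i] - 1) +
      (R_xlen_t)(na * ny) * ns * (ir[i] - 1);
    if (has_q) base += (R_xlen_t)(na * ny) * ns * nr * (iq[i] - 1);
    for (int g = 0; g < ng; ++g) {
      double mid = (g + 0.5) * dt;
      double hE = h0[g] * fi;
      if (td) hE *= std::exp(bt[g] * edi[i]);
      int ia = (int)std::floor(age[i] + mid) - age_min;
      if (ia < 0) ia = 0;
      if (ia > na - 1) ia = na - 1;
      int iy = (int)std::floor(dy[i] + mid) - year_min;
      if (iy < 0) iy = 0;
      if (iy > ny - 1) iy = ny - 1;
      double h = hE + rates[base + ia + (R_xlen_t)na * iy];
      double lam_new = lam + h * dt;
      if (lam_new >= ui) {
        out[i] = g * dt + (ui - lam) / h;
        break;
      }
      lam = lam_new;
    }
  }
  return out;
}
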