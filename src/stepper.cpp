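// Forward-Euler / three-level time stepper for the bursting neural field
// model on a toroidal grid. All ODE fields advance with the same dt; the
// damped-wave flux uses the three-level scheme (solve for the future value).
// Units: ms, mm, mV; rates in 1/ms. The per-step work is fused into a
// single sweep over the grid; all divisions by constants are hoisted as
// reciprocals.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline void record_fields(const List& records, int g, int stride,
                          const std::vector<double*>& fptr, int n) {
  if (stride <= 0 || g % stride != 0) return;
  int nr = records.size();
  for (int r = 0; r < nr; ++r) {
    List rec = records[r];
    int start = as<int>(rec["start"]);
    int end = as<int>(rec["end"]);
    if (g < start || g >= end) continue;
    int code = as<int>(rec["code"]);
    NumericMatrix buf = rec["buf"];
    IntegerVector ctr = rec["counter"];
    int col = ctr[0];
    if (col >= buf.ncol()) continue;
    double* src = fptr[code];
    double* dst = &buf(0, col);
    std::copy(src, src + n, dst);
    ctr[0] = col + 1;
  }
}

} // namespace

// [[Rcpp::export]]
void bf_step_chunk(NumericVector he, NumericVector hi,
                   NumericVector Iee, NumericVector Jee,
                   NumericVector Iei, NumericVector Jei,
                   NumericVector Iie, NumericVector Jie,
                   NumericVector Iii, NumericVector Jii,
                   NumericVector phi, NumericVector phi_prev,
                   NumericVector phi2, NumericVector phi2_prev,
                   NumericVector Ce, NumericVector Ci,
                   NumericMatrix knots, NumericMatrix crw,
                   NumericMatrix scal, List consts, int step0,
                   List records) {
  const int nx = as<int>(consts["nx"]);
  const int ny = as<int>(consts["ny"]);
  const int n = nx * ny;
  const double dt = as<double>(consts["dt"]);
  const double dx = as<double>(consts["dx"]);
  const double dt_itau_e = dt / as<double>(consts["tau_e"]);
  const double dt_itau_i = dt / as<double>(consts["tau_i"]);
  const double hre = as<double>(consts["hre"]);
  const double hri = as<double>(consts["hri"]);
  NumericVector heq = consts["heq"];        // ee, ei, ie, ii
  NumericVector psiden = consts["psiden"];  // |heq_lk - hr_k|, same order
  NumericVector Nb = consts["Nb"];          // ee, ei, ie, ii
  NumericVector Na = consts["Na"];          // ee, ei
  const double ipd_ee = 1.0 / psiden[0], ipd_ei = 1.0 / psiden[1],
               ipd_ie = 1.0 / psiden[2], ipd_ii = 1.0 / psiden[3];
  const double heq_ee = heq[0], heq_ei = heq[1], heq_ie = heq[2],
               heq_ii = heq[3];
  const double Nb_ee = Nb[0], Nb_ei = Nb[1], Nb_ie = Nb[2], Nb_ii = Nb[3];
  const double Na_ee = Na[0], Na_ei = Na[1];
  const double Smax_e = as<double>(consts["Smax_e"]);
  const double Smax_i = as<double>(consts["Smax_i"]);
  const double mu_e = as<double>(consts["mu_e"]);
  const double mu_i = as<double>(consts["mu_i"]);
  const double ce_sig = as<double>(consts["sig_scale"]) /
                        as<double>(consts["sigma_e"]);
  const double ci_sig = as<double>(consts["sig_scale"]) /
                        as<double>(consts["sigma_i"]);
  NumericVector lambda = consts["lambda"];  // ee, ei
  NumericVector vvel = consts["v"];         // ee, ei
  const double pei = as<double>(consts["pei"]);
  const double pee_mean = as<double>(consts["pee_mean"]);
  const double rel_sd = as<double>(consts["rel_sd"]);
  const double iS0e = 1.0 / as<double>(consts["S0e"]);
  const double iS0i = 1.0 / as<double>(consts["S0i"]);
  NumericVector fe = consts["fe"];  // length 1 or n
  NumericVector fi = consts["fi"];
  const double dt_itre = dt / as<double>(consts["tau_rec_e"]);
  const double dt_itri = dt / as<double>(consts["tau_rec_i"]);
  const bool freezeC = as<bool>(consts["freezeC"]);
  const int stride = as<int>(consts["record_stride"]);
  const bool two_phi = phi2.size() == n;

  const int fe_str = fe.size() == 1 ? 0 : 1;
  const int fi_str = fi.size() == 1 ? 0 : 1;
  const int nsub = crw.nrow();

  std::vector<double> phinew(n), phinew2(two_phi ? n : 0);

  double* p_he = REAL(he); double* p_hi = REAL(hi);
  double* p_Iee = REAL(Iee); double* p_Jee = REAL(Jee);
  double* p_Iei = REAL(Iei); double* p_Jei = REAL(Jei);
  double* p_Iie = REAL(Iie); double* p_Jie = REAL(Jie);
  double* p_Iii = REAL(Iii); double* p_Jii = REAL(Jii);
  double* p_phi = REAL(phi); double* p_phip = REAL(phi_prev);
  double* p_phi2 = two_phi ? REAL(phi2) : nullptr;
  double* p_phi2p = two_phi ? REAL(phi2_prev) : nullptr;
  double* p_Ce = REAL(Ce); double* p_Ci = REAL(Ci);
  const double* p_fe = REAL(fe); const double* p_fi = REAL(fi);
  const double* K0 = &knots(0, 0); const double* K1 = &knots(0, 1);
  const double* K2 = &knots(0, 2); const double* K3 = &knots(0, 3);

  // field codes for recording: 0 h_e, 1 h_i, 2 C_e, 3 C_i, 4 phi, 5 I_ee
  std::vector<double*> fptr = {p_he, p_hi, p_Ce, p_Ci, p_phi, p_Iee};

  const double inv_dx2 = 1.0 / (dx * dx);
  double wa[2], wb[2], wl2[2], wden[2];
  for (int w = 0; w < 2; ++w) {
    wa[w] = 1.0 / (vvel[w] * vvel[w] * dt * dt);
    wb[w] = 1.0 / (vvel[w] * lambda[w] * dt);
    wl2[w] = 1.0 / (lambda[w] * lambda[w]);
    wden[w] = 1.0 / (wa[w] + wb[w]);
  }

  for (int s = 0; s < nsub; ++s) {
    const int g = step0 + s;
    record_fields(records, g, stride, fptr, n);

    const double w0 = crw(s, 0), w1 = crw(s, 1), w2 = crw(s, 2),
                 w3 = crw(s, 3);
    const double dtg_ee = dt * scal(s, 0), dtg_ei = dt * scal(s, 1),
                 dtg_ie = dt * scal(s, 2), dtg_ii = dt * scal(s, 3);
    const double dtgt_ee = dt * scal(s, 4), dtgt_ei = dt * scal(s, 5),
                 dtgt_ie = dt * scal(s, 6), dtgt_ii = dt * scal(s, 7);
    const double gn_ee = scal(s, 8), gn_ei = scal(s, 9), gn_ie = scal(s, 10),
                 gn_ii = scal(s, 11);

    for (int x = 0; x < nx; ++x) {
      const int xm = (x == 0 ? nx - 1 : x - 1) * ny;
      const int xp = (x == nx - 1 ? 0 : x + 1) * ny;
      const int xc = x * ny;
      for (int y = 0; y < ny; ++y) {
        const int i = xc + y;
        const int ym = xc + (y == 0 ? ny - 1 : y - 1);
        const int yp = xc + (y == ny - 1 ? 0 : y + 1);

        const double hev = p_he[i], hiv = p_hi[i];
        const double Sev = Smax_e /
            (1.0 + std::exp(-ce_sig * (hev - mu_e)));
        const double Siv = Smax_i /
            (1.0 + std::exp(-ci_sig * (hiv - mu_i)));
        const double Cev = p_Ce[i], Civ = p_Ci[i];
        const double srcv = Cev * Sev;

        // damped wave, three-level scheme (shared field unless two_phi)
        {
          const double Pv = p_phi[i];
          const double lap = (p_phi[xm + y] + p_phi[xp + y] + p_phi[ym] +
                              p_phi[yp] - 4.0 * Pv) * inv_dx2;
          phinew[i] = (srcv * wl2[0] + lap - Pv * wl2[0] +
                       wa[0] * (2.0 * Pv - p_phip[i]) +
                       wb[0] * p_phip[i]) * wden[0];
        }
        double ph_ee = p_phi[i], ph_ei = ph_ee;
        if (two_phi) {
          const double Pv = p_phi2[i];
          const double lap = (p_phi2[xm + y] + p_phi2[xp + y] + p_phi2[ym] +
                              p_phi2[yp] - 4.0 * Pv) * inv_dx2;
          phinew2[i] = (srcv * wl2[1] + lap - Pv * wl2[1] +
                        wa[1] * (2.0 * Pv - p_phi2p[i]) +
                        wb[1] * p_phi2p[i]) * wden[1];
          ph_ei = Pv;
        }

        // synaptic input rates (noise on the ee extracortical input)
        const double z = w0 * K0[i] + w1 * K1[i] + w2 * K2[i] + w3 * K3[i];
        const double pee = pee_mean * (1.0 + rel_sd * z);
        const double A_ee = Nb_ee * srcv + Na_ee * ph_ee + pee;
        const double A_ei = Nb_ei * srcv + Na_ei * ph_ei + pei;
        const double SiC = Civ * Siv;
        const double A_ie = Nb_ie * SiC;
        const double A_ii = Nb_ii * SiC;

        // membrane update from current PSP fields
        p_he[i] = hev + dt_itau_e *
            (hre - hev + (heq_ee - hev) * ipd_ee * p_Iee[i] +
             (heq_ie - hev) * ipd_ie * p_Iie[i]);
        p_hi[i] = hiv + dt_itau_i *
            (hri - hiv + (heq_ei - hiv) * ipd_ei * p_Iei[i] +
             (heq_ii - hiv) * ipd_ii * p_Iii[i]);

        // PSP cascades: dI = gtilde (J - I), dJ = gamma (gain A - J)
        const double Jee0 = p_Jee[i], Jei0 = p_Jei[i], Jie0 = p_Jie[i],
                     Jii0 = p_Jii[i];
        p_Iee[i] += dtgt_ee * (Jee0 - p_Iee[i]);
        p_Jee[i] = Jee0 + dtg_ee * (gn_ee * A_ee - Jee0);
        p_Iei[i] += dtgt_ei * (Jei0 - p_Iei[i]);
        p_Jei[i] = Jei0 + dtg_ei * (gn_ei * A_ei - Jei0);
        p_Iie[i] += dtgt_ie * (Jie0 - p_Iie[i]);
        p_Jie[i] = Jie0 + dtg_ie * (gn_ie * A_ie - Jie0);
        p_Iii[i] += dtgt_ii * (Jii0 - p_Iii[i]);
        p_Jii[i] = Jii0 + dtg_ii * (gn_ii * A_ii - Jii0);

        if (!freezeC) {
          const double fev = p_fe[i * fe_str], fiv = p_fi[i * fi_str];
          p_Ce[i] = Cev + dt_itre *
              (1.0 + fev - (1.0 + Sev * iS0e * fev) * Cev);
          p_Ci[i] = Civ + dt_itri *
              (1.0 + fiv - (1.0 + Siv * iS0i * fiv) * Civ);
        }
      }
    }

    // rotate wave history
    std::swap_ranges(p_phi, p_phi + n, p_phip);   // phip <- old phi
    std::copy(phinew.data(), phinew.data() + n, p_phi);
    if (two_phi) {
      std::swap_ranges(p_phi2, p_phi2 + n, p_phi2p);
      std::copy(phinew2.data(), phinew2.data() + n, p_phi2);
    }
  }

  for (int i = 0; i < n; ++i)
    if (!std::isfinite(p_he[i]))
      stop("field divergence detected at step %d (non-finite h_e)",
           step0 + nsub);
}

// [[Rcpp::export]]
NumericVector bf_tile_average(NumericVector field, int nx, int ny, int tile) {
  if (nx % tile != 0 || ny % tile != 0)
    stop("grid dimensions must be divisible by the tile size");
  const int mx = nx / tile, my = ny / tile;
  NumericVector out(mx * my);
  for (int X = 0; X < mx; ++X)
    for (int Y = 0; Y < my; ++Y) {
      double acc = 0.0;
      for (int dx_ = 0; dx_ < tile; ++dx_)
        for (int dy = 0; dy < tile; ++dy)
          acc += field[(X * tile + dx_) * ny + Y * tile + dy];
      out[X * my + Y] = acc / (tile * tile);
    }
  return out;
}
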