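// Consortium ODE core: right-hand side, analytic Jacobian, and an adaptive
// L-stable Rosenbrock 2(3) integrator (Shampine-Reichelt type).
//
// State layout (0-based), all concentrations mmol/ml:
//   0 M1   sender-1 mRNA            1 A1   sender-1 prepro alpha-factor
//   2 M2   sender-2 mRNA            3 A2   sender-2 prepro alpha-factor
//   4 F3   cell-3 pathway activity  5 Z3   cell-3 repressor (LacI)
//   6 PHIX cell-3 prepro alpha-factor X
//   7 F4   cell-4 pathway activity  8 Z4   cell-4 repressor (LacI)
//   9 PHIY cell-4 prepro alpha-factor Y
//  10 XMED medium alpha-factor X   11 YMED medium alpha-factor Y
//  12 GFP  reporter in cell 4
//
// Parameter vector layout (see expand_params() on the R side):
//   0..7   cell 1: k_tx, k_tx0, k_tl, d_m, k_sec, d_p, K_u, hill_in
//   8..15  cell 2: same fields
//  16..26  cell 3: k_act, k_deact, K_L, F_tot, k34, d_Z, gamma, beta_c,
//                  hill_rep, k_sec, d_p
//  27..37  cell 4: same fields
//  38..41  sigma1..sigma4 (effective per-cell secretion into medium, 1/s)
//  42..43  k_deg_x, k_deg_y (medium clearance, 1/s)
//  44..45  k_gfp (production, mmol/(ml*s)), k_gfp_deg (1/s)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NS = 13;

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

// Hill activation u^n / (K^n + u^n); returns 0 for u <= 0
static inline double hill_act(double u, double K, double n) {
  if (u <= 0.0) return 0.0;
  const double un = std::pow(u, n), Kn = std::pow(K, n);
  return un / (Kn + un);
}

// repressible promoter occupancy 1 / (1 + (Z/beta)^h)
static inline double rep_occ(double Z, double beta, double h) {
  if (Z <= 0.0) return 1.0;
  return 1.0 / (1.0 + std::pow(Z / beta, h));
}

// d/dZ of rep_occ
static inline double rep_occ_dZ(double Z, double beta, double h) {
  if (Z <= 0.0) return 0.0;
  const double r = std::pow(Z / beta, h);
  const double den = 1.0 + r;
  return -(h * r / Z) / (den * den);
}

static void rhs_core(const double* y, const double* p, double Rin, double Sin,
                     bool clamp_medium, double* dy) {
  // sender cells
  for (int c = 0; c < 2; ++c) {
    const double* q = p + 8 * c;
    const double M = y[2 * c], A = y[2 * c + 1];
    const double in = (c == 0) ? Rin : Sin;
    dy[2 * c]     = q[0] * hill_act(in, q[6], q[7]) + q[1] - q[3] * M;
    dy[2 * c + 1] = q[2] * M - (q[4] + q[5]) * A;
  }
  // NOT cells: cell 3 senses YMED, cell 4 senses XMED
  for (int c = 0; c < 2; ++c) {
    const double* q = p + 16 + 11 * c;
    const int i0 = 4 + 3 * c;
    const double F = y[i0], Z = y[i0 + 1], phi = y[i0 + 2];
    const double lig = clamp_medium ? 0.0 : pos(y[c == 0 ? 11 : 10]);
    const double u = lig / (q[2] + lig);           // K_L saturable activation
    dy[i0]     = q[0] * u * (q[3] - F) - q[1] * F; // F_tot - F
    dy[i0 + 1] = q[4] * pos(F) - q[5] * Z;         // k34 * F - d_Z * Z
    dy[i0 + 2] = q[6] * rep_occ(pos(Z), q[7], q[8]) - (q[9] + q[10]) * phi;
  }
  // medium: cell 2 + cell 3 feed X, cell 1 + cell 4 feed Y
  if (clamp_medium) {
    dy[10] = 0.0;
    dy[11] = 0.0;
  } else {
    dy[10] = p[39] * y[3] + p[40] * y[6] - p[42] * y[10];
    dy[11] = p[38] * y[1] + p[41] * y[9] - p[43] * y[11];
  }
  // GFP co-expressed with phi_y (same repressible promoter, cell 4)
  dy[12] = p[44] * rep_occ(pos(y[8]), p[34], p[35]) - p[45] * y[12];
}

static void jac_core(const double* y, const double* p, bool clamp_medium,
                     double* J /* NS x NS, column-major */) {
  std::fill(J, J + NS * NS, 0.0);
  auto at = [J](int r, int c) -> double& { return J[c * NS + r]; };
  // senders
  for (int c = 0; c < 2; ++c) {
    const double* q = p + 8 * c;
    at(2 * c, 2 * c) = -q[3];
    at(2 * c + 1, 2 * c) = q[2];
    at(2 * c + 1, 2 * c + 1) = -(q[4] + q[5]);
  }
  // NOT cells
  for (int c = 0; c < 2; ++c) {
    const double* q = p + 16 + 11 * c;
    const int i0 = 4 + 3 * c, imed = (c == 0) ? 11 : 10;
    const double F = y[i0], Z = y[i0 + 1];
    const double lig = clamp_medium ? 0.0 : pos(y[imed]);
    const double u = lig / (q[2] + lig);
    at(i0, i0) = -q[0] * u - q[1];
    if (!clamp_medium && y[imed] > 0.0) {
      const double dudm = q[2] / ((q[2] + lig) * (q[2] + lig));
      at(i0, imed) = q[0] * dudm * (q[3] - F);
    }
    at(i0 + 1, i0) = (F > 0.0) ? q[4] : 0.0;
    at(i0 + 1, i0 + 1) = -q[5];
    at(i0 + 2, i0 + 1) = q[6] * rep_occ_dZ(pos(Z), q[7], q[8]);
    at(i0 + 2, i0 + 2) = -(q[9] + q[10]);
  }
  // medium
  if (!clamp_medium) {
    at(10, 3) = p[39];
    at(10, 6) = p[40];
    at(10, 10) = -p[42];
    at(11, 1) = p[38];
    at(11, 9) = p[41];
    at(11, 11) = -p[43];
  }
  // GFP
  at(12, 8) = p[44] * rep_occ_dZ(pos(y[8]), p[34], p[35]);
  at(12, 12) = -p[45];
}

// [[Rcpp::export]]
NumericVector circuit_rhs_cpp(NumericVector y, NumericVector pvec,
                              double R, double S, bool clamp_medium) {
  if (y.size() != NS) stop("state must have %d components", NS);
  NumericVector dy(NS);
  rhs_core(y.begin(), pvec.begin(), R, S, clamp_medium, dy.begin());
  return dy;
}

// [[Rcpp::export]]
NumericMatrix circuit_jac_cpp(NumericVector y, NumericVector pvec,
                              bool clamp_medium) {
  NumericMatrix J(NS, NS);
  jac_core(y.begin(), pvec.begin(), clamp_medium, J.begin());
  return J;
}

// Adaptive Rosenbrock 2(3), L-stable, with a third-order error companion.
// Autonomous within one input segment; integration is restarted at input
// breakpoints by the R driver. Output is saved on a regular cadence.
// [[Rcpp::export]]
List rosenbrock_segment(NumericVector y0, double t0, double t1,
                        NumericVector pvec, double R, double S,
                        bool clamp_medium, double rtol, double atol,
                        double save_dt, double h_init, double max_steps) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  const double span = t1 - t0;
  if (span <= 0.0) stop("segment must have positive duration");

  arma::vec y(y0.begin(), NS);
  arma::mat I = arma::eye(NS, NS);

  // save grid: t0, t0 + save_dt, ..., t1 (t1 always included)
  std::vector<double> tsave;
  if (save_dt > 0.0) {
    const int nfull = (int)std::floor(span / save_dt + 1e-9);
    for (int k = 0; k <= nfull; ++k) tsave.push_back(t0 + k * save_dt);
    if (tsave.back() < t1 - 1e-9 * std::max(1.0, std::fabs(t1)))
      tsave.push_back(t1);
    else
      tsave.back() = t1;
  } else {
    tsave.push_back(t0);
    tsave.push_back(t1);
  }
  const int nsave = (int)tsave.size();
  arma::mat out(nsave, NS);
  out.row(0) = y.t();
  int isave = 1;

  double t = t0;
  double h = (h_init > 0.0) ? h_init : std::min(1.0, span);
  long nsteps = 0, nreject = 0;

  arma::vec F0(NS), F1(NS), F2(NS), k1(NS), k2(NS), k3(NS), ynew(NS), err(NS);
  arma::mat J(NS, NS), W(NS, NS);

  rhs_core(y.memptr(), pvec.begin(), R, S, clamp_medium, F0.memptr());

  while (isave < nsave) {
    const double ttarget = tsave[isave];
    if (t >= ttarget - 1e-9 * std::max(1.0, std::fabs(ttarget))) {
      out.row(isave) = y.t();
      ++isave;
      continue;
    }
    h = std::min(h, ttarget - t);
    jac_core(y.memptr(), pvec.begin(), clamp_medium, J.memptr());

    bool accepted = false;
    while (!accepted) {
      if (++nsteps > (long)max_steps)
        stop("integration exceeded max_steps at t = %g s", t);
      W = I - (h * d) * J;
      arma::mat Winv;
      if (!arma::inv(Winv, W))
        stop("singular Rosenbrock matrix at t = %g s", t);

      k1 = Winv * F0;
      rhs_core((y + 0.5 * h * k1).eval().memptr(), pvec.begin(), R, S,
               clamp_medium, F1.memptr());
      k2 = Winv * (F1 - k1) + k1;
      ynew = y + h * k2;
      rhs_core(ynew.memptr(), pvec.begin(), R, S, clamp_medium, F2.memptr());
      k3 = Winv * (F2 - e32 * (k2 - F1) - 2.0 * (k1 - F0));
      err = (h / 6.0) * (k1 - 2.0 * k2 + k3);

      double enorm = 0.0;
      for (int i = 0; i < NS; ++i) {
        const double sc = atol + rtol * std::max(std::fabs(y(i)), std::fabs(ynew(i)));
        enorm = std::max(enorm, std::fabs(err(i)) / sc);
      }
      if (!ynew.is_finite() || !std::isfinite(enorm))
        stop("integration produced non-finite values at t = %g s", t);

      if (enorm <= 1.0) {
        t += h;
        y = ynew;
        F0 = F2; // FSAL
        const double fac = (enorm > 0.0)
          ? std::min(5.0, 0.9 * std::pow(enorm, -1.0 / 3.0)) : 5.0;
        h = std::max(h * fac, 1e-12);
        accepted = true;
      } else {
        ++nreject;
        h = std::max(h * std::max(0.2, 0.9 * std::pow(enorm, -1.0 / 3.0)),
                     1e-12);
      }
    }
  }

  return List::create(_["time"] = NumericVector(tsave.begin(), tsave.end()),
                      _["states"] = wrap(out), _["nsteps"] = (double)nsteps,
                      _["nreject"] = (double)nreject, _["h_last"] = h);
}
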