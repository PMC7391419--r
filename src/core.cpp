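// Fixed-step (explicit Euler) integrator for the visuo-tactile PPS network.
//
// Two N x N unisensory sheets (tactile, visual) with Mexican-hat lateral
// coupling feed one multisensory unit through plastic feedforward weights;
// the multisensory unit feeds back through fixed weights with the same
// spatial pattern as the basal feedforward maps.  The Hebbian update
// (reinforcement gated by post-synaptic activity, plus an activity-
// independent forgetting term toward the basal map) runs every step.
//
// Performance notes:
//  - The lateral Mexican hat is a difference of two Gaussians, each
//    separable, so the 2-D convolution is computed as G * Z * G with
//    symmetric 1-D factor matrices (zero padding implicit).  Sheets whose
//    activity is numerically at rest skip the convolution entirely.
//  - The logistic activation is evaluated in a band |r (q - theta)| < 30;
//    outside it the saturations are exact to double precision.
//  - The moving Gaussian stimulus is built from separable depth/lateral
//    factors.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static inline void act_into(arma::mat& z, const arma::mat& q, double fmin,
                            double fmax, double theta, double r) {
  const double span = fmax - fmin;
  const arma::uword n = q.n_elem;
  const double* qp = q.memptr();
  double* zp = z.memptr();
  for (arma::uword i = 0; i < n; ++i) {
    double x = r * (qp[i] - theta);
    if (x > 30.0)        zp[i] = fmax;
    else if (x < -13.8)  zp[i] = fmin;   // truncated tail (error < 1e-6)
    else                 zp[i] = fmin + span / (1.0 + std::exp(-x));
  }
}

static inline double act_sca(double q, double fmin, double fmax,
                             double theta, double r) {
  double x = r * (q - theta);
  if (x > 30.0) return fmax;
  if (x < -13.8) return fmin;   // truncated tail (error < 1e-6)
  return fmin + (fmax - fmin) / (1.0 + std::exp(-x));
}

// Mexican-hat lateral input, restricted to the bounding box of active
// pre-synaptic elements (the factor matrices stay full, so the input
// spreads beyond the box as the kernel dictates)
static void lateral_into(arma::mat& u, const arma::mat& z,
                         const arma::mat& Gex, const arma::mat& Gin,
                         double lex, double lin, double quiet) {
  const arma::uword n = z.n_rows;
  arma::uword r1 = n, r2 = 0, c1 = n, c2 = 0;
  const double* zp = z.memptr();
  for (arma::uword j = 0; j < n; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      if (zp[j * n + i] > quiet) {
        if (i < r1) r1 = i;
        if (i > r2) r2 = i;
        if (j < c1) c1 = j;
        if (j > c2) c2 = j;
      }
    }
  }
  if (r1 > r2) { u.zeros(); return; }
  arma::mat Zs = z.submat(r1, c1, r2, c2);
  u = lex * (Gex.cols(r1, r2) * Zs * Gex.rows(c1, c2)) -
      lin * (Gin.cols(r1, r2) * Zs * Gin.rows(c1, c2));
}

// [[Rcpp::export]]
List cpp_run_block(List state, List par, List stim, int n_steps) {
  // --- state ---
  arma::mat q_t = as<arma::mat>(state["q_t"]);
  arma::mat q_v = as<arma::mat>(state["q_v"]);
  double q_m = as<double>(state["q_m"]);
  arma::mat W_t = as<arma::mat>(state["W_t"]);
  arma::mat W_v = as<arma::mat>(state["W_v"]);

  // --- fixed parameters ---
  const double dt = as<double>(par["dt"]);
  const double tau_t = as<double>(par["tau_t"]);
  const double tau_v = as<double>(par["tau_v"]);
  const double tau_m = as<double>(par["tau_m"]);
  const arma::vec fmin = as<arma::vec>(par["f_min"]);   // t, v, m
  const arma::vec fmax = as<arma::vec>(par["f_max"]);
  const arma::vec theta = as<arma::vec>(par["theta"]);
  const arma::vec slope = as<arma::vec>(par["r"]);
  const arma::mat Gex = as<arma::mat>(par["Gex"]);
  const arma::mat Gin = as<arma::mat>(par["Gin"]);
  const double lex = as<double>(par["lex"]);
  const double lin = as<double>(par["lin"]);
  const arma::mat B_t = as<arma::mat>(par["B_t"]);
  const arma::mat B_v = as<arma::mat>(par["B_v"]);
  const arma::mat W0_t = as<arma::mat>(par["W0_t"]);
  const arma::mat W0_v = as<arma::mat>(par["W0_v"]);
  const double Wmax_t = as<double>(par["Wmax_t"]);
  const double Wmax_v = as<double>(par["Wmax_v"]);
  const double rho0_t = as<double>(par["rho0_t"]);
  const double rho0_v = as<double>(par["rho0_v"]);
  const double gate_abs = as<double>(par["gate_abs"]);  // theta_gate * f_max^m
  const double k_h = as<double>(par["k_h"]);            // per step
  const bool learn = as<bool>(par["learn"]);
  const arma::mat X_t = as<arma::mat>(par["X_t"]);
  const arma::mat Y_t = as<arma::mat>(par["Y_t"]);

  // visual grid axes (depth varies along rows, lateral along columns)
  const arma::mat D_v = as<arma::mat>(par["D_v"]);
  const arma::mat L_v = as<arma::mat>(par["L_v"]);
  const arma::vec depth_ax = D_v.col(0);
  const arma::rowvec lat_ax = L_v.row(0);

  // --- stimulus description (step indices are 0-based within the block) ---
  const int tact_on  = as<int>(stim["tact_on"]);
  const int tact_off = as<int>(stim["tact_off"]);
  const double tact_amp = as<double>(stim["tact_amp"]);
  const double tact_sigma = as<double>(stim["tact_sigma"]);
  const double tact_x = as<double>(stim["tact_x"]);
  const double tact_y = as<double>(stim["tact_y"]);
  const int vis_on  = as<int>(stim["vis_on"]);
  const int vis_off = as<int>(stim["vis_off"]);
  const double vis_amp = as<double>(stim["vis_amp"]);
  const double vis_sigma = as<double>(stim["vis_sigma"]);
  const double vis_depth0 = as<double>(stim["vis_depth0"]);   // cm at vis_on
  const double vis_vel = as<double>(stim["vis_vel"]);          // cm/s
  const double vis_lat = as<double>(stim["vis_lat"]);

  // optional constant external input maps (added on top of stimuli)
  arma::mat e_t_ext, e_v_ext;
  bool has_ext_t = false, has_ext_v = false;
  if (!Rf_isNull(stim["e_t_ext"])) { e_t_ext = as<arma::mat>(stim["e_t_ext"]); has_ext_t = true; }
  if (!Rf_isNull(stim["e_v_ext"])) { e_v_ext = as<arma::mat>(stim["e_v_ext"]); has_ext_v = true; }

  // static tactile input map
  arma::mat e_t_map;
  if (tact_on >= 0 && tact_amp > 0.0) {
    e_t_map = tact_amp * arma::exp(-(arma::square(X_t - tact_x) +
                                     arma::square(Y_t - tact_y)) /
                                   (2.0 * tact_sigma * tact_sigma));
  }
  // constant lateral factor of the visual stimulus
  arma::rowvec vis_latfac = arma::exp(-arma::square(lat_ax - vis_lat) /
                                      (2.0 * vis_sigma * vis_sigma));
  arma::vec vis_depthfac(depth_ax.n_elem, arma::fill::zeros);

  const arma::uword n = q_t.n_rows;
  arma::mat z_t(n, n), z_v(n, n);
  act_into(z_t, q_t, fmin(0), fmax(0), theta(0), slope(0));
  act_into(z_v, q_v, fmin(1), fmax(1), theta(1), slope(1));
  double z_m = act_sca(q_m, fmin(2), fmax(2), theta(2), slope(2));

  arma::vec sum_zt(n_steps, arma::fill::zeros);
  arma::vec zm_trace(n_steps, arma::fill::zeros);

  const double a_t = dt / tau_t, a_v = dt / tau_v, a_m = dt / tau_m;
  const double quiet = 1e-13;   // elements treated as at-rest below this

  arma::mat u_t(n, n), u_v(n, n);

  for (int s = 0; s < n_steps; ++s) {
    // lateral input, restricted to the active bounding box of each sheet
    lateral_into(u_t, z_t, Gex, Gin, lex, lin, quiet);
    lateral_into(u_v, z_v, Gex, Gin, lex, lin, quiet);

    // feedback from the multisensory unit
    if (z_m > quiet) {
      u_t += B_t * z_m;
      u_v += B_v * z_m;
    }
    if (has_ext_t) u_t += e_t_ext;
    if (has_ext_v) u_v += e_v_ext;
    if (tact_on >= 0 && s >= tact_on && s < tact_off) u_t += e_t_map;
    if (vis_on >= 0 && s >= vis_on && s < vis_off) {
      double pos = vis_depth0 - vis_vel * (s - vis_on) * dt / 1000.0;
      if (pos >= 0.0) {   // the stimulus vanishes at contact
        for (arma::uword i = 0; i < vis_depthfac.n_elem; ++i) {
          double d2 = (depth_ax(i) - pos) * (depth_ax(i) - pos) /
                      (2.0 * vis_sigma * vis_sigma);
          vis_depthfac(i) = d2 > 30.0 ? 0.0 : vis_amp * std::exp(-d2);
        }
        u_v += vis_depthfac * vis_latfac;
      }
    }
    double u_m = arma::accu(W_t % z_t) + arma::accu(W_v % z_v);

    // Euler step of the first-order membrane dynamics
    q_t += a_t * (u_t - q_t);
    q_v += a_v * (u_v - q_v);
    q_m += a_m * (u_m - q_m);

    act_into(z_t, q_t, fmin(0), fmax(0), theta(0), slope(0));
    act_into(z_v, q_v, fmin(1), fmax(1), theta(1), slope(1));
    z_m = act_sca(q_m, fmin(2), fmax(2), theta(2), slope(2));

    // Hebbian update: gated reinforcement + activity-independent
    // forgetting, both terms evaluated on the pre-update weights
    if (learn) {
      double gate = z_m - gate_abs;
      if (gate > 0.0 && z_t.max() > quiet) {
        arma::mat dW = (rho0_t * gate) * ((Wmax_t - W_t) % z_t) -
                       k_h * (W_t - W0_t);
        W_t += dW;
        W_t.clamp(0.0, Wmax_t);
      } else if (k_h > 0.0) {
        W_t -= k_h * (W_t - W0_t);
      }
      if (gate > 0.0 && z_v.max() > quiet) {
        arma::mat dW = (rho0_v * gate) * ((Wmax_v - W_v) % z_v) -
                       k_h * (W_v - W0_v);
        W_v += dW;
        W_v.clamp(0.0, Wmax_v);
      } else if (k_h > 0.0) {
        W_v -= k_h * (W_v - W0_v);
      }
    }

    sum_zt(s) = arma::accu(z_t);
    zm_trace(s) = z_m;
  }

  return List::create(
    _["q_t"] = q_t, _["q_v"] = q_v, _["q_m"] = q_m,
    _["W_t"] = W_t, _["W_v"] = W_v,
    _["sum_zt"] = sum_zt, _["zm"] = zm_trace);
}
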