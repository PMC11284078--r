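// Euler-Maruyama integrator for the ring attractor with short-term plasticity.
//
// State per step: h_e (N synaptic inputs on the ring), h_i (global inhibitory
// pool), u (release probability), x (available transmitter fraction).
// The update implements
//   tau dh_e = [-h_e + rho*(pi/N) sum_k J(.,k) u_k x_k r_k - J_EI r_I
//               + I_ext + I0] dt + sigma0 sqrt(dt) eta
//   tau dh_i = [-h_i + J_IE*(pi/N) sum_k r_k] dt
//   du       = [-u/tau_f + U0 (1-u) r] dt
//   dx       = [(1-x)/tau_d - u x r] dt
// with r = alpha*log(1+exp(h/alpha)) and u, x clipped to [0,1] after each
// step.  External input intervals are piecewise-constant stimulus specs
// (amplitude, sharpness, center, per-step Gaussian pixel noise), evaluated as
// a truncated cosine on the wrapped orientation difference (period pi);
// overlapping intervals sum.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double softplus1(double h, double alpha) {
  double z = h / alpha;
  if (z > 30.0) return alpha * z;
  if (z < -30.0) return alpha * std::exp(z);
  return alpha * std::log1p(std::exp(z));
}

static inline arma::vec softplus(const arma::vec& h, double alpha) {
  arma::vec r(h.n_elem);
  for (arma::uword i = 0; i < h.n_elem; ++i) r[i] = softplus1(h[i], alpha);
  return r;
}

// wrapped orientation difference, period pi, mapped to [-pi/2, pi/2)
static inline double wrap_pi(double d) {
  double w = d - M_PI * std::floor(d / M_PI + 0.5);
  if (w >= M_PI / 2.0) w -= M_PI;  // guard the upper edge
  return w;
}

// [[Rcpp::export]]
List cpp_run_network(arma::vec h_e, double h_i, arma::vec u, arma::vec x,
                     double t0, const arma::mat& conn, const arma::vec& thetas,
                     List params, const arma::mat& schedule, double duration,
                     int record_stride, int group_stride,
                     const arma::mat& group_mask, const arma::vec& snapshot_times,
                     double decode_t0, double decode_t1, double seed) {
  const int n = h_e.n_elem;
  const double tau = params["tau"], rho = params["rho"], j_ei = params["j_ei"],
               j_ie = params["j_ie"], alpha = params["alpha"], i0 = params["i0"],
               sigma0 = params["sigma0"], tau_f = params["tau_f"],
               tau_d = params["tau_d"], u_inc = params["u_increment"],
               dt = params["dt"];
  const double wsum = M_PI / static_cast<double>(n);
  const double noise_scale = sigma0 * std::sqrt(dt) / tau;
  const long n_steps = static_cast<long>(std::llround(duration / dt));

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // precompute stimulus spatial profiles (one row per schedule interval)
  const int n_iv = schedule.n_rows;
  arma::mat profiles(n_iv, n, arma::fill::zeros);
  arma::vec iv_noise(n_iv, arma::fill::zeros);
  for (int j = 0; j < n_iv; ++j) {
    double amp = schedule(j, 2), sharp = schedule(j, 3), cen = schedule(j, 4);
    iv_noise[j] = schedule(j, 5);
    if (amp != 0.0) {
      for (int k = 0; k < n; ++k) {
        double arg = sharp * wrap_pi(thetas[k] - cen);
        if (arg >= -M_PI / 2.0 && arg <= M_PI / 2.0)
          profiles(j, k) = amp * std::cos(arg);
      }
    }
  }

  const int n_groups = group_mask.n_rows;
  arma::vec group_size(n_groups, arma::fill::zeros);
  for (int g = 0; g < n_groups; ++g) group_size[g] = arma::accu(group_mask.row(g));

  // recording buffers
  long n_rec = (record_stride > 0) ? n_steps / record_stride + 1 : 0;
  long n_grec = (group_stride > 0 && n_groups > 0) ? n_steps / group_stride + 1 : 0;
  arma::mat rec_he(n_rec, n), rec_re(n_rec, n), rec_u(n_rec, n), rec_x(n_rec, n);
  arma::vec rec_hi(n_rec), rec_t(n_rec);
  arma::mat grec_r(n_grec, n_groups), grec_ux(n_grec, n_groups);
  arma::vec grec_t(n_grec);
  long i_rec = 0, i_grec = 0;

  const int n_snap = snapshot_times.n_elem;
  arma::mat snap_u(n_snap, n, arma::fill::zeros), snap_x(n_snap, n, arma::fill::zeros);
  std::vector<long> snap_step(n_snap);
  for (int s = 0; s < n_snap; ++s)
    snap_step[s] = static_cast<long>(std::llround((snapshot_times[s] - t0) / dt));

  arma::vec decode_sum(n, arma::fill::zeros);
  long decode_count = 0;

  arma::vec r_e(n), eff(n), I_ext(n);

  auto record_full = [&](double t) {
    rec_t[i_rec] = t; rec_hi[i_rec] = h_i;
    rec_he.row(i_rec) = h_e.t();
    rec_re.row(i_rec) = softplus(h_e, alpha).t();
    rec_u.row(i_rec) = u.t(); rec_x.row(i_rec) = x.t();
    ++i_rec;
  };
  auto record_group = [&](double t) {
    grec_t[i_grec] = t;
    arma::vec re = softplus(h_e, alpha);
    arma::vec ux = u % x;
    for (int g = 0; g < n_groups; ++g) {
      grec_r(i_grec, g) = arma::dot(group_mask.row(g), re) / group_size[g];
      grec_ux(i_grec, g) = arma::dot(group_mask.row(g), ux) / group_size[g];
    }
    ++i_grec;
  };
  auto take_snaps = [&](long step) {
    for (int s = 0; s < n_snap; ++s)
      if (snap_step[s] == step) { snap_u.row(s) = u.t(); snap_x.row(s) = x.t(); }
  };

  if (record_stride > 0) record_full(t0);
  if (group_stride > 0 && n_groups > 0) record_group(t0);
  take_snaps(0);

  double t = t0;
  for (long i = 0; i < n_steps; ++i) {
    r_e = softplus(h_e, alpha);
    double r_i = softplus1(h_i, alpha);
    eff = u % x % r_e;
    arma::vec rec_cur = conn * eff * (wsum * rho);

    // sum all active stimulus intervals (they may overlap)
    I_ext.zeros();
    for (int j = 0; j < n_iv; ++j) {
      if (t >= schedule(j, 0) - dt * 0.5 && t < schedule(j, 1) - dt * 0.5) {
        I_ext += profiles.row(j).t();
        if (iv_noise[j] > 0.0)
          for (int k = 0; k < n; ++k) I_ext[k] += iv_noise[j] * gauss(rng);
      }
    }

    arma::vec dh = (dt / tau) * (-h_e + rec_cur - j_ei * r_i + I_ext + i0);
    if (noise_scale > 0.0)
      for (int k = 0; k < n; ++k) dh[k] += noise_scale * gauss(rng);
    double dhi = (dt / tau) * (-h_i + j_ie * wsum * arma::accu(r_e));
    arma::vec du = dt * (-u / tau_f + u_inc * (1.0 - u) % r_e);
    arma::vec dx = dt * ((1.0 - x) / tau_d - u % x % r_e);

    h_e += dh; h_i += dhi;
    u = arma::clamp(u + du, 0.0, 1.0);
    x = arma::clamp(x + dx, 0.0, 1.0);
    t = t0 + (i + 1) * dt;

    if (decode_t1 > decode_t0 && t >= decode_t0 && t <= decode_t1 + dt * 0.5) {
      decode_sum += softplus(h_e, alpha);
      ++decode_count;
    }
    if (record_stride > 0 && (i + 1) % record_stride == 0) record_full(t);
    if (group_stride > 0 && n_groups > 0 && (i + 1) % group_stride == 0) record_group(t);
    take_snaps(i + 1);

    if ((i & 511) == 0 || i == n_steps - 1) {
      if (!h_e.is_finite() || !std::isfinite(h_i))
        stop("network integration blew up at t = %f (max |h_E| = %f)", t,
             h_e.is_finite() ? arma::abs(h_e).max() : R_PosInf);
    }
  }

  List out = List::create(
      _["h_e"] = h_e, _["h_i"] = h_i, _["u"] = u, _["x"] = x, _["t"] = t);
  if (record_stride > 0)
    out["trace"] = List::create(_["t"] = rec_t, _["h_e"] = rec_he,
                                _["r_e"] = rec_re, _["u"] = rec_u,
                                _["x"] = rec_x, _["h_i"] = rec_hi);
  if (group_stride > 0 && n_groups > 0)
    out["group_trace"] = List::create(_["t"] = grec_t, _["r"] = grec_r,
                                      _["ux"] = grec_ux);
  if (n_snap > 0)
    out["snapshots"] = List::create(_["t"] = snapshot_times, _["u"] = snap_u,
                                    _["x"] = snap_x);
  if (decode_t1 > decode_t0)
    out["decode_profile"] = (decode_count > 0)
                                ? arma::vec(decode_sum / decode_count)
                                : arma::vec(n, arma::fill::zeros);
  return out;
}
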