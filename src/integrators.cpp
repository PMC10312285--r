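#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled Stuart-Landau network in
// Cartesian coordinates:
//   dx_i = [a_i x_i - (x_i^2+y_i^2) x_i - w_i y_i + G sum_j C_ij (x_j - x_i)] dt + nu dW
//   dy_i = [a_i y_i - (x_i^2+y_i^2) y_i + w_i x_i + G sum_j C_ij (y_j - y_i)] dt + nu dW
// The transient is discarded and x is kept every `stride` steps.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_hopf(NumericVector a, NumericVector omega,
                                NumericMatrix C, double G, double nu,
                                double dt, int n_steps, int n_transient,
                                int stride, NumericVector x0,
                                NumericVector y0) {
  const int N = a.size();
  std::vector<double> Cf(C.begin(), C.end());  // column-major flat copy
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> rowsum(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) rowsum[i] += Cf[i + N * j];

  const int n_keep = (n_steps - n_transient) / stride;
  NumericMatrix out(N, n_keep);
  const double sq = std::sqrt(dt);
  int kept = 0;

  std::vector<double> cx(N), cy(N), xn(N), yn(N);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < N; ++i) {
      double sx = 0.0, sy = 0.0;
      for (int j = 0; j < N; ++j) {
        sx += Cf[i + N * j] * x[j];
        sy += Cf[i + N * j] * y[j];
      }
      cx[i] = G * (sx - rowsum[i] * x[i]);
      cy[i] = G * (sy - rowsum[i] * y[i]);
    }
    for (int i = 0; i < N; ++i) {
      const double r2 = x[i] * x[i] + y[i] * y[i];
      xn[i] = x[i] + dt * ((a[i] - r2) * x[i] - omega[i] * y[i] + cx[i]);
      yn[i] = y[i] + dt * ((a[i] - r2) * y[i] + omega[i] * x[i] + cy[i]);
      if (nu > 0.0) {
        xn[i] += sq * nu * norm_rand();
        yn[i] += sq * nu * norm_rand();
      }
      if (!std::isfinite(xn[i]) || std::fabs(xn[i]) > 1e6)
        stop("Stuart-Landau integration diverged (|z| > 1e6); reduce dt (dt = %g)", dt);
    }
    x.swap(xn);
    y.swap(yn);
    if (t >= n_transient && (t - n_transient) % stride == 0 && kept < n_keep) {
      for (int i = 0; i < N; ++i) out(i, kept) = x[i];
      ++kept;
    }
  }
  return out;
}

// Nondimensional exact mean-field (firing-rate) whole-brain network: per
// region an excitatory and an inhibitory QIF population,
//   re' = de/pi + 2 re ve
//   ve' = ve^2 + eta - (pi re)^2 + jee re + jei ri + G jee sum_p C_np re_p
//   ri' = di/pi + 2 ri vi
//   vi' = vi^2 + 1 - (pi ri)^2 + jii ri + jie re
// with optional additive Gaussian noise on the voltage equations.
// Returns the excitatory rate, transient discarded, kept every `stride` steps.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_fre(NumericVector de, NumericVector di,
                               double eta, double jee, double jei,
                               double jie, double jii, double G,
                               NumericMatrix C, double noise_v, double dt,
                               int n_steps, int n_transient, int stride,
                               NumericVector re0, NumericVector ve0,
                               NumericVector ri0, NumericVector vi0) {
  const int N = de.size();
  const double pi = M_PI;
  std::vector<double> Cf(C.begin(), C.end());
  std::vector<double> re(re0.begin(), re0.end()), ve(ve0.begin(), ve0.end());
  std::vector<double> ri(ri0.begin(), ri0.end()), vi(vi0.begin(), vi0.end());

  const int n_keep = (n_steps - n_transient) / stride;
  NumericMatrix out(N, n_keep);
  const double sq = std::sqrt(dt);
  int kept = 0;

  std::vector<double> coup(N);
  for (int t = 0; t < n_steps; ++t) {
    if (G != 0.0) {
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j) s += Cf[i + N * j] * re[j];
        coup[i] = G * jee * s;
      }
    } else {
      std::fill(coup.begin(), coup.end(), 0.0);
    }
    for (int i = 0; i < N; ++i) {
      const double dre = de[i] / pi + 2.0 * re[i] * ve[i];
      const double dve = ve[i] * ve[i] + eta - pi * pi * re[i] * re[i] +
                         jee * re[i] + jei * ri[i] + coup[i];
      const double dri = di[i] / pi + 2.0 * ri[i] * vi[i];
      const double dvi = vi[i] * vi[i] + 1.0 - pi * pi * ri[i] * ri[i] +
                         jii * ri[i] + jie * re[i];
      re[i] += dt * dre;
      ve[i] += dt * dve;
      ri[i] += dt * dri;
      vi[i] += dt * dvi;
      if (noise_v > 0.0) {
        ve[i] += sq * noise_v * norm_rand();
        vi[i] += sq * noise_v * norm_rand();
      }
      if (re[i] < 0.0) re[i] = 0.0;  // rates are nonnegative
      if (ri[i] < 0.0) ri[i] = 0.0;
      if (!std::isfinite(ve[i]) || std::fabs(ve[i]) > 1e8)
        stop("mean-field integration diverged; reduce dt (dt = %g)", dt);
    }
    if (t >= n_transient && (t - n_transient) % stride == 0 && kept < n_keep) {
      for (int i = 0; i < N; ++i) out(i, kept) = re[i];
      ++kept;
    }
  }
  return out;
}

// Microscopic QIF population with all-to-all recurrent coupling:
//   tau_m dV_k/dt = V_k^2 + eta_k + J tau_m R(t)
// with spike-and-reset at +-v_peak. The instantaneous population rate is the
// spike count per step / (n dt). Returns per-step rate and mean voltage.
// [[Rcpp::export]]
List cpp_simulate_qif(NumericVector eta, double J, double tau_m,
                      double v_peak, double dt, int n_steps,
                      NumericVector v0) {
  const int n = eta.size();
  std::vector<double> v(v0.begin(), v0.end());
  NumericVector rate(n_steps), vmean(n_steps);
  double R = 0.0;  // rate from previous step's spikes

  for (int t = 0; t < n_steps; ++t) {
    int spikes = 0;
    double vsum = 0.0;
    const double drive = J * tau_m * R;
    for (int k = 0; k < n; ++k) {
      v[k] += dt / tau_m * (v[k] * v[k] + eta[k] + drive);
      if (v[k] >= v_peak) {
        v[k] = -v_peak;
        ++spikes;
      }
      vsum += v[k];
    }
    R = spikes / (n * dt);
    rate[t] = R;
    vmean[t] = vsum / n;
  }
  return List::create(_["rate"] = rate, _["v_mean"] = vmean);
}

// Balloon-Windkessel hemodynamic transform. Per region, driven by the neural
// input z(t) (columns of `z` sampled at dt):
//   ds/dt = z - kappa s - gamma (f - 1)
//   df/dt = s
//   tau dv/dt = f - v^(1/alpha)
//   tau dq/dt = f E(f)/rho - v^(1/alpha) q / v,  E(f) = 1 - (1-rho)^(1/f)
//   BOLD = V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v))
// [[Rcpp::export]]
NumericMatrix cpp_balloon_windkessel(NumericMatrix z, double dt, double kappa,
                                     double gamma, double tau, double alpha,
                                     double rho, double V0) {
  const int N = z.nrow(), T = z.ncol();
  std::vector<double> zf(z.begin(), z.end());
  NumericMatrix bold(N, T);
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ialpha = 1.0 / alpha;

  for (int i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      const double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      const double fv = std::pow(v, ialpha);
      const double ds = zf[i + (size_t)N * t] - kappa * s - gamma * (f - 1.0);
      const double df = s;
      const double dv = (f - fv) / tau;
      const double dq = (f * E / rho - fv * q / v) / tau;
      s += dt * ds;
      f += dt * df;
      v += dt * dv;
      q += dt * dq;
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      if (q < 1e-6) q = 1e-6;
      if (!std::isfinite(s) || std::fabs(s) > 1e8)
        stop("hemodynamic integration diverged; reduce dt (dt = %g)", dt);
      bold(i, t) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return bold;
}
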