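#include <Rcpp.h>
using namespace Rcpp;

// Trajectory integrator for the coupled mass-fraction / growth-rate model.
//
// State: proteome mass fractions phi_i and one Ornstein-Uhlenbeck state per
// noise source (one private source per protein plus optional shared sources).
// Per step:
//   mu_d  <- growth function evaluated on phi / sum(phi)   (intensive)
//   pi_i  <- f_i * mu_d + N_i + sum_k w_{k,i} * N_k(shared)
//   mu    <- mu_d + sum(all N)        (equals sum(pi) identically)
//   phi   <- phi + dt * (pi - mu * phi)          (Euler)
//   phi   <- phi / sum(phi)                      (optional simplex projection)
//   N     <- N * exp(-beta dt) + Normal(0, theta^2 (1 - e^{-2 beta dt})/(2 beta))
// The OU update is the exact Gaussian transition, so the noise driver carries
// no discretization bias; only the phi update is first order.
//
// All randomness flows through R's RNG (RNGScope), so set.seed() in R makes
// runs bit-reproducible. Draw order: private states (protein order), then
// shared states, at initialization and within every step.

static double growth_eval(int type, const std::vector<double>& phi, double S,
                          const NumericVector& f, const NumericVector& gcc, double mu0,
                          double mu_max, double phi_half, const IntegerVector& target) {
  if (type == 1) { // Monod on the summed target fraction
    double phiO = 0.0;
    for (int k = 0; k < target.size(); ++k) phiO += phi[target[k]];
    phiO /= S;
    return mu_max * phiO / (phi_half + phiO);
  }
  // linearized growth: mu_d = mu0 * (1 + sum_i gcc_i * (phi_i/S - f_i) / f_i)
  double acc = 0.0;
  for (int i = 0; i < f.size(); ++i)
    if (gcc[i] != 0.0) acc += gcc[i] * (phi[i] / S - f[i]) / f[i];
  return mu0 * (1.0 + acc);
}

// [[Rcpp::export]]
List gn_simulate_cpp(NumericVector f, NumericVector theta_p, NumericVector beta_p,
                     List shared_src,
                     int growth_type, NumericVector gcc, double mu0,
                     double mu_max, double phi_half, IntegerVector target,
                     double duration, double dt, double burn_in,
                     int record_stride, IntegerVector record_idx,
                     bool record_noise, bool renormalize,
                     NumericVector phi_floor) {
  const int np = f.size();
  const int nsh = shared_src.size();
  const long n_steps = (long)std::llround(duration / dt);
  const long burn_steps = (long)std::llround(burn_in / dt);
  if (burn_steps >= n_steps) stop("duration must exceed burn_in");
  const long nrec = (n_steps - burn_steps) / record_stride + 1;
  const int nri = record_idx.size();

  // shared-source wiring, unpacked
  std::vector<double> sh_theta(nsh), sh_beta(nsh);
  std::vector<std::vector<int>> sh_idx(nsh);
  std::vector<std::vector<double>> sh_w(nsh);
  for (int k = 0; k < nsh; ++k) {
    List s = shared_src[k];
    sh_theta[k] = as<double>(s["theta"]);
    sh_beta[k]  = as<double>(s["beta"]);
    IntegerVector ii = s["idx"];
    NumericVector ww = s["w"];
    sh_idx[k] = std::vector<int>(ii.begin(), ii.end());
    sh_w[k]   = std::vector<double>(ww.begin(), ww.end());
  }

  // exact OU transition coefficients
  std::vector<double> dec_p(np), sdq_p(np), Np(np);
  for (int i = 0; i < np; ++i) {
    dec_p[i] = std::exp(-beta_p[i] * dt);
    double V = theta_p[i] * theta_p[i] / (2.0 * beta_p[i]);
    sdq_p[i] = std::sqrt(V * (1.0 - dec_p[i] * dec_p[i]));
  }
  std::vector<double> dec_s(nsh), sdq_s(nsh), Ns(nsh);
  for (int k = 0; k < nsh; ++k) {
    dec_s[k] = std::exp(-sh_beta[k] * dt);
    double V = sh_theta[k] * sh_theta[k] / (2.0 * sh_beta[k]);
    sdq_s[k] = std::sqrt(V * (1.0 - dec_s[k] * dec_s[k]));
  }

  RNGScope rng;
  // stationary initial draw
  for (int i = 0; i < np; ++i)
    Np[i] = theta_p[i] > 0 ? R::rnorm(0.0, theta_p[i] / std::sqrt(2.0 * beta_p[i])) : 0.0;
  for (int k = 0; k < nsh; ++k)
    Ns[k] = sh_theta[k] > 0 ? R::rnorm(0.0, sh_theta[k] / std::sqrt(2.0 * sh_beta[k])) : 0.0;

  std::vector<double> phi(f.begin(), f.end()), pi(np);

  const int n_noise_rec = record_noise ? (nri + nsh) : 0;
  NumericVector t_rec(nrec), mu_rec(nrec);
  NumericMatrix phi_rec(nrec, nri), pi_rec(nrec, nri);
  NumericMatrix noise_rec(record_noise ? nrec : 0, n_noise_rec);

  double max_drift = 0.0;
  long irec = 0;

  for (long s = 0; s <= n_steps; ++s) {
    double S = 0.0;
    for (int i = 0; i < np; ++i) S += phi[i];
    if (S <= 0.0) stop("total mass fraction became non-positive at t = %g h", s * dt);

    double mu_d = growth_eval(growth_type, phi, S, f, gcc, mu0, mu_max, phi_half, target);
    if (!std::isfinite(mu_d)) stop("non-finite growth rate at t = %g h", s * dt);

    double sumN = 0.0;
    for (int i = 0; i < np; ++i) { pi[i] = f[i] * mu_d + Np[i]; sumN += Np[i]; }
    for (int k = 0; k < nsh; ++k) {
      sumN += Ns[k];
      for (size_t m = 0; m < sh_idx[k].size(); ++m)
        pi[sh_idx[k][m]] += sh_w[k][m] * Ns[k];
    }
    double mu = mu_d + sumN;

    if (s >= burn_steps && (s - burn_steps) % record_stride == 0 && irec < nrec) {
      t_rec[irec] = s * dt;
      mu_rec[irec] = mu;
      for (int j = 0; j < nri; ++j) {
        phi_rec(irec, j) = phi[record_idx[j]];
        pi_rec(irec, j)  = pi[record_idx[j]];
      }
      if (record_noise) {
        for (int j = 0; j < nri; ++j) noise_rec(irec, j) = Np[record_idx[j]];
        for (int k = 0; k < nsh; ++k) noise_rec(irec, nri + k) = Ns[k];
      }
      ++irec;
    }
    if (s == n_steps) break;

    // Euler step on phi, then simplex projection
    double Snew = 0.0;
    for (int i = 0; i < np; ++i) {
      phi[i] += dt * (pi[i] - mu * phi[i]);
      Snew += phi[i];
    }
    if (s >= burn_steps) {
      double drift = std::fabs(Snew - 1.0);
      if (drift > max_drift) max_drift = drift;
    }
    if (renormalize) {
      if (Snew <= 0.0) stop("total mass fraction became non-positive at t = %g h", (s + 1) * dt);
      for (int i = 0; i < np; ++i) phi[i] /= Snew;
    }
    for (int i = 0; i < np; ++i) {
      if (phi[i] < phi_floor[i])
        stop("mass fraction %d fell below -10 stationary SD at t = %g h; "
             "the small-noise regime is violated (reduce dt or noise amplitudes)",
             i + 1, (s + 1) * dt);
    }

    // exact OU advance
    for (int i = 0; i < np; ++i)
      Np[i] = Np[i] * dec_p[i] + (sdq_p[i] > 0 ? R::rnorm(0.0, sdq_p[i]) : 0.0);
    for (int k = 0; k < nsh; ++k)
      Ns[k] = Ns[k] * dec_s[k] + (sdq_s[k] > 0 ? R::rnorm(0.0, sdq_s[k]) : 0.0);
  }

  return List::create(_["t"] = t_rec, _["mu"] = mu_rec, _["phi"] = phi_rec,
                      _["pi"] = pi_rec, _["noise"] = noise_rec,
                      _["max_drift"] = max_drift);
}

// Pearson cross-correlation r(tau) = corr(x(t), y(t + tau)) on an evenly
// sampled grid, with the standard ccf convention: deviations from the global
// means, denominator n * sd_x * sd_y (population sds). Standard errors by
// circular block bootstrap: the paired series is resampled in contiguous
// circularly-wrapped blocks and the whole statistic is recomputed.

static void ccf_at_lags(const std::vector<double>& x, const std::vector<double>& y,
                        const IntegerVector& lags, std::vector<double>& out) {
  const long n = (long)x.size();
  double mx = 0, my = 0;
  for (long t = 0; t < n; ++t) { mx += x[t]; my += y[t]; }
  mx /= n; my /= n;
  double vx = 0, vy = 0;
  for (long t = 0; t < n; ++t) {
    vx += (x[t] - mx) * (x[t] - mx);
    vy += (y[t] - my) * (y[t] - my);
  }
  double denom = std::sqrt(vx * vy); // = n * sd_x * sd_y with population sds
  if (denom <= 0.0) stop("undefined correlation: at least one signal is constant");
  for (int j = 0; j < lags.size(); ++j) {
    const int L = lags[j];
    double acc = 0.0;
    const long lo = L >= 0 ? 0 : -(long)L;
    const long hi = L >= 0 ? n - L : n;
    for (long t = lo; t < hi; ++t) acc += (x[t] - mx) * (y[t + L] - my);
    out[j] = acc / denom;
  }
}

// [[Rcpp::export]]
List gn_xcorr_cpp(NumericVector x, NumericVector y, IntegerVector lags,
                  int block_len, int n_boot) {
  const long n = x.size();
  if (y.size() != n) stop("signals must have equal length");
  if (block_len < 1) block_len = 1;
  const int nl = lags.size();

  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<double> r(nl);
  ccf_at_lags(xv, yv, lags, r);

  NumericVector se(nl);
  if (n_boot > 0) {
    RNGScope rng;
    const long n_blocks = (n + block_len - 1) / block_len;
    std::vector<double> xb(n), yb(n), rb(nl);
    std::vector<double> acc(nl, 0.0), acc2(nl, 0.0);
    for (int b = 0; b < n_boot; ++b) {
      long pos = 0;
      for (long k = 0; k < n_blocks && pos < n; ++k) {
        long start = (long)std::floor(unif_rand() * n);
        if (start >= n) start = n - 1;
        for (int m = 0; m < block_len && pos < n; ++m, ++pos) {
          long idx = (start + m) % n;
          xb[pos] = xv[idx];
          yb[pos] = yv[idx];
        }
      }
      ccf_at_lags(xb, yb, lags, rb);
      for (int j = 0; j < nl; ++j) { acc[j] += rb[j]; acc2[j] += rb[j] * rb[j]; }
    }
    for (int j = 0; j < nl; ++j) {
      double m = acc[j] / n_boot;
      double v = acc2[j] / n_boot - m * m;
      se[j] = std::sqrt(std::max(v, 0.0) * n_boot / std::max(n_boot - 1, 1));
    }
  }
  return List::create(_["r"] = NumericVector(r.begin(), r.end()), _["se"] = se);
}

// Exact simulation of a single stationary OU path, recorded at every
// `record_stride`-th step after burn-in; used for driver-exactness checks.
// [[Rcpp::export]]
NumericVector gn_ou_path_cpp(double theta, double beta, double duration,
                             double dt, double burn_in, int record_stride) {
  const long n_steps = (long)std::llround(duration / dt);
  const long burn_steps = (long)std::llround(burn_in / dt);
  const long nrec = (n_steps - burn_steps) / record_stride + 1;
  const double dec = std::exp(-beta * dt);
  const double V = theta * theta / (2.0 * beta);
  const double sdq = std::sqrt(V * (1.0 - dec * dec));
  RNGScope rng;
  double N = theta > 0 ? R::rnorm(0.0, std::sqrt(V)) : 0.0;
  NumericVector out(nrec);
  long irec = 0;
  for (long s = 0; s <= n_steps; ++s) {
    if (s >= burn_steps && (s - burn_steps) % record_stride == 0 && irec < nrec)
      out[irec++] = N;
    if (s == n_steps) break;
    N = N * dec + (sdq > 0 ? R::rnorm(0.0, sdq) : 0.0);
  }
  return out;
}
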