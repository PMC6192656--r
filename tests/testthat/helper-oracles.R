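# Independent oracles and small fixture builders used across the suite.

# Time-domain quadrature oracle for the A-type correlator
# Cov(x(t + tau), N(t)) with x the response of dx/dt = -mu0 x + N:
# substituting x(t + tau) = int_0^inf e^{-mu0 u} N(t + tau - u) du and the OU
# autocovariance V e^{-beta |.|} gives a single absolutely convergent
# integral, evaluated here numerically.
oracle_A <- function(theta, beta, mu0, tau) {
  V <- theta^2 / (2 * beta)
  vapply(tau, function(tt) {
    stats::integrate(function(u) exp(-mu0 * u) * V * exp(-beta * abs(tt - u)),
                     0, Inf, rel.tol = 1e-12)$value
  }, 0)
}

# Wiener-Khinchin oracle for the S-type correlator: the OU spectral density
# theta^2/(beta^2 + w^2) through the squared filter gain 1/(mu0^2 + w^2),
# inverted by cosine transform.
oracle_S <- function(theta, beta, mu0, tau) {
  vapply(tau, function(tt) {
    stats::integrate(function(w)
      theta^2 * cos(w * tt) / ((beta^2 + w^2) * (mu0^2 + w^2)),
      0, Inf, rel.tol = 1e-12, subdivisions = 2000L)$value / pi
  }, 0)
}

# Hand evaluation of the stationary CV of the two-protein toy (private
# sources only): eta_Y^2 = (1-phi_Y)^2/phi_Y^2 * v_Y + v_X with
# v = Var(N)/(mu0 (mu0 + beta)). Written out independently of the package.
toy_cv_oracle <- function(f_Y = 0.33, theta = 0.5, beta = 4, mu0 = 1) {
  v <- (theta^2 / (2 * beta)) / (mu0 * (mu0 + beta))
  sqrt((1 - f_Y)^2 / f_Y^2 * v + v)
}

# A random private-source cell model with forward-computed (hence feasible)
# CV targets; used for round-trip properties.
random_feasible_model <- function(n = 4) {
  f <- rexp(n) + 0.2
  f <- f / sum(f)
  beta <- runif(n, 1, 8)
  theta <- runif(n, 0.05, 0.4)
  mu0 <- runif(1, 0.3, 1.5)
  ids <- paste0("p", seq_len(n))
  proteins <- data.frame(id = ids, f = f, theta = theta, beta = beta,
                         gcc = 0, nonmetabolic = FALSE,
                         operon = NA_character_, stringsAsFactors = FALSE)
  cell_model(proteins, mu0 = mu0)
}

# Batch-means standard error of a statistic computed on a long stationary
# series: split into n_seg contiguous segments, evaluate per segment, take
# sd/sqrt(n_seg).
batch_se <- function(x, stat, n_seg = 20) {
  n <- length(x)
  idx <- split(seq_len(n - n %% n_seg), rep(seq_len(n_seg),
                                            each = (n - n %% n_seg) / n_seg))
  vals <- vapply(idx, function(i) stat(x[i]), 0)
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n_seg))
}

# Dual-reporter fixture: two identical reporters R and G plus a noise-free
# bulk protein carrying the remaining mass; all GCCs zero.
dual_reporter_model <- function(phi_b = 0.05, theta_b = 0.5, beta_b = 4,
                                mu0 = 1, theta_bulk = 0, beta_bulk = 4) {
  proteins <- rbind(
    protein("R", f = phi_b, theta = theta_b, beta = beta_b, gcc = 0),
    protein("G", f = phi_b, theta = theta_b, beta = beta_b, gcc = 0),
    protein("bulk", f = 1 - 2 * phi_b, theta = theta_bulk, beta = beta_bulk,
            gcc = 0)
  )
  cell_model(proteins, mu0 = mu0)
}

# Lag grid scaled to a model's slowest timescale, for cross-condition
# comparisons of peak height and asymmetry.
scaled_tau <- function(mu0, width = 6, n = 241) {
  seq(-width / mu0, width / mu0, length.out = n)
}
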